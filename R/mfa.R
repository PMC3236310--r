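#' Assemble a metabolic flux analysis problem
#'
#' Pairs a network partition with a vector of measured fluxes and their
#' variances. Fluxes are in any consistent per-cell rate unit (e.g.
#' nmol/(1e6 cells * h)); variances are in that unit squared.
#'
#' @param net a [stoich_network()] with measured flags.
#' @param v_m named numeric vector of measured fluxes; names must cover the
#'   network's measured flux ids (order free).
#' @param sigma optional variance specification: a single number (common
#'   variance), a named vector of per-flux *standard deviations*, or a full
#'   variance matrix. When `NULL`, sd = `cv * |v_m|` with an absolute floor
#'   `sd_floor` so zero-valued measurements keep finite weight.
#' @param cv relative measurement error used for the default variance model
#'   (default 0.16, i.e. 16% error on measured exchange fluxes).
#' @param sd_floor absolute standard-deviation floor (measurement units).
#' @return list of class `mfa_problem`: `net`, `A_m`, `A_e`, `v_m`,
#'   `Sigma_m`, `measured_ids`, `unmeasured_ids`.
#' @export
mfa_problem <- function(net, v_m, sigma = NULL, cv = 0.16, sd_floor = 1e-6) {
  part <- partition_network(net)
  if (is.null(names(v_m))) {
    if (length(v_m) != length(part$measured_ids))
      stop("v_m length does not match the number of measured fluxes")
    names(v_m) <- part$measured_ids
  }
  missing <- setdiff(part$measured_ids, names(v_m))
  if (length(missing) > 0)
    stop("measured fluxes missing from v_m: ", paste(missing, collapse = ", "))
  v_m <- v_m[part$measured_ids]
  n <- length(v_m)
  if (is.null(sigma)) {
    sds <- pmax(cv * abs(v_m), sd_floor)
    Sigma <- diag(sds^2, n)
  } else if (is.matrix(sigma)) {
    Sigma <- sigma
  } else if (length(sigma) == 1) {
    Sigma <- diag(rep(as.numeric(sigma), n), n)
  } else {
    sds <- sigma[part$measured_ids]
    Sigma <- diag(as.numeric(sds)^2, n)
  }
  dimnames(Sigma) <- list(part$measured_ids, part$measured_ids)
  if (any(diag(Sigma) <= 0))
    stop("measurement variances must be strictly positive")
  structure(list(net = net, A_m = part$A_m, A_e = part$A_e, v_m = v_m,
                 Sigma_m = Sigma, measured_ids = part$measured_ids,
                 unmeasured_ids = part$unmeasured_ids),
            class = "mfa_problem")
}

check_Ae_rank <- function(A_e, tol = NULL) {
  if (ncol(A_e) == 0) return(invisible(TRUE))
  r <- matrix_rank(A_e, tol)
  if (r < ncol(A_e)) {
    s <- svd(A_e, nv = ncol(A_e))
    null_basis <- s$v[, (r + 1):ncol(A_e), drop = FALSE]
    combos <- apply(null_basis, 2, function(y) {
      big <- which(abs(y) > 0.1 * max(abs(y)))
      paste(sprintf("%+.3f*%s", y[big], colnames(A_e)[big]), collapse = " ")
    })
    stop("A_e is rank deficient; unidentifiable flux combination(s): ",
         paste(combos, collapse = " ; "))
  }
  invisible(TRUE)
}

#' Unweighted least-squares flux estimation
#'
#' Solves the steady-state balances `A_m v_m + A_e v_e = 0` for the
#' unmeasured fluxes: `v_e = -pinv(A_e) A_m v_m`. The residual is orthogonal
#' to the range of `A_e`.
#'
#' @param problem an [mfa_problem()].
#' @param v_m optional replacement measured-flux vector (same order).
#' @return named numeric vector of estimated fluxes.
#' @export
solve_unweighted <- function(problem, v_m = problem$v_m) {
  check_Ae_rank(problem$A_e)
  if (ncol(problem$A_e) == 0) return(stats::setNames(numeric(0), character(0)))
  v_e <- drop(-pinv(problem$A_e) %*% (problem$A_m %*% v_m))
  stats::setNames(v_e, problem$unmeasured_ids)
}

#' Reduced redundancy matrix
#'
#' Projects the measured-flux balances onto the subspace not reachable by
#' any choice of unmeasured fluxes: `R = (I - A_e pinv(A_e)) A_m`, reduced
#' to independent rows. `R v_m = 0` holds exactly for any measurement vector
#' consistent with some steady-state fluxome; its row count is the number of
#' redundant measurements.
#'
#' @param problem an [mfa_problem()].
#' @param tol rank tolerance.
#' @return matrix with one independent row per redundancy (possibly 0 rows),
#'   columns named by measured flux ids.
#' @export
redundancy_matrix <- function(problem, tol = NULL) {
  A_e <- problem$A_e; A_m <- problem$A_m
  P <- diag(nrow(A_m)) - if (ncol(A_e) > 0) A_e %*% pinv(A_e) else 0
  R_full <- P %*% A_m
  # the number of independent redundancies is structural; computing it as a
  # rank difference avoids keeping roundoff singular values of P %*% A_m
  n_red <- matrix_rank(cbind(A_m, A_e), tol) - matrix_rank(A_e, tol)
  if (n_red == 0)
    return(matrix(0, 0, ncol(A_m), dimnames = list(NULL, colnames(A_m))))
  s <- svd(R_full)
  # orthonormal row basis of the row space: keeps R*Sigma*R' well conditioned
  R <- t(s$v[, seq_len(n_red), drop = FALSE])
  colnames(R) <- colnames(A_m)
  R
}

#' Balance measurements and test consistency
#'
#' Adjusts the measured fluxes according to their variances so the redundant
#' balances close exactly, computes the consistency index `h` (the weighted
#' squared norm of the redundancy residual) and compares it with the 95%
#' chi-squared critical value at the redundancy degrees of freedom; `h`
#' above the critical value signals gross measurement errors or a wrong
#' biochemistry / pseudo-steady-state assumption. Estimates are always
#' reported, with the `consistent` flag recording the verdict.
#'
#' @param problem an [mfa_problem()].
#' @param level confidence level of the chi-squared test (default 0.95).
#' @param tol rank tolerance.
#' @return object of class `mfa_result`: `v_e` (estimated unmeasured
#'   fluxes), `v_m_adj` (adjusted measurements), `epsilon` (redundancy
#'   residual), `h`, `redundancy_dof`, `chi2_critical`, `consistent`,
#'   `Sigma_e` (propagated variance of `v_e`), `sd_e`, plus the inputs.
#' @export
balance_and_test <- function(problem, level = 0.95, tol = NULL) {
  check_Ae_rank(problem$A_e, tol)
  R <- redundancy_matrix(problem, tol)
  v_m <- problem$v_m
  Sigma <- problem$Sigma_m
  n_red <- nrow(R)
  if (n_red == 0) {
    epsilon <- numeric(0)
    h <- 0
    v_m_adj <- v_m
    Adj <- diag(length(v_m))
  } else {
    Phi <- R %*% Sigma %*% t(R)
    cond <- rcond(Phi)
    if (!is.finite(cond) || cond < .Machine$double.eps * 1e3) {
      stop("R * Sigma_m * R' is singular; collinear measurements among: ",
           paste(colnames(R)[colSums(abs(R)) > 0], collapse = ", "))
    }
    Phi_inv <- solve(Phi)
    epsilon <- drop(R %*% v_m)
    h <- drop(t(epsilon) %*% Phi_inv %*% epsilon)
    Adj <- diag(length(v_m)) - Sigma %*% t(R) %*% Phi_inv %*% R
    v_m_adj <- drop(Adj %*% v_m)
    names(v_m_adj) <- names(v_m)
  }
  v_e <- solve_unweighted(problem, v_m_adj)
  # full linearization: v_e = J * Adj * v_m
  J <- if (ncol(problem$A_e) > 0) -pinv(problem$A_e) %*% problem$A_m else
    matrix(0, 0, length(v_m))
  J_tot <- J %*% Adj
  dimnames(J_tot) <- list(problem$unmeasured_ids, problem$measured_ids)
  Sigma_e <- J_tot %*% Sigma %*% t(J_tot)
  dimnames(Sigma_e) <- list(problem$unmeasured_ids, problem$unmeasured_ids)
  chi2_critical <- stats::qchisq(level, df = n_red)
  structure(list(
    v_e = v_e, v_m_adj = v_m_adj, epsilon = epsilon, h = h,
    redundancy_dof = n_red, chi2_critical = chi2_critical,
    consistent = h <= chi2_critical,
    Sigma_e = Sigma_e, sd_e = sqrt(pmax(diag(Sigma_e), 0)),
    J_total = J_tot, problem = problem, level = level
  ), class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat(sprintf(
    "MFA result: %d estimated fluxes, h = %.4g vs chi2(%d, %g%%) = %.4g -> %s\n",
    length(x$v_e), x$h, x$redundancy_dof, 100 * x$level, x$chi2_critical,
    if (x$consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Re-estimate after omitting one measurement
#'
#' Moves one flux from the measured to the unmeasured partition and re-runs
#' the balancing, reporting the estimate of the omitted flux next to its
#' original measurement. Used to probe how well the stoichiometry pins down
#' quantities such as growth rate or product synthesis.
#'
#' @param net a [stoich_network()].
#' @param v_m named measured-flux vector covering the network's measured ids.
#' @param flux_id the measured flux to omit.
#' @param ... passed to [mfa_problem()] (variance model) and
#'   [balance_and_test()] is run with defaults.
#' @return list: `result` (the new [balance_and_test()] output), `flux_id`,
#'   `measured_value`, `estimated_value`.
#' @export
scenario_omit_measurement <- function(net, v_m, flux_id, ...) {
  if (!flux_id %in% net$flux_ids) stop("unknown flux id: ", flux_id)
  if (!net$measured[[flux_id]]) stop("flux '", flux_id, "' is not measured")
  net2 <- net
  net2$measured[[flux_id]] <- FALSE
  net2$reactions[[flux_id]]$measured <- FALSE
  if (sum(net2$measured) == 0 ||
      classify_system(net2)$category == "underdetermined")
    stop("omitting '", flux_id, "' makes the system underdetermined")
  v_m2 <- v_m[setdiff(names(v_m), flux_id)]
  res <- balance_and_test(mfa_problem(net2, v_m2, ...))
  list(result = res, flux_id = flux_id,
       measured_value = unname(v_m[flux_id]),
       estimated_value = unname(res$v_e[flux_id]))
}

#' Fluxome divergence between two estimates
#'
#' Mean absolute relative change, in percent, over the shared fluxes:
#' `100 * mean(|v_new - v_old| / pmax(|v_old|, floor))`. This is the
#' package's own scenario-comparison metric; alternatives can be supplied
#' as a function.
#'
#' @param v_old,v_new named flux vectors; compared over common names.
#' @param floor denominator floor guarding near-zero reference fluxes.
#' @export
fluxome_change <- function(v_old, v_new, floor = 1e-6) {
  shared <- intersect(names(v_old), names(v_new))
  if (length(shared) == 0) return(NA_real_)
  100 * mean(abs(v_new[shared] - v_old[shared]) /
               pmax(abs(v_old[shared]), floor))
}

#' Re-estimate after deleting reactions
#'
#' Removes the named reactions (columns) from the network — and their
#' measurements if measured — re-runs the balancing, and quantifies the
#' divergence of the shared estimated fluxes with a configurable metric.
#' Balanced metabolites orphaned by the deletion (all-zero rows) are dropped
#' with a warning.
#'
#' @param net a [stoich_network()].
#' @param v_m named measured-flux vector.
#' @param flux_ids reactions to delete.
#' @param change_metric function(v_old, v_new) -> numeric; default
#'   [fluxome_change()].
#' @param ... passed to [mfa_problem()].
#' @return list: `result`, `deleted`, `fluxome_change`, `baseline`.
#' @export
scenario_delete_reactions <- function(net, v_m, flux_ids,
                                      change_metric = fluxome_change, ...) {
  unknown <- setdiff(flux_ids, net$flux_ids)
  if (length(unknown) > 0)
    stop("unknown flux ids: ", paste(unknown, collapse = ", "))
  baseline <- balance_and_test(mfa_problem(net, v_m, ...))
  keep <- setdiff(net$flux_ids, flux_ids)
  reactions <- net$reactions[keep]
  net2 <- stoich_network(reactions, external = net$external)
  orphaned <- setdiff(net$metabolites, net2$metabolites)
  if (length(orphaned) > 0)
    warning("dropping orphaned balanced metabolite(s): ",
            paste(orphaned, collapse = ", "))
  check_Ae_rank(partition_network(net2)$A_e)
  v_m2 <- v_m[intersect(names(v_m), keep)]
  res <- balance_and_test(mfa_problem(net2, v_m2, ...))
  list(result = res, deleted = flux_ids,
       fluxome_change = change_metric(baseline$v_e, res$v_e),
       baseline = baseline)
}
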