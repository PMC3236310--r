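#' Monte Carlo configuration
#'
#' @param n_samples number of perturbed datasets (default 1000, giving a
#'   coefficient population of 1001 including the unperturbed fit).
#' @param cv_flux relative error of measured exchange fluxes (default 0.16).
#' @param cv_target relative error of the productivity target (default
#'   0.22).
#' @param seed integer seed stamped on every sampled population.
#' @param sampling_mode `"marginal"` draws each estimated flux
#'   independently from its propagated normal error; `"covariance"` draws
#'   jointly per culture from the propagated covariance; `"re-estimate"`
#'   perturbs the raw measurements at `cv_flux` and re-runs the MFA
#'   balancing for every draw.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_samples = 1000, cv_flux = 0.16, cv_target = 0.22,
                      seed = 1L,
                      sampling_mode = c("marginal", "covariance",
                                        "re-estimate")) {
  sampling_mode <- match.arg(sampling_mode)
  if (n_samples < 0) stop("n_samples must be >= 0")
  if (cv_flux < 0 || cv_target < 0) stop("error CVs must be >= 0")
  structure(list(n_samples = as.integer(n_samples), cv_flux = cv_flux,
                 cv_target = cv_target, seed = as.integer(seed),
                 sampling_mode = sampling_mode),
            class = "mc_config")
}

#' Sample perturbed fluxome populations
#'
#' Generates `cfg$n_samples` perturbed copies of the estimated fluxome
#' table using the error variances obtained by propagating a `cv_flux`
#' relative error on the measured fluxes through the MFA estimator
#' (per-culture, via the stored total Jacobian), and perturbs the target
#' with relative error `cv_target`. In `"re-estimate"` mode the raw
#' measurements are perturbed at `cv_flux` and the whole MFA is re-run per
#' draw.
#'
#' @param mfa_results list of [balance_and_test()] results, one per
#'   culture.
#' @param target numeric target vector, one value per culture.
#' @param cfg an [mc_config()].
#' @param cultures optional culture labels.
#' @return list: `baseline` ([fluxome_table()] of the unperturbed
#'   estimates) and `samples` (list of perturbed fluxome tables), plus the
#'   `cfg` used.
#' @export
sample_population <- function(mfa_results, target, cfg = mc_config(),
                              cultures = NULL) {
  n_cult <- length(mfa_results)
  if (length(target) != n_cult)
    stop("target length must equal the number of cultures")
  if (is.null(cultures)) cultures <- names(mfa_results)
  if (is.null(cultures)) cultures <- as.character(seq_len(n_cult))
  flux_ids <- names(mfa_results[[1]]$v_e)
  V <- t(vapply(mfa_results, function(r) r$v_e[flux_ids], numeric(length(flux_ids))))
  baseline <- fluxome_table(V, target, cultures = cultures,
                            flux_ids = flux_ids)
  mode <- cfg$sampling_mode
  # propagate the configured measurement CV through the (stored) total
  # Jacobian, so cfg$cv_flux governs the sampled spread; cv_flux = 0 makes
  # every replicate identical to the point estimate
  covs <- lapply(mfa_results, function(r) {
    sm <- (cfg$cv_flux * abs(r$problem$v_m))^2
    S <- r$J_total %*% (t(r$J_total) * sm)
    dimnames(S) <- dimnames(r$Sigma_e)
    S
  })
  chols <- NULL
  if (mode == "covariance") {
    chols <- lapply(covs, function(S)
      tryCatch(chol(S), error = function(e) NULL))
    if (any(vapply(chols, is.null, logical(1)))) {
      warning("non-positive-definite Sigma_e; falling back to marginal sampling")
      mode <- "marginal"
    }
  }
  sds <- t(vapply(covs, function(S) sqrt(pmax(diag(S), 0))[flux_ids],
                  numeric(length(flux_ids))))
  set.seed(cfg$seed)
  samples <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    Vp <- switch(mode,
      marginal = V + matrix(stats::rnorm(length(V)), nrow(V)) * sds,
      covariance = {
        Vp <- V
        for (i in seq_len(n_cult))
          Vp[i, ] <- V[i, ] +
            drop(stats::rnorm(ncol(V)) %*% chols[[i]])
        Vp
      },
      `re-estimate` = {
        Vp <- V
        for (i in seq_len(n_cult)) {
          pr <- mfa_results[[i]]$problem
          vm <- pr$v_m * (1 + cfg$cv_flux * stats::rnorm(length(pr$v_m)))
          res <- balance_and_test(mfa_problem(pr$net, vm, cv = cfg$cv_flux))
          Vp[i, ] <- res$v_e[flux_ids]
        }
        Vp
      })
    tp <- target + cfg$cv_target * abs(target) * stats::rnorm(n_cult)
    samples[[s]] <- fluxome_table(Vp, tp, cultures = cultures,
                                  flux_ids = flux_ids)
  }
  list(baseline = baseline, samples = samples, cfg = cfg)
}

#' Population of PLS regression coefficients
#'
#' Fits the baseline table and every perturbed replicate with the same
#' number of latent variables and preprocessing policy, collecting the
#' standardized regression coefficients. Replicates in which a flux column
#' degenerates to zero variance have that coefficient recorded as missing.
#'
#' @param population output of [sample_population()].
#' @param n_lv number of latent variables for every fit.
#' @return matrix (1 + n_samples) x fluxes of standardized coefficients;
#'   row `"baseline"` is the unperturbed fit. Attributes: `n_lv`,
#'   `n_dropped` (count of replicate-level column drops), `baseline_model`.
#' @export
coefficient_population <- function(population, n_lv) {
  base_fit <- fit_pls1(population$baseline, n_lv)
  flux_ids <- base_fit$flux_ids
  n_rep <- length(population$samples)
  rep_names <- if (n_rep > 0) paste0("rep", seq_len(n_rep)) else character(0)
  B <- matrix(NA_real_, n_rep + 1, length(flux_ids),
              dimnames = list(c("baseline", rep_names), flux_ids))
  B["baseline", ] <- base_fit$B
  n_dropped <- 0L
  for (s in seq_len(n_rep)) {
    fit <- tryCatch(fit_pls1(population$samples[[s]], n_lv),
                    error = function(e) NULL)
    if (is.null(fit)) next
    common <- intersect(flux_ids, fit$flux_ids)
    n_dropped <- n_dropped + (length(flux_ids) - length(common))
    B[s + 1, common] <- fit$B[common]
  }
  structure(B, n_lv = n_lv, n_dropped = n_dropped,
            baseline_model = base_fit)
}

#' Coefficient confidence intervals and strength of association
#'
#' For each flux, the standard deviation of its coefficient over the Monte
#' Carlo population gives a confidence half-width
#' `sd_B * t((1 + level)/2, dg)` with `dg = population size - number of
#' fluxes`. The strength of association `alpha = |B| / half-width` filters
#' the coefficients: `alpha < 1` means the confidence interval contains
#' zero, i.e. the flux-target association is not statistically meaningful.
#'
#' @param population matrix from [coefficient_population()].
#' @param level confidence level (default 0.95, i.e. t at 0.975).
#' @param alpha_mode `"coef_over_ci"` (default) reports
#'   `|B| / half-width`, meaningful when >= 1; `"ci_over_coef"` reports the
#'   reciprocal, meaningful when <= 1. The meaningful flag is identical in
#'   both modes.
#' @return data.frame of class `coefficient_stats`: `flux_id`, `B`
#'   (baseline standardized coefficient), `sd_B`, `ci_halfwidth`, `alpha`,
#'   `meaningful`; attributes `dg`, `level`, `alpha_mode`, `n_population`.
#' @export
confidence_and_alpha <- function(population, level = 0.95,
                                 alpha_mode = c("coef_over_ci",
                                                "ci_over_coef")) {
  alpha_mode <- match.arg(alpha_mode)
  n_pop <- nrow(population)
  p <- ncol(population)
  dg <- n_pop - p
  if (dg <= 0)
    stop("population size (", n_pop, ") must exceed the number of fluxes (",
         p, ")")
  B <- population["baseline", ]
  sd_B <- apply(population, 2, stats::sd, na.rm = TRUE)
  tq <- stats::qt((1 + level) / 2, df = dg)
  ci <- sd_B * tq
  ratio <- ifelse(ci == 0, ifelse(abs(B) > 0, Inf, 0), abs(B) / ci)
  meaningful <- ratio >= 1
  alpha <- if (alpha_mode == "coef_over_ci") ratio else
    ifelse(ratio == 0, Inf, 1 / ratio)
  out <- data.frame(flux_id = colnames(population), B = B, sd_B = sd_B,
                    ci_halfwidth = ci, alpha = alpha,
                    meaningful = meaningful, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, dg = dg, level = level, alpha_mode = alpha_mode,
            n_population = n_pop, class = c("coefficient_stats",
                                            "data.frame"))
}

#' Partition fluxes by the meaningful-association filter
#'
#' @param stats a [confidence_and_alpha()] table.
#' @return list: `retained` and `excluded` flux ids, each ordered by
#'   decreasing strength of association.
#' @export
filter_meaningful <- function(stats) {
  ratio <- if (attr(stats, "alpha_mode") == "ci_over_coef")
    ifelse(stats$alpha == 0, Inf, 1 / stats$alpha) else stats$alpha
  ord <- order(ratio, decreasing = TRUE)
  s <- stats[ord, ]
  list(retained = s$flux_id[s$meaningful],
       excluded = s$flux_id[!s$meaningful])
}
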