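#' Jacobian of estimated fluxes with respect to measurements
#'
#' For the linear estimator `v_e = -pinv(A_e) A_m v_m` the Jacobian is the
#' constant matrix `J = -pinv(A_e) A_m`: entry (i, j) is the absolute
#' sensitivity of estimated flux i to measured flux j, independent of the
#' measurement values themselves.
#'
#' @param problem an [mfa_problem()].
#' @return matrix, rows = unmeasured fluxes, columns = measured fluxes.
#' @export
mfa_jacobian <- function(problem) {
  check_Ae_rank(problem$A_e)
  J <- if (ncol(problem$A_e) > 0) -pinv(problem$A_e) %*% problem$A_m else
    matrix(0, 0, ncol(problem$A_m))
  dimnames(J) <- list(problem$unmeasured_ids, problem$measured_ids)
  J
}

#' Fractional (relative) sensitivities
#'
#' Rescales the absolute Jacobian by reference magnitudes — typically the
#' average measured rates and average estimated fluxes over all available
#' culture conditions — so entry (i, j) is the fractional change in
#' estimated flux i per fractional change in measured flux j:
#' `S[i, j] = J[i, j] * avg_measured[j] / avg_estimated[i]`.
#' Rows whose reference estimate is below `floor` in magnitude are
#' undefined and returned as `NA` (never as a fake zero sensitivity).
#'
#' @param J Jacobian from [mfa_jacobian()].
#' @param avg_measured reference magnitudes for the measured fluxes
#'   (length = ncol(J)).
#' @param avg_estimated reference magnitudes for the estimated fluxes
#'   (length = nrow(J)).
#' @param floor magnitude below which a reference estimate is treated as
#'   zero.
#' @return matrix of fractional sensitivities, same dimnames as `J`.
#' @export
fractional_sensitivities <- function(J, avg_measured, avg_estimated,
                                     floor = 1e-12) {
  if (length(avg_measured) != ncol(J))
    stop("avg_measured length must equal ncol(J)")
  if (length(avg_estimated) != nrow(J))
    stop("avg_estimated length must equal nrow(J)")
  S <- J * rep(avg_measured, each = nrow(J)) / avg_estimated
  S[abs(avg_estimated) < floor, ] <- NA_real_
  S
}

#' Long-format sensitivity table
#'
#' @param J absolute Jacobian.
#' @param S_frac fractional sensitivities (same shape), optional.
#' @return data.frame with columns `estimated_flux`, `measured_flux`,
#'   `absolute`, `fractional`.
#' @export
sensitivity_table <- function(J, S_frac = NULL) {
  df <- data.frame(
    estimated_flux = rep(rownames(J), times = ncol(J)),
    measured_flux = rep(colnames(J), each = nrow(J)),
    absolute = as.vector(J),
    stringsAsFactors = FALSE)
  df$fractional <- if (is.null(S_frac)) NA_real_ else as.vector(S_frac)
  df
}
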