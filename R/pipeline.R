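#' Read a per-culture measurements table
#'
#' Expected columns: `culture_id`, one column per measured flux id,
#' optional `<id>_sd` columns with per-flux standard deviations, optional
#' target column.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurements file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (!"culture_id" %in% names(df))
    stop("measurements table needs a 'culture_id' column")
  df
}

#' Run the MFA balancing for every culture
#'
#' For each culture row, builds the weighted estimation problem (per-flux
#' `<id>_sd` columns when present, otherwise the `cv_flux` relative-error
#' model), balances the measurements, and tests consistency.
#'
#' @param net a [stoich_network()].
#' @param measurements data.frame as from [read_measurements()].
#' @param cv_flux relative measurement error for the default variance
#'   model (default 0.16).
#' @param level chi-squared test confidence level (default 0.95).
#' @return list of class `mfa_run`: `results` (named list of
#'   [balance_and_test()] outputs), `summary` (data.frame with `culture_id`,
#'   `h`, `redundancy_dof`, `chi2_critical`, `consistent`), `estimates`
#'   (cultures x estimated-fluxes matrix), `sd_estimates`, `net`.
#' @export
run_mfa <- function(net, measurements, cv_flux = 0.16, level = 0.95) {
  part <- partition_network(net)
  missing <- setdiff(part$measured_ids, names(measurements))
  if (length(missing) > 0)
    stop("measured flux column(s) missing: ", paste(missing, collapse = ", "))
  ids <- as.character(measurements$culture_id)
  results <- vector("list", nrow(measurements))
  names(results) <- ids
  for (i in seq_len(nrow(measurements))) {
    v_m <- unlist(measurements[i, part$measured_ids])
    sd_cols <- paste0(part$measured_ids, "_sd")
    sigma <- NULL
    if (all(sd_cols %in% names(measurements)))
      sigma <- stats::setNames(unlist(measurements[i, sd_cols]),
                               part$measured_ids)
    prob <- mfa_problem(net, v_m, sigma = sigma, cv = cv_flux)
    results[[i]] <- balance_and_test(prob, level = level)
  }
  summary <- data.frame(
    culture_id = ids,
    h = vapply(results, function(r) r$h, numeric(1)),
    redundancy_dof = vapply(results, function(r) r$redundancy_dof, integer(1)),
    chi2_critical = vapply(results, function(r) r$chi2_critical, numeric(1)),
    consistent = vapply(results, function(r) r$consistent, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  est <- t(vapply(results, function(r) r$v_e,
                  numeric(length(part$unmeasured_ids))))
  sde <- t(vapply(results, function(r) r$sd_e,
                  numeric(length(part$unmeasured_ids))))
  if (length(part$unmeasured_ids) == 1) { est <- t(est); sde <- t(sde) }
  dimnames(est) <- dimnames(sde) <- list(ids, part$unmeasured_ids)
  structure(list(results = results, summary = summary, estimates = est,
                 sd_estimates = sde, net = net),
            class = "mfa_run")
}

#' Run the full hybrid MFA-PLS pipeline
#'
#' Chains: MFA balancing per culture, PLS1 regression of the estimated
#' fluxome against the target, Monte Carlo resampling of the coefficient
#' population, the strength-of-association filter, and hierarchical
#' clustering of the retained fluxes. Every random stage uses the seed in
#' `cfg`.
#'
#' @param net a [stoich_network()].
#' @param measurements data.frame including the target column.
#' @param target_col name of the target column (default `"target"`).
#' @param cfg an [mc_config()].
#' @param lv_cap maximum number of latent variables (default 3).
#' @param level confidence level for both the chi-squared consistency test
#'   and the coefficient intervals.
#' @param linkage_method clustering linkage (default `"single"`).
#' @param alpha_mode see [confidence_and_alpha()].
#' @return list of class `hybrid_result`: `mfa`, `table`, `model`,
#'   `population`, `stats`, `filter`, `clustering` (NULL with a notice
#'   when fewer than 2 fluxes are retained), `n_lv`, `cfg`.
#' @export
run_hybrid <- function(net, measurements, target_col = "target",
                       cfg = mc_config(), lv_cap = 3, level = 0.95,
                       linkage_method = "single",
                       alpha_mode = "coef_over_ci") {
  if (nrow(measurements) < 3)
    stop("need at least 3 cultures for the hybrid pipeline")
  if (!target_col %in% names(measurements))
    stop("target column '", target_col, "' not found")
  mfa <- run_mfa(net, measurements, cv_flux = cfg$cv_flux, level = level)
  target <- measurements[[target_col]]
  table <- fluxome_table(mfa$estimates, target)
  std <- withCallingHandlers(standardize_fluxome(table),
                             warning = function(w) invokeRestart("muffleWarning"))
  n_lv <- min(lv_cap, nrow(table$values) - 1, ncol(std$X), matrix_rank(std$X))
  model <- fit_pls1(table, n_lv)
  if (cfg$n_samples == 0) {
    warning("mc_samples = 0: coefficients reported without confidence intervals")
    stats_df <- data.frame(flux_id = model$flux_ids, B = model$B,
                           sd_B = NA_real_, ci_halfwidth = NA_real_,
                           alpha = NA_real_, meaningful = NA,
                           stringsAsFactors = FALSE)
    return(structure(list(mfa = mfa, table = table, model = model,
                          population = NULL, stats = stats_df,
                          filter = NULL, clustering = NULL, n_lv = n_lv,
                          cfg = cfg), class = "hybrid_result"))
  }
  population <- sample_population(mfa$results, target, cfg)
  coef_pop <- coefficient_population(population, n_lv)
  stats_df <- confidence_and_alpha(coef_pop, level = level,
                                   alpha_mode = alpha_mode)
  filt <- filter_meaningful(stats_df)
  clustering <- NULL
  if (length(filt$retained) >= 2) {
    clustering <- cluster_fluxes(stats_df, linkage_method = linkage_method)
  } else {
    message("fewer than 2 meaningful fluxes; clustering skipped")
  }
  structure(list(mfa = mfa, table = table, model = model,
                 population = coef_pop, stats = stats_df, filter = filt,
                 clustering = clustering, n_lv = n_lv, cfg = cfg),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat("Hybrid MFA-PLS result\n")
  cat(sprintf("  cultures: %d, estimated fluxes: %d, latent variables: %d\n",
              length(x$table$cultures), length(x$table$flux_ids), x$n_lv))
  cat(sprintf("  consistent cultures: %d/%d\n", sum(x$mfa$summary$consistent),
              nrow(x$mfa$summary)))
  if (!is.null(x$filter))
    cat(sprintf("  meaningful fluxes (alpha >= 1): %d of %d\n",
                length(x$filter$retained), nrow(x$stats)))
  if (!is.null(x$clustering))
    cat(sprintf("  cophenetic correlation: %.3f\n",
                x$clustering$cophenetic_c))
  invisible(x)
}

#' Fit on a calibration subset and predict held-out cultures
#'
#' Splits the cultures, selects the latent-variable count by total
#' (calibration + validation) target variance explained capped at
#' `lv_cap`, fits on the calibration subset only, and predicts the
#' held-out cultures.
#'
#' @param net a [stoich_network()].
#' @param measurements data.frame including the target column.
#' @param target_col target column name.
#' @param holdout culture labels/positions for validation, or
#' @param preset a named split (`"strategy1"`, `"strategy2"`; see
#'   [validation_split()]).
#' @param lv_cap latent-variable cap (default 3).
#' @param lv_tol parsimony tolerance for [select_n_lv()].
#' @param cv_flux relative measurement error.
#' @return list of class `validation_result`: `predictions` (data.frame
#'   `culture_id`, `measured`, `predicted`), `n_lv`, `selection`
#'   diagnostics, `model`.
#' @export
run_validation <- function(net, measurements, target_col = "target",
                           holdout = NULL, preset = NULL, lv_cap = 3,
                           lv_tol = 0.02, cv_flux = 0.16) {
  if (!target_col %in% names(measurements))
    stop("target column '", target_col, "' not found")
  mfa <- run_mfa(net, measurements, cv_flux = cv_flux)
  table <- fluxome_table(mfa$estimates, measurements[[target_col]])
  split <- validation_split(table, holdout = holdout, preset = preset)
  sel <- select_n_lv(split$calibration, split$validation, cap = lv_cap,
                     tol = lv_tol)
  model <- fit_pls1(split$calibration, sel$n_lv)
  pred <- predict(model, split$validation$values)
  structure(list(
    predictions = data.frame(culture_id = split$validation$cultures,
                             measured = split$validation$target,
                             predicted = as.numeric(pred),
                             stringsAsFactors = FALSE),
    n_lv = sel$n_lv, selection = sel, model = model, mfa = mfa,
    split = split), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Validation with %d latent variable(s):\n", x$n_lv))
  print(x$predictions, row.names = FALSE)
  invisible(x)
}
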