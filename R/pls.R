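#' Assemble a fluxome table
#'
#' Couples the per-culture estimated fluxome (cultures x fluxes) with the
#' measured productivity target for regression.
#'
#' @param values numeric matrix, cultures in rows, fluxes in columns.
#' @param target numeric vector of per-culture target values (e.g. specific
#'   productivity in 1e3 infectious particles / (1e6 cells * h)).
#' @param cultures,flux_ids optional labels; default dimnames of `values`.
#' @return object of class `fluxome_table`.
#' @export
fluxome_table <- function(values, target, cultures = rownames(values),
                          flux_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cultures)) cultures <- as.character(seq_len(nrow(values)))
  if (is.null(flux_ids)) flux_ids <- paste0("v", seq_len(ncol(values)))
  if (length(target) != nrow(values))
    stop("target length must equal the number of cultures")
  if (anyNA(values) || anyNA(target))
    stop("fluxome table must not contain missing values")
  dimnames(values) <- list(cultures, flux_ids)
  structure(list(values = values, target = as.numeric(target),
                 cultures = cultures, flux_ids = flux_ids),
            class = "fluxome_table")
}

subset_cultures <- function(table, idx) {
  fluxome_table(table$values[idx, , drop = FALSE], table$target[idx],
                cultures = table$cultures[idx], flux_ids = table$flux_ids)
}

#' Standardize a fluxome table
#'
#' Autoscales each flux column to mean 0 / sd 1 and centers (but does not
#' scale) the target. Constant flux columns carry no information and are
#' dropped with a warning; the drop is recorded so downstream reports can
#' state it.
#'
#' @param table a [fluxome_table()].
#' @return list: `X` (standardized predictor matrix), `y` (centered
#'   target), `center`, `scale` (per kept flux), `target_center`,
#'   `dropped` (ids of constant columns).
#' @export
standardize_fluxome <- function(table) {
  if (nrow(table$values) < 2) stop("need at least 2 cultures to standardize")
  ctr <- colMeans(table$values)
  scl <- apply(table$values, 2, stats::sd)
  dropped <- table$flux_ids[scl == 0 | !is.finite(scl)]
  if (length(dropped) > 0)
    warning("dropping constant flux column(s): ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(table$flux_ids, dropped)
  X <- sweep(sweep(table$values[, keep, drop = FALSE], 2, ctr[keep]),
             2, scl[keep], "/")
  ty <- mean(table$target)
  list(X = X, y = table$target - ty, center = ctr[keep], scale = scl[keep],
       target_center = ty, dropped = dropped)
}

#' Fit a single-target PLS (PLS1) regression
#'
#' Sequential (NIPALS-style) decomposition of the standardized fluxome:
#' each latent variable's weight vector maximizes covariance between the
#' deflated predictor block and the current target residual. The regression
#' vector `B = W (P'W)^-1 q` links standardized fluxes to the centered
#' target; it is also reported back-transformed to original flux units.
#' Weight vectors follow a deterministic sign convention (largest-magnitude
#' element positive) so repeated runs are bit-identical.
#'
#' @param table a [fluxome_table()].
#' @param n_lv number of latent variables, `1 <= n_lv <=
#'   min(cultures - 1, fluxes)` and at most the usable rank of the
#'   standardized predictors.
#' @return object of class `pls_model`: `W` (weights), `T_scores`,
#'   `P_loadings` (predictor loadings), `q_loadings` (target loading per
#'   LV), `B` (standardized space), `B_original`, `intercept_original`,
#'   scaling record, residuals `E` (predictors) and `f_resid` (target),
#'   `n_lv`, `flux_ids` (kept), `dropped`.
#' @export
fit_pls1 <- function(table, n_lv) {
  std <- withCallingHandlers(standardize_fluxome(table),
                             warning = function(w) invokeRestart("muffleWarning"))
  X <- std$X; y <- std$y
  n <- nrow(X); p <- ncol(X)
  max_lv <- min(n - 1, p)
  if (n_lv < 1 || n_lv > max_lv)
    stop("n_lv must be between 1 and ", max_lv)
  r <- matrix_rank(X)
  if (n_lv > r)
    stop("n_lv exceeds the usable rank of the predictors (maximum ", r, ")")
  W <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  Xd <- X; yd <- y
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * p)
      stop("no covariance left to extract at latent variable ", a,
           " (maximum ", a - 1, ")")
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    q[a] <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - t_ * q[a]
    W[, a] <- w; Tm[, a] <- t_; P[, a] <- p_
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("LV", seq_len(n_lv)))
  dimnames(Tm) <- list(rownames(X), paste0("LV", seq_len(n_lv)))
  B <- drop(W %*% solve(crossprod(P, W), q))
  names(B) <- colnames(X)
  B_orig <- B / std$scale
  structure(list(
    W = W, T_scores = Tm, P_loadings = P, q_loadings = q,
    B = B, B_original = B_orig,
    intercept_original = std$target_center - sum(B_orig * std$center),
    center = std$center, scale = std$scale,
    target_center = std$target_center,
    E = Xd, f_resid = yd, n_lv = n_lv,
    flux_ids = colnames(X), dropped = std$dropped,
    X0 = X, y0 = y
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  ve <- variance_explained(x)
  cat(sprintf(
    "PLS1 model: %d latent variables over %d fluxes, %d cultures\n",
    x$n_lv, length(x$flux_ids), nrow(x$T_scores)))
  cat(sprintf("  cumulative variance explained: predictors %.1f%%, target %.1f%%\n",
              100 * ve$cumulative_predictors[x$n_lv],
              100 * ve$cumulative_target[x$n_lv]))
  invisible(x)
}

#' Predict productivity for new fluxome vectors
#'
#' Applies the stored centering/scaling, the regression vector, and the
#' target un-centering. Negative predictions are legitimate output (the
#' model is linear in standardized fluxes).
#'
#' @param object a [fit_pls1()] model.
#' @param newdata named numeric vector or matrix (cultures x fluxes)
#'   covering the model's kept flux ids.
#' @param ... unused.
#' @return numeric vector of predicted target values.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  missing <- setdiff(object$flux_ids, colnames(newdata))
  if (length(missing) > 0)
    stop("flux id(s) missing from new data: ", paste(missing, collapse = ", "))
  X <- newdata[, object$flux_ids, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  drop(Xs %*% object$B) + object$target_center
}

#' Variance explained per latent variable
#'
#' Fractions of the standardized predictor block and of the centered target
#' captured by each latent variable, with cumulative totals. At full rank
#' the cumulative target fraction equals the ordinary least-squares R^2.
#'
#' @param model a [fit_pls1()] model.
#' @return list of per-LV and cumulative fractions for predictors and
#'   target.
#' @export
variance_explained <- function(model) {
  ssx_tot <- sum(model$X0^2)
  ssy_tot <- sum(model$y0^2)
  tt <- colSums(model$T_scores^2)
  ssx_lv <- tt * colSums(model$P_loadings^2)
  ssy_lv <- tt * model$q_loadings^2
  list(per_lv_predictors = ssx_lv / ssx_tot,
       per_lv_target = ssy_lv / ssy_tot,
       cumulative_predictors = cumsum(ssx_lv) / ssx_tot,
       cumulative_target = cumsum(ssy_lv) / ssy_tot)
}

#' Split a fluxome table into calibration and validation subsets
#'
#' Two named presets mirror deliberate validation designs: `"strategy1"`
#' holds out cultures 6, 7, 8, 9 and 13 (by position in the table), a block
#' of rationally designed experiments; `"strategy2"` holds out the three
#' highest-productivity cultures to prevent interpolation.
#'
#' @param table a [fluxome_table()].
#' @param holdout culture labels (or integer positions) to reserve for
#'   validation; ignored when `preset` is given.
#' @param preset `"strategy1"` or `"strategy2"`.
#' @return list with `calibration` and `validation` fluxome tables.
#' @export
validation_split <- function(table, holdout = NULL, preset = NULL) {
  n <- length(table$cultures)
  if (!is.null(preset)) {
    idx <- switch(preset,
      strategy1 = c(6L, 7L, 8L, 9L, 13L),
      strategy2 = order(table$target, decreasing = TRUE)[1:3],
      stop("unknown preset: ", preset))
    if (max(idx) > n) stop("preset '", preset, "' needs at least ",
                           max(idx), " cultures")
  } else {
    if (is.null(holdout) || length(holdout) == 0)
      stop("holdout must be non-empty")
    idx <- if (is.numeric(holdout)) as.integer(holdout) else
      match(as.character(holdout), table$cultures)
    bad <- is.na(idx) | idx < 1 | idx > n
    bad[is.na(bad)] <- TRUE
    if (any(bad))
      stop("unknown culture label(s) in holdout: ",
           paste(holdout[bad], collapse = ", "))
  }
  idx <- sort(unique(idx))
  if (length(idx) >= n) stop("holdout must be a proper subset of the cultures")
  list(calibration = subset_cultures(table, setdiff(seq_len(n), idx)),
       validation = subset_cultures(table, idx))
}

#' Choose the number of latent variables
#'
#' Fits 1..`cap` latent variables on the calibration set and returns the
#' count maximizing the total target variance explained over calibration
#' plus validation. Near-ties go to the smaller count: an extra latent
#' variable must raise the total by more than `tol` (default 0.02, i.e.
#' 2% of variance) to be kept, the usual parsimony rule in latent-variable
#' model selection. Note that using the validation set for this choice
#' leaks information into model selection; the diagnostics expose both
#' components so the leak is visible.
#'
#' @param calibration,validation [fluxome_table()]s over disjoint cultures.
#' @param cap maximum number of latent variables (default 3).
#' @param tol parsimony tolerance on the total explained-variance gain.
#' @return list: `n_lv`, `diagnostics` (data.frame per candidate count with
#'   calibration/validation/total explained fractions),
#'   `calibration_only` flag (TRUE when the validation set was empty and
#'   the criterion fell back to calibration variance alone).
#' @export
select_n_lv <- function(calibration, validation = NULL, cap = 3,
                        tol = 0.02) {
  std <- withCallingHandlers(standardize_fluxome(calibration),
                             warning = function(w) invokeRestart("muffleWarning"))
  max_lv <- min(nrow(calibration$values) - 1, ncol(std$X), matrix_rank(std$X),
                cap)
  has_val <- !is.null(validation) && length(validation$cultures) > 0
  rows <- lapply(seq_len(max_lv), function(k) {
    fit <- fit_pls1(calibration, k)
    cal <- variance_explained(fit)$cumulative_target[k]
    val <- if (has_val) {
      pred <- predict(fit, validation$values)
      ss_tot <- sum((validation$target - mean(validation$target))^2)
      if (ss_tot == 0) NA_real_ else
        1 - sum((validation$target - pred)^2) / ss_tot
    } else NA_real_
    data.frame(n_lv = k, explained_calibration = cal,
               explained_validation = val,
               explained_total = cal + ifelse(is.na(val), 0, val))
  })
  diag_df <- do.call(rbind, rows)
  best <- min(which(diag_df$explained_total >=
                      max(diag_df$explained_total) - tol))
  list(n_lv = diag_df$n_lv[best], diagnostics = diag_df,
       calibration_only = !has_val)
}
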