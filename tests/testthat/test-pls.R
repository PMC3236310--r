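test_that("standardization centers, scales, drops constants and round-trips", {
  set.seed(51)
  X <- cbind(a = rnorm(10, 5, 2), b = rnorm(10, -1, 0.5), c = rep(3, 10))
  tab <- fluxome_table(X, rnorm(10))
  expect_warning(std <- standardize_fluxome(tab), "constant")
  expect_equal(std$dropped, "c")
  expect_equal(unname(colMeans(std$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$X, 2, sd)), c(1, 1), tolerance = 1e-12)
  # inverse transform recovers the input
  back <- sweep(sweep(std$X, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(unname(back), unname(X[, c("a", "b")]), tolerance = 1e-12)
  # already standardized input: identity within tolerance
  Z <- scale(matrix(rnorm(40), 10, 4))
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  tab2 <- fluxome_table(Z, rnorm(10))
  std2 <- standardize_fluxome(tab2)
  expect_equal(unname(std2$X), unname(Z[, ]), tolerance = 1e-8)
})

test_that("univariate PLS1 equals the least-squares slope", {
  set.seed(52)
  tab <- fluxome_table(matrix(rnorm(15), ncol = 1,
                              dimnames = list(NULL, "f1")),
                      rnorm(15))
  fit <- fit_pls1(tab, 1)
  z <- scale(tab$values[, 1])
  slope <- cov(z, tab$target) / var(z[, 1])
  expect_equal(unname(fit$B), as.numeric(slope), tolerance = 1e-10)
})

test_that("full-rank PLS reproduces multiple-OLS predictions", {
  set.seed(53)
  for (i in 1:4) {
    n <- 12; p <- 4
    tab <- linear_fluxome(n, p, coefs = rnorm(p), noise_sd = 0.5,
                          seed = 53 + i)
    fit <- fit_pls1(tab, p)
    df <- data.frame(y = tab$target, tab$values)
    ols <- lm(y ~ ., data = df)
    expect_equal(unname(predict(fit, tab$values)),
                 unname(fitted(ols)), tolerance = 1e-8)
    # and the coefficient vector matches in original units
    expect_equal(unname(fit$B_original), unname(coef(ols)[-1]),
                 tolerance = 1e-8)
  }
})

test_that("scores are mutually orthogonal", {
  set.seed(54)
  for (i in 1:5) {
    tab <- linear_fluxome(10, 6, coefs = rnorm(3), noise_sd = 1,
                          seed = 100 + i)
    fit <- fit_pls1(tab, 3)
    G <- crossprod(fit$T_scores)
    off <- abs(G[upper.tri(G)])
    norms <- sqrt(diag(G))
    expect_lt(max(off / (norms[1] * norms[2])), 1e-8)
  }
})

test_that("row permutation permutes scores and leaves B unchanged", {
  set.seed(55)
  tab <- linear_fluxome(11, 5, coefs = c(1, -2), noise_sd = 0.3)
  fit <- fit_pls1(tab, 2)
  perm <- sample(11)
  tab2 <- fluxome_table(tab$values[perm, ], tab$target[perm])
  fit2 <- fit_pls1(tab2, 2)
  expect_equal(fit2$B, fit$B, tolerance = 1e-10)
  expect_equal(unname(fit2$T_scores), unname(fit$T_scores[perm, ]),
               tolerance = 1e-10)
})

test_that("a noise-free single-driver target is fit exactly with one LV", {
  # single predictor: trivially exact
  tab1 <- linear_fluxome(10, 1, coefs = 2, noise_sd = 0)
  fit1 <- fit_pls1(tab1, 1)
  expect_equal(unname(predict(fit1, tab1$values)), tab1$target,
               tolerance = 1e-8)
  # several predictors, mutually orthogonal and centered in-sample
  # (Helmert contrasts): the first weight vector points exactly along
  # the driver
  H <- contr.helmert(10)[, 1:4]
  colnames(H) <- paste0("f", 1:4)
  y <- unname(3 * H[, 2] / sd(H[, 2]))
  tab <- fluxome_table(H, y)
  fit <- fit_pls1(tab, 1)
  expect_equal(unname(predict(fit, tab$values)), y, tolerance = 1e-8)
})

test_that("prediction respects centering and errors on missing fluxes", {
  set.seed(56)
  tab <- linear_fluxome(12, 5, coefs = c(1, 1), noise_sd = 0.2)
  fit <- fit_pls1(tab, 3)
  # the all-means vector predicts the target mean
  expect_equal(unname(predict(fit, colMeans(tab$values))),
               mean(tab$target), tolerance = 1e-10)
  expect_error(predict(fit, setNames(rnorm(2), c("f1", "f2"))), "f3")
})

test_that("variance explained is monotone and equals OLS R2 at full rank", {
  set.seed(57)
  tab <- linear_fluxome(14, 4, coefs = c(2, -1), noise_sd = 0.7)
  fit <- fit_pls1(tab, 4)
  ve <- variance_explained(fit)
  expect_true(all(diff(ve$cumulative_target) >= -1e-12))
  expect_true(all(diff(ve$cumulative_predictors) >= -1e-12))
  expect_true(all(ve$per_lv_target >= -1e-12 & ve$per_lv_target <= 1 + 1e-12))
  r2 <- summary(lm(tab$target ~ tab$values))$r.squared
  expect_equal(unname(ve$cumulative_target[4]), r2, tolerance = 1e-8)
})

test_that("a target independent of the predictors explains almost nothing", {
  set.seed(58)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- fluxome_table(X, rnorm(200))
  fit <- fit_pls1(tab, 3)
  expect_lt(max(variance_explained(fit)$per_lv_target), 0.1)
})

test_that("n_lv bounds are enforced with an informative maximum", {
  tab <- linear_fluxome(6, 3, coefs = 1, noise_sd = 0.1)
  expect_error(fit_pls1(tab, 0), "between 1 and")
  expect_error(fit_pls1(tab, 5), "between 1 and")
  # duplicated column: usable rank below ncol
  X <- tab$values; X <- cbind(X, f4 = X[, 1])
  tab2 <- fluxome_table(X, tab$target)
  expect_error(fit_pls1(tab2, 4), "rank")
})

test_that("validation splits are exact partitions with named presets", {
  set.seed(59)
  tab <- linear_fluxome(13, 4, coefs = c(1, -1), noise_sd = 0.3)
  sp <- validation_split(tab, holdout = "3")
  expect_equal(length(sp$validation$cultures), 1)
  expect_setequal(c(sp$calibration$cultures, sp$validation$cultures),
                  tab$cultures)
  # strategy1 holds out positions 6,7,8,9,13
  sp1 <- validation_split(tab, preset = "strategy1")
  expect_equal(sp1$validation$cultures, tab$cultures[c(6:9, 13)])
  # strategy2 holds out the three top producers
  sp2 <- validation_split(tab, preset = "strategy2")
  top3 <- tab$cultures[order(tab$target, decreasing = TRUE)[1:3]]
  expect_setequal(sp2$validation$cultures, top3)
  expect_error(validation_split(tab, holdout = "nope"), "nope")
  expect_error(validation_split(tab, holdout = tab$cultures), "proper subset")
})

test_that("latent-variable selection maximizes total explained variance", {
  set.seed(60)
  tab <- linear_fluxome(16, 6, coefs = c(2, -1.5), noise_sd = 0.4)
  sp <- validation_split(tab, holdout = 1:4)
  sel <- select_n_lv(sp$calibration, sp$validation, cap = 3)
  expect_true(sel$n_lv %in% 1:3)
  # the choice is within the parsimony tolerance of the maximum, and no
  # smaller count is
  tot <- sel$diagnostics$explained_total
  expect_gte(tot[sel$n_lv], max(tot) - 0.02)
  if (sel$n_lv > 1) expect_lt(tot[sel$n_lv - 1], max(tot) - 0.02)
  # with zero tolerance the strict argmax is returned
  sel0 <- select_n_lv(sp$calibration, sp$validation, cap = 3, tol = 0)
  expect_equal(sel0$n_lv, which.max(sel0$diagnostics$explained_total))
  # cap 1 forces 1
  expect_equal(select_n_lv(sp$calibration, sp$validation, cap = 1)$n_lv, 1)
  # empty validation set falls back to calibration-only, flagged
  sel2 <- select_n_lv(sp$calibration, NULL, cap = 3)
  expect_true(sel2$calibration_only)
})

test_that("a rank-2 latent structure rarely needs a third latent variable", {
  hits <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 20; p <- 8
    Tm <- matrix(rnorm(n * 2), n, 2)          # two latent factors
    P <- matrix(rnorm(p * 2), p, 2)
    X <- Tm %*% t(P) + 0.05 * matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", 1:p)
    y <- drop(Tm %*% c(2, -1.5)) + rnorm(n, 0, 0.3)
    sp <- validation_split(fluxome_table(X, y), holdout = 1:6)
    sel <- select_n_lv(sp$calibration, sp$validation, cap = 3)
    if (sel$n_lv <= 2) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})
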