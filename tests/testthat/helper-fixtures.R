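# Fixtures are built in code; nothing is read from disk unless a test
# writes it first.

# Single balanced node A: v1 in, v2 + v3 out, all three measured.
toy_node_network <- function() {
  stoich_network(list(
    v1 = list(stoichiometry = c(S_ext = -1, A = 1), measured = TRUE),
    v2 = list(stoichiometry = c(A = -1, P_ext = 1), measured = TRUE),
    v3 = list(stoichiometry = c(A = -1, Q_ext = 1), measured = TRUE)
  ), external = c("S_ext", "P_ext", "Q_ext"))
}

# Linear chain A -> B -> C with only the uptake measured (determined).
toy_chain_network <- function() {
  stoich_network(list(
    uptake = list(stoichiometry = c(A_ext = -1, B = 1), measured = TRUE),
    mid = list(stoichiometry = c(B = -1, C = 1), measured = FALSE),
    out = list(stoichiometry = c(C = -1, D_ext = 1), measured = FALSE)
  ), external = c("A_ext", "D_ext"))
}

# Random small overdetermined network with full-column-rank A_e and at
# least one redundancy; returns the network plus the raw blocks for
# oracle computations.
rand_overdetermined_network <- function() {
  repeat {
    m <- sample(3:8, 1)
    n <- m + sample(2:4, 1)
    A <- matrix(sample(-2:2, m * n, replace = TRUE,
                       prob = c(.1, .15, .3, .3, .15)), m, n)
    colnames(A) <- paste0("v", 1:n)
    rownames(A) <- paste0("M", 1:m)
    nm <- sample(2:(n - 1), 1)
    meas <- sort(sample(n, nm))
    Am <- A[, meas, drop = FALSE]
    Ae <- A[, -meas, drop = FALSE]
    cols_ok <- all(colSums(A != 0) > 0)
    dof <- n - qr(A)$rank
    if (cols_ok && nm > dof && ncol(Ae) > 0 &&
        qr(Ae)$rank == ncol(Ae) &&
        qr(cbind(Am, Ae))$rank - qr(Ae)$rank > 0) break
  }
  rx <- lapply(1:n, function(j) {
    st <- A[, j]; st <- st[st != 0]
    list(stoichiometry = st, measured = j %in% meas)
  })
  names(rx) <- paste0("v", 1:n)
  list(net = stoich_network(rx), A = A, A_m = Am, A_e = Ae,
       measured = paste0("v", meas),
       unmeasured = paste0("v", setdiff(1:n, meas)))
}

# Fluxome table with a target exactly linear in chosen predictors.
linear_fluxome <- function(n = 12, p = 5, coefs = c(2, -1),
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- drop(scale(X[, seq_along(coefs), drop = FALSE]) %*% coefs) +
    rnorm(n, 0, noise_sd)
  fluxome_table(X, y)
}
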