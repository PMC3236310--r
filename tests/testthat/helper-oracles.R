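# Independent oracles: brute-force or closed-form routes that never call
# the implementation paths they check.

# Weighted balancing by direct minimization over the null space of the
# full stoichiometric matrix: minimize (v_m - adj)' Sigma^-1 (v_m - adj)
# subject to [A_m A_e] %*% c(adj, v_e) = 0.
oracle_weighted_balance <- function(A_m, A_e, v_m, sds) {
  M <- cbind(A_m, A_e)
  s <- svd(M, nv = ncol(M))
  r <- sum(s$d > max(dim(M)) * .Machine$double.eps * max(s$d))
  N <- s$v[, (r + 1):ncol(M), drop = FALSE]
  nm <- ncol(A_m)
  Nm <- N[1:nm, , drop = FALSE]
  Ne <- N[-(1:nm), , drop = FALSE]
  Sinv <- diag(1 / sds^2, nm)
  beta <- solve(t(Nm) %*% Sinv %*% Nm, t(Nm) %*% Sinv %*% v_m)
  adj <- drop(Nm %*% beta)
  v_e <- drop(Ne %*% beta)
  names(adj) <- colnames(A_m)
  names(v_e) <- colnames(A_e)
  list(v_m_adj = adj, v_e = v_e,
       h = drop(t(v_m - adj) %*% Sinv %*% (v_m - adj)))
}

# Normal-equations solution of the unweighted estimation.
oracle_normal_equations <- function(A_m, A_e, v_m) {
  drop(solve(crossprod(A_e), -crossprod(A_e, A_m %*% v_m)))
}

# Brute-force agglomerative clustering from the full distance matrix.
# Returns merge heights in merge order for single/complete/average linkage.
oracle_linkage_heights <- function(D, method = "single") {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(ci, cj) {
    d <- D[ci, cj, drop = FALSE]
    switch(method, single = min(d), complete = max(d), average = mean(d))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- link(clusters[[i]], clusters[[j]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Cophenetic distances by explicit lowest-common-merge heights.
oracle_cophenetic <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  C <- matrix(0, n, n)
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    grp <- lapply(kids, function(j) if (j < 0) -j else members[[j]])
    for (a in grp[[1]]) for (b in grp[[2]])
      C[a, b] <- C[b, a] <- hc$height[k]
    members[[k]] <- unlist(grp)
  }
  stats::as.dist(C)
}

# Inconsistency by explicit depth-limited traversal, written against the
# definition rather than sharing the package's recursion.
oracle_inconsistency <- function(hc, depth = 2) {
  m <- hc$merge
  sapply(seq_len(nrow(m)), function(k) {
    frontier <- k
    collected <- integer(0)
    for (lev in seq_len(depth)) {
      collected <- c(collected, frontier)
      frontier <- unlist(lapply(frontier, function(kk) {
        kids <- m[kk, ]
        kids[kids > 0]
      }))
      if (length(frontier) == 0) break
    }
    hs <- hc$height[collected]
    if (length(hs) < 2 || stats::sd(hs) == 0) return(0)
    (hc$height[k] - mean(hs)) / stats::sd(hs)
  })
}
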