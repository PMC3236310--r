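test_that("the hand-computable node balances exactly", {
  prob <- mfa_problem(toy_node_network(), c(v1 = 10, v2 = 6, v3 = 5),
                      sigma = 1)
  R <- redundancy_matrix(prob)
  expect_equal(nrow(R), 1)
  # one row proportional to the node balance v1 - v2 - v3
  expect_equal(R[1, ] / R[1, "v1"], c(v1 = 1, v2 = -1, v3 = -1),
               tolerance = 1e-12)
  res <- balance_and_test(prob)
  expect_equal(res$h, 1 / 3, tolerance = 1e-12)
  expect_equal(unname(res$v_m_adj), c(31, 17, 14) / 3, tolerance = 1e-12)
  # adjusted balance closes exactly
  expect_lt(abs(res$v_m_adj["v1"] - res$v_m_adj["v2"] - res$v_m_adj["v3"]),
            1e-12)
})

test_that("unweighted solve matches the normal-equations oracle", {
  set.seed(101)
  for (i in 1:8) {
    fix <- rand_overdetermined_network()
    v_m <- rnorm(length(fix$measured), 5, 2)
    names(v_m) <- fix$measured
    prob <- mfa_problem(fix$net, v_m, sigma = 1)
    v_e <- solve_unweighted(prob)
    oracle <- oracle_normal_equations(fix$A_m, fix$A_e, v_m[colnames(fix$A_m)])
    expect_equal(unname(v_e[colnames(fix$A_e)]), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("weighted balancing matches the brute-force null-space oracle", {
  set.seed(202)
  for (i in 1:8) {
    fix <- rand_overdetermined_network()
    nm <- length(fix$measured)
    v_m <- rnorm(nm, 5, 2)
    names(v_m) <- fix$measured
    sds <- runif(nm, 0.5, 2)
    prob <- mfa_problem(fix$net, v_m, sigma = setNames(sds, fix$measured))
    res <- balance_and_test(prob)
    oracle <- oracle_weighted_balance(fix$A_m, fix$A_e,
                                      v_m[colnames(fix$A_m)], sds)
    scale <- max(abs(unlist(oracle)))
    expect_lt(abs(res$h - oracle$h) / scale, 1e-8)
    expect_lt(max(abs(res$v_m_adj - oracle$v_m_adj[names(res$v_m_adj)])) /
                scale, 1e-8)
    expect_lt(max(abs(res$v_e - oracle$v_e[names(res$v_e)])) / scale, 1e-8)
  }
})

test_that("redundancy rows annihilate A_e and adjusted measurements", {
  set.seed(303)
  for (i in 1:5) {
    fix <- rand_overdetermined_network()
    v_m <- setNames(rnorm(length(fix$measured), 5, 2), fix$measured)
    prob <- mfa_problem(fix$net, v_m)
    R <- redundancy_matrix(prob)
    # the projector behind R annihilates every column of A_e
    P_perp <- diag(nrow(prob$A_e)) -
      prob$A_e %*% fluxpls:::pinv(prob$A_e)
    expect_lt(max(abs(P_perp %*% prob$A_e)), 1e-9 * max(abs(prob$A_e)))
    # and R v_m vanishes for measurements consistent with a steady state
    v_full <- oracle_weighted_balance(prob$A_m, prob$A_e,
                                      prob$v_m, rep(1, length(prob$v_m)))
    expect_lt(max(abs(R %*% v_full$v_m_adj)), 1e-9 * max(1, max(abs(v_m))))
    res <- balance_and_test(prob)
    expect_lt(max(abs(R %*% res$v_m_adj)), 1e-9 * max(1, max(abs(v_m))))
  }
})

test_that("determined systems need no adjustment", {
  net <- toy_chain_network()
  prob <- mfa_problem(net, c(uptake = 10))
  res <- balance_and_test(prob)
  expect_equal(res$h, 0)
  expect_equal(res$redundancy_dof, 0)
  expect_equal(res$v_m_adj, prob$v_m)
  expect_equal(unname(res$v_e), c(10, 10), tolerance = 1e-12)
  expect_true(res$consistent)
})

test_that("chi-squared critical values at 95% match tabulated values", {
  # redundancy 3: fully measured 4-reaction chain; redundancy 4: 5-reaction
  for (k in c(3, 4)) {
    net <- generate_network("chain", k + 1)
    net$measured[] <- TRUE
    for (id in names(net$reactions)) net$reactions[[id]]$measured <- TRUE
    v <- setNames(rep(10, k + 1), net$flux_ids)
    res <- balance_and_test(mfa_problem(net, v))
    expect_equal(res$redundancy_dof, k)
    expect_equal(round(res$chi2_critical, 1), c(`3` = 7.8, `4` = 9.5)[[as.character(k)]])
  }
})

test_that("h is invariant when a measurement is rescaled with its variance", {
  prob <- mfa_problem(toy_node_network(), c(v1 = 10, v2 = 6, v3 = 5),
                      sigma = c(v1 = 1, v2 = 2, v3 = 0.5))
  h0 <- balance_and_test(prob)$h
  # express v2 in different units (x10): scale its column, value and sd
  net <- toy_node_network()
  net$reactions$v2$stoichiometry <- c(A = -0.1, P_ext = 0.1)
  net2 <- stoich_network(net$reactions, external = net$external)
  prob2 <- mfa_problem(net2, c(v1 = 10, v2 = 60, v3 = 5),
                       sigma = c(v1 = 1, v2 = 20, v3 = 0.5))
  expect_equal(balance_and_test(prob2)$h, h0, tolerance = 1e-10)
})

test_that("uniform-variance weighting agrees with unweighted solve on adjusted data", {
  set.seed(404)
  fix <- rand_overdetermined_network()
  v_m <- setNames(rnorm(length(fix$measured), 5, 2), fix$measured)
  prob <- mfa_problem(fix$net, v_m, sigma = 2)
  res <- balance_and_test(prob)
  expect_equal(res$v_e, solve_unweighted(prob, res$v_m_adj),
               tolerance = 1e-10)
})

test_that("omitting a measurement re-partitions and estimates it", {
  net <- toy_node_network()
  v <- c(v1 = 10, v2 = 6, v3 = 5)
  sc <- scenario_omit_measurement(net, v, "v3", sigma = 1)
  expect_equal(sc$estimated_value, 4, tolerance = 1e-10)
  expect_equal(sc$measured_value, 5)
  expect_equal(sc$result$redundancy_dof, 0)  # was 1, drops by 1
  # re-adding restores the original classification (involution)
  expect_equal(classify_system(net)$category, "overdetermined")
  # omission that breaks determinacy errors
  net2 <- toy_chain_network()
  expect_error(scenario_omit_measurement(net2, c(uptake = 10), "uptake"),
               "underdetermined")
})

test_that("deleting a parallel reaction member redistributes its flux", {
  # 4-flux toy: S -> A (measured), A -> B twice (one measured), B -> P
  net <- stoich_network(list(
    v1 = list(stoichiometry = c(S_ext = -1, A = 1), measured = TRUE),
    v2 = list(stoichiometry = c(A = -1, B = 1), measured = FALSE),
    v3 = list(stoichiometry = c(A = -1, B = 1), measured = TRUE),
    v4 = list(stoichiometry = c(B = -1, P_ext = 1), measured = TRUE)
  ), external = c("S_ext", "P_ext"))
  v <- c(v1 = 10, v3 = 3, v4 = 10)
  base <- balance_and_test(mfa_problem(net, v, sigma = 1))
  expect_equal(unname(base$v_e["v2"]), 7, tolerance = 1e-10)
  sc <- scenario_delete_reactions(net, v, "v3", sigma = 1)
  # the surviving member absorbs the pair's total flux
  expect_equal(unname(sc$result$v_e["v2"]),
               unname(base$v_e["v2"]) + v[["v3"]], tolerance = 1e-8)
  expect_gt(sc$fluxome_change, 0)
})

test_that("deleting reactions that orphan a metabolite warns and drops the row", {
  net <- toy_chain_network()
  expect_warning(
    sc <- scenario_delete_reactions(net, c(uptake = 10), c("mid", "out")),
    "orphaned")
})

test_that("rank-deficient A_e is reported with the unidentifiable combination", {
  net <- stoich_network(list(
    v1 = list(stoichiometry = c(S_ext = -1, A = 1), measured = TRUE),
    v2 = list(stoichiometry = c(A = -1, P_ext = 1), measured = FALSE),
    v3 = list(stoichiometry = c(A = -1, P_ext = 1), measured = FALSE)
  ), external = c("S_ext", "P_ext"))
  prob <- mfa_problem(net, c(v1 = 10))
  expect_error(solve_unweighted(prob), "rank deficient.*v2.*v3")
})

test_that("consistent simulated data are rejected at the nominal 5% rate", {
  set.seed(505)
  n_rep <- 2000
  net <- toy_node_network()
  cv <- 0.16
  rejected <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    v2 <- 6; v3 <- 5; v1 <- v2 + v3
    true <- c(v1 = v1, v2 = v2, v3 = v3)
    obs <- true + cv * abs(true) * rnorm(3)
    res <- balance_and_test(mfa_problem(net, obs, sigma = cv * abs(true)))
    rejected[r] <- !res$consistent
  }
  expect_gt(mean(rejected), 0.02)
  expect_lt(mean(rejected), 0.08)
})
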