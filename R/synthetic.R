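#' Generate a fixture network
#'
#' Builds small steady-state-consistent networks with a measured-flag
#' preset that makes the flux-estimation system overdetermined, so the
#' whole estimation/regression pipeline can be exercised on them.
#'
#' Templates:
#' \describe{
#'   \item{chain}{linear pathway `S_ext -> M1 -> ... -> P_ext` with `size`
#'     reactions; uptake and excretion measured (one redundancy).}
#'   \item{branched}{a hub metabolite feeding `size` independent branches
#'     `Hub -> M_i -> P_i_ext`; uptake and all branch exits measured (one
#'     redundancy, `size` estimated intracellular fluxes).}
#'   \item{cycle}{a `size`-membered conservation-free cycle with an uptake
#'     into the cycle and a respiration-like exit branch; uptake, exit and
#'     one cycle edge measured (the cycle flux itself is unobservable from
#'     exchange rates alone).}
#'   \item{cofactor}{the branched template with 3 branches, an NADH/NAD
#'     pair reduced by the first branch and re-oxidized by a
#'     respiration-like reaction, adding exactly one conservation
#'     relation.}
#' }
#'
#' @param template one of `"chain"`, `"branched"`, `"cycle"`,
#'   `"cofactor"`.
#' @param size template size (reactions in the chain, branches, or cycle
#'   length); defaults per template.
#' @return a [stoich_network()].
#' @export
generate_network <- function(template = c("chain", "branched", "cycle",
                                          "cofactor"), size = NULL) {
  template <- match.arg(template)
  rx <- function(st, measured = FALSE)
    list(stoichiometry = st, reversible = FALSE, measured = measured)
  reactions <- switch(template,
    chain = {
      n <- if (is.null(size)) 3L else as.integer(size)
      if (n < 2) stop("chain needs size >= 2")
      mets <- paste0("M", seq_len(n - 1))
      r <- list()
      r[["uptake"]] <- rx(c(S_ext = -1, stats::setNames(1, mets[1])),
                          measured = TRUE)
      if (n > 2) for (i in seq_len(n - 2))
        r[[paste0("v", i)]] <- rx(stats::setNames(c(-1, 1),
                                                  mets[c(i, i + 1)]))
      r[["excretion"]] <- rx(c(stats::setNames(-1, mets[n - 1]), P_ext = 1),
                             measured = TRUE)
      r
    },
    branched = {
      k <- if (is.null(size)) 10L else as.integer(size)
      if (k < 2) stop("branched needs size >= 2")
      r <- list(uptake = rx(c(S_ext = -1, Hub = 1), measured = TRUE))
      for (i in seq_len(k)) {
        mi <- paste0("M", i)
        r[[paste0("a", i)]] <- rx(stats::setNames(c(-1, 1), c("Hub", mi)))
        r[[paste0("b", i)]] <- rx(stats::setNames(c(-1, 1),
                                                  c(mi, paste0("P", i, "_ext"))),
                                  measured = TRUE)
      }
      r
    },
    cycle = {
      m <- if (is.null(size)) 6L else as.integer(size)
      if (m < 4) stop("cycle needs size >= 4")
      r <- list(uptake = rx(c(S_ext = -1, C1 = 1), measured = TRUE))
      for (i in seq_len(m)) {
        from <- paste0("C", i); to <- paste0("C", if (i < m) i + 1 else 1)
        r[[paste0("c", i)]] <- rx(stats::setNames(c(-1, 1), c(from, to)),
                                  measured = i == 2)
      }
      r[["resp"]] <- rx(c(C3 = -1, CO2_ext = 1), measured = TRUE)
      r
    },
    cofactor = {
      k <- if (is.null(size)) 3L else as.integer(size)
      if (k < 2) stop("cofactor needs size >= 2")
      r <- list(uptake = rx(c(S_ext = -1, Hub = 1), measured = TRUE))
      for (i in seq_len(k)) {
        mi <- paste0("M", i)
        st_a <- stats::setNames(c(-1, 1), c("Hub", mi))
        if (i == 1) st_a <- c(st_a, NAD = -1, NADH = 1)
        r[[paste0("a", i)]] <- rx(st_a)
        r[[paste0("b", i)]] <- rx(
          stats::setNames(c(-1, 1), c(mi, paste0("P", i, "_ext"))),
          measured = TRUE)
      }
      # respiration-like recycler keeps NADH/NAD the only conserved pair
      r[["resp"]] <- rx(c(NADH = -1, NAD = 1, RQ_ext = 1))
      r
    })
  ext <- unique(unlist(lapply(reactions, function(r)
    grep("_ext$", names(r$stoichiometry), value = TRUE))))
  stoich_network(reactions, external = ext)
}

#' Simulation specification
#'
#' Describes a synthetic multi-culture study: each culture gets a steady-
#' state true fluxome drawn from the network's flux space (cultures differ
#' mainly in flux partitioning, as supplementation experiments do), and the
#' productivity target is a noisy linear function of a known subset of
#' standardized driver fluxes. Error magnitudes default to 16% on measured
#' fluxes and 22% on the target.
#'
#' @param template network template name (see [generate_network()]).
#' @param size template size.
#' @param n_cultures number of cultures (default 15, >= 3).
#' @param driver_fluxes flux ids whose (standardized) true values drive the
#'   target; defaults to the first two intracellular fluxes of the
#'   template.
#' @param driver_effects standardized effect sizes, same length as
#'   `driver_fluxes` (default `c(1.5, 1)`).
#' @param cv_flux relative measurement error on measured fluxes (0.16).
#' @param cv_target relative error on the target (0.22).
#' @param seed integer seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(template = "branched", size = 10,
                            n_cultures = 15, driver_fluxes = NULL,
                            driver_effects = c(1.5, 1), cv_flux = 0.16,
                            cv_target = 0.22, seed = 1L) {
  if (n_cultures < 3) stop("need at least 3 cultures")
  if (is.null(driver_fluxes))
    driver_fluxes <- switch(template,
      branched = , cofactor = c("a1", "a2"),
      chain = "uptake",
      cycle = c("c1", "uptake"))
  if (length(driver_effects) != length(driver_fluxes))
    stop("driver_effects must match driver_fluxes in length")
  structure(list(template = template, size = size,
                 n_cultures = as.integer(n_cultures),
                 driver_fluxes = driver_fluxes,
                 driver_effects = driver_effects,
                 cv_flux = cv_flux, cv_target = cv_target,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Draw one steady-state-exact true flux vector per culture. Free fluxes
# (the coordinates of the network's flux space) are sampled log-normally
# so all rates stay positive and cultures vary mainly in partitioning.
sample_true_fluxes <- function(net, spec) {
  n <- spec$n_cultures
  ln <- function(mu, sdlog, n) stats::rlnorm(n, meanlog = log(mu),
                                             sdlog = sdlog)
  V <- switch(spec$template,
    chain = {
      f <- ln(10, 0.4, n)
      matrix(f, n, length(net$flux_ids),
             dimnames = list(NULL, net$flux_ids))
    },
    branched = , cofactor = {
      k <- sum(startsWith(net$flux_ids, "a"))
      b <- matrix(ln(10, 0.5, n * k), n, k)
      V <- cbind(rowSums(b),
                 b[, rep(seq_len(k), each = 2)])
      # columns: uptake, a1, b1, a2, b2, ...
      colnames(V) <- c("uptake",
                       as.vector(rbind(paste0("a", seq_len(k)),
                                       paste0("b", seq_len(k)))))
      if ("resp" %in% net$flux_ids)       # cofactor recycling runs at a1
        V <- cbind(V, resp = V[, "a1"])
      V[, net$flux_ids, drop = FALSE]
    },
    cycle = {
      m <- sum(startsWith(net$flux_ids, "c") &
                 net$flux_ids != "uptake")
      u <- ln(10, 0.4, n)
      w0 <- ln(5, 0.5, n)
      V <- matrix(0, n, length(net$flux_ids),
                  dimnames = list(NULL, net$flux_ids))
      V[, "uptake"] <- u
      V[, "resp"] <- u
      V[, "c1"] <- u + w0
      V[, "c2"] <- u + w0
      for (i in 3:m) V[, paste0("c", i)] <- w0
      V
    },
    stop("unknown template: ", spec$template))
  rownames(V) <- as.character(seq_len(n))
  V
}

#' Simulate a multi-culture dataset
#'
#' Draws exact steady-state true fluxomes, computes the true target as a
#' linear combination of standardized driver fluxes, then emits measured
#' fluxes and the target with multiplicative Gaussian noise at the
#' specified CVs. The ground truth is always returned (and written, when
#' `dir` is given) next to the observed data.
#'
#' @param net a network from [generate_network()] matching
#'   `spec$template`.
#' @param spec a [simulation_spec()].
#' @param dir optional output directory; when given, writes
#'   `measurements_seed<seed>.csv` and `truth_seed<seed>.csv`.
#' @return list: `measurements` (data.frame `culture_id`, one column per
#'   measured flux, `target`), `truth` (all true fluxes plus the noise-free
#'   `target_true`), `net`, `spec`, and file `paths` when written.
#' @export
simulate_cultures <- function(net, spec, dir = NULL) {
  set.seed(spec$seed)
  V <- sample_true_fluxes(net, spec)
  # steady state must be exact by construction
  resid <- max(abs(net$matrix %*% t(V)))
  if (resid > 1e-8 * max(abs(V)))
    stop("internal error: sampled fluxes violate steady state")
  missing <- setdiff(spec$driver_fluxes, net$flux_ids)
  if (length(missing) > 0)
    stop("driver flux(es) not in network: ", paste(missing, collapse = ", "))
  Z <- scale(V[, spec$driver_fluxes, drop = FALSE])
  if (anyNA(Z)) stop("infeasible spec: a driver flux has no variation")
  t_det <- drop(Z %*% spec$driver_effects)
  t_obs <- t_det + spec$cv_target * abs(t_det) * stats::rnorm(nrow(V))
  meas_ids <- net$flux_ids[net$measured]
  Vm <- V[, meas_ids, drop = FALSE]
  Vm_obs <- Vm * (1 + spec$cv_flux * matrix(stats::rnorm(length(Vm)),
                                            nrow(Vm)))
  measurements <- data.frame(culture_id = rownames(V), Vm_obs,
                             target = t_obs, check.names = FALSE,
                             stringsAsFactors = FALSE)
  truth <- data.frame(culture_id = rownames(V), V, target_true = t_det,
                      check.names = FALSE, stringsAsFactors = FALSE)
  out <- list(measurements = measurements, truth = truth, net = net,
              spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mp <- file.path(dir, sprintf("measurements_seed%d.csv", spec$seed))
    tp <- file.path(dir, sprintf("truth_seed%d.csv", spec$seed))
    utils::write.csv(measurements, mp, row.names = FALSE)
    utils::write.csv(truth, tp, row.names = FALSE)
    out$paths <- c(measurements = mp, truth = tp)
  }
  out
}
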