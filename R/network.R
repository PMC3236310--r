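# Default tolerance used everywhere a numerical rank is needed: singular
# values below max(dim) * eps * sigma_max are treated as zero.
rank_tolerance <- function(A, tol = NULL) {
  if (!is.null(tol)) return(tol)
  d <- svd(A, nu = 0, nv = 0)$d
  if (length(d) == 0 || max(d) == 0) return(.Machine$double.eps)
  max(dim(A)) * .Machine$double.eps * max(d)
}

#' Numerical matrix rank by singular-value thresholding
#'
#' @param A numeric matrix.
#' @param tol zero threshold for singular values; default
#'   `max(dim(A)) * eps * max(singular values)`.
#' @return integer rank.
#' @export
matrix_rank <- function(A, tol = NULL) {
  if (length(A) == 0) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > rank_tolerance(A, tol))
}

# Moore-Penrose pseudo-inverse with the same singular-value threshold as
# matrix_rank, so rank decisions and solves never disagree.
pinv <- function(A, tol = NULL) {
  if (length(A) == 0) return(t(A))
  s <- svd(A)
  keep <- s$d > rank_tolerance(A, tol)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Construct a stoichiometric network
#'
#' A network holds the stoichiometric matrix over *balanced* (intracellular)
#' metabolites only; external metabolites are recorded but excluded from the
#' steady-state balances (pseudo-steady-state assumption).
#'
#' @param reactions named list of reactions; each is a list with fields
#'   `stoichiometry` (named numeric: negative = consumed, positive =
#'   produced, external species included), `reversible`, `measured`.
#' @param external character vector of external metabolite labels.
#' @return object of class `stoich_network` with elements `matrix`
#'   (balanced metabolites x fluxes), `metabolites`, `flux_ids`, `measured`
#'   (named logical), `reversible`, `external`, `reactions`.
#' @export
stoich_network <- function(reactions, external = character()) {
  ids <- names(reactions)
  if (is.null(ids) || anyDuplicated(ids))
    stop("reaction ids must be unique and named")
  for (id in ids) {
    st <- reactions[[id]]$stoichiometry
    if (length(st) == 0 || all(st == 0))
      stop("reaction '", id, "' has no nonzero coefficient")
  }
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  balanced <- setdiff(mets, external)
  A <- matrix(0, nrow = length(balanced), ncol = length(ids),
              dimnames = list(balanced, ids))
  for (j in seq_along(ids)) {
    st <- reactions[[ids[j]]]$stoichiometry
    keep <- intersect(names(st), balanced)
    A[keep, j] <- st[keep]
  }
  structure(list(
    matrix      = A,
    metabolites = balanced,
    flux_ids    = ids,
    measured    = vapply(reactions, function(r) isTRUE(r$measured), logical(1)),
    reversible  = vapply(reactions, function(r) isTRUE(r$reversible), logical(1)),
    external    = external,
    reactions   = reactions
  ), class = "stoich_network")
}

#' @export
print.stoich_network <- function(x, ...) {
  cat("Stoichiometric network:", length(x$flux_ids), "fluxes,",
      length(x$metabolites), "balanced metabolites,",
      length(x$external), "external species\n")
  cat("  measured fluxes:", sum(x$measured), "\n")
  invisible(x)
}

parse_equation <- function(eq, line_no = NA) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else if
    (grepl("->", eq, fixed = TRUE)) "->" else
    stop("cannot parse equation (no '->' or '<->') at line ", line_no, ": ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("cannot parse equation at line ", line_no, ": ", eq)
  term_coefs <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(); nm <- character()
    for (tm in terms) {
      if (tm == "") stop("empty term in equation at line ", line_no, ": ", eq)
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1) { coef <- 1; met <- parts[1] }
      else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop("bad coefficient '", parts[1], "' at line ", line_no, ": ", eq)
        met <- parts[2]
      } else stop("cannot parse term '", tm, "' at line ", line_no, ": ", eq)
      out <- c(out, sign * coef); nm <- c(nm, met)
    }
    names(out) <- nm
    out
  }
  lhs <- term_coefs(sides[1], -1)
  rhs <- term_coefs(sides[2], +1)
  st <- tapply(c(lhs, rhs), names(c(lhs, rhs)), sum)
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<->")
}

#' Parse a reaction network file
#'
#' Two dialects are supported. The reaction-table dialect (`"tsv"`) has one
#' reaction per line, `id<TAB>equation<TAB>measured(true|false)`, with `#`
#' comments; external metabolites carry an `_ext` suffix or appear on an
#' `@external` header line (`@external M1 M2 ...`). The matrix dialect
#' (`"matrix"`) is a CSV with flux ids as the header, metabolite ids in the
#' first column, and a final `__measured__` row of 0/1 flags.
#'
#' @param path file path.
#' @param dialect `"auto"` (default, by extension/content), `"tsv"` or
#'   `"matrix"`.
#' @return a [stoich_network()].
#' @export
parse_network <- function(path, dialect = c("auto", "tsv", "matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl(",", first) && !grepl("\t", first)) "matrix" else "tsv"
  }
  if (dialect == "matrix") return(parse_network_matrix(path))
  lines <- readLines(path)
  external <- character()
  reactions <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "@external")) {
      rest <- sub("^@external:?[[:space:]]*", "", ln)
      external <- c(external, strsplit(rest, "[,[:space:]]+")[[1]])
      next
    }
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop("expected 'id<TAB>equation[<TAB>measured]' at line ", i)
    id <- trimws(fields[1])
    if (id %in% names(reactions))
      stop("duplicate reaction id '", id, "' at line ", i)
    parsed <- parse_equation(fields[2], line_no = i)
    measured <- length(fields) >= 3 &&
      tolower(trimws(fields[3])) %in% c("true", "1", "yes")
    reactions[[id]] <- list(stoichiometry = parsed$stoichiometry,
                            reversible = parsed$reversible,
                            measured = measured)
  }
  if (length(reactions) == 0) stop("no reactions found in ", path)
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  external <- unique(c(external, mets[endsWith(mets, "_ext")]))
  for (id in names(reactions)) {
    st <- reactions[[id]]$stoichiometry
    if (all(names(st) %in% external))
      warning("reaction '", id, "' touches only external metabolites")
  }
  stoich_network(reactions, external = external)
}

parse_network_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  mrow <- which(rn == "__measured__")
  if (length(mrow) != 1) stop("matrix dialect requires a final '__measured__' row")
  measured <- as.numeric(vals[mrow, ]) != 0
  A <- vals[-mrow, , drop = FALSE]
  storage.mode(A) <- "double"
  rownames(A) <- rn[-mrow]
  reactions <- lapply(seq_len(ncol(A)), function(j) {
    st <- stats::setNames(as.numeric(A[, j]), rownames(A))
    st <- st[st != 0]
    list(stoichiometry = st, reversible = FALSE, measured = measured[j])
  })
  names(reactions) <- colnames(A)
  stoich_network(reactions)
}

#' Serialize a network to the reaction-table dialect
#'
#' Writing then re-parsing reproduces the stoichiometric matrix, labels and
#' measured flags exactly.
#'
#' @param net a [stoich_network()].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  lines <- character()
  if (length(net$external) > 0)
    lines <- paste("@external", paste(net$external, collapse = " "))
  fmt_side <- function(st) {
    paste(vapply(names(st), function(m) {
      if (st[m] == 1) m else paste(format(st[m], digits = 15), m)
    }, character(1)), collapse = " + ")
  }
  for (id in net$flux_ids) {
    r <- net$reactions[[id]]
    st <- r$stoichiometry
    lhs <- -st[st < 0]; rhs <- st[st > 0]
    arrow <- if (isTRUE(r$reversible)) "<->" else "->"
    eq <- paste(fmt_side(lhs), arrow, fmt_side(rhs))
    lines <- c(lines, paste(id, eq,
                            ifelse(net$measured[[id]], "true", "false"),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Conservation relations (left null space of the stoichiometric matrix)
#'
#' Conserved moieties such as NADH + NAD+ give weighted metabolite sums
#' invariant under every reaction; each reduces the rank of the balance
#' system by one.
#'
#' @param net a [stoich_network()].
#' @param tol rank tolerance, see [matrix_rank()].
#' @return list with `basis` (metabolites x n_relations orthonormal matrix,
#'   each column y satisfying t(y) %*% A = 0) and `count`.
#' @export
conservation_relations <- function(net, tol = NULL) {
  A <- net$matrix
  if (length(A) == 0) stop("empty stoichiometric matrix")
  s <- svd(A, nu = nrow(A))
  r <- sum(s$d > rank_tolerance(A, tol))
  k <- nrow(A) - r
  basis <- if (k > 0) s$u[, (r + 1):nrow(A), drop = FALSE] else
    matrix(0, nrow(A), 0)
  rownames(basis) <- net$metabolites
  list(basis = basis, count = k)
}

#' Classify the determinacy of a flux-estimation system
#'
#' @param net a [stoich_network()] with measured flags set.
#' @param tol rank tolerance.
#' @return list of class `system_classification`: `n_fluxes`, `rank`
#'   (independent balances), `n_conservation`, `dof` (degrees of freedom =
#'   fluxes - rank), `n_measured`, `n_redundant`, and `category` in
#'   underdetermined / determined / overdetermined.
#' @export
classify_system <- function(net, tol = NULL) {
  if (all(!net$measured) && length(net$measured) > 0)
    stop("no measured flags set on any flux")
  A <- net$matrix
  r <- matrix_rank(A, tol)
  n_cons <- nrow(A) - r
  dof <- ncol(A) - r
  n_meas <- sum(net$measured)
  part <- partition_network(net)
  Ae_full_rank <- ncol(part$A_e) == 0 ||
    matrix_rank(part$A_e, tol) == ncol(part$A_e)
  n_red <- max(0L, n_meas - dof)
  category <- if (!Ae_full_rank || n_meas < dof) "underdetermined"
    else if (n_meas == dof) "determined" else "overdetermined"
  structure(list(n_fluxes = ncol(A), rank = r, n_conservation = n_cons,
                 dof = dof, n_measured = n_meas, n_redundant = n_red,
                 category = category),
            class = "system_classification")
}

#' @export
print.system_classification <- function(x, ...) {
  cat(sprintf(
    "%s system: %d fluxes, %d independent balances (%d conservation relations),\n  %d degrees of freedom, %d measured, %d redundant\n",
    x$category, x$n_fluxes, x$rank, x$n_conservation, x$dof, x$n_measured,
    x$n_redundant))
  invisible(x)
}

#' Partition the stoichiometric matrix into measured and unmeasured blocks
#'
#' @param net a [stoich_network()].
#' @return list with `A_m`, `A_e` (column blocks of the full matrix),
#'   `measured_ids`, `unmeasured_ids`. Reassembling the columns in the
#'   original order reproduces the full matrix.
#' @export
partition_network <- function(net) {
  m <- net$measured
  list(A_m = net$matrix[, m, drop = FALSE],
       A_e = net$matrix[, !m, drop = FALSE],
       measured_ids = net$flux_ids[m],
       unmeasured_ids = net$flux_ids[!m])
}
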