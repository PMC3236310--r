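#' Hierarchically cluster meaningful fluxes
#'
#' Clusters fluxes in the two-dimensional (regression coefficient,
#' confidence half-width) plane with Euclidean distances, so fluxes sharing
#' both the strength and the precision of their association with the target
#' group together. Coordinates are used raw by default: both axes live in
#' the same standardized-coefficient units.
#'
#' @param stats a [confidence_and_alpha()] table (or any data.frame with
#'   `flux_id`, `B`, `ci_halfwidth`, `meaningful`).
#' @param linkage_method agglomeration method for [stats::hclust()]
#'   (default `"single"`).
#' @param only_meaningful cluster only the fluxes passing the alpha filter
#'   (default TRUE).
#' @param scale_coords standardize the two coordinates before computing
#'   distances (default FALSE).
#' @param inconsistency_depth neighbourhood depth for
#'   [inconsistency_coefficients()] (default 2).
#' @return object of class `flux_clustering`: `hclust`, `dist`, `coords`,
#'   `cophenetic_c`, `inconsistency`, `method`.
#' @export
cluster_fluxes <- function(stats, linkage_method = "single",
                           only_meaningful = TRUE, scale_coords = FALSE,
                           inconsistency_depth = 2) {
  s <- if (only_meaningful) stats[stats$meaningful, , drop = FALSE] else stats
  if (nrow(s) < 2)
    stop("need at least 2 fluxes to cluster (got ", nrow(s), ")")
  coords <- cbind(B = s$B, ci = s$ci_halfwidth)
  rownames(coords) <- s$flux_id
  if (!all(is.finite(coords))) stop("non-finite clustering coordinates")
  if (scale_coords) coords <- scale(coords)
  d <- stats::dist(coords, method = "euclidean")
  hc <- stats::hclust(d, method = linkage_method)
  structure(list(hclust = hc, dist = d, coords = coords,
                 cophenetic_c = cophenetic_correlation(hc, d),
                 inconsistency = inconsistency_coefficients(
                   hc, depth = inconsistency_depth),
                 method = linkage_method),
            class = "flux_clustering")
}

#' @export
print.flux_clustering <- function(x, ...) {
  cat(sprintf(
    "Flux clustering (%s linkage): %d fluxes, cophenetic c = %.3f\n",
    x$method, length(x$hclust$order), x$cophenetic_c))
  invisible(x)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' dendrogram-implied (cophenetic) distances; values close to 1 indicate
#' the tree represents the data faithfully.
#'
#' @param hc an [stats::hclust()] tree.
#' @param d the original [stats::dist()] object.
#' @return correlation in [-1, 1], or `NA` (with a warning) when either
#'   distance vector has zero variance.
#' @export
cophenetic_correlation <- function(hc, d) {
  coph <- stats::cophenetic(hc)
  sd_d <- stats::sd(d); sd_c <- stats::sd(coph)
  if (length(d) < 2 || is.na(sd_d) || is.na(sd_c) || sd_d == 0 || sd_c == 0) {
    warning("zero variance in distances; cophenetic correlation undefined")
    return(NA_real_)
  }
  stats::cor(as.vector(d), as.vector(coph))
}

# Link indices (rows of hc$merge) reachable from link k by descending at
# most `depth` levels, counting k itself as level 1.
links_within_depth <- function(merge, k, depth) {
  if (depth == 0) return(integer())
  kids <- merge[k, ]
  below <- unlist(lapply(kids[kids > 0], links_within_depth,
                         merge = merge, depth = depth - 1))
  c(k, below)
}

#' Inconsistency coefficient per dendrogram link
#'
#' Compares the height of each link with the heights of the links in its
#' neighbourhood (the link itself plus sub-links within `depth` levels):
#' `I = (height - mean(neighbour heights)) / sd(neighbour heights)`, with
#' `I = 0` when the neighbourhood has a single link or zero spread. Large
#' values mark links that join much more distant groups than their
#' sub-structure, suggesting natural division points.
#'
#' @param hc an [stats::hclust()] tree.
#' @param depth neighbourhood depth (default 2).
#' @return numeric vector, one value per merge in `hc$merge` order.
#' @export
inconsistency_coefficients <- function(hc, depth = 2) {
  if (depth < 1) stop("depth must be >= 1")
  m <- hc$merge
  vapply(seq_len(nrow(m)), function(k) {
    hs <- hc$height[links_within_depth(m, k, depth)]
    if (length(hs) < 2) return(0)
    s <- stats::sd(hs)
    if (s == 0) 0 else (hc$height[k] - mean(hs)) / s
  }, numeric(1))
}

# Cluster assignment when links with inconsistency > threshold are cut:
# a node roots a cluster if no link in its subtree (itself included)
# exceeds the threshold and its parent does (or it has no parent).
cut_by_inconsistency <- function(hc, inconsistency, threshold) {
  m <- hc$merge
  n_links <- nrow(m)
  intact <- logical(n_links)
  for (k in seq_len(n_links)) {
    kids <- m[k, ]
    kids_ok <- all(intact[kids[kids > 0]])
    intact[k] <- kids_ok && inconsistency[k] <= threshold
  }
  n_leaves <- n_links + 1
  assign <- integer(n_leaves)
  cluster_id <- 0L
  leaves_of <- function(k) {
    kids <- m[k, ]
    unlist(lapply(kids, function(j) if (j < 0) -j else leaves_of(j)))
  }
  parent <- integer(n_links)
  for (k in seq_len(n_links))
    for (j in m[k, ]) if (j > 0) parent[j] <- k
  for (k in seq_len(n_links)) {
    is_root <- parent[k] == 0 || !intact[parent[k]]
    if (intact[k] && is_root) {
      cluster_id <- cluster_id + 1L
      assign[leaves_of(k)] <- cluster_id
    }
  }
  for (i in which(assign == 0)) {
    cluster_id <- cluster_id + 1L
    assign[i] <- cluster_id
  }
  names(assign) <- hc$labels
  assign
}

#' Survey natural divisions of the dendrogram
#'
#' Sweeps decreasing inconsistency thresholds and reports, for each, how
#' many clusters emerge and the smallest cluster size. A large jump in the
#' cluster count, together with the appearance of very small clusters,
#' suggests a natural division; the largest jump is flagged but the choice
#' of cut is left to the user.
#'
#' @param clustering a [cluster_fluxes()] result.
#' @return data.frame with columns `threshold`, `n_clusters`,
#'   `min_cluster_size`; attribute `flagged_threshold` marks the threshold
#'   after the largest discontinuity in cluster count (`NA` when the count
#'   never jumps by more than 1).
#' @export
natural_divisions <- function(clustering) {
  hc <- clustering$hclust
  I <- clustering$inconsistency
  thresholds <- sort(unique(I), decreasing = TRUE)
  rows <- lapply(thresholds, function(tau) {
    a <- cut_by_inconsistency(hc, I, tau)  # links with I <= tau stay intact
    data.frame(threshold = tau, n_clusters = max(a),
               min_cluster_size = min(table(a)))
  })
  out <- do.call(rbind, rows)
  jumps <- diff(out$n_clusters)
  flagged <- if (length(jumps) > 0 && max(jumps) > 1)
    out$threshold[which.max(jumps) + 1] else NA_real_
  structure(out, flagged_threshold = flagged)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights, so the tree can be
#' inspected in any phylogenetics viewer.
#'
#' @param clustering a [cluster_fluxes()] result (or an `hclust`).
#' @param path output file.
#' @export
export_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "flux_clustering")) clustering$hclust else
    clustering
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write the merge table as CSV
#'
#' @param clustering a [cluster_fluxes()] result.
#' @param path output file.
#' @export
write_linkage_csv <- function(clustering, path) {
  hc <- clustering$hclust
  df <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                   height = hc$height,
                   inconsistency = clustering$inconsistency)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
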