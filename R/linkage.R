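#' Two-point linkage statistics for all marker pairs
#'
#' For every pair of markers in a recoded (A/H) pseudo-testcross matrix:
#' N is the number of progeny typed at both, R the recombinant count with
#' the linkage phase chosen so that R <= N/2, rf = R/N, and the LOD score
#' is R log10(2 rhat) + (N - R) log10(2 (1 - rhat)) with
#' rhat = max(R/N, tiny), i.e. the base-10 likelihood ratio of linkage at
#' the estimate against free recombination.  Pairs with N = 0 are
#' reported unlinked (rf = 0.5, LOD = 0).  Computed with matrix
#' cross-products, so symmetric and invariant to individual order by
#' construction.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (recoded; any remaining "B"
#'   is treated as the homozygous class).
#' @param tiny floor for the recombination estimate inside the LOD (so a
#'   pair with R = 0 gets LOD = N log10 2).
#' @return a \linkS4class{PairwiseLinkage}.
#' @export
pairwiseLinkage <- function(gm, tiny = 1e-6) {
  g <- gm@geno
  typed <- !is.na(g)
  het <- typed & g == "H"
  X <- matrix(as.numeric(het), nrow(g))
  Tm <- matrix(as.numeric(typed), nrow(g))
  N <- tcrossprod(Tm)
  same <- tcrossprod(X) + tcrossprod(Tm - X)
  D <- N - same
  R <- pmin(D, N - D)
  rf <- ifelse(N > 0, R / N, 0.5)
  rhat <- pmax(ifelse(N > 0, R / N, 0.5), tiny)
  lod <- ifelse(N > 0,
                R * log10(2 * rhat) + (N - R) * log10(2 * (1 - rhat)),
                0)
  diag(lod) <- 0
  ids <- gm@markerInfo$marker_id
  dimnames(N) <- dimnames(R) <- dimnames(rf) <- dimnames(lod) <-
    list(ids, ids)
  new("PairwiseLinkage", markers = ids, N = N, R = R, rf = rf,
      lod = lod)
}

#' Assign markers to linkage groups
#'
#' Linkage groups are the connected components of the graph whose edges
#' join marker pairs with LOD at or above the threshold.  Singleton
#' components are reported separately.
#'
#' @param pl a \linkS4class{PairwiseLinkage}.
#' @param lodThreshold grouping threshold (default 7.0).
#' @return list with \code{groups}, a list of marker-id vectors ordered
#'   by decreasing size (ties by smallest member id), and
#'   \code{singletons}, ids linked to nothing.
#' @export
groupMarkers <- function(pl, lodThreshold = 7) {
  adj <- pl@lod >= lodThreshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  members <- split(pl@markers, comp$membership)
  sizes <- lengths(members)
  single <- sort(unlist(members[sizes == 1], use.names = FALSE))
  members <- members[sizes > 1]
  members <- lapply(members, sort)
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1))
  list(groups = unname(members[ord]),
       singletons = as.character(single))
}

#' Sum of adjacent recombination fractions of a marker order
#'
#' @param order marker ids in map order.
#' @param pl a \linkS4class{PairwiseLinkage} (or an rf matrix with
#'   dimnames).
#' @return the SARF value; 0 for groups of fewer than two markers.
#' @export
sarf <- function(order, pl) {
  d <- if (is(pl, "PairwiseLinkage")) pl@rf else pl
  n <- length(order)
  if (n < 2) return(0)
  sum(d[cbind(order[-n], order[-1])])
}
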