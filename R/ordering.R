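.permCache <- new.env(parent = emptyenv())

# all permutations of 1..n as an (n!) x n matrix, in lexicographic
# order; cached, as exhaustive ordering calls this repeatedly
allPerms <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  out <- allPermsCompute(n)
  if (n <= 8) .permCache[[key]] <- out
  out
}

allPermsCompute <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

# SARF of every row of a permutation matrix over distance matrix d
permSarf <- function(P, d) {
  n <- ncol(P)
  s <- numeric(nrow(P))
  for (k in seq_len(n - 1L))
    s <- s + d[P[, k] + (P[, k + 1L] - 1L) * nrow(d)]
  s
}

# orientation rule: lexicographically smallest terminal marker first
orientOrder <- function(ids) {
  n <- length(ids)
  if (n >= 2 && ids[n] < ids[1]) rev(ids) else ids
}

greedySeriation <- function(ids, d, lod) {
  n <- length(ids)
  # seed with the strongest-linked pair (max LOD, ties by min rf then id)
  ut <- which(upper.tri(lod), arr.ind = TRUE)
  sc <- order(-lod[ut], d[ut], ut[, 1], ut[, 2])[1]
  path <- c(ut[sc, 1], ut[sc, 2])
  left <- setdiff(seq_len(n), path)
  while (length(left)) {
    e1 <- path[1]
    e2 <- path[length(path)]
    c1 <- left[order(d[e1, left], ids[left])[1]]
    c2 <- left[order(d[e2, left], ids[left])[1]]
    if (d[e1, c1] < d[e2, c2]) {
      path <- c(c1, path)
      left <- setdiff(left, c1)
    } else {
      path <- c(path, c2)
      left <- setdiff(left, c2)
    }
  }
  path
}

# 2-opt: reverse the segment i..j of the path if it shortens the SARF
twoOptPass <- function(path, d) {
  n <- length(path)
  edge <- function(a, b) if (a < 1 || b > n) 0 else d[path[a], path[b]]
  best <- 0
  bi <- bj <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (i == 1L && j == n) next  # whole-path reversal is a no-op
      delta <- edge(i - 1L, j) + edge(i, j + 1L) -
        edge(i - 1L, i) - edge(j, j + 1L)
      if (delta < best - 1e-12) {
        best <- delta
        bi <- i
        bj <- j
      }
    }
  }
  if (bi > 0L) path[bi:bj] <- path[bj:bi]
  list(path = path, improved = bi > 0L)
}

# Or-opt: relocate a short segment (length 1..maxLen, either
# orientation) to the position that most shortens the SARF.  Deltas are
# incremental: internal segment edges are unchanged by a move (and by
# reversal, d being symmetric), so only three boundary edges change.
relocatePass <- function(path, d, maxLen = 3L) {
  improved <- FALSE
  n <- length(path)
  for (L in seq_len(min(maxLen, n - 1L))) {
    k <- 1L
    while (k + L - 1L <= length(path)) {
      idx <- k:(k + L - 1L)
      seg <- path[idx]
      rest <- path[-idx]
      m <- length(rest)
      edge <- function(a, b)
        if (a < 1 || b > m + L) 0 else d[path[a], path[b]]
      gainOut <- edge(k - 1L, k) + edge(k + L - 1L, k + L) -
        (if (k > 1 && k + L <= m + L) d[path[k - 1L], path[k + L]]
         else 0)
      # insertion cost after position p of rest (0 = front)
      left <- c(0, d[rest, seg[1]])          # rest[p] -> seg start
      leftR <- c(0, d[rest, seg[L]])         # reversed orientation
      right <- c(d[seg[L], rest], 0)         # seg end -> rest[p+1]
      rightR <- c(d[seg[1], rest], 0)
      gap <- c(0, d[cbind(rest[-m], rest[-1])], 0)  # edge split open
      cost <- pmin(left + right, leftR + rightR) - gap
      p <- which.min(cost)
      if (cost[p] < gainOut - 1e-12) {
        s <- if (left[p] + right[p] <= leftR[p] + rightR[p]) seg else
          rev(seg)
        path <- append(rest, s, after = p - 1L)
        improved <- TRUE
      }
      k <- k + 1L
    }
  }
  list(path = path, improved = improved)
}

# window ripple: exhaustively permute every sliding window, keeping a
# permutation only when it strictly shortens the SARF
ripplePass <- function(path, d, window = 6L) {
  n <- length(path)
  if (n <= window) return(list(path = path, improved = FALSE))
  P <- allPerms(window)
  improved <- FALSE
  for (w in seq_len(n - window + 1L)) {
    idx <- w:(w + window - 1L)
    seg <- path[idx]
    segP <- matrix(seg[P], nrow(P))
    tot <- permSarf(segP, d)
    if (w > 1) tot <- tot + d[path[w - 1L], segP[, 1]]
    if (w + window <= n) tot <- tot + d[segP[, window], path[w + window]]
    cur <- tot[1]  # row 1 of allPerms is the identity
    b <- which.min(tot)
    if (tot[b] < cur - 1e-12) {
      path[idx] <- segP[b, ]
      improved <- TRUE
    }
  }
  list(path = path, improved = improved)
}

#' Order the markers of a linkage group
#'
#' Finds the marker order minimising the sum of adjacent recombination
#' fractions (SARF).  Groups of up to \code{exhaustiveMax} markers are
#' solved exactly by enumerating permutations; larger groups use greedy
#' seriation from the strongest-linked pair refined by 2-opt segment
#' reversals and single-marker relocations until no move improves the
#' SARF.  Equal-SARF optima are resolved toward the lexicographically
#' smallest marker sequence, and the whole order is oriented so the
#' lexicographically smaller terminal marker comes first.
#'
#' @param markers marker ids of one linkage group.
#' @param pl a \linkS4class{PairwiseLinkage} covering them.
#' @param exhaustiveMax largest group solved by full enumeration
#'   (default 8).
#' @return marker ids in map order.
#' @export
orderMarkers <- function(markers, pl, exhaustiveMax = 8) {
  n <- length(markers)
  if (n <= 1) return(markers)
  ids <- sort(markers)
  d <- pl@rf[ids, ids, drop = FALSE]
  if (n == 2) return(ids)
  if (n <= exhaustiveMax) {
    P <- allPerms(n)
    s <- permSarf(P, d)
    cand <- which(s <= min(s) + 1e-12)
    seqs <- vapply(cand, function(i) {
      o <- orientOrder(ids[P[i, ]])
      paste(o, collapse = "\r")
    }, character(1))
    best <- cand[order(seqs)[1]]
    return(orientOrder(ids[P[best, ]]))
  }
  lod <- pl@lod[ids, ids, drop = FALSE]
  path <- greedySeriation(ids, d, lod)
  repeat {
    t2 <- twoOptPass(path, d)
    path <- t2$path
    t3 <- relocatePass(path, d)
    path <- t3$path
    t4 <- ripplePass(path, d)
    path <- t4$path
    if (!t2$improved && !t3$improved && !t4$improved) break
  }
  orientOrder(ids[path])
}
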