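#' Kosambi map function and its inverse
#'
#' \code{kosambiCM} converts a recombination fraction to a map distance in
#' centimorgans, d = 25 ln((1+2r)/(1-2r)); \code{inverseKosambi} converts a
#' distance in cM back to a recombination fraction,
#' r = (e^{0.04 d} - 1) / (2 (e^{0.04 d} + 1)) = tanh(0.02 d)/2.  The
#' Kosambi function partially accounts for crossover interference; the
#' round trip is exact to numerical precision.
#'
#' @param r recombination fraction(s) in [0, 0.5).  Values at or above 0.5
#'   are rejected; cap unlinked pairs (e.g. at 0.4999) before calling.
#' @param d map distance(s) in cM, >= 0.
#' @return distance in cM, or recombination fraction.
#' @examples
#' kosambiCM(0.25)        # 25 * log(3) ~ 27.47 cM
#' inverseKosambi(10)     # ~ 0.0987
#' @export
kosambiCM <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambiCM
#' @export
inverseKosambi <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  e <- exp(0.04 * d)
  (e - 1) / (2 * (e + 1))
}

#' Chakravarti corrected map length
#'
#' Inflates each linkage-group length by (m + 1)/(m - 1) to account for
#' chromosome ends beyond the terminal markers, where m is the number of
#' (distinct) marker positions in the group.  Groups with m < 2 cannot be
#' corrected and are excluded with a warning.
#'
#' @param lengths observed per-group genetic lengths (cM).
#' @param m per-group marker-position counts.
#' @return list with \code{per_group} corrected lengths (NA where
#'   excluded) and \code{total}, their sum over corrected groups.
#' @examples
#' correctedLength(100, 11)$total  # 120
#' @export
correctedLength <- function(lengths, m) {
  stopifnot(length(lengths) == length(m))
  bad <- m < 2
  if (any(bad))
    warning(sum(bad), " group(s) with m < 2 excluded from correction")
  per <- ifelse(bad, NA_real_, lengths * (m + 1) / (m - 1))
  list(per_group = per, total = sum(per, na.rm = TRUE))
}

#' Genome coverage of a genetic map
#'
#' c = 1 - exp(-2 d n / L), the expected fraction of the genome within d
#' cM of a mapped marker, with d the average marker interval (cM), n the
#' marker count and L the (corrected) map length in cM.
#'
#' @param d average marker interval in cM.
#' @param n number of markers.
#' @param L map length in cM.
#' @return coverage fraction in [0, 1).
#' @export
genomeCoverage <- function(d, n, L) {
  stopifnot(d > 0, n > 0, L > 0)
  1 - exp(-2 * d * n / L)
}
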