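#' @import methods
#' @importFrom stats median pchisq runif rbinom rmultinom cor setNames
#' @importFrom utils head read.csv write.csv combn
NULL

GENO_CODES <- c("A", "B", "H")
PARENT_CODES <- c("dam", "sire", "both")

#' GenotypeMatrix: backcross genotype calls with per-marker metadata
#'
#' Markers are rows, individuals are columns. Calls are coded \code{"A"}
#' (homozygote), \code{"B"} (alternate homozygote, a synonym of \code{"A"}
#' under the pseudo-testcross backcross model), \code{"H"} (heterozygote)
#' and \code{NA} (missing).  Each marker carries the parent in which it is
#' heterozygous (\code{"dam"}, \code{"sire"} or \code{"both"}) and an
#' optional physical locus identifier shared by co-located markers.
#'
#' @slot geno character matrix of genotype codes, markers x individuals.
#' @slot markerInfo data.frame with columns \code{marker_id},
#'   \code{informative_parent} and \code{locus_id}.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(geno = "matrix", markerInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@geno
  mi <- object@markerInfo
  msg <- character()
  if (!is.character(g)) msg <- c(msg, "genotype matrix must be character")
  bad <- !is.na(g) & !(g %in% GENO_CODES)
  if (any(bad))
    msg <- c(msg, paste0("invalid genotype codes: ",
                         paste(unique(g[bad]), collapse = ", ")))
  if (nrow(g) != nrow(mi))
    msg <- c(msg, "markerInfo rows must match genotype rows")
  if (!all(c("marker_id", "informative_parent") %in% names(mi)))
    msg <- c(msg, "markerInfo needs marker_id and informative_parent")
  else {
    if (anyDuplicated(mi$marker_id))
      msg <- c(msg, "duplicate marker ids")
    if (!all(mi$informative_parent %in% PARENT_CODES))
      msg <- c(msg, "informative_parent must be dam/sire/both")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param geno character matrix (markers x individuals) of codes
#'   A/B/H/NA.  Rownames, if present, seed marker ids.
#' @param informative_parent character vector, one of dam/sire/both per
#'   marker (recycled if length 1).
#' @param marker_id marker identifiers; defaults to rownames.
#' @param locus_id optional physical-locus labels (co-located markers
#'   share one); defaults to \code{marker_id}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(geno, informative_parent = "dam",
                           marker_id = rownames(geno),
                           locus_id = NULL) {
  if (is.null(marker_id))
    marker_id <- paste0("M", seq_len(nrow(geno)))
  if (is.null(locus_id)) locus_id <- marker_id
  informative_parent <- rep_len(informative_parent, nrow(geno))
  rownames(geno) <- marker_id
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  new("GenotypeMatrix", geno = geno,
      markerInfo = data.frame(marker_id = marker_id,
                              informative_parent = informative_parent,
                              locus_id = locus_id,
                              stringsAsFactors = FALSE))
}

#' PairwiseLinkage: two-point linkage statistics for all marker pairs
#'
#' @slot markers character vector of marker ids (matrix dimnames).
#' @slot N integer-valued matrix, progeny typed at both markers.
#' @slot R matrix, recombinant count with phase chosen so R <= N/2.
#' @slot rf matrix of recombination-fraction estimates R/N.
#' @slot lod matrix of base-10 LOD scores against free recombination.
#' @exportClass PairwiseLinkage
setClass("PairwiseLinkage",
  representation(markers = "character", N = "matrix", R = "matrix",
                 rf = "matrix", lod = "matrix"))

setValidity("PairwiseLinkage", function(object) {
  n <- length(object@markers)
  for (s in c("N", "R", "rf", "lod")) {
    m <- slot(object, s)
    if (!all(dim(m) == c(n, n)))
      return(paste0("slot ", s, " has wrong dimensions"))
  }
  if (any(object@R > object@N)) return("R must not exceed N")
  TRUE
})

#' GeneticMap: ordered markers with cumulative Kosambi positions
#'
#' @slot table data.frame with columns \code{linkage_group}, \code{rank},
#'   \code{marker_id}, \code{position_cM}, \code{n_typed}.
#' @slot sex map label, e.g. "female" or "male".
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(table = "data.frame", sex = "character"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("linkage_group", "rank", "marker_id", "position_cM")
  if (!all(need %in% names(tb)))
    return(paste("map table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tb)) {
    byg <- split(tb$position_cM[order(tb$linkage_group, tb$rank)],
                 tb$linkage_group[order(tb$linkage_group, tb$rank)])
    ok <- vapply(byg, function(p)
      abs(p[1]) < 1e-9 && all(diff(p) >= -1e-9), logical(1))
    if (!all(ok))
      return("positions must start at 0 and be non-decreasing per group")
  }
  TRUE
})

#' Construct a GeneticMap
#'
#' @param table data.frame with columns linkage_group, rank, marker_id,
#'   position_cM (and optionally n_typed).
#' @param sex map label.
#' @return a \linkS4class{GeneticMap}.
#' @export
GeneticMap <- function(table, sex = "female") {
  new("GeneticMap", table = table, sex = sex)
}

#' OxfordGrid: chromosome-by-chromosome conserved-segment counts
#'
#' @slot counts integer matrix; rows are chromosomes of species A, columns
#'   chromosomes of species B.
#' @slot species character(2), the species labels for rows and columns.
#' @slot nExcluded segments left out because unplaced in either species.
#' @exportClass OxfordGrid
setClass("OxfordGrid",
  representation(counts = "matrix", species = "character",
                 nExcluded = "numeric"))

setValidity("OxfordGrid", function(object) {
  if (any(object@counts < 0)) return("grid counts must be non-negative")
  if (length(object@species) != 2) return("species must be length 2")
  TRUE
})

#' RearrangementScenario: post-duplication fusion/fission event series
#'
#' Events apply to a duplicated ancestral karyotype.  Each event is a list
#' with elements \code{lineage} (one of \code{"common"}, \code{"speciesA"},
#' \code{"speciesB"}), \code{type} (\code{"fusion"} or \code{"fission"})
#' and operands: fusions name two chromosomes (\code{chr1}, \code{chr2}),
#' fissions name one chromosome and a \code{breakpoint} (number of leading
#' segment copies retained on the first product).
#'
#' @slot nAncestral number of pre-duplication chromosomes.
#' @slot events list of event lists, applied in order (all common-lineage
#'   events must precede lineage-specific ones).
#' @slot label free-text scenario name.
#' @exportClass RearrangementScenario
setClass("RearrangementScenario",
  representation(nAncestral = "numeric", events = "list",
                 label = "character"))

#' Construct a RearrangementScenario
#'
#' @param nAncestral pre-duplication chromosome count.
#' @param events list of events (see class docs); default none.
#' @param label scenario name used in reports.
#' @return a \linkS4class{RearrangementScenario}.
#' @export
RearrangementScenario <- function(nAncestral, events = list(),
                                  label = "scenario") {
  obj <- new("RearrangementScenario", nAncestral = nAncestral,
             events = events, label = label)
  lin <- vapply(events, `[[`, "", "lineage")
  if (!all(lin %in% c("common", "speciesA", "speciesB")))
    stop("event lineage must be common/speciesA/speciesB")
  specific <- which(lin != "common")
  if (length(specific) && any(which(lin == "common") > min(specific)))
    stop("common-lineage events must precede lineage-specific events")
  # applying the events validates operand references; use a segment
  # resolution that accommodates the largest fission breakpoint
  bps <- vapply(events, function(e)
    if (e$type == "fission") e$breakpoint else 0, numeric(1))
  invisible(applyScenario(obj, segmentsPer = max(1, bps) + 1L))
  obj
}

#' Event constructors for rearrangement scenarios
#'
#' \code{fusionEvent} joins two chromosomes end to end;
#' \code{fissionEvent} splits one chromosome after \code{breakpoint}
#' segment copies.
#'
#' @param lineage "common", "speciesA" or "speciesB".
#' @param chr,chr1,chr2 chromosome names at the time the event applies
#'   (duplicated ancestral chromosomes are named \code{"c<k>.1"} and
#'   \code{"c<k>.2"}; a fusion product is \code{"<chr1>+<chr2>"}).
#' @param breakpoint positive integer, segment copies before the split.
#' @return an event list consumable by \code{\link{RearrangementScenario}}.
#' @name scenario-events
NULL

#' @rdname scenario-events
#' @export
fusionEvent <- function(lineage, chr1, chr2)
  list(lineage = lineage, type = "fusion", chr1 = chr1, chr2 = chr2)

#' @rdname scenario-events
#' @export
fissionEvent <- function(lineage, chr, breakpoint)
  list(lineage = lineage, type = "fission", chr = chr,
       breakpoint = breakpoint)
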