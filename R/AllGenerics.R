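#' Accessors for ddRADmap classes
#'
#' \code{genotypes} returns the raw genotype code matrix;
#' \code{markerInfo} the per-marker metadata; \code{mapTable} the ordered
#' marker table of a map; \code{gridCounts} the count matrix of an Oxford
#' grid; \code{groupLengths} the genetic length (last position) of each
#' linkage group.
#'
#' @param x a ddRADmap object.
#' @return the slot contents (see description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname accessors
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))
#' @rdname accessors
#' @export
setGeneric("gridCounts", function(x) standardGeneric("gridCounts"))
#' @rdname accessors
#' @export
setGeneric("groupLengths", function(x) standardGeneric("groupLengths"))

#' @rdname accessors
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)
#' @rdname accessors
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markerInfo)
#' @rdname accessors
setMethod("mapTable", "GeneticMap", function(x) x@table)
#' @rdname accessors
setMethod("gridCounts", "OxfordGrid", function(x) x@counts)

#' @rdname accessors
setMethod("groupLengths", "GeneticMap", function(x) {
  tb <- x@table
  if (!nrow(tb)) return(numeric())
  vapply(split(tb$position_cM, tb$linkage_group), max, numeric(1))
})

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@geno
  ip <- table(object@markerInfo$informative_parent)
  cat("GenotypeMatrix:", nrow(g), "markers x", ncol(g), "individuals\n")
  cat("  informative parent:",
      paste(names(ip), ip, sep = "=", collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(g)), sprintf("(%.1f%%)\n",
      100 * mean(is.na(g))))
})

setMethod("show", "PairwiseLinkage", function(object) {
  cat("PairwiseLinkage over", length(object@markers), "markers\n")
})

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  gl <- groupLengths(object)
  cat("GeneticMap (", object@sex, "): ", length(gl),
      " linkage groups, ", nrow(tb), " markers, ",
      sprintf("%.1f cM total\n", sum(gl)), sep = "")
})

setMethod("show", "OxfordGrid", function(object) {
  cat("OxfordGrid ", object@species[1], " x ", object@species[2], ": ",
      nrow(object@counts), " x ", ncol(object@counts), " chromosomes, ",
      sum(object@counts), " segments (", object@nExcluded,
      " excluded)\n", sep = "")
})

setMethod("show", "RearrangementScenario", function(object) {
  cat("RearrangementScenario '", object@label, "': ",
      object@nAncestral, " ancestral chromosomes, ",
      length(object@events), " events\n", sep = "")
})

#' Number of markers / individuals in a GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @return integer count.
#' @export
nMarkers <- function(x) nrow(genotypes(x))

#' @rdname nMarkers
#' @export
nIndividuals <- function(x) ncol(genotypes(x))
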