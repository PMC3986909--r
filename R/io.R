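pkgVersion <- function()
  as.character(utils::packageVersion("ddRADmap"))

provenanceHeader <- function(seed = NULL) {
  paste0("# ddRADmap ", pkgVersion(),
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

# read a delimited file, skipping "#" provenance lines and normalising
# CRLF; returns the data lines plus their original line numbers.
readDataLines <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

checkFieldCounts <- function(parts, lineno, path) {
  n <- lengths(parts)
  if (length(unique(n)) > 1) {
    bad <- lineno[n != n[1]][1]
    stop("inconsistent column count at line ", bad, " of ", path)
  }
}

#' Read and write genotype matrices as CSV
#'
#' The format is one marker per row: columns \code{marker_id},
#' \code{informative_parent} (dam/sire/both), \code{locus_id}, then one
#' column per individual with codes A/B/H and "-" for missing.  Writers
#' prepend a "#" provenance line (tool version, seed); readers skip "#"
#' lines, accept CRLF or LF, and report malformed content with the
#' offending line number (unknown genotype code, duplicate marker id,
#' inconsistent column count).
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @return \code{readGenotypesCSV} returns a
#'   \linkS4class{GenotypeMatrix}; \code{writeGenotypesCSV} returns the
#'   path invisibly.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
writeGenotypesCSV <- function(gm, path, seed = NULL) {
  g <- gm@geno
  g[is.na(g)] <- "-"
  df <- cbind(gm@markerInfo[c("marker_id", "informative_parent",
                              "locus_id")], as.data.frame(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname genotype-io
#' @export
readGenotypesCSV <- function(path) {
  dl <- readDataLines(path)
  parts <- strsplit(dl$lines, ",", fixed = TRUE)
  checkFieldCounts(parts, dl$lineno, path)
  header <- parts[[1]]
  need <- c("marker_id", "informative_parent", "locus_id")
  if (!identical(header[1:3], need))
    stop("genotype CSV must start with columns: ",
         paste(need, collapse = ", "))
  body <- parts[-1]
  lineno <- dl$lineno[-1]
  ids <- vapply(body, `[`, "", 1)
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[1]
    stop("duplicate marker id '", ids[dup], "' at line ", lineno[dup],
         " of ", path)
  }
  inds <- header[-(1:3)]
  geno <- matrix(NA_character_, length(body), length(inds),
                 dimnames = list(ids, inds))
  for (i in seq_along(body)) {
    v <- body[[i]][-(1:3)]
    bad <- !(v %in% c(GENO_CODES, "-"))
    if (any(bad))
      stop("unknown genotype code '", v[bad][1], "' at line ",
           lineno[i], " of ", path)
    v[v == "-"] <- NA_character_
    geno[i, ] <- v
  }
  GenotypeMatrix(geno,
                 informative_parent = vapply(body, `[`, "", 2),
                 marker_id = ids,
                 locus_id = vapply(body, `[`, "", 3))
}

writeTSV <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

readTSVBody <- function(path, colClasses = NA) {
  dl <- readDataLines(path)
  parts <- strsplit(dl$lines, "\t", fixed = TRUE)
  checkFieldCounts(parts, dl$lineno, path)
  read.csv(text = paste(dl$lines, collapse = "\n"), sep = "\t",
           stringsAsFactors = FALSE, colClasses = colClasses)
}

#' Read and write genetic maps as TSV
#'
#' Columns: linkage_group, rank, marker_id, position_cM, n_typed.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path file path.
#' @param seed provenance seed.
#' @param sex map label applied on read.
#' @return the map (read) or the path, invisibly (write).
#' @name map-io
NULL

#' @rdname map-io
#' @export
writeMapTSV <- function(map, path, seed = NULL)
  writeTSV(mapTable(map), path, seed)

#' @rdname map-io
#' @export
readMapTSV <- function(path, sex = "female")
  GeneticMap(readTSVBody(path), sex = sex)

#' Read and write similarity hit tables (BLAST outfmt-6 dialect)
#'
#' Twelve tab-separated columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.  No header line in
#' the body, matching the BLAST convention; "#" lines are skipped.
#'
#' @param hits a hit data.frame.
#' @param path file path.
#' @param seed provenance seed.
#' @return the hit data.frame (read) or the path, invisibly (write).
#' @name hit-io
NULL

outfmt6Cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' @rdname hit-io
#' @export
writeHitTable <- function(hits, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed), con)
  utils::write.table(hits[outfmt6Cols], con, sep = "\t",
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname hit-io
#' @export
readHitTable <- function(path) {
  dl <- readDataLines(path)
  parts <- strsplit(dl$lines, "\t", fixed = TRUE)
  checkFieldCounts(parts, dl$lineno, path)
  if (length(parts[[1]]) != 12)
    stop("hit table must have 12 columns (line ", dl$lineno[1], " of ",
         path, ")")
  df <- read.csv(text = paste(dl$lines, collapse = "\n"), sep = "\t",
                 header = FALSE, stringsAsFactors = FALSE)
  names(df) <- outfmt6Cols
  df
}

#' Read and write conserved-segment tables as TSV
#'
#' Columns: segment_id, then one chromosome column per species (chrA,
#' chrB and optionally chrC), with "NA" marking segments unplaced in
#' that species.
#'
#' @param segments a segment data.frame.
#' @param path file path.
#' @param seed provenance seed.
#' @return the segment data.frame (read) or the path, invisibly
#'   (write).
#' @name segment-io
NULL

#' @rdname segment-io
#' @export
writeSegmentTable <- function(segments, path, seed = NULL)
  writeTSV(segments, path, seed)

#' @rdname segment-io
#' @export
readSegmentTable <- function(path) {
  df <- readTSVBody(path, colClasses = "character")
  if (names(df)[1] != "segment_id")
    stop("segment table must start with a segment_id column")
  if (anyDuplicated(df$segment_id))
    stop("duplicate segment ids in ", path)
  df
}

#' Write an AGP-like scaffold-order table
#'
#' One row per anchored scaffold: linkage_group, rank, scaffold_id,
#' length_bp, orientation (always "?"), anchor_cM_female,
#' anchor_cM_male, status.
#'
#' @param orders output of \code{\link{orderScaffolds}}.
#' @param path file path.
#' @param seed provenance seed.
#' @return the path, invisibly.
#' @export
writeScaffoldOrder <- function(orders, path, seed = NULL)
  writeTSV(orders, path, seed)

#' Write an Oxford grid as a labelled TSV matrix
#'
#' @param grid an \linkS4class{OxfordGrid}.
#' @param path file path.
#' @param seed provenance seed.
#' @return the path, invisibly.
#' @export
writeGridTSV <- function(grid, path, seed = NULL) {
  m <- gridCounts(grid)
  df <- cbind(data.frame(chrom = rownames(m)), as.data.frame(m))
  writeTSV(df, path, seed)
}

#' Write simulated chromosome sequences as FASTA
#'
#' @param sequences a \code{DNAStringSet}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeGenomeFASTA <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}
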