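# Readers and writers for the interchange tables.
#
# All tables are tab-delimited with a header line. Empty strings and
# undefined values are written as "." (as in VCF) so that files round-trip
# losslessly through the readers.

.DOT <- "."

.na_to_dot <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- .DOT
  x
}

.dot_to_empty <- function(x) {
  x[x == .DOT] <- ""
  x
}

.dot_to_na <- function(x) {
  x[x == .DOT] <- NA
  x
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = .DOT)
  invisible(path)
}

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read and write SV call tables
#'
#' Columns: `id, sample, type, chrom1, pos1, chrom2, pos2, moleculePos1,
#' moleculePos2, offset, insertedBases, size, moleculeId, moleculeSeq`.
#' `moleculeSeq` is optional (`.` when absent); `size` is undefined (`.`)
#' for interchromosomal calls; `insertedBases` is empty unless the offset
#' is positive.
#'
#' @param path File path.
#' @param calls A calls data frame as produced by [simulate_cohort()] or
#'   assembled by the caller.
#' @return `read_sv_calls` returns a data frame with typed columns;
#'   `write_sv_calls` returns `path` invisibly.
#' @export
read_sv_calls <- function(path) {
  df <- .read_tsv(path, c("id", "sample", "type", "chrom1", "pos1",
                          "chrom2", "pos2", "offset", "insertedBases",
                          "size", "moleculeId"))
  out <- data.frame(
    id = df$id, sample = df$sample, type = df$type,
    chrom1 = df$chrom1, pos1 = as.integer(df$pos1),
    chrom2 = df$chrom2, pos2 = as.integer(df$pos2),
    moleculePos1 = if ("moleculePos1" %in% names(df))
      as.integer(.dot_to_na(df$moleculePos1)) else NA_integer_,
    moleculePos2 = if ("moleculePos2" %in% names(df))
      as.integer(.dot_to_na(df$moleculePos2)) else NA_integer_,
    offset = as.integer(df$offset),
    insertedBases = .dot_to_empty(df$insertedBases),
    size = as.integer(.dot_to_na(df$size)),
    moleculeId = df$moleculeId,
    moleculeSeq = if ("moleculeSeq" %in% names(df))
      .dot_to_na(df$moleculeSeq) else NA_character_,
    stringsAsFactors = FALSE
  )
  .validate_calls(out)
  out
}

#' @rdname read_sv_calls
#' @export
write_sv_calls <- function(calls, path) {
  df <- calls
  df$insertedBases <- .na_to_dot(df$insertedBases)
  df$moleculeSeq <- .na_to_dot(df$moleculeSeq)
  df$size <- .na_to_dot(df$size)
  .write_tsv(df, path)
}

.validate_calls <- function(calls) {
  bad <- which(nchar(calls$insertedBases) != pmax(calls$offset, 0L))
  if (length(bad)) {
    stop("call(s) ", paste(utils::head(calls$id[bad], 5L), collapse = ", "),
         ": length(insertedBases) must equal max(offset, 0)")
  }
  intra <- calls$chrom1 == calls$chrom2
  bad <- which(intra & calls$pos1 > calls$pos2)
  if (length(bad)) {
    stop("call(s) ", paste(utils::head(calls$id[bad], 5L), collapse = ", "),
         ": pos1 must be <= pos2 for intrachromosomal calls")
  }
  invisible(calls)
}

#' Read and write source-molecule tables
#'
#' Columns: `moleculeId, sample, chrom, outerStart, outerEnd,
#' readPairCount, mapq1, mapq2, carriesSv` (0/1).
#'
#' @param path File path.
#' @param molecules A molecules data frame.
#' @return A typed data frame, or `path` invisibly for the writer.
#' @export
read_molecules <- function(path) {
  df <- .read_tsv(path, c("moleculeId", "sample", "chrom", "outerStart",
                          "outerEnd", "readPairCount", "mapq1", "mapq2",
                          "carriesSv"))
  out <- data.frame(
    moleculeId = df$moleculeId, sample = df$sample, chrom = df$chrom,
    outerStart = as.integer(df$outerStart),
    outerEnd = as.integer(df$outerEnd),
    readPairCount = as.integer(df$readPairCount),
    mapq1 = as.integer(df$mapq1), mapq2 = as.integer(df$mapq2),
    carriesSv = as.integer(df$carriesSv) != 0L,
    stringsAsFactors = FALSE
  )
  if (any(out$outerEnd < out$outerStart)) stop("molecule outerEnd < outerStart")
  if (any(out$readPairCount < 1L)) stop("molecule readPairCount < 1")
  out
}

#' @rdname read_molecules
#' @export
write_molecules <- function(molecules, path) {
  df <- molecules
  df$carriesSv <- as.integer(df$carriesSv)
  .write_tsv(df, path)
}

#' Read and write the sample manifest
#'
#' Columns: `sample, group, batch`.
#'
#' @param path File path.
#' @param samples A samples data frame.
#' @return A data frame, or `path` invisibly for the writer.
#' @export
read_manifest <- function(path) {
  df <- .read_tsv(path, c("sample", "group", "batch"))
  if (any(!nzchar(df$group)) || any(!nzchar(df$batch))) {
    stop("manifest group and batch labels must be non-empty")
  }
  df
}

#' @rdname read_manifest
#' @export
write_manifest <- function(samples, path) .write_tsv(samples, path)

#' Read and write capture target regions (BED)
#'
#' Target BED files use 0-based half-open intervals; internally the package
#' works with 1-based inclusive coordinates (`captureStart`, `captureEnd`).
#' The BED strand column carries the transcription strand of the captured
#' gene; the padding that defines the allowable breakpoint span is a
#' property of the analysis (default 800 kb) and is attached on read.
#'
#' @param path File path.
#' @param targets A targets data frame with `name, chrom, captureStart,
#'   captureEnd, pad, transcriptionStrand`.
#' @param pad Padding in bp applied on each side of each target to define
#'   the allowable SV breakpoint span.
#' @return A targets data frame, or `path` invisibly for the writer.
#' @export
read_targets <- function(path, pad = 800000L) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  nm <- if (!is.null(gr$name)) gr$name else paste0("target", seq_along(gr))
  data.frame(
    name = nm,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    captureStart = BiocGenerics::start(gr),
    captureEnd = BiocGenerics::end(gr),
    pad = as.integer(pad),
    transcriptionStrand = strand,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  df <- data.frame(
    chrom = targets$chrom,
    start = targets$captureStart - 1L,
    end = targets$captureEnd,
    name = targets$name,
    score = 0L,
    strand = targets$transcriptionStrand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences (typically length 1).
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_reference
#' @param sequences Named character vector of sequences.
#' @export
write_reference <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a simulation truth table
#'
#' @param path File path.
#' @return A typed data frame of per-SV mechanism truth.
#' @export
read_truth <- function(path) {
  df <- .read_tsv(path, c("svId", "mechanism"))
  for (col in c("mhLen", "insertSize", "templateStart", "templateEnd",
                "primingMh", "resolvingMh", "distance", "templateSide")) {
    if (col %in% names(df)) df[[col]] <- as.integer(.dot_to_na(df[[col]]))
  }
  if ("templated" %in% names(df)) df$templated <- df$templated == "1"
  for (col in c("insertedBases", "templateClass", "templateStrand")) {
    if (col %in% names(df)) df[[col]] <- .dot_to_na(df[[col]])
  }
  df
}

.write_truth <- function(truth, path) {
  df <- truth
  df$templated <- as.integer(df$templated)
  for (col in names(df)) df[[col]] <- .na_to_dot(df[[col]])
  .write_tsv(df, path)
}
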