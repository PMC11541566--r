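#' SV filtering configuration
#'
#' Thresholds for molecule-level SV filtering: junctions must be found in
#' a single source molecule in a single sample, sequenced by at least
#' three redundant read pairs, with mapping quality >= 30 in one flanking
#' alignment and >= 20 in both; at least one breakpoint must fall in an
#' unpadded capture target with both inside the padded span; deletions and
#' duplications are restricted to 10 kb - 1.2 Mb and inversions to >= 50 kb
#' (small-inversion artifacts of transposase library end fill-in).
#'
#' @param minReadPairs Minimum read pairs supporting a source molecule.
#' @param mapqBoth Minimum mapping quality required on both sides.
#' @param mapqOne Minimum mapping quality required on at least one side.
#' @param minSizeDelDup,maxSize Size window for deletions and duplications.
#' @param minSizeInv Minimum inversion size.
#' @param pad Target padding defining the allowable breakpoint span.
#' @param terminalDeadZone Unalignable bases at each molecule end,
#'   subtracted (2 x 20 bp) from molecule lengths for coverage.
#' @return A list of class `svj_filter_config`.
#' @export
filter_config <- function(minReadPairs = 3L, mapqBoth = 20L, mapqOne = 30L,
                          minSizeDelDup = 10000L, maxSize = 1200000L,
                          minSizeInv = 50000L, pad = 800000L,
                          terminalDeadZone = 20L) {
  cfg <- list(minReadPairs = as.integer(minReadPairs),
              mapqBoth = as.integer(mapqBoth), mapqOne = as.integer(mapqOne),
              minSizeDelDup = as.integer(minSizeDelDup),
              maxSize = as.integer(maxSize),
              minSizeInv = as.integer(minSizeInv), pad = as.integer(pad),
              terminalDeadZone = as.integer(terminalDeadZone))
  if (any(unlist(cfg) < 0L)) stop("filter thresholds must be >= 0")
  if (cfg$maxSize <= cfg$minSizeDelDup) {
    stop("maxSize must exceed minSizeDelDup")
  }
  class(cfg) <- "svj_filter_config"
  cfg
}

#' Filter SV calls to unique, well-supported, on-target junctions
#'
#' Applies the molecule-level filters in a fixed order so rejection
#' reasons are reproducible: (1) `not_unique` -- the junction (keyed by
#' type and breakpoint pair, canonicalized when a reference is supplied)
#' occurs in more than one source molecule or sample across the batch;
#' (2) `read_support` -- the supporting molecule has fewer than
#' `minReadPairs` read pairs; (3) `mapq` -- mapping quality below 30 on
#' both sides or below 20 on either; (4) `off_target` -- no breakpoint in
#' an unpadded target, or a breakpoint outside the padded span;
#' (5) `size` -- outside the per-type size window. Each rejected call
#' records the first failing rule.
#'
#' @param calls SV calls data frame.
#' @param molecules Source molecules data frame.
#' @param samples Sample manifest data frame (presence validated).
#' @param targets Targets data frame.
#' @param config A [filter_config()].
#' @param reference Optional reference sequence; when supplied together
#'   with molecule sequences, junctions are canonicalized to maximal
#'   microhomology before uniqueness keying.
#' @return A list with `kept` (calls data frame) and `rejections`
#'   (data frame with `id`, `reason`).
#' @export
filter_svs <- function(calls, molecules, samples, targets,
                       config = filter_config(), reference = NULL) {
  if (nrow(calls) == 0L) {
    return(list(kept = calls,
                rejections = data.frame(id = character(0L),
                                        reason = character(0L))))
  }
  mIdx <- match(calls$moleculeId, molecules$moleculeId)
  if (anyNA(mIdx)) {
    stop("integrity error: call(s) reference missing molecule(s): ",
         paste(utils::head(calls$moleculeId[is.na(mIdx)], 5L),
               collapse = ", "))
  }
  if (!all(calls$sample %in% samples$sample)) {
    stop("integrity error: call sample(s) missing from the manifest")
  }
  if (!is.null(reference)) calls <- .canonicalize_calls(calls, reference)
  mol <- molecules[mIdx, , drop = FALSE]

  reason <- rep(NA_character_, nrow(calls))

  # (1) single molecule, single sample per junction across the batch
  jkey <- paste(calls$type, calls$chrom1, calls$pos1, calls$chrom2,
                calls$pos2, sep = ":")
  mkey <- paste(mol$sample, mol$outerStart, mol$outerEnd, sep = ":")
  nSupport <- vapply(split(mkey, jkey), function(x) length(unique(x)), 1L)
  reason[is.na(reason) & nSupport[jkey] > 1L] <- "not_unique"

  # (2) read-pair support
  reason[is.na(reason) & mol$readPairCount < config$minReadPairs] <-
    "read_support"

  # (3) mapping quality: >= mapqOne on one side AND >= mapqBoth on both
  mq_ok <- pmax(mol$mapq1, mol$mapq2) >= config$mapqOne &
    pmin(mol$mapq1, mol$mapq2) >= config$mapqBoth
  reason[is.na(reason) & !mq_ok] <- "mapq"

  # (4) on-target: >= 1 breakpoint in an unpadded target, both in padded span
  inT1 <- .in_targets(calls$chrom1, calls$pos1, targets, 0L)
  inT2 <- .in_targets(calls$chrom2, calls$pos2, targets, 0L)
  inP1 <- .in_targets(calls$chrom1, calls$pos1, targets, config$pad)
  inP2 <- .in_targets(calls$chrom2, calls$pos2, targets, config$pad)
  reason[is.na(reason) & !((inT1 | inT2) & inP1 & inP2)] <- "off_target"

  # (5) size window by type
  sz_ok <- rep(TRUE, nrow(calls))
  dd <- calls$type %in% c("DEL", "DUP")
  sz_ok[dd] <- !is.na(calls$size[dd]) &
    calls$size[dd] >= config$minSizeDelDup &
    calls$size[dd] <= config$maxSize
  iv <- calls$type == "INV"
  sz_ok[iv] <- !is.na(calls$size[iv]) &
    calls$size[iv] >= config$minSizeInv & calls$size[iv] <= config$maxSize
  reason[is.na(reason) & !sz_ok] <- "size"

  keep <- is.na(reason)
  list(kept = calls[keep, , drop = FALSE],
       rejections = data.frame(id = calls$id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

.in_targets <- function(chrom, pos, targets, pad) {
  ok <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(targets))) {
    ok <- ok | (chrom == targets$chrom[i] &
                  pos >= targets$captureStart[i] - pad &
                  pos <= targets$captureEnd[i] + pad)
  }
  ok
}

#' Compute adjusted target coverage
#'
#' Source molecules with fewer than `minReadPairs` read pairs are excluded
#' and SV-carrying molecules are set aside; the remaining molecule lengths
#' are reduced by 2 x 20 bp (the terminal bases where a junction could not
#' be called, floored at zero). Scalar target coverage is the summed
#' adjusted length of on-target molecules divided by the summed unpadded
#' target length; for visualization, base-level coverage is averaged over
#' 100 bp bins anchored at each target's start (partial terminal bins are
#' averaged over their actual width).
#'
#' @param molecules Molecules data frame.
#' @param targets Targets data frame.
#' @param config A [filter_config()].
#' @param binSize Bin width in bp for the binned track.
#' @return An object of class `svj_coverage`: a list with scalar
#'   `coverage` and a `bins` data frame (`name, chrom, start, end,
#'   meanCoverage`).
#' @export
compute_coverage <- function(molecules, targets, config = filter_config(),
                             binSize = 100L) {
  if (nrow(targets) == 0L) stop("config error: empty target set")
  dz <- config$terminalDeadZone
  mol <- molecules[molecules$readPairCount >= config$minReadPairs &
                     !molecules$carriesSv, , drop = FALSE]
  len <- mol$outerEnd - mol$outerStart + 1L
  adj <- pmax(len - 2L * dz, 0L)

  onTarget <- rep(FALSE, nrow(mol))
  for (i in seq_len(nrow(targets))) {
    onTarget <- onTarget | (mol$chrom == targets$chrom[i] &
                              mol$outerStart <= targets$captureEnd[i] &
                              mol$outerEnd >= targets$captureStart[i])
  }
  totalTarget <- sum(targets$captureEnd - targets$captureStart + 1L)
  scalar <- sum(as.numeric(adj[onTarget])) / totalTarget

  bins <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    tr <- targets[i, ]
    use <- mol$chrom == tr$chrom & adj > 0L
    covBins <- .binned_mean_coverage(
      start = mol$outerStart[use] + dz, end = mol$outerEnd[use] - dz,
      lo = tr$captureStart, hi = tr$captureEnd, binSize = binSize
    )
    cbind(data.frame(name = tr$name, chrom = tr$chrom,
                     stringsAsFactors = FALSE), covBins)
  }))
  structure(list(coverage = scalar, bins = bins, binSize = as.integer(binSize),
                 config = config),
            class = "svj_coverage")
}

# mean per-base coverage of [start,end] intervals over bins tiling [lo,hi]
.binned_mean_coverage <- function(start, end, lo, hi, binSize) {
  width <- hi - lo + 1L
  binStart <- seq.int(lo, hi, by = binSize)
  binEnd <- pmin(binStart + binSize - 1L, hi)
  if (length(start) == 0L) {
    return(data.frame(start = binStart, end = binEnd,
                      meanCoverage = rep(0, length(binStart))))
  }
  s <- pmax(start, lo); e <- pmin(end, hi)
  ok <- s <= e
  cov <- IRanges::coverage(IRanges::IRanges(s[ok] - lo + 1L, e[ok] - lo + 1L),
                           width = width)
  v <- IRanges::Views(cov, binStart - lo + 1L, binEnd - lo + 1L)
  data.frame(start = binStart, end = binEnd,
             meanCoverage = IRanges::viewMeans(v))
}

#' @export
print.svj_coverage <- function(x, ...) {
  cat("Adjusted target coverage:", format(x$coverage, digits = 6), "fold\n")
  cat(nrow(x$bins), "bins of", x$binSize, "bp\n")
  invisible(x)
}

#' SV frequency
#'
#' The observed junction count divided by the target-region fold-coverage;
#' approximates the fraction of sequenced target haplotypes carrying a de
#' novo SV.
#'
#' @param keptCalls Filtered calls data frame (or an integer count).
#' @param coverage An `svj_coverage` object or scalar fold-coverage.
#' @return A list with `nSvs`, `coverage`, `frequency`.
#' @export
sv_frequency <- function(keptCalls, coverage) {
  n <- if (is.data.frame(keptCalls)) nrow(keptCalls) else as.integer(keptCalls)
  cv <- if (inherits(coverage, "svj_coverage")) coverage$coverage
        else as.numeric(coverage)
  if (cv <= 0) stop("undefined SV frequency: coverage must be > 0")
  list(nSvs = n, coverage = cv, frequency = n / cv)
}

#' Breakpoint density in 5 kb bins
#'
#' Counts each breakpoint of each kept call once into 5 kb bins anchored
#' at the target's start and spanning the padded breakpoint region.
#' Coverage-normalized density (count / mean adjusted coverage) is defined
#' only on bins whose coverage is at least `minCoverage` (500 by default);
#' other bins carry `NA`, never zero.
#'
#' @param keptCalls Filtered calls data frame.
#' @param molecules Molecules data frame (for the per-bin adjusted
#'   coverage).
#' @param targets Targets data frame.
#' @param config A [filter_config()].
#' @param binSize Bin width (5 kb by default).
#' @param minCoverage Coverage mask threshold.
#' @return A data frame with `name, chrom, start, end, count, coverage,
#'   density` (density `NA` on masked bins).
#' @export
breakpoint_density <- function(keptCalls, molecules, targets,
                               config = filter_config(), binSize = 5000L,
                               minCoverage = 500) {
  dz <- config$terminalDeadZone
  mol <- molecules[molecules$readPairCount >= config$minReadPairs &
                     !molecules$carriesSv, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    tr <- targets[i, ]
    lo <- max(1L, tr$captureStart - tr$pad)
    hi <- tr$captureEnd + tr$pad
    use <- mol$chrom == tr$chrom &
      (mol$outerEnd - mol$outerStart + 1L) > 2L * dz
    covBins <- .binned_mean_coverage(
      start = mol$outerStart[use] + dz, end = mol$outerEnd[use] - dz,
      lo = lo, hi = hi, binSize = binSize
    )
    pos <- c(keptCalls$pos1[keptCalls$chrom1 == tr$chrom],
             keptCalls$pos2[keptCalls$chrom2 == tr$chrom])
    pos <- pos[pos >= lo & pos <= hi]
    binIdx <- (pos - lo) %/% binSize + 1L
    count <- tabulate(binIdx, nbins = nrow(covBins))
    density <- ifelse(covBins$meanCoverage >= minCoverage,
                      count / covBins$meanCoverage, NA_real_)
    cbind(data.frame(name = tr$name, chrom = tr$chrom,
                     stringsAsFactors = FALSE),
          covBins[, c("start", "end")],
          data.frame(count = count, coverage = covBins$meanCoverage,
                     density = density))
  }))
  rownames(out) <- NULL
  out
}
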