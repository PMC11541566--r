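# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code at test time under fixed seeds.

# A small reference chunk big enough for one junction with 500 bp search
# windows on each breakpoint (junction size fixed at 12 kb).
CHUNK_LEN <- 13450L
CHUNK_POS1 <- 701L
CHUNK_SIZE <- 12000L

random_chunk <- function() {
  paste(sample(c("A", "C", "G", "T"), CHUNK_LEN, replace = TRUE),
        collapse = "")
}

# Plant n junctions, each on its own fresh random chunk, drawing mechanism
# parameters from the generator's configured distributions.
plant_many <- function(n, config, seed) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- random_chunk()
    draw <- svjunctions:::.draw_sv_params(config)
    pl <- plant_junction(
      ref, CHUNK_SIZE, draw$mechanism, svType = draw$type,
      pos1 = CHUNK_POS1, mhLen = draw$mhLen, insertSize = draw$insertSize,
      templated = draw$templated, templateClass = draw$templateClass,
      templateSide = draw$templateSide,
      templateDistance = draw$templateDistance,
      primingMh = draw$primingMh, resolvingMh = draw$resolvingMh
    )
    out[[i]] <- pl
  }
  out
}

# Plant n insertion junctions of one size (templated or not), each on a
# fresh random chunk.
plant_insertions <- function(n, insertSize, seed, templated = FALSE,
                             templateClass = "foldback",
                             templateDistance = NULL,
                             primingMh = NULL, resolvingMh = NULL) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- random_chunk()
    side <- sample(1:2, 1L)
    out[[i]] <- plant_junction(
      ref, CHUNK_SIZE, "insertion", svType = "DEL", pos1 = CHUNK_POS1,
      insertSize = insertSize, templated = templated,
      templateClass = templateClass, templateSide = side,
      templateDistance = templateDistance, primingMh = primingMh,
      resolvingMh = resolvingMh
    )
  }
  out
}

# Independent brute-force template scanner: checks every position of both
# strands of both breakpoint windows by direct substring comparison, then
# extends flanks base by base using character vectors. Written without any
# of the production scanner's code paths.
oracle_scan <- function(query, refChr, call, window = 500L) {
  q <- query$querySeq
  qrc <- revcomp(q)
  n <- nchar(q)
  N <- nchar(refChr)
  molCh <- strsplit(call$moleculeSeq, "")[[1L]]
  refCh <- strsplit(refChr, "")[[1L]]
  compMap <- c(A = "T", C = "G", G = "C", T = "A")
  P <- c(call$pos1, call$pos2)
  rows <- list()
  for (bp in 1:2) {
    lo <- max(1L, P[bp] - window)
    hi <- min(N, P[bp] + window)
    starts <- lo:(hi - n + 1L)
    s <- substring(refChr, starts, starts + n - 1L)
    for (strand in c("top", "bottom")) {
      where <- starts[s == (if (strand == "top") q else qrc)]
      for (t0 in where) {
        t1 <- t0 + n - 1L
        # naive extension
        pe <- 0L; re <- 0L
        if (strand == "top") {
          while (query$qs - 1L - pe >= 1L && t0 - 1L - pe >= 1L &&
                 molCh[query$qs - 1L - pe] == refCh[t0 - 1L - pe]) pe <- pe + 1L
          while (query$qe + 1L + re <= length(molCh) && t1 + 1L + re <= N &&
                 molCh[query$qe + 1L + re] == refCh[t1 + 1L + re]) re <- re + 1L
          rs <- t0 - pe; rend <- t1 + re
        } else {
          while (query$qs - 1L - pe >= 1L && t1 + 1L + pe <= N &&
                 molCh[query$qs - 1L - pe] ==
                   compMap[[refCh[t1 + 1L + pe]]]) pe <- pe + 1L
          while (query$qe + 1L + re <= length(molCh) && t0 - 1L - re >= 1L &&
                 molCh[query$qe + 1L + re] ==
                   compMap[[refCh[t0 - 1L - re]]]) re <- re + 1L
          rs <- t0 - re; rend <- t1 + pe
        }
        rows[[length(rows) + 1L]] <- data.frame(
          breakpointIndex = bp, strand = strand, matchStart = t0,
          matchEnd = t1, refStart = rs, refEnd = rend,
          primingMh = query$flankPerSide + pe,
          resolvingMh = query$flankPerSide + re,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[, c("breakpointIndex", "strand", "refStart",
                              "refEnd")]), , drop = FALSE]
  df[order(df$breakpointIndex, df$strand, df$matchStart), , drop = FALSE]
}

# hand-built small cohort tables for filter tests
toy_filter_fixture <- function() {
  targets <- data.frame(
    name = "t1", chrom = "chr1", captureStart = 1000000L,
    captureEnd = 1400000L, pad = 800000L, transcriptionStrand = "+",
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample = c("s1", "s2"), group = c("A", "B"),
                        batch = "b1", stringsAsFactors = FALSE)
  mk_mol <- function(id, sample, start, end, rp = 3L, mq1 = 35L, mq2 = 25L,
                     sv = TRUE) {
    data.frame(moleculeId = id, sample = sample, chrom = "chr1",
               outerStart = start, outerEnd = end, readPairCount = rp,
               mapq1 = mq1, mapq2 = mq2, carriesSv = sv,
               stringsAsFactors = FALSE)
  }
  mk_call <- function(id, sample, type, pos1, pos2, molId) {
    data.frame(id = id, sample = sample, type = type, chrom1 = "chr1",
               pos1 = pos1, chrom2 = "chr1", pos2 = pos2,
               moleculePos1 = 200L, moleculePos2 = 201L, offset = 0L,
               insertedBases = "", size = pos2 - pos1, moleculeId = molId,
               moleculeSeq = NA_character_, stringsAsFactors = FALSE)
  }
  list(targets = targets, samples = samples, mk_mol = mk_mol,
       mk_call = mk_call)
}
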