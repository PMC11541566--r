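#' Build the insertion-template query for an insertion junction
#'
#' The query is the inserted bases plus flanking microhomology bases on
#' each side as they appear in the SV molecule, with enough flanking bases
#' to make at least seven query bases in total and at least one base of
#' flanking homology per side: a single-base insertion is queried with
#' three bases of initial microhomology on each side, a four-base
#' insertion with two bases per side, and insertions of five or more bases
#' with one base per side (odd flank totals are split symmetrically by
#' ceiling, so a two-base insertion also gets three bases per side).
#'
#' @param svCall A one-row insertion call with `offset >= 1`, a
#'   `moleculeSeq`, and molecule breakpoint positions.
#' @return A list of class `svj_template_query` with `insertSize`,
#'   `flankPerSide`, `querySeq`, `nTemplateBases`, and the query's
#'   molecule coordinates `qs`, `qe`.
#' @export
build_template_query <- function(svCall) {
  k <- as.integer(svCall$offset)
  if (is.na(k) || k < 1L) {
    stop("not an insertion: template queries require offset >= 1")
  }
  mol <- svCall$moleculeSeq
  if (is.null(mol) || is.na(mol) || !nzchar(mol)) {
    stop("data error: moleculeSeq is required to build a template query")
  }
  ord <- .mol_order(svCall$type)
  mpos <- c(svCall$moleculePos1, svCall$moleculePos2)
  a <- mpos[ord[1L]]; b <- mpos[ord[2L]]
  f <- max(1L, as.integer(ceiling((7L - k) / 2)))
  qs <- a - f + 1L; qe <- b + f - 1L
  if (qs < 1L || qe > nchar(mol)) {
    stop("data error: molecule flanks too short for the template query")
  }
  structure(list(insertSize = k, flankPerSide = f,
                 querySeq = substr(mol, qs, qe),
                 nTemplateBases = k + 2L * f, qs = qs, qe = qe),
            class = "svj_template_query")
}

#' Scan breakpoint windows for insertion templates
#'
#' Searches for exact matches of the query sequence on both strands in a
#' span of `window` bp upstream and downstream of each of the two
#' breakpoints (2 breakpoints x 2 strands x 2 sides x 500 bp = 4 kb of
#' genomic sequence at the default). Each match is extended: the flanking
#' microhomologies grow from the initial query to the maximum possible
#' extent, stopping just before the first mismatch between the junction
#' (molecule) and template sequences. Distinct maximal hits are counted as
#' candidates and the preferred hit is selected by [select_template()].
#'
#' @param query An `svj_template_query` from [build_template_query()].
#' @param reference Reference sequence (character, raw, or `DNAString`).
#' @param svCall The insertion call the query was built from.
#' @param window Search span per side of each breakpoint, in bp. Windows
#'   truncated by a contig edge are searched over the reduced span and
#'   reported as truncated.
#' @return A list of class `svj_template_result` with `allHits` (data
#'   frame), `nCandidates`, `selectedHit` (one-row data frame or `NULL`),
#'   `searchSpace` (= 4 kb at defaults), and `truncated`.
#' @export
scan_templates <- function(query, reference, svCall, window = 500L) {
  stopifnot(inherits(query, "svj_template_query"))
  ref <- .as_seq_raw(reference)
  N <- length(ref)
  mol <- charToRaw(svCall$moleculeSeq)
  P <- c(svCall$pos1, svCall$pos2)
  q <- query$querySeq
  qrc <- revcomp(q)
  L0 <- nchar(q)
  f <- query$flankPerSide

  truncated <- c(FALSE, FALSE)
  rows <- list()
  for (bp in 1:2) {
    lo <- P[bp] - window; hi <- P[bp] + window
    if (lo < 1L || hi > N) truncated[bp] <- TRUE
    lo <- max(1L, lo); hi <- min(N, hi)
    win <- Biostrings::DNAString(rawToChar(ref[lo:hi]))
    for (strand in c("top", "bottom")) {
      pat <- if (strand == "top") q else qrc
      mt <- Biostrings::matchPattern(pat, win)
      starts <- BiocGenerics::start(mt)
      for (s0 in starts) {
        t0 <- lo + s0 - 1L
        t1 <- t0 + L0 - 1L
        ext <- .extend_hit(mol, ref, query$qs, query$qe, t0, t1, strand)
        rows[[length(rows) + 1L]] <- data.frame(
          svId = svCall$id, breakpointIndex = bp, strand = strand,
          matchStart = t0, matchEnd = t1,
          refStart = ext$refStart, refEnd = ext$refEnd,
          primingMh = f + ext$pe, resolvingMh = f + ext$re,
          totalSpan = ext$refEnd - ext$refStart + 1L,
          distanceToJunction = .hit_distance(ext$refStart, ext$refEnd,
                                             bp, P[1L], P[2L]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  # merge overlapping sub-hits: distinct maximal hits only
  hits <- hits[!duplicated(hits[, c("breakpointIndex", "strand",
                                    "refStart", "refEnd")]), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(allHits = hits, nCandidates = nrow(hits),
                 selectedHit = select_template(hits),
                 searchSpace = 4L * as.integer(window) * 2L,
                 truncated = truncated),
            class = "svj_template_result")
}

.empty_hits <- function() {
  data.frame(svId = character(0L), breakpointIndex = integer(0L),
             strand = character(0L), matchStart = integer(0L),
             matchEnd = integer(0L), refStart = integer(0L),
             refEnd = integer(0L), primingMh = integer(0L),
             resolvingMh = integer(0L), totalSpan = integer(0L),
             distanceToJunction = integer(0L), stringsAsFactors = FALSE)
}

# maximal flank extension of a template match against the molecule
.extend_hit <- function(mol, ref, qs, qe, t0, t1, strand) {
  nm <- length(mol); N <- length(ref)
  pe <- 0L; re <- 0L
  if (strand == "top") {
    while (qs - 1L - pe >= 1L && t0 - 1L - pe >= 1L &&
           mol[qs - 1L - pe] == ref[t0 - 1L - pe]) pe <- pe + 1L
    while (qe + 1L + re <= nm && t1 + 1L + re <= N &&
           mol[qe + 1L + re] == ref[t1 + 1L + re]) re <- re + 1L
    list(refStart = t0 - pe, refEnd = t1 + re, pe = pe, re = re)
  } else {
    while (qs - 1L - pe >= 1L && t1 + 1L + pe <= N &&
           mol[qs - 1L - pe] == .comp_raw(ref[t1 + 1L + pe])) pe <- pe + 1L
    while (qe + 1L + re <= nm && t0 - 1L - re >= 1L &&
           mol[qe + 1L + re] == .comp_raw(ref[t0 - 1L - re])) re <- re + 1L
    list(refStart = t0 - re, refEnd = t1 + pe, pe = pe, re = re)
  }
}

# signed distance of the nearest template base to its breakpoint:
# negative into retained sequence, positive into lost, 0 when crossing
.hit_distance <- function(refStart, refEnd, bp, P1, P2) {
  if (bp == 1L) { dLo <- refStart - P1; dHi <- refEnd - P1 }
  else { dLo <- P2 - refEnd; dHi <- P2 - refStart }
  if (dLo <= 0L && dHi >= 0L) return(0L)
  if (dHi < 0L) dHi else dLo
}

#' Select the preferred template among candidate hits
#'
#' Prefers the template with the longest span including the flanking
#' microhomologies; ties are broken by the template closest to the
#' junction, then deterministically by breakpoint 1 before 2, top strand
#' before bottom, and smaller start coordinate.
#'
#' @param hits A hits data frame or an `svj_template_result`.
#' @return A one-row data frame, or `NULL` when there are no hits.
#' @export
select_template <- function(hits) {
  if (inherits(hits, "svj_template_result")) hits <- hits$allHits
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(-hits$totalSpan, abs(hits$distanceToJunction),
             hits$breakpointIndex, hits$strand == "bottom", hits$refStart)
  hits[o[1L], , drop = FALSE]
}

#' Classify an insertion template by strand and placement
#'
#' Relative to a deletion junction oriented to transcription: foldback and
#' palindrome templates lie in retained sequence on the bottom strand
#' (palindrome when the extended template equals its own reverse
#' complement), cross-junction templates in retained sequence on the top
#' strand, strand-switching templates on the bottom strand at least
#' partially in lost sequence, and expansion templates on the top strand
#' crossing the breakpoint from retained into lost sequence. Top-strand
#' hits fully within lost sequence are flagged `unclassified`. Retained
#' and lost segments are defined relative to the breakpoint positions, and
#' cleanly only for deletions: for duplications and inversions the same
#' geometric rule is applied but the class is flagged low-confidence.
#'
#' @param hit A one-row hit data frame from [scan_templates()].
#' @param svCall The call the hit belongs to.
#' @param reference Optional reference, needed for the palindrome
#'   subclassification.
#' @return A list with `class` and `lowConfidence`.
#' @export
classify_template <- function(hit, svCall, reference = NULL) {
  P1 <- svCall$pos1; P2 <- svCall$pos2
  span <- hit$refStart:hit$refEnd
  nLost <- sum(span > P1 & span < P2)
  nRetained <- length(span) - nLost
  cls <- if (hit$strand == "bottom") {
    if (nLost == 0L) "foldback" else "strand_switching"
  } else {
    if (nLost == 0L) "cross_junction"
    else if (nRetained >= 1L) "expansion"
    else "unclassified"
  }
  if (cls == "foldback" && !is.null(reference)) {
    ref <- .as_seq_raw(reference)
    s <- rawToChar(ref[hit$refStart:hit$refEnd])
    if (identical(s, revcomp(s))) cls <- "palindrome"
  }
  list(class = cls, lowConfidence = !identical(svCall$type, "DEL"))
}

#' Discover and classify insertion templates for a cohort of calls
#'
#' Runs [build_template_query()], [scan_templates()], [select_template()],
#' and [classify_template()] over every insertion call carrying a molecule
#' sequence, producing a per-SV summary and the full candidate hit table.
#'
#' @param calls Calls data frame.
#' @param reference Reference sequence.
#' @param window Search window per side (bp).
#' @return A list with `summary` (one row per searched insertion: query
#'   size, candidate count, selected-hit fields, class) and `hits` (all
#'   candidate hits).
#' @export
discover_templates <- function(calls, reference, window = 500L) {
  ref <- .as_seq_raw(reference)
  ins <- calls[!is.na(calls$offset) & calls$offset >= 1L &
                 !is.na(calls$moleculeSeq), , drop = FALSE]
  sm <- list(); allh <- list()
  for (i in seq_len(nrow(ins))) {
    call <- ins[i, ]
    qu <- build_template_query(call)
    res <- scan_templates(qu, ref, call, window = window)
    sel <- res$selectedHit
    cl <- if (!is.null(sel)) classify_template(sel, call, ref)
    sm[[i]] <- data.frame(
      svId = call$id, insertSize = qu$insertSize,
      nTemplateBases = qu$nTemplateBases, nCandidates = res$nCandidates,
      found = !is.null(sel),
      breakpointIndex = if (!is.null(sel)) sel$breakpointIndex else NA_integer_,
      strand = if (!is.null(sel)) sel$strand else NA_character_,
      matchStart = if (!is.null(sel)) sel$matchStart else NA_integer_,
      matchEnd = if (!is.null(sel)) sel$matchEnd else NA_integer_,
      refStart = if (!is.null(sel)) sel$refStart else NA_integer_,
      refEnd = if (!is.null(sel)) sel$refEnd else NA_integer_,
      primingMh = if (!is.null(sel)) sel$primingMh else NA_integer_,
      resolvingMh = if (!is.null(sel)) sel$resolvingMh else NA_integer_,
      totalSpan = if (!is.null(sel)) sel$totalSpan else NA_integer_,
      distanceToJunction = if (!is.null(sel)) sel$distanceToJunction
                           else NA_integer_,
      class = if (!is.null(sel)) cl$class else NA_character_,
      lowConfidence = if (!is.null(sel)) cl$lowConfidence else NA,
      pos1 = call$pos1, pos2 = call$pos2,
      txFlipped = isTRUE(call$txFlipped),
      stringsAsFactors = FALSE
    )
    if (nrow(res$allHits)) allh[[length(allh) + 1L]] <- res$allHits
  }
  summary <- if (length(sm)) do.call(rbind, sm) else NULL
  hits <- if (length(allh)) do.call(rbind, allh) else .empty_hits()
  rownames(hits) <- NULL
  if (!is.null(summary)) rownames(summary) <- NULL
  list(summary = summary, hits = hits)
}

#' Pileup of template-contributing positions by class and breakpoint side
#'
#' For each selected template hit, every base of the maximally extended
#' template contributes one unit at its position relative to the hit's
#' breakpoint (negative into retained sequence, positive into lost).
#' Breakpoint side labels follow transcription orientation: for calls
#' flagged `txFlipped` the side labels are swapped.
#'
#' @param templateSummary The `summary` data frame from
#'   [discover_templates()] (rows with `found == TRUE` are used).
#' @return A data frame with `class`, `side`, `position`, `count`.
#' @export
template_position_pileup <- function(templateSummary) {
  ts <- templateSummary[!is.na(templateSummary$found) &
                          templateSummary$found, , drop = FALSE]
  if (nrow(ts) == 0L) {
    return(data.frame(class = character(0L), side = integer(0L),
                      position = integer(0L), count = integer(0L)))
  }
  rows <- lapply(seq_len(nrow(ts)), function(i) {
    h <- ts[i, ]
    span <- h$refStart:h$refEnd
    pos <- if (h$breakpointIndex == 1L) span - h$pos1 else h$pos2 - span
    side <- h$breakpointIndex
    if (isTRUE(h$txFlipped)) side <- 3L - side
    data.frame(class = h$class, side = side, position = pos,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(long))),
                          by = long[, c("class", "side", "position")],
                          FUN = sum)
  agg[order(agg$class, agg$side, agg$position), , drop = FALSE]
}
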