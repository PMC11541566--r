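#' @title SV junction data model and junction characterization
#'
#' @description
#' An SV call records one de novo breakpoint junction with breakpoints in
#' two coordinate systems: the reference genome (`refPos`, 1-based position
#' of the last aligned base nearest the junction on each side) and the
#' SV-containing source molecule (`moleculePos`, 1-based index of that same
#' base in the molecule sequence). The junction structure is summarized by a
#' signed breakpoint offset in molecule coordinates: microhomologies are
#' negative offsets (the same molecule bases align to both reference
#' breakpoints), blunt joints are offset 0, and de novo insertions are
#' positive offsets with the inserted bases recorded.
#'
#' @details
#' Conventions used throughout the package:
#' * reference positions are 1-based inclusive; BED input/output converts
#'   from 0-based half-open at the boundary;
#' * "top strand" always means the reference forward strand; transcription
#'   orientation is applied only at reporting and classification;
#' * for intrachromosomal calls `pos1 <= pos2` in the reference; the segment
#'   order in the molecule follows the SV type (a tandem duplication
#'   junction runs from the `pos2` side into the `pos1` side).
#'
#' @name junction-model
NULL

# molecule-order segment indices per SV type: which stored breakpoint is the
# first (left) aligned segment of the molecule and which is the second
.mol_order <- function(type) {
  if (identical(type, "DUP")) c(2L, 1L) else c(1L, 2L)
}

# strand of the second aligned segment in molecule order
.seg2_strand <- function(type) if (identical(type, "INV")) "-" else "+"

.bp_pos <- function(bp, field) {
  if (is.list(bp)) {
    v <- bp[[field]]
    if (is.null(v)) stop("breakpoint is missing field '", field, "'")
    return(as.integer(v))
  }
  as.integer(bp)
}

#' Characterize a junction from dual-coordinate breakpoints
#'
#' Computes the signed breakpoint offset and any inserted bases of one SV
#' junction from the molecule-coordinate positions of its two breakpoints.
#' With `a` the molecule index of the first segment's last aligned base and
#' `b` the molecule index of the second segment's first aligned base, the
#' offset is `b - a - 1`: negative for microhomology (overlapping
#' alignments, microhomology length `-offset`), zero for a blunt joint, and
#' positive for a de novo insertion whose bases are `moleculeSeq[(a+1)..(b-1)]`.
#'
#' @param moleculeSeq Character string, the SV source molecule sequence.
#' @param bp1 First breakpoint in molecule order: either the molecule
#'   position of its last aligned base, or a list with a `moleculePos` field.
#' @param bp2 Second breakpoint in molecule order (its first aligned base),
#'   same forms accepted.
#' @return A list with elements `offset` (integer) and `insertedBases`
#'   (character, empty unless `offset > 0`).
#' @export
#' @examples
#' characterize_junction("ACGTACGTAC", 5, 6)   # blunt
#' characterize_junction("ACGTACGTAC", 5, 3)   # 3 bp microhomology
#' characterize_junction("ACGTACGTAC", 3, 7)   # 3 bp insertion "TAC"
characterize_junction <- function(moleculeSeq, bp1, bp2) {
  a <- .bp_pos(bp1, "moleculePos")
  b <- .bp_pos(bp2, "moleculePos")
  n <- nchar(moleculeSeq)
  if (b < 1L || a > n) {
    stop("malformed call: breakpoint molecule positions (a=", a, ", b=", b,
         ") fall outside the molecule (length ", n, ")")
  }
  offset <- b - a - 1L
  inserted <- if (offset > 0L) substr(moleculeSeq, a + 1L, b - 1L) else ""
  list(offset = offset, insertedBases = inserted)
}

#' Canonicalize a junction to maximal microhomology
#'
#' Upstream aligners place ambiguous (shiftable) breakpoints arbitrarily.
#' This extends both alignments against the molecule to the maximal extent
#' supported by the reference flanks -- each alignment grows toward (and,
#' for microhomologies, past) the other until the first mismatch -- so the
#' reported microhomology is the maximal number of bases identical between
#' the two reference flanks across the junction. The operation is
#' idempotent, never decreases microhomology length, and never turns a
#' microhomology into an insertion.
#'
#' @param moleculeSeq Character string, the SV molecule.
#' @param reference Reference sequence (character string, raw vector, or
#'   `DNAString`); flanks of at least 50 bp around both breakpoints must be
#'   available.
#' @param bp1,bp2 Breakpoints in molecule order, lists with `refPos` and
#'   `moleculePos` fields.
#' @param strand2 Strand of the second aligned segment: `"+"` (deletions,
#'   duplications) or `"-"` (inversion junctions).
#' @return A list with `offset`, `insertedBases`, and canonicalized `bp1`
#'   and `bp2` (each a list with `refPos` and `moleculePos`).
#' @export
canonicalize_offset <- function(moleculeSeq, reference, bp1, bp2,
                                strand2 = "+") {
  ref <- .as_seq_raw(reference)
  mol <- charToRaw(moleculeSeq)
  n <- length(mol)
  a <- .bp_pos(bp1, "moleculePos"); u <- .bp_pos(bp1, "refPos")
  b <- .bp_pos(bp2, "moleculePos"); v <- .bp_pos(bp2, "refPos")
  if (u < 1L || u > length(ref) || v < 1L || v > length(ref)) {
    stop("reference window unavailable for breakpoints at ", u, " and ", v)
  }
  if (b < 1L || a > n) stop("malformed call: molecule positions out of range")

  # extend segment 1 rightward along the reference
  while (a + 1L <= n && u + 1L <= length(ref) && mol[a + 1L] == ref[u + 1L]) {
    a <- a + 1L; u <- u + 1L
  }
  # extend segment 2 leftward (strand-aware on the reference)
  repeat {
    if (b - 1L < 1L) break
    prv <- if (identical(strand2, "+")) {
      if (v - 1L < 1L) break
      ref[v - 1L]
    } else {
      if (v + 1L > length(ref)) break
      .comp_raw(ref[v + 1L])
    }
    if (mol[b - 1L] != prv) break
    b <- b - 1L
    v <- if (identical(strand2, "+")) v - 1L else v + 1L
  }
  offset <- b - a - 1L
  inserted <- if (offset > 0L) rawToChar(mol[(a + 1L):(b - 1L)]) else ""
  list(offset = offset, insertedBases = inserted,
       bp1 = list(refPos = u, moleculePos = a),
       bp2 = list(refPos = v, moleculePos = b))
}

# canonicalize every row of a calls table in place; requires moleculeSeq
.canonicalize_calls <- function(calls, reference) {
  ref <- .as_seq_raw(reference)
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$moleculeSeq[i]) || !nzchar(calls$moleculeSeq[i])) next
    ord <- .mol_order(calls$type[i])
    pos <- c(calls$pos1[i], calls$pos2[i])
    mpos <- c(calls$moleculePos1[i], calls$moleculePos2[i])
    cz <- canonicalize_offset(
      calls$moleculeSeq[i], ref,
      bp1 = list(refPos = pos[ord[1L]], moleculePos = mpos[ord[1L]]),
      bp2 = list(refPos = pos[ord[2L]], moleculePos = mpos[ord[2L]]),
      strand2 = .seg2_strand(calls$type[i])
    )
    pos[ord[1L]] <- cz$bp1$refPos; pos[ord[2L]] <- cz$bp2$refPos
    mpos[ord[1L]] <- cz$bp1$moleculePos; mpos[ord[2L]] <- cz$bp2$moleculePos
    calls$pos1[i] <- pos[1L]; calls$pos2[i] <- pos[2L]
    calls$moleculePos1[i] <- mpos[1L]; calls$moleculePos2[i] <- mpos[2L]
    calls$offset[i] <- cz$offset
    calls$insertedBases[i] <- cz$insertedBases
    if (calls$chrom1[i] == calls$chrom2[i]) {
      calls$size[i] <- abs(calls$pos2[i] - calls$pos1[i])
    }
  }
  calls
}

#' Orient an SV call to the transcription strand of its target gene
#'
#' Junction reporting conventions (left/right breakpoint, template pileup
#' sides) follow the transcription direction of the captured gene. When the
#' gene is on the reference minus strand, both the molecule and the locus
#' are viewed reverse-complemented: breakpoint side labels swap while
#' template strand labels are unchanged (a foldback stays a foldback).
#' Orientation is a reporting-level toggle -- storage coordinates are never
#' rewritten -- and applying the operation twice restores the original call.
#'
#' @param svCall A one-row data frame (or list) with at least `chrom1`,
#'   `pos1`, `chrom2`, `pos2`; a `txFlipped` logical field is added/toggled.
#' @param targetRegion A one-row data frame (or list) with `chrom`,
#'   `captureStart`, `captureEnd`, `pad`, `transcriptionStrand`.
#' @return The call with its `txFlipped` field set.
#' @export
orient_to_transcription <- function(svCall, targetRegion) {
  tr <- as.list(targetRegion)
  if (!svCall$chrom1 == svCall$chrom2) {
    stop("orientation is defined for intrachromosomal calls only")
  }
  lo <- tr$captureStart - tr$pad
  hi <- tr$captureEnd + tr$pad
  if (svCall$chrom1 != tr$chrom ||
      svCall$pos2 < lo || svCall$pos1 > hi) {
    stop("call does not overlap the target interrogation span")
  }
  cur <- isTRUE(svCall$txFlipped)
  svCall$txFlipped <- xor(cur, identical(tr$transcriptionStrand, "-"))
  svCall
}
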