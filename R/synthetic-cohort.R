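#' Configuration for a synthetic SV-junction cohort
#'
#' Builds the full parameter set of the synthetic-cohort generator. The
#' defaults emulate the empirical junction profile of replication-stress
#' deletions at common fragile sites: a microhomology peak at 2 bp, a
#' substantial minority (~25%) of de novo insertions, insertion templates
#' concentrated within ~20 bp of breakpoints, and priming/resolving
#' microhomologies peaking at 2-3 bp. Three presets are provided via
#' `mode`: `"TMEJ"` (the defaults), `"NHEJ_like"` (shorter microhomology,
#' more blunt joints, few templated insertions), and `"POLQ_KO"` (near
#' absence of insertions >= 3 bp and a peak microhomology shift from 2 bp
#' to 1 bp).
#'
#' @param seed Integer seed; fully determines every generated byte.
#' @param genomeLength Reference length in bp.
#' @param target 1-based inclusive (start, end) of the single capture
#'   target region.
#' @param nSamplesPerGroup Samples per experimental group.
#' @param groups Group labels.
#' @param batches Batch labels, assigned round-robin within each group.
#' @param meanCoverage Mean adjusted target fold-coverage per sample.
#' @param svRatePerHaplotype Named per-group Poisson rate of de novo SVs
#'   per unit of fold-coverage (the SV frequency being simulated).
#' @param dispersionTheta Negative-binomial shape for per-sample SV counts.
#' @param mechanismMix Probabilities over junction mechanisms
#'   (`microhomology`, `blunt`, `insertion`).
#' @param mhLengthDist Categorical distribution over microhomology lengths
#'   1..10 bp.
#' @param insertionSizeDist Categorical distribution over insertion sizes
#'   1..20 bp.
#' @param templatedFraction Probability that an insertion at a deletion
#'   junction is copied from a local template.
#' @param templateClassMix Probabilities over template classes
#'   (`foldback`, `cross_junction`, `strand_switching`, `expansion`).
#' @param templateDistanceDist Categorical distribution over template
#'   distances 0..50 bp from the breakpoint.
#' @param primingResolvingMhDist Categorical distribution over planted
#'   priming/resolving microhomology lengths 1..5 bp.
#' @param svSizeDist List with `medianBp`, `sdLog`, `minBp`, `maxBp`:
#'   log-normal SV sizes truncated to the stated window.
#' @param svTypeMix Probabilities over SV types (`DEL`, `DUP`, `INV`).
#' @param pad Target padding in bp defining the allowable breakpoint span.
#' @param transcriptionStrand Transcription strand of the simulated gene.
#' @param moleculeLenRange Source molecule length range in bp.
#' @param chrom Name of the simulated contig.
#' @param mode Preset profile; explicit arguments override preset values.
#' @return An object of class `svj_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genomeLength = 4e6,
                       target = c(1800001L, 2200000L),
                       nSamplesPerGroup = 6L,
                       groups = c("A", "B"),
                       batches = c("b1", "b2"),
                       meanCoverage = 100,
                       svRatePerHaplotype = c(A = 0.02, B = 0.10),
                       dispersionTheta = 10,
                       mechanismMix = NULL,
                       mhLengthDist = NULL,
                       insertionSizeDist = NULL,
                       templatedFraction = NULL,
                       templateClassMix = c(foldback = 0.45,
                                            cross_junction = 0.30,
                                            strand_switching = 0.05,
                                            expansion = 0.20),
                       templateDistanceDist = NULL,
                       primingResolvingMhDist = c(0.15, 0.30, 0.30,
                                                  0.15, 0.10),
                       svSizeDist = list(medianBp = 2e5, sdLog = 0.8,
                                         minBp = 1e4, maxBp = 1.2e6),
                       svTypeMix = c(DEL = 0.8, DUP = 0.1, INV = 0.1),
                       pad = 800000L,
                       transcriptionStrand = "+",
                       moleculeLenRange = c(300L, 600L),
                       chrom = "simref",
                       mode = c("TMEJ", "NHEJ_like", "POLQ_KO")) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    TMEJ = list(
      mechanismMix = c(microhomology = 0.62, blunt = 0.12, insertion = 0.26),
      mhLengthDist = c(0.22, 0.34, 0.16, 0.10, 0.06, 0.04, 0.03, 0.02,
                       0.02, 0.01),
      insertionSizeDist = local({
        w <- exp(-0.22 * (0:19)); w / sum(w)
      }),
      templatedFraction = 0.5
    ),
    NHEJ_like = list(
      mechanismMix = c(microhomology = 0.42, blunt = 0.40, insertion = 0.18),
      mhLengthDist = c(0.40, 0.22, 0.13, 0.09, 0.06, 0.04, 0.03, 0.01,
                       0.01, 0.01),
      insertionSizeDist = local({
        w <- exp(-0.5 * (0:19)); w / sum(w)
      }),
      templatedFraction = 0.1
    ),
    POLQ_KO = list(
      mechanismMix = c(microhomology = 0.80, blunt = 0.16, insertion = 0.04),
      mhLengthDist = c(0.40, 0.25, 0.13, 0.08, 0.05, 0.03, 0.02, 0.02,
                       0.01, 0.01),
      insertionSizeDist = local({
        w <- c(0.70, 0.25, 0.05 * exp(-0.5 * (0:17)) /
                 sum(exp(-0.5 * (0:17))))
        w / sum(w)
      }),
      templatedFraction = 0
    )
  )
  if (is.null(mechanismMix)) mechanismMix <- preset$mechanismMix
  if (is.null(mhLengthDist)) mhLengthDist <- preset$mhLengthDist
  if (is.null(insertionSizeDist)) insertionSizeDist <- preset$insertionSizeDist
  if (is.null(templatedFraction)) templatedFraction <- preset$templatedFraction
  if (is.null(templateDistanceDist)) {
    w <- exp(-(0:50) / 12)
    templateDistanceDist <- w / sum(w)
  }

  cfg <- list(
    seed = as.integer(seed), genomeLength = as.integer(genomeLength),
    target = as.integer(target), nSamplesPerGroup = as.integer(nSamplesPerGroup),
    groups = groups, batches = batches, meanCoverage = meanCoverage,
    svRatePerHaplotype = svRatePerHaplotype,
    dispersionTheta = dispersionTheta,
    mechanismMix = mechanismMix, mhLengthDist = mhLengthDist,
    insertionSizeDist = insertionSizeDist,
    templatedFraction = templatedFraction,
    templateClassMix = templateClassMix,
    templateDistanceDist = templateDistanceDist,
    primingResolvingMhDist = primingResolvingMhDist,
    svSizeDist = svSizeDist, svTypeMix = svTypeMix,
    pad = as.integer(pad), transcriptionStrand = transcriptionStrand,
    moleculeLenRange = as.integer(moleculeLenRange), chrom = chrom,
    mode = mode
  )
  class(cfg) <- "svj_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config An `svj_sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "svj_sim_config"))
  .stopifnot_prob_vector(config$mechanismMix, "mechanismMix")
  .stopifnot_prob_vector(config$mhLengthDist, "mhLengthDist")
  .stopifnot_prob_vector(config$insertionSizeDist, "insertionSizeDist")
  .stopifnot_prob_vector(config$templateClassMix, "templateClassMix")
  .stopifnot_prob_vector(config$templateDistanceDist, "templateDistanceDist")
  .stopifnot_prob_vector(config$primingResolvingMhDist,
                         "primingResolvingMhDist")
  .stopifnot_prob_vector(config$svTypeMix, "svTypeMix")
  if (length(config$groups) < 1L || config$nSamplesPerGroup < 1L) {
    stop("config error: at least one group with at least one sample required")
  }
  if (config$meanCoverage <= 0) stop("config error: zero coverage")
  if (!all(config$groups %in% names(config$svRatePerHaplotype))) {
    stop("svRatePerHaplotype must be named for every group")
  }
  span <- config$target[2L] - config$target[1L] + 1L
  need <- 2 * (config$svSizeDist$maxBp + 500) + span
  if (config$genomeLength < need) {
    stop("sizing error: genomeLength ", config$genomeLength,
         " too small for max SV size plus search windows (need >= ", need, ")")
  }
  if (config$target[1L] <= 1000L ||
      config$target[2L] >= config$genomeLength - 1000L) {
    stop("target must leave room for breakpoint windows inside the genome")
  }
  config
}

#' Generate a random reference sequence
#'
#' I.i.d. uniform A/C/G/T bases; the seed fully determines the sequence.
#'
#' @param seed Integer seed.
#' @param genomeLength Length in bp; must leave room for the largest SV
#'   plus its breakpoint search windows on a target-sized region.
#' @param maxSvSize,window,targetSpan Sizing guards (defaults match the
#'   analysis defaults: 1.2 Mb maximum SV, 500 bp search window, 400 kb
#'   target).
#' @return A character string of uppercase bases.
#' @export
#' @examples
#' s <- make_reference(1, 3e6)
#' substr(s, 1, 10)
make_reference <- function(seed, genomeLength = 4e6, maxSvSize = 1.2e6,
                           window = 500, targetSpan = 4e5) {
  need <- 2 * (maxSvSize + window) + targetSpan
  if (genomeLength < need) {
    stop("sizing error: genomeLength ", genomeLength, " < required ", need)
  }
  .with_seed(seed, rawToChar(.random_bases(as.integer(genomeLength))))
}

# --- junction planting -------------------------------------------------

# Plant one junction into a raw reference vector. The reference is edited
# so that the planted structure is genuinely present and MAXIMAL: planted
# microhomology bases really match both breakpoint flanks and the next
# base mismatches on both sides; planted templates really occur at their
# coordinates with extension stopping exactly at the planted flanks.
# Every plant is re-verified by characterize/canonicalize round-trip.
.plant_junction_raw <- function(ref, type = "DEL", pos1, size,
                                mechanism, mhLen = 2L, insertSize = 3L,
                                templated = FALSE,
                                templateClass = "foldback",
                                templateSide = NULL,
                                templateDistance = NULL,
                                primingMh = NULL, resolvingMh = NULL,
                                leftFlank = NULL, rightFlank = NULL,
                                maxTries = 50L) {
  N <- length(ref)
  pos1 <- as.integer(pos1); size <- as.integer(size)
  pos2 <- pos1 + size
  if (pos1 - 700L < 1L || pos2 + 700L > N) {
    stop("sizing error: junction windows fall outside the reference")
  }
  if (size < 2000L) stop("sizing error: SV size too small for flanks")
  if (type == "DUP") { u <- pos2; v <- pos1; s2 <- "+" }
  else if (type == "INV") { u <- pos1; v <- pos2; s2 <- "-" }
  else { u <- pos1; v <- pos2; s2 <- "+" }
  lf <- if (is.null(leftFlank)) sample(150:300, 1L) else as.integer(leftFlank)
  rf <- if (is.null(rightFlank)) sample(150:300, 1L) else as.integer(rightFlank)

  seg2base <- function(j) {
    if (s2 == "+") ref[v + j - 1L] else .comp_raw(ref[v - j + 1L])
  }
  set_seg2base <- function(j, val) {
    if (s2 == "+") ref[v + j - 1L] <<- val
    else ref[v - j + 1L] <<- .comp_raw(val)
  }
  seg2prev <- function(i) {
    if (s2 == "+") ref[v - i] else .comp_raw(ref[v + i])
  }
  set_seg2prev <- function(i, val) {
    if (s2 == "+") ref[v - i] <<- val else ref[v + i] <<- .comp_raw(val)
  }
  seg2flank <- function(n) {
    if (s2 == "+") ref[v:(v + n - 1L)]
    else .comp_raw(ref[seq.int(v, v - n + 1L)])
  }
  in_windows <- function(x) {
    (x >= pos1 - 700L & x <= pos1 + 700L) |
      (x >= pos2 - 700L & x <= pos2 + 700L)
  }

  winIdx <- unique(c(
    seq.int(max(1L, pos1 - 700L), min(N, pos1 + 700L)),
    seq.int(max(1L, pos2 - 700L), min(N, pos2 + 700L))
  ))
  snap <- ref[winIdx]

  truth <- list(mechanism = mechanism, mhLen = NA_integer_,
                insertSize = NA_integer_, insertedBases = NA_character_,
                templated = FALSE, templateClass = NA_character_,
                templateStrand = NA_character_, templateSide = NA_integer_,
                matchStart = NA_integer_, matchEnd = NA_integer_,
                templateStart = NA_integer_, templateEnd = NA_integer_,
                primingMh = NA_integer_, resolvingMh = NA_integer_,
                distance = NA_integer_)

  for (try in seq_len(maxTries)) {
    ref[winIdx] <- snap
    ok <- TRUE

    if (mechanism == "microhomology") {
      m <- as.integer(mhLen)
      stopifnot(m >= 1L, m <= 50L)
      for (j in seq_len(m)) set_seg2base(j, ref[u - m + j])
      if (seg2base(m + 1L) == ref[u + 1L]) {
        ref[u + 1L] <- .base_not_in(seg2base(m + 1L))
      }
      if (ref[u - m] == seg2prev(1L)) {
        set_seg2prev(1L, .base_not_in(ref[u - m]))
      }
      molSeq <- rawToChar(c(ref[(u - lf + 1L):u], seg2flank(rf)[(m + 1L):rf]))
      a <- lf; b <- lf - m + 1L
      plannedOffset <- -m
      truth$mhLen <- m
    } else if (mechanism == "blunt") {
      if (seg2base(1L) == ref[u + 1L]) {
        ref[u + 1L] <- .base_not_in(seg2base(1L))
      }
      if (ref[u] == seg2prev(1L)) set_seg2prev(1L, .base_not_in(ref[u]))
      molSeq <- rawToChar(c(ref[(u - lf + 1L):u], seg2flank(rf)))
      a <- lf; b <- lf + 1L
      plannedOffset <- 0L
      truth$mhLen <- 0L
    } else if (mechanism == "insertion" && !templated) {
      k <- as.integer(insertSize)
      I <- .random_bases(k)
      # inserted end bases must not extend either alignment
      if (k == 1L) {
        I[1L] <- .base_not_in(c(ref[u + 1L], seg2prev(1L)))
      } else {
        I[1L] <- .base_not_in(ref[u + 1L])
        I[k] <- .base_not_in(seg2prev(1L))
      }
      molSeq <- rawToChar(c(ref[(u - lf + 1L):u], I, seg2flank(rf)))
      a <- lf; b <- lf + k + 1L
      plannedOffset <- k
      truth$insertSize <- k
      truth$insertedBases <- rawToChar(I)
    } else if (mechanism == "insertion" && templated) {
      if (type != "DEL") stop("templated insertions are planted on DEL only")
      k <- as.integer(insertSize)
      f <- max(1L, as.integer(ceiling((7L - k) / 2)))
      p <- if (is.null(primingMh)) max(f, 2L) else as.integer(primingMh)
      r <- if (is.null(resolvingMh)) max(f, 2L) else as.integer(resolvingMh)
      if (p < f || r < f) {
        stop("priming/resolving microhomology must be >= flankPerSide (", f, ")")
      }
      side <- if (is.null(templateSide)) sample(1:2, 1L)
              else as.integer(templateSide)
      cls <- templateClass
      I <- .random_bases(k)

      if (cls %in% c("foldback", "cross_junction", "strand_switching")) {
        L <- p + k + r
        d <- if (is.null(templateDistance)) {
          if (cls == "strand_switching") 10L
          else max(p, r) + 2L + 8L
        } else as.integer(templateDistance)
        if (cls == "strand_switching") {
          if (d < 1L) stop("strand-switching template distance must be >= 1")
          if (side == 1L) { t <- u + 1L + d; e <- t + L - 1L }
          else            { e <- v - 1L - d; t <- e - L + 1L }
          if (t < u + 2L || e > v - 2L) {
            stop("template site does not fit in lost sequence")
          }
        } else {
          if (side == 1L) {
            if (d < p + 2L) stop("retained template distance must be >= primingMh + 2")
            e <- u - d; t <- e - L + 1L
          } else {
            if (d < r + 2L) stop("retained template distance must be >= resolvingMh + 2")
            t <- v + d; e <- t + L - 1L
          }
        }
        if (!in_windows(t - 1L) || !in_windows(e + 1L)) {
          stop("template site falls outside the 500 bp breakpoint windows")
        }
        Tfull <- c(ref[(u - p + 1L):u], I, ref[v:(v + r - 1L)])
        top <- cls == "cross_junction"
        ref[t:e] <- if (top) Tfull else .revcomp_raw(Tfull)
        # stop maximal extension exactly at the planted flanks
        stopL <- if (top) ref[u - p] else .comp_raw(ref[v + r])
        stopR <- if (top) ref[v + r] else .comp_raw(ref[u - p])
        exL <- c(stopL, if (t - 1L == u + 1L) I[1L],
                 if (t - 1L == v - 1L) I[k])
        exR <- c(stopR, if (e + 1L == u + 1L) I[1L],
                 if (e + 1L == v - 1L) I[k])
        if (ref[t - 1L] == stopL) ref[t - 1L] <- .base_not_in(exL)
        if (ref[e + 1L] == stopR) ref[e + 1L] <- .base_not_in(exR)
        if (I[1L] == ref[u + 1L] || I[k] == ref[v - 1L]) next
        truth$templateStart <- t; truth$templateEnd <- e
        if (top) {
          truth$matchStart <- t + (p - f); truth$matchEnd <- e - (r - f)
        } else {
          truth$matchStart <- t + (r - f); truth$matchEnd <- e - (p - f)
        }
        truth$templateStrand <- if (top) "top" else "bottom"
        truth$primingMh <- p; truth$resolvingMh <- r
        truth$distance <- if (cls == "strand_switching") d + 1L else -d
      } else if (cls == "expansion") {
        mUnits <- as.integer(ceiling(f / k)) + 1L
        if (side == 1L) {
          if (I[1L] == ref[v]) next
          blockStart <- u - mUnits * k + 1L
          ref[blockStart:u] <- rep(I, mUnits)
          if (I[k] == ref[v - 1L]) ref[v - 1L] <- .base_not_in(I[k])
          ref[(u + 1L):(u + f)] <- ref[v:(v + f - 1L)]
          if (ref[u + f + 1L] == ref[v + f]) {
            ref[u + f + 1L] <- .base_not_in(ref[v + f])
          }
          if (ref[blockStart - 1L] == ref[blockStart - 1L + k]) {
            ref[blockStart - 1L] <- .base_not_in(ref[blockStart - 1L + k])
          }
          truth$matchStart <- u - f - k + 1L; truth$matchEnd <- u + f
          truth$templateStart <- blockStart; truth$templateEnd <- u + f
        } else {
          if (I[k] == ref[u]) next
          blockEnd <- v + mUnits * k - 1L
          ref[v:blockEnd] <- rep(I, mUnits)
          ref[(v - f):(v - 1L)] <- ref[(u - f + 1L):u]
          if (I[1L] == ref[u + 1L]) ref[u + 1L] <- .base_not_in(I[1L])
          if (ref[v - f - 1L] == ref[u - f]) {
            ref[v - f - 1L] <- .base_not_in(ref[u - f])
          }
          if (ref[blockEnd + 1L] == ref[blockEnd + 1L - k]) {
            ref[blockEnd + 1L] <- .base_not_in(ref[blockEnd + 1L - k])
          }
          truth$matchStart <- v - f; truth$matchEnd <- v + k + f - 1L
          truth$templateStart <- v - f; truth$templateEnd <- blockEnd
        }
        truth$templateStrand <- "top"
        truth$distance <- 0L
      } else {
        stop("unknown template class '", cls, "'")
      }

      truth$templated <- TRUE
      truth$templateClass <- cls
      truth$templateSide <- side
      molSeq <- rawToChar(c(ref[(u - lf + 1L):u], I, seg2flank(rf)))
      a <- lf; b <- lf + k + 1L
      plannedOffset <- k
      truth$insertSize <- k
      truth$insertedBases <- rawToChar(I)
    } else {
      stop("unknown mechanism '", mechanism, "'")
    }

    # re-verify: the planted structure must round-trip exactly
    cz <- canonicalize_offset(molSeq, ref,
                              bp1 = list(refPos = u, moleculePos = a),
                              bp2 = list(refPos = v, moleculePos = b),
                              strand2 = s2)
    ok <- cz$offset == plannedOffset && cz$bp1$refPos == u &&
      cz$bp2$refPos == v
    if (ok && isTRUE(truth$templated)) {
      qSeq <- rawToChar(c(ref[(u - f + 1L):u], charToRaw(truth$insertedBases),
                          ref[v:(v + f - 1L)]))
      site <- rawToChar(ref[truth$matchStart:truth$matchEnd])
      ok <- if (truth$templateStrand == "top") identical(site, qSeq)
            else identical(revcomp(site), qSeq)
    }
    if (ok) break
    if (try == maxTries) {
      stop("planted edit kept creating a longer accidental microhomology; ",
           "giving up after ", maxTries, " attempts")
    }
  }

  mo <- .mol_order(type)
  mpos <- integer(2L); mpos[mo[1L]] <- a; mpos[mo[2L]] <- b
  outer <- switch(type,
    DEL = c(pos1 - lf + 1L, pos2 + rf - 1L),
    INV = c(pos1 - lf + 1L, pos2),
    DUP = c(pos1, pos2)
  )
  list(
    reference = ref,
    call = list(type = type, pos1 = pos1, pos2 = pos2,
                moleculePos1 = mpos[1L], moleculePos2 = mpos[2L],
                offset = plannedOffset,
                insertedBases = if (plannedOffset > 0L)
                  truth$insertedBases else "",
                size = size),
    moleculeSeq = molSeq,
    outerStart = outer[1L], outerEnd = outer[2L],
    truth = truth
  )
}

#' Plant a single SV junction into a reference sequence
#'
#' Edits the reference locally so that the requested junction mechanism is
#' genuinely and maximally present (planted microhomology bases match both
#' breakpoint flanks with a mismatch immediately beyond on both sides;
#' planted insertion templates occur exactly at their recorded coordinates
#' with extension stopping at the planted priming/resolving
#' microhomologies), then emits the junction-spanning molecule sequence,
#' the SV call, and a truth record. Each plant is verified by a
#' characterize/canonicalize round-trip; construction is retried with
#' fresh random draws if an edit would create a longer accidental
#' microhomology, and fails with an error if retries are exhausted.
#'
#' @param reference Reference sequence (character string or raw vector).
#' @param svSize SV size in bp (`pos2 - pos1`).
#' @param mechanism One of `"microhomology"`, `"blunt"`, `"insertion"`.
#' @param svType One of `"DEL"`, `"DUP"`, `"INV"`.
#' @param pos1 Reference position of the left breakpoint; defaults to the
#'   center of the reference.
#' @param mhLen Microhomology length for `mechanism = "microhomology"`.
#' @param insertSize Insertion size for `mechanism = "insertion"`.
#' @param templated Whether the insertion is copied from a local template
#'   (DEL only).
#' @param templateClass Template class to plant: `"foldback"`,
#'   `"cross_junction"`, `"strand_switching"`, or `"expansion"`.
#' @param templateSide Breakpoint (1 or 2) near which the template is
#'   placed; random if `NULL`.
#' @param templateDistance Distance in bp from the breakpoint to the
#'   nearest template base (class-dependent minimum applies).
#' @param primingMh,resolvingMh Planted flanking microhomology lengths
#'   (each must be at least the query flank size for the insertion size).
#' @param leftFlank,rightFlank Molecule flank lengths in bp (random
#'   150-300 if `NULL`).
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A list with `reference` (edited, same representation as the
#'   input), `call` (one-row data frame), `moleculeSeq`, and `truth`
#'   (one-row data frame).
#' @export
plant_junction <- function(reference, svSize, mechanism,
                           svType = "DEL", pos1 = NULL,
                           mhLen = 2L, insertSize = 3L, templated = FALSE,
                           templateClass = "foldback", templateSide = NULL,
                           templateDistance = NULL, primingMh = NULL,
                           resolvingMh = NULL, leftFlank = NULL,
                           rightFlank = NULL, seed = NULL) {
  ref <- .as_seq_raw(reference)
  if (is.null(pos1)) pos1 <- as.integer(floor(length(ref) / 2 - svSize / 2))
  run <- function() {
    .plant_junction_raw(ref, type = svType, pos1 = pos1, size = svSize,
                        mechanism = mechanism, mhLen = mhLen,
                        insertSize = insertSize, templated = templated,
                        templateClass = templateClass,
                        templateSide = templateSide,
                        templateDistance = templateDistance,
                        primingMh = primingMh, resolvingMh = resolvingMh,
                        leftFlank = leftFlank, rightFlank = rightFlank)
  }
  res <- if (is.null(seed)) run() else .with_seed(seed, run())
  call <- data.frame(
    id = "sv1", sample = "sample1", type = res$call$type,
    chrom1 = "ref", pos1 = res$call$pos1, chrom2 = "ref",
    pos2 = res$call$pos2, moleculePos1 = res$call$moleculePos1,
    moleculePos2 = res$call$moleculePos2, offset = res$call$offset,
    insertedBases = res$call$insertedBases, size = res$call$size,
    moleculeId = "mol1", moleculeSeq = res$moleculeSeq,
    stringsAsFactors = FALSE
  )
  truth <- cbind(data.frame(svId = "sv1", stringsAsFactors = FALSE),
                 as.data.frame(res$truth, stringsAsFactors = FALSE))
  list(reference = .seq_like(reference, res$reference), call = call,
       moleculeSeq = res$moleculeSeq, truth = truth)
}

# draw from a categorical distribution over `values`
.draw_cat <- function(values, prob, n = 1L) {
  values[sample.int(length(values), n, replace = TRUE, prob = prob)]
}

# draw conditioned on values >= lo (renormalized)
.draw_cat_min <- function(values, prob, lo) {
  keep <- values >= lo
  if (!any(keep & prob > 0)) stop("conditional draw has empty support")
  .draw_cat(values[keep], prob[keep])
}

.draw_trunc_lnorm <- function(n, medianBp, sdLog, minBp, maxBp) {
  out <- integer(0L)
  while (length(out) < n) {
    x <- stats::rlnorm(n * 2L, meanlog = log(medianBp), sdlog = sdLog)
    x <- x[x >= minBp & x <= maxBp]
    out <- c(out, as.integer(round(x)))
  }
  out[seq_len(n)]
}

.rp_draw <- function(n) {
  # >=3 read pairs for ~96% of molecules so the support filter sees both
  # passing and failing records
  hi <- stats::runif(n) < 0.96
  out <- integer(n)
  out[hi] <- 3L + stats::rgeom(sum(hi), 0.45)
  out[!hi] <- sample(1:2, sum(!hi), replace = TRUE)
  out
}

.mapq_draw <- function(n, pHigh = 0.92) {
  hi <- stats::runif(n) < pHigh
  out <- integer(n)
  out[hi] <- 60L
  out[!hi] <- sample(0:59, sum(!hi), replace = TRUE)
  out
}

#' Simulate a full synthetic capture-sequencing cohort
#'
#' Generates a random reference with one capture target, a sample manifest
#' with group and batch structure, per-sample source molecules reaching the
#' configured mean adjusted coverage, and de novo SV calls whose per-sample
#' counts are negative-binomial (mean = group rate x sample coverage,
#' shape = `dispersionTheta`). Every SV junction is planted into the
#' reference with known mechanism truth ([plant_junction()]), so that
#' junction characterization, template discovery, and the downstream
#' statistics can all be validated against the truth table.
#'
#' @param config An [sim_config()] object.
#' @param dir Optional output directory; when given, writes
#'   `reference.fa`, `targets.bed`, `molecules.tsv`, `svcalls.tsv`,
#'   `manifest.tsv`, `truth.tsv`, and echoes `config.yaml`.
#' @return A list with `reference` (character), `targets`, `samples`,
#'   `molecules`, `calls`, `truth` data frames, and the `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  config <- validate_sim_config(config)
  .with_seed(config$seed, .simulate_cohort_impl(config, dir))
}

.simulate_cohort_impl <- function(config, dir) {
  ref <- .random_bases(config$genomeLength)
  tStart <- config$target[1L]; tEnd <- config$target[2L]
  targetLen <- tEnd - tStart + 1L
  chrom <- config$chrom

  targets <- data.frame(
    name = "cfs_target", chrom = chrom, captureStart = tStart,
    captureEnd = tEnd, pad = config$pad,
    transcriptionStrand = config$transcriptionStrand,
    stringsAsFactors = FALSE
  )

  samples <- do.call(rbind, lapply(config$groups, function(g) {
    idx <- seq_len(config$nSamplesPerGroup)
    data.frame(
      sample = sprintf("%s_s%02d", g, idx), group = g,
      batch = config$batches[((idx - 1L) %% length(config$batches)) + 1L],
      stringsAsFactors = FALSE
    )
  }))

  # per-molecule expected adjusted contribution: mean(len) - 40, thinned by
  # the read-pair support retention, so measured coverage matches the config
  meanAdj <- mean(config$moleculeLenRange) - 40
  contrib <- 0.96 * meanAdj

  maxBpPos <- min(tEnd + config$pad, config$genomeLength - 701L)
  reserved <- matrix(numeric(0L), ncol = 2L)
  svCounter <- 0L

  # per-sample coverage, molecule demand, and SV demand
  nS <- nrow(samples)
  covS <- config$meanCoverage * exp(stats::rnorm(nS, 0, 0.1))
  nMolS <- as.integer(round(covS * targetLen / contrib))
  nSvsS <- stats::rnbinom(nS, size = config$dispersionTheta,
                          mu = config$svRatePerHaplotype[samples$group] * covS)

  # background (non-SV) molecules, placed inside the target
  mol_list <- lapply(seq_len(nS), function(si) {
    s <- samples$sample[si]; nMol <- nMolS[si]
    len <- sample(config$moleculeLenRange[1L]:config$moleculeLenRange[2L],
                  nMol, replace = TRUE)
    start <- tStart + floor(stats::runif(nMol) * (targetLen - len + 1L))
    data.frame(
      moleculeId = sprintf("%s_m%06d", s, seq_len(nMol)), sample = s,
      chrom = chrom, outerStart = as.integer(start),
      outerEnd = as.integer(start + len - 1L),
      readPairCount = .rp_draw(nMol), mapq1 = .mapq_draw(nMol),
      mapq2 = .mapq_draw(nMol), carriesSv = FALSE,
      stringsAsFactors = FALSE
    )
  })

  # plant SVs in a globally shuffled sample order so that any placement
  # failures (breakpoint-window collisions) are exchangeable across
  # samples rather than penalizing the samples processed last
  tasks <- rep(seq_len(nS), nSvsS)
  if (length(tasks) > 1L) tasks <- sample(tasks)
  plantedS <- integer(nS)
  sv_mols <- list(); sv_calls <- list(); sv_truths <- list()
  for (si in tasks) {
    s <- samples$sample[si]
    draw <- .draw_sv_params(config)
    placed <- FALSE
    for (attempt in 1:200) {
      p1 <- sample(tStart:tEnd, 1L)
      p2 <- p1 + draw$size
      if (p2 > maxBpPos) next
      w <- rbind(c(p1 - 700, p1 + 700), c(p2 - 700, p2 + 700))
      if (nrow(reserved) > 0L &&
          any(outer(w[, 1L], reserved[, 2L], "<=") &
              outer(w[, 2L], reserved[, 1L], ">="))) next
      placed <- TRUE
      break
    }
    if (!placed) next
    res <- tryCatch(
      .plant_junction_raw(ref, type = draw$type, pos1 = p1,
                          size = draw$size, mechanism = draw$mechanism,
                          mhLen = draw$mhLen, insertSize = draw$insertSize,
                          templated = draw$templated,
                          templateClass = draw$templateClass,
                          templateSide = draw$templateSide,
                          templateDistance = draw$templateDistance,
                          primingMh = draw$primingMh,
                          resolvingMh = draw$resolvingMh),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ref <- res$reference
    reserved <- rbind(reserved, w)
    svCounter <- svCounter + 1L
    plantedS[si] <- plantedS[si] + 1L
    molId <- sprintf("%s_sv%04d", s, plantedS[si])
    svId <- sprintf("sv%05d", svCounter)
    sv_mols[[svCounter]] <- data.frame(
      moleculeId = molId, sample = s, chrom = chrom,
      outerStart = res$outerStart, outerEnd = res$outerEnd,
      readPairCount = .rp_draw(1L), mapq1 = .mapq_draw(1L, 0.97),
      mapq2 = .mapq_draw(1L, 0.97), carriesSv = TRUE,
      stringsAsFactors = FALSE
    )
    sv_calls[[svCounter]] <- data.frame(
      id = svId, sample = s, type = res$call$type, chrom1 = chrom,
      pos1 = res$call$pos1, chrom2 = chrom, pos2 = res$call$pos2,
      moleculePos1 = res$call$moleculePos1,
      moleculePos2 = res$call$moleculePos2, offset = res$call$offset,
      insertedBases = res$call$insertedBases, size = res$call$size,
      moleculeId = molId, moleculeSeq = res$moleculeSeq,
      stringsAsFactors = FALSE
    )
    sv_truths[[svCounter]] <- cbind(
      data.frame(svId = svId, stringsAsFactors = FALSE),
      as.data.frame(res$truth, stringsAsFactors = FALSE)
    )
  }

  molecules <- rbind(do.call(rbind, mol_list), do.call(rbind, sv_mols))
  calls <- do.call(rbind, sv_calls)
  truth <- do.call(rbind, sv_truths)
  if (!is.null(calls)) {
    # stable order: by sample, then id
    o <- order(match(calls$sample, samples$sample), calls$id)
    calls <- calls[o, , drop = FALSE]
    truth <- truth[o, , drop = FALSE]
  }
  if (is.null(calls)) {
    calls <- data.frame(id = character(0L))
    truth <- data.frame(svId = character(0L))
  }
  rownames(molecules) <- rownames(calls) <- rownames(truth) <- NULL

  out <- list(reference = rawToChar(ref), targets = targets,
              samples = samples, molecules = molecules, calls = calls,
              truth = truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_reference(stats::setNames(out$reference, chrom),
                    file.path(dir, "reference.fa"))
    write_targets(targets, file.path(dir, "targets.bed"))
    write_molecules(molecules, file.path(dir, "molecules.tsv"))
    write_sv_calls(calls, file.path(dir, "svcalls.tsv"))
    write_manifest(samples, file.path(dir, "manifest.tsv"))
    .write_truth(truth, file.path(dir, "truth.tsv"))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(out)
}

# draw per-SV mechanism parameters from the configured distributions
.draw_sv_params <- function(config) {
  type <- .draw_cat(names(config$svTypeMix), config$svTypeMix)
  size <- .draw_trunc_lnorm(1L, config$svSizeDist$medianBp,
                            config$svSizeDist$sdLog,
                            config$svSizeDist$minBp, config$svSizeDist$maxBp)
  mech <- .draw_cat(names(config$mechanismMix), config$mechanismMix)
  out <- list(type = type, size = size, mechanism = mech,
              mhLen = 2L, insertSize = 3L, templated = FALSE,
              templateClass = "foldback", templateSide = NULL,
              templateDistance = NULL, primingMh = NULL, resolvingMh = NULL)
  if (mech == "microhomology") {
    out$mhLen <- .draw_cat(1:10, config$mhLengthDist)
  } else if (mech == "insertion") {
    k <- .draw_cat(1:20, config$insertionSizeDist)
    out$insertSize <- k
    out$templated <- type == "DEL" &&
      stats::runif(1L) < config$templatedFraction
    if (out$templated) {
      f <- max(1L, as.integer(ceiling((7L - k) / 2)))
      cls <- .draw_cat(names(config$templateClassMix), config$templateClassMix)
      out$templateClass <- cls
      out$templateSide <- sample(1:2, 1L)
      p <- .draw_cat_min(1:5, config$primingResolvingMhDist, f)
      r <- .draw_cat_min(1:5, config$primingResolvingMhDist, f)
      out$primingMh <- p; out$resolvingMh <- r
      if (cls == "strand_switching") {
        out$templateDistance <- .draw_cat_min(0:50,
                                              config$templateDistanceDist, 1L)
      } else if (cls != "expansion") {
        dmin <- if (out$templateSide == 1L) p + 2L else r + 2L
        out$templateDistance <- .draw_cat_min(0:50,
                                              config$templateDistanceDist,
                                              dmin)
      }
    }
  }
  out
}
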