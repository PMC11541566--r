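#' Binomial enrichment test for insertion-template yield
#'
#' Some insertion templates are expected locally by chance: exact matches
#' of an n-base query in the 4 kb searched around a junction arise at a
#' Poisson rate `mu = searchSpace / 4^nTemplateBases`, so the probability
#' that a junction yields at least one random match is
#' `pTrial = 1 - exp(-mu)`. Treating each searched junction of a given
#' insertion size as an independent Bernoulli trial, the p-value is the
#' upper binomial tail `P(X >= nFound)` with `X ~ Binomial(nSearched,
#' pTrial)` -- the likelihood of finding as many or more templates by
#' chance. p < 0.05 is conventionally taken as significant evidence for
#' local templating.
#'
#' @param nSearched Number of junctions searched.
#' @param nFound Number of junctions with a template found.
#' @param nTemplateBases Query length in bases (>= 7 by construction).
#' @param searchSpace Searched genomic bases per junction (4000 at the
#'   default 500 bp windows).
#' @return A list of class `svj_enrichment` with `mu`, `pTrial`, `pValue`
#'   and the inputs.
#' @export
#' @examples
#' enrichment_test(nSearched = 100, nFound = 40, nTemplateBases = 7)
enrichment_test <- function(nSearched, nFound, nTemplateBases,
                            searchSpace = 4000) {
  if (!.is_count(nSearched) || nSearched < 1) {
    stop("undefined test: nSearched must be a positive count")
  }
  if (!.is_count(nFound) || nFound > nSearched) {
    stop("nFound must be a count <= nSearched")
  }
  if (nTemplateBases < 7) stop("nTemplateBases must be >= 7")
  mu <- searchSpace * 4^(-nTemplateBases)
  pTrial <- -expm1(-mu)
  pValue <- stats::pbinom(nFound - 1, nSearched, pTrial, lower.tail = FALSE)
  structure(list(nSearched = as.integer(nSearched),
                 nFound = as.integer(nFound),
                 nTemplateBases = as.integer(nTemplateBases),
                 searchSpace = searchSpace, mu = mu, pTrial = pTrial,
                 pValue = pValue),
            class = "svj_enrichment")
}

#' @export
print.svj_enrichment <- function(x, ...) {
  cat("Template enrichment: ", x$nFound, "/", x$nSearched,
      " found (n=", x$nTemplateBases, " bases, pTrial=",
      format(x$pTrial, digits = 4), ", p=", format(x$pValue, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Per-insertion-size template enrichment over a cohort
#'
#' Stratifies searched insertion junctions by insertion size and applies
#' [enrichment_test()] within each stratum, using the initial query length
#' for that size as `nTemplateBases`.
#'
#' @param templateSummary The `summary` data frame from
#'   [discover_templates()].
#' @param searchSpace Searched bases per junction.
#' @return A data frame with one row per insertion size: `insertSize,
#'   nTemplateBases, nSearched, nFound, mu, pTrial, pValue`.
#' @export
enrichment_by_size <- function(templateSummary, searchSpace = 4000) {
  sizes <- sort(unique(templateSummary$insertSize))
  do.call(rbind, lapply(sizes, function(k) {
    sub <- templateSummary[templateSummary$insertSize == k, , drop = FALSE]
    et <- enrichment_test(nrow(sub), sum(sub$found),
                          sub$nTemplateBases[1L], searchSpace)
    data.frame(insertSize = k, nTemplateBases = et$nTemplateBases,
               nSearched = et$nSearched, nFound = et$nFound, mu = et$mu,
               pTrial = et$pTrial, pValue = et$pValue)
  }))
}

#' Junction profile summaries
#'
#' Two axes summarize a sample's junction profile: the mean microhomology
#' length over all junctions without a de novo insertion (offset <= 0,
#' blunt joints contributing zero), which reflects the strand-annealing
#' preference of the repair mechanism, and the fraction of all junctions
#' carrying a 2-15 bp insertion (inclusive), which reflects the extent of
#' potentially templated insertion synthesis.
#'
#' @param calls Calls data frame with offsets.
#' @return A list of class `svj_junction_profile` with
#'   `meanMhNoInsertion`, `fracInsertion2to15`, `offsetHistogram`
#'   (a table over offsets), and `nJunctions`. An empty call set yields an
#'   empty-profile marker (`nJunctions = 0`, `NA` summaries).
#' @export
junction_profile <- function(calls) {
  off <- calls$offset
  if (length(off) == 0L) {
    return(structure(list(meanMhNoInsertion = NA_real_,
                          fracInsertion2to15 = NA_real_,
                          offsetHistogram = table(integer(0L)),
                          nJunctions = 0L),
                     class = "svj_junction_profile"))
  }
  structure(list(
    meanMhNoInsertion = mean(-off[off <= 0L]),
    fracInsertion2to15 = mean(off >= 2L & off <= 15L),
    offsetHistogram = table(off),
    nJunctions = length(off)
  ), class = "svj_junction_profile")
}

#' @export
print.svj_junction_profile <- function(x, ...) {
  cat("Junction profile over", x$nJunctions, "junctions:\n")
  cat("  mean microhomology (non-insertion junctions):",
      format(x$meanMhNoInsertion, digits = 4), "bp\n")
  cat("  fraction with 2-15 bp insertions:",
      format(x$fracInsertion2to15, digits = 4), "\n")
  invisible(x)
}

#' Per-sample junction profiles
#'
#' @param calls Calls data frame.
#' @param samples Sample manifest; samples without calls get `NA` rows.
#' @return A data frame with one row per sample.
#' @export
junction_profiles_by_sample <- function(calls, samples) {
  do.call(rbind, lapply(samples$sample, function(s) {
    pr <- junction_profile(calls[calls$sample == s, , drop = FALSE])
    data.frame(sample = s,
               nJunctions = pr$nJunctions,
               meanMhNoInsertion = pr$meanMhNoInsertion,
               fracInsertion2to15 = pr$fracInsertion2to15,
               stringsAsFactors = FALSE)
  }))
}

#' Count kept SVs per sample
#'
#' @param keptCalls Filtered calls data frame.
#' @param samples Sample manifest.
#' @return Named integer vector over all manifest samples (zeros kept).
#' @export
count_svs_per_sample <- function(keptCalls, samples) {
  n <- table(factor(keptCalls$sample, levels = samples$sample))
  stats::setNames(as.integer(n), samples$sample)
}

#' Compare SV frequency between two experimental groups
#'
#' Detected SV counts follow a Poisson process whose exposure is the
#' sample's target fold-coverage; inter-sample technical variation makes
#' the counts overdispersed, so the comparison fits a negative-binomial
#' GLM, `nSvs ~ group + batch + offset(log(coverage))`, with group and
#' batch as independent covariates and coverage as an offset of slope 1
#' (so the group coefficient is the log SV-frequency ratio). The reported
#' p-value is the two-sided Wald test on the group coefficient. When the
#' overdispersed fit fails (non-convergence, or a dispersion estimate
#' implying variance/mean below 1 + 1e-6), the model is refit as plain
#' Poisson and flagged `poisson_fallback`. A batch perfectly confounded
#' with group is dropped with a warning. The conventional significance
#' threshold for intergroup comparisons is p <= 0.01.
#'
#' @param counts Data frame with columns `sample, group, batch, nSvs,
#'   coverage` (one row per sample).
#' @param groupRef,groupAlt The two group labels to contrast; the
#'   coefficient measures `groupAlt` relative to `groupRef`.
#' @return A list of class `svj_freq_comparison`: `logRateRatio`, `se`,
#'   `pValue`, `rateRatio`, `modelUsed` (`negative_binomial` or
#'   `poisson_fallback`), `theta`, `nSamples`, `batchDropped`, `fit`.
#' @export
compare_frequency <- function(counts, groupRef, groupAlt) {
  d <- counts[counts$group %in% c(groupRef, groupAlt), , drop = FALSE]
  if (!all(c(groupRef, groupAlt) %in% d$group)) {
    stop("both contrast groups need at least one sample")
  }
  if (any(d$coverage <= 0)) stop("coverage must be > 0 for every sample")
  d$group <- factor(d$group, levels = c(groupRef, groupAlt))
  d$batch <- factor(d$batch)

  useBatch <- nlevels(d$batch) > 1L
  batchDropped <- FALSE
  if (useBatch) {
    # a batch appearing in only one group for every batch level means batch
    # is perfectly confounded with group
    tab <- table(d$group, d$batch)
    if (all(colSums(tab > 0L) == 1L)) {
      warning("batch is perfectly confounded with group; dropping batch")
      useBatch <- FALSE
      batchDropped <- TRUE
    }
  }
  form <- if (useBatch) {
    nSvs ~ group + batch + offset(log(coverage))
  } else {
    nSvs ~ group + offset(log(coverage))
  }

  nbFit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = d)),
    error = function(e) NULL
  )
  ok <- !is.null(nbFit) && isTRUE(nbFit$converged)
  if (ok) {
    # dispersion implying variance/mean < 1 + 1e-6 counts as a failed
    # overdispersed fit
    muBar <- mean(stats::fitted(nbFit))
    if (!is.finite(nbFit$theta) || muBar / nbFit$theta < 1e-6) ok <- FALSE
  }

  if (ok) {
    fit <- nbFit
    modelUsed <- "negative_binomial"
    theta <- nbFit$theta
  } else {
    fit <- stats::glm(form, data = d, family = stats::poisson())
    modelUsed <- "poisson_fallback"
    theta <- Inf
  }
  co <- stats::coef(summary(fit))
  rowName <- paste0("group", groupAlt)
  if (!rowName %in% rownames(co)) stop("group coefficient not estimable")
  est <- co[rowName, 1L]; se <- co[rowName, 2L]; p <- co[rowName, 4L]

  if (any(tapply(d$nSvs, d$group, sum) == 0L)) {
    warning("a contrast group has zero total SVs; ",
            "the rate ratio is unstable")
  }
  structure(list(groupRef = groupRef, groupAlt = groupAlt,
                 logRateRatio = est, se = se, pValue = p,
                 rateRatio = exp(est), modelUsed = modelUsed, theta = theta,
                 nSamples = table(d$group), batchDropped = batchDropped,
                 fit = fit),
            class = "svj_freq_comparison")
}

#' @export
print.svj_freq_comparison <- function(x, ...) {
  cat("SV frequency comparison: ", x$groupAlt, " vs ", x$groupRef, "\n",
      sep = "")
  cat("  rate ratio ", format(x$rateRatio, digits = 4),
      " (log ", format(x$logRateRatio, digits = 4), " +/- ",
      format(x$se, digits = 3), ")\n", sep = "")
  cat("  Wald p = ", format(x$pValue, digits = 4), "  [", x$modelUsed,
      if (x$batchDropped) ", batch dropped" else "", "]\n", sep = "")
  invisible(x)
}
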