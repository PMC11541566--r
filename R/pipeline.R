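#' Run the full SV-junction analysis pipeline
#'
#' Orchestrates the analysis stages in order: filter -> coverage ->
#' characterize (canonicalization + transcription orientation) ->
#' templates -> statistics, writing every result table and a
#' machine-readable run summary to `outDir`. The output is a pure
#' function of the input files and configuration; rerunning with the same
#' inputs reproduces byte-identical tables.
#'
#' @param reference Reference FASTA path, or a character sequence.
#' @param targets Targets BED path, or a targets data frame.
#' @param molecules Molecules TSV path, or a data frame.
#' @param calls SV-calls TSV path, or a data frame.
#' @param manifest Manifest TSV path, or a samples data frame.
#' @param outDir Output directory (created if missing). `NULL` skips
#'   writing.
#' @param contrasts List of `c(groupRef, groupAlt)` pairs for the
#'   frequency comparison; defaults to consecutive pairs of the groups in
#'   the manifest.
#' @param filterConfig A [filter_config()].
#' @param window Template search window per side (bp).
#' @param pad Target padding if targets are read from BED.
#' @return A list with every stage result (`kept`, `rejections`,
#'   `coverage`, `density`, `templates`, `pileup`, `enrichment`,
#'   `profiles`, `comparisons`, `summary`).
#' @export
run_pipeline <- function(reference, targets, molecules, calls, manifest,
                         outDir = NULL, contrasts = NULL,
                         filterConfig = filter_config(), window = 500L,
                         pad = 800000L) {
  refSeq <- if (is.character(reference) && length(reference) == 1L &&
                file.exists(reference)) read_reference(reference)[[1L]]
            else reference
  tg <- if (is.character(targets)) read_targets(targets, pad = pad)
        else targets
  mols <- if (is.character(molecules)) read_molecules(molecules)
          else molecules
  cl <- if (is.character(calls)) read_sv_calls(calls) else calls
  sm <- if (is.character(manifest)) read_manifest(manifest) else manifest
  ref <- .as_seq_raw(refSeq)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # filter
  flt <- stage("filter",
               filter_svs(cl, mols, sm, tg, filterConfig, reference = ref))
  kept <- flt$kept
  message("filter: ", nrow(cl), " calls in, ", nrow(kept), " kept, ",
          nrow(flt$rejections), " rejected")

  # coverage
  cov <- stage("coverage", compute_coverage(mols, tg, filterConfig))
  covBySample <- stage("coverage", vapply(sm$sample, function(s) {
    compute_coverage(mols[mols$sample == s, , drop = FALSE], tg,
                     filterConfig)$coverage
  }, numeric(1L)))
  message("coverage: ", format(cov$coverage, digits = 5), " fold over ",
          nrow(tg), " target(s)")

  # characterize: orient kept calls to transcription
  kept$txFlipped <- FALSE
  for (i in seq_len(nrow(kept))) {
    kept[i, "txFlipped"] <- orient_to_transcription(
      kept[i, ], tg[match(TRUE, .in_targets(kept$chrom1[i], kept$pos1[i],
                                            tg, tg$pad[1L])), ])$txFlipped
  }
  dens <- stage("density",
                breakpoint_density(kept, mols, tg, filterConfig))

  # templates
  haveSeq <- any(!is.na(kept$moleculeSeq) & nzchar(kept$moleculeSeq))
  if (haveSeq) {
    tmpl <- stage("templates", discover_templates(kept, ref, window))
    pile <- stage("templates",
                  if (!is.null(tmpl$summary))
                    template_position_pileup(tmpl$summary)
                  else NULL)
    enr <- stage("enrichment",
                 if (!is.null(tmpl$summary))
                   enrichment_by_size(tmpl$summary, searchSpace = 4L * window * 2L)
                 else NULL)
    message("templates: ", if (is.null(tmpl$summary)) 0L
            else nrow(tmpl$summary), " insertion junctions searched")
  } else {
    warning("moleculeSeq column empty: template stage skipped")
    tmpl <- NULL; pile <- NULL; enr <- NULL
  }

  # statistics
  profiles <- stage("profiles", junction_profiles_by_sample(kept, sm))
  nPer <- count_svs_per_sample(kept, sm)
  countsDf <- data.frame(sample = sm$sample, group = sm$group,
                         batch = sm$batch, nSvs = as.integer(nPer),
                         coverage = as.numeric(covBySample),
                         stringsAsFactors = FALSE)
  if (is.null(contrasts)) {
    g <- unique(sm$group)
    contrasts <- if (length(g) >= 2L) list(c(g[1L], g[2L])) else list()
  }
  comparisons <- lapply(contrasts, function(ct) {
    stage("compare", compare_frequency(countsDf, ct[1L], ct[2L]))
  })
  compDf <- do.call(rbind, lapply(comparisons, function(x) {
    data.frame(groupRef = x$groupRef, groupAlt = x$groupAlt,
               logRateRatio = x$logRateRatio, se = x$se,
               rateRatio = x$rateRatio, pValue = x$pValue,
               modelUsed = x$modelUsed, theta = x$theta,
               stringsAsFactors = FALSE)
  }))

  summary <- list(
    nCallsIn = nrow(cl), nKept = nrow(kept),
    nRejected = nrow(flt$rejections),
    rejectionReasons = as.list(table(flt$rejections$reason)),
    coverage = cov$coverage,
    nInsertionsSearched = if (!is.null(tmpl) && !is.null(tmpl$summary))
      nrow(tmpl$summary) else 0L,
    nTemplatesFound = if (!is.null(tmpl) && !is.null(tmpl$summary))
      sum(tmpl$summary$found) else 0L,
    version = as.character(utils::packageVersion("svjunctions"))
  )

  out <- list(kept = kept, rejections = flt$rejections, coverage = cov,
              coverageBySample = covBySample, density = dens,
              templates = tmpl, pileup = pile, enrichment = enr,
              profiles = profiles, counts = countsDf,
              comparisons = comparisons, comparisonTable = compDf,
              summary = summary)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    wt <- function(df, f) if (!is.null(df)) .write_tsv(df, file.path(outDir, f))
    write_sv_calls(kept, file.path(outDir, "kept_calls.tsv"))
    wt(flt$rejections, "rejections.tsv")
    covOut <- data.frame(chrom = cov$bins$chrom,
                         start = cov$bins$start - 1L, end = cov$bins$end,
                         value = cov$bins$meanCoverage)
    wt(covOut, "coverage_bins.tsv")
    wt(dens, "breakpoint_density.tsv")
    if (!is.null(tmpl)) {
      wt(tmpl$summary, "templates.tsv")
      wt(tmpl$hits, "template_hits.tsv")
      wt(pile, "template_pileup.tsv")
      wt(enr, "enrichment.tsv")
    }
    wt(profiles, "junction_profiles.tsv")
    wt(countsDf, "sample_counts.tsv")
    wt(compDf, "frequency_comparisons.tsv")
    cfgPath <- file.path(outDir, "run_config.json")
    jsonlite::write_json(list(filterConfig = unclass(filterConfig),
                              window = window, contrasts = contrasts),
                         cfgPath, auto_unbox = TRUE, pretty = TRUE)
    summary$configHash <- unname(tools::md5sum(cfgPath))
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$summary <- summary
  }
  out
}
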