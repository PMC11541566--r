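test_that("query flank sizes follow the seven-base minimum rule", {
  mk_call <- function(k) {
    flank <- paste(rep("A", 20), collapse = "")
    ins <- paste(rep("C", k), collapse = "")
    data.frame(id = "sv1", type = "DEL", offset = k,
               insertedBases = ins,
               moleculeSeq = paste0(flank, ins, flank),
               moleculePos1 = 20L, moleculePos2 = 20L + k + 1L,
               stringsAsFactors = FALSE)
  }
  q1 <- build_template_query(mk_call(1L))
  expect_equal(q1$flankPerSide, 3L)
  expect_equal(q1$nTemplateBases, 7L)
  q2 <- build_template_query(mk_call(2L))
  expect_equal(q2$flankPerSide, 3L)  # odd totals split by ceiling
  expect_equal(q2$nTemplateBases, 8L)
  q4 <- build_template_query(mk_call(4L))
  expect_equal(q4$flankPerSide, 2L)
  expect_equal(q4$nTemplateBases, 8L)
  q5 <- build_template_query(mk_call(5L))
  expect_equal(q5$flankPerSide, 1L)
  expect_equal(q5$nTemplateBases, 7L)
  expect_equal(q5$querySeq, paste0("A", paste(rep("C", 5), collapse = ""), "A"))

  bad <- mk_call(3L); bad$offset <- -2L
  expect_error(build_template_query(bad), "not an insertion")
  noseq <- mk_call(3L); noseq$moleculeSeq <- NA_character_
  expect_error(build_template_query(noseq), "data error")
})

test_that("scanner equals the exhaustive brute-force oracle on simulated junctions", {
  n <- 250L
  set.seed(501)
  sizes <- sample(c(1:12), n, replace = TRUE)
  nAgree <- 0L
  for (i in seq_len(n)) {
    templated <- i %% 2L == 0L
    pl <- plant_insertions(1L, sizes[i], seed = 5000L + i,
                           templated = templated)[[1L]]
    qu <- build_template_query(pl$call)
    res <- scan_templates(qu, pl$reference, pl$call)
    ora <- oracle_scan(qu, pl$reference, pl$call)
    cols <- c("breakpointIndex", "strand", "matchStart", "matchEnd",
              "refStart", "refEnd", "primingMh", "resolvingMh")
    got <- res$allHits[order(res$allHits$breakpointIndex,
                             res$allHits$strand,
                             res$allHits$matchStart), cols]
    rownames(got) <- NULL
    if (is.null(ora)) {
      expect_identical(nrow(got), 0L)
    } else {
      rownames(ora) <- NULL
      expect_identical(got, ora[, cols])
    }
    nAgree <- nAgree + 1L

    # extension maximality: the base beyond each flank mismatches
    mol <- strsplit(pl$call$moleculeSeq, "")[[1L]]
    refc <- strsplit(pl$reference, "")[[1L]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (j in seq_len(nrow(res$allHits))) {
      h <- res$allHits[j, ]
      pe <- h$primingMh - qu$flankPerSide
      re <- h$resolvingMh - qu$flankPerSide
      mL <- qu$qs - 1L - pe; mR <- qu$qe + 1L + re
      if (h$strand == "top") {
        if (mL >= 1L && h$refStart - 1L >= 1L) {
          expect_false(mol[mL] == refc[h$refStart - 1L])
        }
        if (mR <= length(mol) && h$refEnd + 1L <= length(refc)) {
          expect_false(mol[mR] == refc[h$refEnd + 1L])
        }
      } else {
        if (mL >= 1L && h$refEnd + 1L <= length(refc)) {
          expect_false(mol[mL] == comp[[refc[h$refEnd + 1L]]])
        }
        if (mR <= length(mol) && h$refStart - 1L >= 1L) {
          expect_false(mol[mR] == comp[[refc[h$refStart - 1L]]])
        }
      }
    }
  }
  expect_identical(nAgree, n)
})

test_that("planted templates are recovered at exact coordinates with the planted class", {
  classes <- c("foldback", "cross_junction", "strand_switching", "expansion")
  nPer <- 40L
  recovered <- 0L; classOk <- 0L; total <- 0L
  for (cls in classes) {
    set.seed(match(cls, classes) * 1000L)
    for (i in seq_len(nPer)) {
      k <- sample(3:10, 1L)
      f <- max(1L, as.integer(ceiling((7L - k) / 2)))
      p <- sample(f:4, 1L); r <- sample(f:4, 1L)
      d <- if (cls == "strand_switching") sample(1:30, 1L)
           else if (cls == "expansion") NULL
           else sample((max(p, r) + 2L):40L, 1L)
      pl <- plant_insertions(1L, k, seed = 9000L + total, templated = TRUE,
                             templateClass = cls, templateDistance = d,
                             primingMh = p, resolvingMh = r)[[1L]]
      qu <- build_template_query(pl$call)
      res <- scan_templates(qu, pl$reference, pl$call)
      sel <- res$selectedHit
      total <- total + 1L
      if (!is.null(sel) &&
          sel$matchStart == pl$truth$matchStart &&
          sel$matchEnd == pl$truth$matchEnd &&
          sel$strand == pl$truth$templateStrand) {
        recovered <- recovered + 1L
        got <- classify_template(sel, pl$call, pl$reference)$class
        want <- pl$truth$templateClass
        if (got == want || (want == "foldback" && got == "palindrome")) {
          classOk <- classOk + 1L
        }
      }
    }
  }
  expect_gte(recovered / total, 0.9)
  # class labels agree for every unambiguous (exactly recovered) plant
  expect_identical(classOk, recovered)

  # recovered priming/resolving flanks equal the plant for non-expansion
  pl <- plant_insertions(1L, 6L, seed = 31, templated = TRUE,
                         templateClass = "foldback", templateDistance = 20L,
                         primingMh = 3L, resolvingMh = 2L)[[1L]]
  sel <- scan_templates(build_template_query(pl$call), pl$reference,
                        pl$call)$selectedHit
  expect_identical(sel$primingMh, 3L)
  expect_identical(sel$resolvingMh, 2L)
  expect_identical(sel$refStart, pl$truth$templateStart)
  expect_identical(sel$refEnd, pl$truth$templateEnd)
})

test_that("template selection prefers span, then distance, then the documented tie-break", {
  hit <- function(span, dist, bp = 1L, strand = "top", refStart = 100L) {
    data.frame(svId = "sv1", breakpointIndex = bp, strand = strand,
               matchStart = refStart, matchEnd = refStart + span - 1L,
               refStart = refStart, refEnd = refStart + span - 1L,
               primingMh = 1L, resolvingMh = 1L, totalSpan = span,
               distanceToJunction = dist, stringsAsFactors = FALSE)
  }
  # longest span wins
  h <- rbind(hit(9L, 5L), hit(12L, 30L))
  expect_equal(select_template(h)$totalSpan, 12L)
  # equal spans: closest to the junction
  h <- rbind(hit(10L, 30L), hit(10L, -5L))
  expect_equal(select_template(h)$distanceToJunction, -5L)
  # fully tied: breakpoint 1, top strand, leftmost
  h <- rbind(hit(10L, 8L, bp = 2L, strand = "bottom", refStart = 50L),
             hit(10L, 8L, bp = 1L, strand = "bottom", refStart = 300L),
             hit(10L, 8L, bp = 1L, strand = "top", refStart = 400L),
             hit(10L, 8L, bp = 1L, strand = "top", refStart = 200L))
  sel <- select_template(h)
  expect_equal(sel$breakpointIndex, 1L)
  expect_equal(sel$strand, "top")
  expect_equal(sel$refStart, 200L)
  expect_null(select_template(h[0, ]))
})

test_that("classification follows strand and retained/lost placement", {
  call <- data.frame(id = "sv1", type = "DEL", pos1 = 1000L, pos2 = 15000L,
                     stringsAsFactors = FALSE)
  mk_hit <- function(refStart, refEnd, strand) {
    data.frame(breakpointIndex = 1L, strand = strand, refStart = refStart,
               refEnd = refEnd, stringsAsFactors = FALSE)
  }
  expect_equal(classify_template(mk_hit(900L, 920L, "bottom"), call)$class,
               "foldback")
  expect_equal(classify_template(mk_hit(900L, 920L, "top"), call)$class,
               "cross_junction")
  expect_equal(classify_template(mk_hit(1005L, 1020L, "bottom"), call)$class,
               "strand_switching")
  expect_equal(classify_template(mk_hit(995L, 1010L, "top"), call)$class,
               "expansion")
  expect_equal(classify_template(mk_hit(1005L, 1020L, "top"), call)$class,
               "unclassified")
  # palindrome: extended template equal to its own reverse complement
  ref <- paste0(paste(rep("A", 899), collapse = ""), "ACGCGT",
                paste(rep("C", 200), collapse = ""))
  cl <- classify_template(mk_hit(900L, 905L, "bottom"), call, ref)
  expect_equal(cl$class, "palindrome")
  # non-DEL classes are low-confidence
  dup <- call; dup$type <- "DUP"
  expect_true(classify_template(mk_hit(900L, 920L, "bottom"), dup)$lowConfidence)
  expect_false(classify_template(mk_hit(900L, 920L, "bottom"), call)$lowConfidence)
})

test_that("pileup counts one unit per template base at signed positions", {
  summ <- data.frame(
    svId = "sv1", found = TRUE, class = "foldback", breakpointIndex = 1L,
    strand = "bottom", refStart = 983L, refEnd = 990L, pos1 = 1000L,
    pos2 = 15000L, txFlipped = FALSE, stringsAsFactors = FALSE
  )
  pile <- template_position_pileup(summ)
  # hit at distance -10 spanning 8 bases: unit counts at -10..-17
  expect_setequal(pile$position, -17:-10)
  expect_true(all(pile$count == 1L))
  empty <- template_position_pileup(summ[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("random-match probability is calibrated to the Poisson expectation", {
  # untemplated k-base insertions have query length n = k + 2, so sizes
  # 5..8 probe n = 7..10; per-junction hit probability should match
  # 1 - exp(-4000 / 4^n) within 3 SE
  nJ <- 150L
  for (k in c(5L, 6L, 7L, 8L)) {
    n <- k + 2L
    plants <- plant_insertions(nJ, k, seed = 600L + k, templated = FALSE)
    found <- vapply(plants, function(pl) {
      qu <- build_template_query(pl$call)
      scan_templates(qu, pl$reference, pl$call)$nCandidates > 0L
    }, TRUE)
    p <- -expm1(-4000 / 4^n)
    se <- sqrt(p * (1 - p) / nJ)
    expect_lt(abs(mean(found) - p), 3 * se + 1e-9,
              label = paste("hit rate at n =", n))
  }
})

test_that("queries matching at the window edge are included", {
  # place a cross-junction template with its far end exactly at the edge
  # of the 500 bp window
  k <- 8L; p <- 2L; r <- 2L; L <- p + k + r
  d <- 500L - L + 1L  # refStart lands exactly at pos1 - 500
  pl <- plant_insertions(1L, k, seed = 41, templated = TRUE,
                         templateClass = "cross_junction",
                         templateDistance = d, primingMh = p,
                         resolvingMh = r)[[1L]]
  qu <- build_template_query(pl$call)
  res <- scan_templates(qu, pl$reference, pl$call)
  expect_gte(res$nCandidates, 1L)
  expect_true(any(res$allHits$matchStart == pl$truth$matchStart))
})
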