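# Internal sequence and RNG helpers.
#
# Reference sequences are manipulated internally as raw byte vectors so that
# junction planting can edit single bases in place; character strings and
# Biostrings objects appear only at API and file boundaries.

.BASES <- charToRaw("ACGT")

# complement lookup over the full byte range (non-ACGT bytes map to 'N',
# which never matches anything in homology extension)
.COMP <- {
  x <- rep(charToRaw("N"), 256L)
  x[as.integer(charToRaw("A")) + 1L] <- charToRaw("T")
  x[as.integer(charToRaw("C")) + 1L] <- charToRaw("G")
  x[as.integer(charToRaw("G")) + 1L] <- charToRaw("C")
  x[as.integer(charToRaw("T")) + 1L] <- charToRaw("A")
  x
}

.comp_raw <- function(b) .COMP[as.integer(b) + 1L]

.revcomp_raw <- function(b) rev(.comp_raw(b))

.as_seq_raw <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(charToRaw(x))
  if (inherits(x, "DNAString")) return(charToRaw(as.character(x)))
  if (inherits(x, "DNAStringSet")) return(charToRaw(as.character(x[[1L]])))
  stop("cannot interpret object of class '", class(x)[1L], "' as a sequence")
}

.seq_like <- function(template, raw) {
  # return `raw` in the same representation the caller supplied
  if (is.raw(template)) raw else rawToChar(raw)
}

#' Reverse complement of a DNA string
#'
#' Small convenience wrapper used throughout junction planting and template
#' classification. Non-ACGT characters complement to `N`.
#'
#' @param x A single character string (or raw vector) of DNA bases.
#' @return A character string.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) rawToChar(.revcomp_raw(.as_seq_raw(x)))

# run code under a fixed, fully pinned RNG state, restoring the caller's
# state afterwards; all package randomness funnels through this
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# draw n bases as raw bytes
.random_bases <- function(n) sample(.BASES, n, replace = TRUE)

# a base different from every byte in `exclude`
.base_not_in <- function(exclude) {
  ok <- .BASES[!(.BASES %in% exclude)]
  if (length(ok) == 0L) stop("no base available outside the excluded set")
  if (length(ok) == 1L) ok else sample(ok, 1L)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.stopifnot_prob_vector <- function(p, what) {
  if (any(p < 0)) stop(what, " has negative entries")
  if (abs(sum(p) - 1) > 1e-9) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  invisible(p)
}
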