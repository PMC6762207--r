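## Small shared helpers. Sequences are plain uppercase character scalars
## over {A,C,G,T,N}; genomes are named character vectors.

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over `{A,C,G,T,N}` (IUPAC
#'   ambiguity codes are complemented too).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards. All stochastic operations in the
## package go through this so that a user-level seed fully determines
## output without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Random i.i.d. DNA of length n at the given GC content.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## round() uses banker's rounding; summary tables conventionally round
## half away from zero, so percentages are rounded explicitly.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Split a sequence into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## Gap (bp) between two 0-based half-open intervals on the same chromosome;
## 0 when they overlap or touch.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s2 - e1, s1 - e2), 0L)
}

## Hamming mismatch count between equal-length strings.
hamming <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}
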