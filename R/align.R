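## Alignment primitives: free-end-gap global identity (the clustering /
## dating workhorse), gapless x-drop extension (the structural detector
## workhorse) and a small Smith-Waterman used for PBS screening.

#' Global alignment identity over the aligned span
#'
#' Aligns two sequences end-to-end (Needleman-Wunsch; match +2,
#' mismatch -2, gap open -10, gap extend -1) and reports identity as
#' matches divided by alignment columns, where internal gap columns
#' count against identity and any terminal-gap columns are excluded
#' from the denominator - the identity notion used by greedy centroid
#' clustering tools. End gaps carry the ordinary gap cost during
#' alignment, which keeps unrelated sequence pairs from scoring a
#' spuriously high identity over a short chance overlap; the price is
#' that long overhangs of one sequence dilute the identity, which is
#' conservative for the intended full-length-element comparisons.
#' With `strand_mode = "both"` the reverse complement of `b` is also
#' tried and the better strand reported.
#'
#' @param a,b non-empty nucleotide strings.
#' @param strand_mode `"plus"` or `"both"`.
#' @return list with `identity` (fraction), `matches`, `columns` and
#'   `strand` (`"+"` or `"-"`, the orientation of `b` used).
#' @export
#' @examples
#' global_identity("ACGT", "ACGA")$identity  # 0.75
global_identity <- function(a, b, strand_mode = c("plus", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(nzchar(a), nzchar(b))
  fwd <- .overlap_identity(a, b)
  if (strand_mode == "plus") return(c(fwd, strand = "+"))
  rev <- .overlap_identity(a, revcomp(b))
  if (rev$identity > fwd$identity) c(rev, strand = "-") else c(fwd, strand = "+")
}

.overlap_sm <- local({
  sm <- NULL
  function() {
    if (is.null(sm))
      sm <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
    sm
  }
})

.overlap_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .overlap_sm(),
    gapOpening = 10, gapExtension = 1)
  pa <- seq_chars(as.character(Biostrings::pattern(aln)))
  sa <- seq_chars(as.character(Biostrings::subject(aln)))
  both <- which(pa != "-" & sa != "-")
  if (length(both) == 0L)
    return(list(identity = 0, matches = 0L, columns = 0L))
  keep <- both[1L]:both[length(both)]   # drop terminal-gap columns
  matches <- sum(pa[keep] == sa[keep] & pa[keep] != "-")
  list(identity = matches / length(keep), matches = matches,
       columns = length(keep))
}

## Gapless x-drop extension. Starting just outside positions `from`
## (0-based, exclusive) walk outward in direction `dir` (+1 or -1)
## comparing s[p1] to s[p2]; stop when the running score drops more than
## `xdrop` below its maximum or a sequence end is reached. Returns the
## number of steps giving the maximal score, and that score.
xdrop_extend <- function(chars, p1, p2, dir, match, mismatch, xdrop) {
  n <- length(chars)
  best <- 0; run <- 0; best_k <- 0L; k <- 0L
  repeat {
    k <- k + 1L
    i <- p1 + dir * k; j <- p2 + dir * k
    if (i < 1L || j < 1L || i > n || j > n) break
    run <- run + if (chars[i] == chars[j] && chars[i] != "N") match else mismatch
    if (run > best) { best <- run; best_k <- k }
    if (run < best - xdrop) break
  }
  list(steps = best_k, score = best)
}

## Gapless pair score of s[a1..a2] vs the window at diagonal offset d
## (i.e. s[a1+d .. a2+d]), used for boundary-consistency checks.
gapless_score <- function(chars, a1, a2, d, match, mismatch) {
  if (a2 < a1) return(0)
  x <- chars[a1:a2]; y <- chars[(a1 + d):(a2 + d)]
  ok <- x == y & x != "N"
  sum(ok) * match + sum(!ok) * mismatch
}

## Small Smith-Waterman with per-cell origin/match/column tracking,
## linear gap cost. Returns every cell-local optimum as a candidate:
## a data frame with score, matches, columns, sub_start/sub_end
## (1-based in `subject`), q_start/q_end (1-based in `query`).
## Intended for short query vs short window (PBS screening).
sw_candidates <- function(query, subject, match = 1, mismatch = -1, gap = -2) {
  q <- seq_chars(query); s <- seq_chars(subject)
  nq <- length(q); ns <- length(s)
  ## DP matrices, row i = query pos, col j = subject pos
  H <- matrix(0, nq + 1L, ns + 1L)
  M <- matrix(0L, nq + 1L, ns + 1L)   # matches on best path
  C <- matrix(0L, nq + 1L, ns + 1L)   # alignment columns on best path
  OQ <- matrix(0L, nq + 1L, ns + 1L)  # query start of path
  OS <- matrix(0L, nq + 1L, ns + 1L)  # subject start of path
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      mm <- q[i] == s[j] && q[i] != "N"
      diag <- H[i, j] + if (mm) match else mismatch
      up <- H[i, j + 1L] + gap
      left <- H[i + 1L, j] + gap
      best <- max(diag, up, left, 0)
      if (best == 0) next
      if (best == diag) {
        fresh <- H[i, j] == 0
        OQ[i + 1L, j + 1L] <- if (fresh) i else OQ[i, j]
        OS[i + 1L, j + 1L] <- if (fresh) j else OS[i, j]
        M[i + 1L, j + 1L] <- M[i, j] + as.integer(mm)
        C[i + 1L, j + 1L] <- C[i, j] + 1L
      } else if (best == up) {
        OQ[i + 1L, j + 1L] <- OQ[i, j + 1L]; OS[i + 1L, j + 1L] <- OS[i, j + 1L]
        M[i + 1L, j + 1L] <- M[i, j + 1L]; C[i + 1L, j + 1L] <- C[i, j + 1L] + 1L
      } else {
        OQ[i + 1L, j + 1L] <- OQ[i + 1L, j]; OS[i + 1L, j + 1L] <- OS[i + 1L, j]
        M[i + 1L, j + 1L] <- M[i + 1L, j]; C[i + 1L, j + 1L] <- C[i + 1L, j] + 1L
      }
      H[i + 1L, j + 1L] <- best
    }
  }
  idx <- which(H > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(score = numeric(0), matches = integer(0),
                      columns = integer(0), q_start = integer(0),
                      q_end = integer(0), sub_start = integer(0),
                      sub_end = integer(0)))
  data.frame(
    score = H[idx],
    matches = M[idx],
    columns = C[idx],
    q_start = OQ[idx],
    q_end = idx[, 1L] - 1L,
    sub_start = OS[idx],
    sub_end = idx[, 2L] - 1L)
}
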