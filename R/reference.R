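## A deterministic synthetic reference element. The true reference
## accession of the family this package was shaped around is not
## bundled; instead a synthetic element reproducing its canonical
## architecture is generated in code: 4867 bp, 400-bp identical LTRs,
## a TSD-ready TG...CA frame, PBS at offset 2, and the promoter CRE
## layout of the 5' LTR (CGCG box at 89-94, MYB cores CTGTTG at
## 176-181 and CTGTTA at 204-209, ABRE-like at 332-337, CE3 at
## 357-366; positions 1-based within the element). It is synthetic and
## is labelled as such wherever it appears.

#' Synthetic reference element with the canonical CRE architecture
#'
#' Deterministically generates a 4867-bp synthetic LTR retrotransposon
#' whose 5' LTR carries the canonical promoter motif layout (see file
#' header), for self-contained positional-fidelity tests and examples.
#' The two LTRs are identical (a young, active element).
#'
#' @return list with `seq` (4867-bp string), `ltr_len` (400), `motifs`
#'   (data frame of planted name/pattern/offset, 0-based LTR offsets)
#'   and `trnas` (the tRNA set whose first entry primes the PBS).
#' @export
synthetic_rider_reference <- function() {
  motifs <- data.frame(
    name = c("CGCGBOXAT", "MYBCORE_G", "MYBCORE_A", "ABRE_like", "CE3"),
    pattern = c("ACGCGG", "CTGTTG", "CTGTTA", "TACGTG", "AACGCGTGTC"),
    offset = c(88L, 175L, 203L, 331L, 356L),
    stringsAsFactors = FALSE)
  trnas <- default_trnas(424242L)
  spec <- synth_spec(genome_len = 60000L, gc = 0.38, n_intact = 1L,
                     n_solo_ltr = 0L, n_truncated = 0L, ltr_len = 400L,
                     internal_len = 4067L, divergences = 0,
                     pbs_offset = 2L, pbs_len = 18L, trnas = trnas,
                     planted_motifs = motifs, seed = 424242L)
  el <- with_seed(.reference_seed, build_element(spec, 0))
  stopifnot(nchar(el$seq) == 4867L)
  list(seq = el$seq, ltr_len = 400L, motifs = motifs, trnas = trnas)
}

## Generation seed for the synthetic reference, fixed so that the
## planted motif occurrences are the first of their pattern within the
## element (no spurious earlier copies arise from the random stuffer).
.reference_seed <- 20260101L

#' Embed the synthetic reference in a synthetic host genome
#'
#' Places the [synthetic_rider_reference()] element, flanked by a
#' duplicated 5-bp TSD, in an i.i.d. background chromosome, for
#' end-to-end detection and motif-position tests.
#'
#' @param flank bp of background on each side (default 8000).
#' @param tsd TSD sequence duplicated on both flanks.
#' @param seed background seed.
#' @return list with `genome` (named character vector), `start`/`end`
#'   (0-based half-open element coordinates, TSD-exclusive),
#'   `reference` (the [synthetic_rider_reference()] list).
#' @export
reference_host_genome <- function(flank = 8000L, tsd = "ACGTA", seed = 7L) {
  ref <- synthetic_rider_reference()
  with_seed(seed, {
    left <- random_dna(flank, 0.38)
    right <- random_dna(flank, 0.38)
    seq <- paste0(left, tsd, ref$seq, tsd, right)
    start <- flank + nchar(tsd)
    list(genome = c(chrRef = seq), start = start,
         end = start + nchar(ref$seq), reference = ref)
  })
}
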