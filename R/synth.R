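## Synthetic genomes with planted LTR retrotransposons and companion
## truth tables. The generator is first-class: every structural feature
## the detector looks for (LTR pair with controlled divergence, TSD,
## PBS, TG...CA termini, long ORF, polypurine tract, planted promoter
## motifs, solo LTRs, truncated copies) is planted explicitly and its
## realized (post-mutation) state recorded, so that recovery can be
## scored against ground truth.

#' Specification for a synthetic genome
#'
#' Defaults emulate, at desk scale, a repeat-poor assembly carrying a
#' handful of young-to-middle-aged intact elements: 400-bp LTRs around
#' a 4-kb internal region (so that elements satisfy the detector's
#' default distance bounds), TSDs of 4-6 bp as typical for Copia-type
#' integrases, a perfect 18-nt PBS at offset 2 from the 5' LTR, and
#' LTR-pair divergences up to 10%.
#'
#' @param genome_len background length in bp.
#' @param gc background GC content.
#' @param n_intact,n_solo_ltr,n_truncated numbers of planted intact
#'   elements, solo LTRs and 5'-truncated copies.
#' @param ltr_len,internal_len LTR and internal-region lengths (bp).
#' @param divergences per-intact-element LTR-pair divergence (fraction
#'   in `[0, 0.2]`); recycled; each LTR copy is mutated independently at
#'   half this rate.
#' @param tsd_len_range inclusive range the TSD length is drawn from.
#' @param pbs_offset,pbs_len PBS placement: offset from the 5' LTR end
#'   and length of the planted complementarity to the tRNA 3' end.
#' @param trnas named character vector of tRNA sequences; the first is
#'   used for the planted PBS. Default: one synthetic 76-nt tRNA,
#'   generated from `seed`.
#' @param planted_motifs optional data frame with columns `name`,
#'   `pattern` (concrete sequence written into the LTR before mutation)
#'   and `offset` (0-based within the LTR).
#' @param seed integer; every random choice derives from it.
#' @param chrom_name name of the single synthetic chromosome.
#' @return a list of class `"synth_spec"`.
#' @export
synth_spec <- function(genome_len = 120000L, gc = 0.38, n_intact = 4L,
                       n_solo_ltr = 1L, n_truncated = 1L, ltr_len = 400L,
                       internal_len = 4000L, divergences = c(0.02, 0.1),
                       tsd_len_range = c(4L, 6L), pbs_offset = 2L,
                       pbs_len = 18L, trnas = NULL,
                       planted_motifs = NULL, seed = 1L,
                       chrom_name = "chrS") {
  if (is.null(trnas)) trnas <- default_trnas(seed)
  divergences <- rep_len(divergences, max(n_intact, 1L))
  stopifnot(all(divergences >= 0), all(divergences <= 0.2),
            ltr_len >= 100L, internal_len + ltr_len >= 4000L)
  footprint <- (n_intact * (2L * ltr_len + internal_len) +
                  (n_solo_ltr + n_truncated) * (ltr_len + internal_len))
  if (footprint >= genome_len / 2)
    stop("planted footprint exceeds half the genome length")
  structure(list(genome_len = genome_len, gc = gc, n_intact = n_intact,
                 n_solo_ltr = n_solo_ltr, n_truncated = n_truncated,
                 ltr_len = ltr_len, internal_len = internal_len,
                 divergences = divergences, tsd_len_range = tsd_len_range,
                 pbs_offset = pbs_offset, pbs_len = pbs_len, trnas = trnas,
                 planted_motifs = planted_motifs, seed = seed,
                 chrom_name = chrom_name),
            class = "synth_spec")
}

#' Synthetic tRNA set
#'
#' One random 76-nt "tRNA" generated deterministically from `seed`;
#' only its 3' end matters for PBS planting and screening.
#'
#' @param seed integer seed.
#' @return named character vector of length 1.
#' @export
default_trnas <- function(seed = 1L) {
  with_seed(seed + 990000L,
            c(tRNA_Met_synth = random_dna(76L, gc = 0.5)))
}

#' Point-mutate a sequence
#'
#' Substitution-only mutation: each position is replaced by one of the
#' three other bases with probability `rate`, except positions covered
#' by `protect` (1-based index vector).
#'
#' @param seq nucleotide string.
#' @param rate per-site substitution probability.
#' @param protect integer vector of 1-based positions left untouched.
#' @return mutated string.
#' @export
mutate_seq <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

## Random open reading frame of approximately `len` bp (rounded up to
## whole codons, incl. stop): ATG + non-stop codons + stop codon.
make_orf <- function(len = 900L) {
  n_codon <- max(2L, ceiling(len / 3L)) - 2L
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  good <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(good, n_codon, replace = TRUE), collapse = ""),
         "TAA")
}

#' Build one intact element sequence and its truth record
#'
#' The element is `LTR5 + [offset spacer] + PBS + stuffer + ORF +
#' stuffer + polypurine tract + LTR3`. Both LTR copies derive from one
#' ancestral LTR and are independently point-mutated at `divergence/2`
#' each, so the expected pair identity is about `1 - divergence`;
#' TG/CA termini are re-enforced after mutation and the *realized* pair
#' identity is recomputed by direct alignment. Planted motifs are
#' written into the ancestral LTR before mutation and their
#' post-mutation status is recorded.
#'
#' @param spec a [synth_spec()] (its per-element fields are used).
#' @param divergence LTR-pair divergence for this element, in `[0, 0.2]`.
#' @return list with `seq` (the element, no TSD), `ltr_len` and a
#'   `truth` list (realized identity, PBS offset/length, motif status).
#' @export
build_element <- function(spec, divergence) {
  stopifnot(divergence >= 0, divergence <= 0.2)
  L <- spec$ltr_len
  base_ltr <- random_dna(L, spec$gc)
  if (!is.null(spec$planted_motifs)) {
    for (i in seq_len(nrow(spec$planted_motifs))) {
      off <- spec$planted_motifs$offset[i]
      pat <- spec$planted_motifs$pattern[i]
      if (off + nchar(pat) > L) stop("motif offset exceeds LTR length")
      substr(base_ltr, off + 1L, off + nchar(pat)) <- pat
    }
  }
  substr(base_ltr, 1L, 2L) <- "TG"
  substr(base_ltr, L - 1L, L) <- "CA"
  ltr5 <- mutate_seq(base_ltr, divergence / 2)
  ltr3 <- mutate_seq(base_ltr, divergence / 2)
  substr(ltr5, 1L, 2L) <- "TG"; substr(ltr5, L - 1L, L) <- "CA"
  substr(ltr3, 1L, 2L) <- "TG"; substr(ltr3, L - 1L, L) <- "CA"

  trna <- spec$trnas[[1L]]
  if (spec$pbs_len > nchar(trna)) stop("pbs_len exceeds tRNA length")
  pbs <- revcomp(substr(trna, nchar(trna) - spec$pbs_len + 1L, nchar(trna)))
  ppt <- paste(sample(c("A", "G"), 15L, replace = TRUE, prob = c(.4, .6)),
               collapse = "")
  orf <- make_orf(900L)
  used <- spec$pbs_offset + spec$pbs_len + nchar(orf) + nchar(ppt)
  if (used + 20L > spec$internal_len)
    stop("internal_len too small for PBS + ORF + PPT")
  pad_total <- spec$internal_len - used
  pad1 <- random_dna(pad_total %/% 2L, spec$gc)
  pad2 <- random_dna(pad_total - nchar(pad1), spec$gc)
  internal <- paste0(random_dna(spec$pbs_offset, spec$gc), pbs, pad1, orf,
                     pad2, ppt)
  seq <- paste0(ltr5, internal, ltr3)

  motif_status <- NULL
  if (!is.null(spec$planted_motifs)) {
    motif_status <- vapply(seq_len(nrow(spec$planted_motifs)), function(i) {
      off <- spec$planted_motifs$offset[i]
      pat <- spec$planted_motifs$pattern[i]
      substr(ltr5, off + 1L, off + nchar(pat)) == pat
    }, logical(1))
    names(motif_status) <- spec$planted_motifs$name
  }
  gi <- global_identity(ltr5, ltr3)
  list(seq = seq, ltr_len = L,
       truth = list(pair_identity = gi$identity,
                    divergence_nominal = divergence,
                    pbs_offset = spec$pbs_offset, pbs_len = spec$pbs_len,
                    pbs_trna = names(spec$trnas)[1L],
                    motif_intact = motif_status))
}

#' Build a synthetic genome with planted elements and a truth table
#'
#' Plants `n_intact` intact elements (each flanked by a freshly drawn
#' TSD duplicated on both sides), `n_solo_ltr` solo LTRs (single LTR
#' with TSD, no partner repeat) and `n_truncated` 5'-truncated copies
#' (3' half plus one LTR, no TSD) at non-overlapping uniform positions
#' in an i.i.d. background; strands are drawn uniformly and minus-strand
#' features inserted as reverse complements. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return list of class `"synth_genome"` with `genome` (named
#'   character vector of length 1), `truth` (data frame: `id`, `kind`,
#'   `chrom`, `start`, `end` 0-based half-open and TSD-exclusive,
#'   `strand`, `ltr_len`, `pair_identity` realized by re-alignment,
#'   `divergence_nominal`, `tsd_seq`, `pbs_offset`, `pbs_len`) and
#'   `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    inserts <- list()
    k <- 0L
    for (i in seq_len(spec$n_intact)) {
      el <- build_element(spec, spec$divergences[i])
      k <- k + 1L
      inserts[[k]] <- list(kind = "intact", seq = el$seq,
                           ltr_len = el$ltr_len, truth = el$truth)
    }
    for (i in seq_len(spec$n_solo_ltr)) {
      el <- build_element(spec, 0)
      solo <- substr(el$seq, 1L, spec$ltr_len)
      k <- k + 1L
      inserts[[k]] <- list(kind = "solo_ltr", seq = solo,
                           ltr_len = spec$ltr_len, truth = NULL)
    }
    for (i in seq_len(spec$n_truncated)) {
      el <- build_element(spec, spec$divergences[1L])
      keep_from <- spec$ltr_len + spec$internal_len %/% 2L
      trunc <- substr(el$seq, keep_from + 1L, nchar(el$seq))
      k <- k + 1L
      inserts[[k]] <- list(kind = "truncated", seq = trunc,
                           ltr_len = spec$ltr_len, truth = NULL)
    }
    if (k == 0L) {
      genome <- setNames(random_dna(spec$genome_len, spec$gc),
                         spec$chrom_name)
      return(structure(list(genome = genome,
                            truth = .empty_truth(), spec = spec),
                       class = "synth_genome"))
    }
    ## non-overlapping uniform insertion points in the background,
    ## kept >= 300 bp apart so boundary vicinities never interleave
    min_gap <- 300L
    points <- integer(0)
    for (i in seq_len(k)) {
      placed <- FALSE
      for (att in seq_len(10000L)) {
        cand <- sample.int(spec$genome_len - 1L, 1L)
        if (all(abs(cand - points) >= min_gap)) {
          points <- c(points, cand); placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place feature ", i,
                        " without overlap after 10000 attempts")
    }
    ord <- order(points)
    inserts <- inserts[ord]; points <- points[ord]

    background <- random_dna(spec$genome_len, spec$gc)
    pieces <- character(0)
    truth_rows <- list()
    prev <- 0L; offset <- 0L
    for (i in seq_len(k)) {
      ins <- inserts[[i]]
      strand <- sample(c("+", "-"), 1L)
      has_tsd <- ins$kind %in% c("intact", "solo_ltr")
      tsd_len <- if (has_tsd)
        sample(spec$tsd_len_range[1L]:spec$tsd_len_range[2L], 1L) else 0L
      tsd <- if (has_tsd) random_dna(tsd_len, spec$gc) else ""
      body <- if (strand == "-") revcomp(ins$seq) else ins$seq
      pieces <- c(pieces, substr(background, prev + 1L, points[i]),
                  tsd, body, tsd)
      start <- offset + points[i] + tsd_len          # 0-based, TSD-exclusive
      end <- start + nchar(body)
      offset <- offset + 2L * tsd_len + nchar(body)
      prev <- points[i]
      tr <- ins$truth
      truth_rows[[i]] <- data.frame(
        id = sprintf("planted_%02d", i), kind = ins$kind,
        chrom = spec$chrom_name, start = start, end = end, strand = strand,
        ltr_len = ins$ltr_len,
        pair_identity = if (is.null(tr)) NA_real_ else tr$pair_identity,
        divergence_nominal = if (is.null(tr)) NA_real_
                             else tr$divergence_nominal,
        tsd_seq = tsd,
        pbs_offset = if (is.null(tr)) NA_integer_ else tr$pbs_offset,
        pbs_len = if (is.null(tr)) NA_integer_ else tr$pbs_len,
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, substr(background, prev + 1L, spec$genome_len))
    genome <- setNames(paste(pieces, collapse = ""), spec$chrom_name)
    structure(list(genome = genome, truth = do.call(rbind, truth_rows),
                   spec = spec),
              class = "synth_genome")
  })
}

.empty_truth <- function() {
  data.frame(id = character(0), kind = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             ltr_len = integer(0), pair_identity = numeric(0),
             divergence_nominal = numeric(0), tsd_seq = character(0),
             pbs_offset = integer(0), pbs_len = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.synth_genome <- function(x, ...) {
  cat("Synthetic genome:", nchar(x$genome), "bp;",
      nrow(x$truth), "planted features (",
      sum(x$truth$kind == "intact"), "intact,",
      sum(x$truth$kind == "solo_ltr"), "solo LTR,",
      sum(x$truth$kind == "truncated"), "truncated )\n")
  invisible(x)
}

#' Export a synthetic genome to FASTA + truth GFF3 + truth TSV
#'
#' @param sim a `"synth_genome"` object.
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.truth.gff3`, `<prefix>.truth.tsv`.
#' @return the three paths, invisibly.
#' @export
export_synth <- function(sim, prefix) {
  fa <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".truth.gff3")
  tsv <- paste0(prefix, ".truth.tsv")
  write_fasta(sim$genome, fa)
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  tr <- sim$truth
  for (i in seq_len(nrow(tr)))
    writeLines(paste(tr$chrom[i], "riderscout_synth", tr$kind[i],
                     tr$start[i] + 1L, tr$end[i], ".", tr$strand[i], ".",
                     sprintf("ID=%s", tr$id[i]), sep = "\t"), con)
  close(con)
  write.table(tr, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, gff, tsv))
}

#' Draw LTR pairs whose realized identities land in given age classes
#'
#' For dating fixtures: draws LTR pairs by mutating a fresh ancestral
#' LTR at class-interior divergences and re-draws until the *realized*
#' pair identity (recomputed by alignment) falls inside the requested
#' identity class, so that class counts computed from realized
#' identities are exact by construction.
#'
#' @param counts named integer vector over classes `"98-100"`,
#'   `"95-98"`, `"85-95"`.
#' @param ltr_len LTR length in bp.
#' @param gc GC content.
#' @param seed integer seed.
#' @return data frame with `ltr5`, `ltr3`, `identity`, `class`.
#' @export
sample_ltr_pairs_by_class <- function(counts = c("98-100" = 10L,
                                                 "95-98" = 29L,
                                                 "85-95" = 32L),
                                      ltr_len = 400L, gc = 0.38, seed = 1L) {
  bounds <- list("98-100" = c(0.98, 1), "95-98" = c(0.95, 0.98),
                 "85-95" = c(0.85, 0.95))
  stopifnot(all(names(counts) %in% names(bounds)))
  with_seed(seed, {
    rows <- list()
    for (cl in names(counts)) {
      b <- bounds[[cl]]
      for (i in seq_len(counts[[cl]])) {
        repeat {
          target <- runif(1L, b[1L] + 0.02 * diff(b), b[2L] - 0.02 * diff(b))
          base <- random_dna(ltr_len, gc)
          d <- 1 - target
          l5 <- mutate_seq(base, d / 2); l3 <- mutate_seq(base, d / 2)
          id <- global_identity(l5, l3)$identity
          hi_ok <- if (b[2L] == 1) id <= 1 else id < b[2L]
          if (id >= b[1L] && hi_ok) break
        }
        rows[[length(rows) + 1L]] <- data.frame(
          ltr5 = l5, ltr3 = l3, identity = id, class = cl,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
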