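## Classification and summarisation of cross-genome homology screens
## consumed as BLAST tabular (outfmt-6) hit tables.

.hit_cols <- c("query_id", "subject_id", "pident", "align_len",
               "mismatches", "gap_opens", "qstart", "qend", "sstart",
               "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Twelve tab-separated columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. `send < sstart`
#' encodes a minus-strand subject alignment and is recorded as
#' `strand = "-"`.
#'
#' @param path hit table path.
#' @param species_map optional data frame with `subject_id`, `species`
#'   columns (or a named character vector) assigning each subject to a
#'   species/genome.
#' @return data frame with the 12 standard columns plus `strand` and
#'   `species`.
#' @export
read_hit_table <- function(path, species_map = NULL) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L) stop("empty hit table: ", path)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L))
    stop("line ", which(nc != 12L)[1L], " of '", path, "' has ",
         nc[nc != 12L][1L], " columns; expected 12")
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- .hit_cols
  num_cols <- setdiff(.hit_cols, c("query_id", "subject_id"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) stop("non-numeric value in column '", cl, "' at line ",
                       which(is.na(v))[1L])
    df[[cl]] <- v
  }
  if (any(df$pident < 0 | df$pident > 100))
    stop("pident outside [0, 100] at line ",
         which(df$pident < 0 | df$pident > 100)[1L])
  if (any(df$qstart > df$qend))
    stop("qstart > qend at line ", which(df$qstart > df$qend)[1L])
  if (any(df$qstart < 1))
    stop("qstart < 1 at line ", which(df$qstart < 1)[1L])
  df$strand <- ifelse(df$send < df$sstart, "-", "+")
  df$species <- NA_character_
  if (!is.null(species_map)) {
    if (is.data.frame(species_map))
      species_map <- setNames(species_map$species, species_map$subject_id)
    df$species <- unname(species_map[df$subject_id])
  }
  df
}

#' Filter hits to family-like status
#'
#' Keeps hits with percent identity at least `min_pident` and
#' alignment length at least `min_len_frac` of the query length -
#' the ">= 50% sequence homology and >= 50% sequence length" rule at
#' its defaults.
#'
#' @param hits hit data frame ([read_hit_table()]).
#' @param query_len length of the reference query (bp).
#' @param min_pident minimum percent identity (default 50).
#' @param min_len_frac minimum alignment length as a fraction of
#'   `query_len` (default 0.5).
#' @return the kept subset, with a `per_species` count table attached
#'   as attribute `"species_counts"` when species are assigned.
#' @export
filter_rider_like <- function(hits, query_len, min_pident = 50,
                              min_len_frac = 0.5) {
  stopifnot(query_len > 0)
  keep <- hits$pident >= min_pident &
    hits$align_len >= min_len_frac * query_len
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!all(is.na(out$species)))
    attr(out, "species_counts") <- table(out$species)
  out
}

#' Per-position hit coverage over the query
#'
#' @param hits hit data frame sharing one query.
#' @param query_len query length (bp).
#' @return list with `coverage` (integer vector of length `query_len`:
#'   number of hits covering each 1-based query position) and
#'   `align_len` (the alignment-length distribution of the hits).
#' @export
coverage_profile <- function(hits, query_len) {
  if (length(unique(hits$query_id)) > 1L)
    stop("hits must share a single query")
  delta <- integer(query_len + 1L)
  for (i in seq_len(nrow(hits))) {
    a <- max(1L, as.integer(hits$qstart[i]))
    b <- min(query_len, as.integer(hits$qend[i]))
    if (b < a) next
    delta[a] <- delta[a] + 1L
    delta[b + 1L] <- delta[b + 1L] - 1L
  }
  list(coverage = cumsum(delta[seq_len(query_len)]),
       align_len = hits$align_len)
}

#' Classify LTR-query hits into length regimes
#'
#' After applying the family-likeness filter, hits are labelled
#' `long_LTR` when the alignment length is within 350-450 bp,
#' `short_LTR` within 150-300 bp, `other` otherwise.
#'
#' @param hits hit data frame from an LTR-only query.
#' @param query_len LTR query length (bp).
#' @param min_pident,min_len_frac passed to [filter_rider_like()].
#' @param long_range,short_range inclusive alignment-length bands.
#' @return the filtered hits with an added `ltr_class` column.
#' @export
classify_ltr_hits <- function(hits, query_len, min_pident = 50,
                              min_len_frac = 0.5,
                              long_range = c(350, 450),
                              short_range = c(150, 300)) {
  kept <- filter_rider_like(hits, query_len, min_pident, min_len_frac)
  cls <- rep("other", nrow(kept))
  cls[kept$align_len >= long_range[1] & kept$align_len <= long_range[2]] <-
    "long_LTR"
  cls[kept$align_len >= short_range[1] & kept$align_len <= short_range[2]] <-
    "short_LTR"
  kept$ltr_class <- cls
  kept
}

#' Confirm homolog hits by reciprocal search
#'
#' A forward hit is confirmed when any of the top `top_n` (by bitscore)
#' reverse hits of its subject region overlaps a known family locus by
#' at least 1 bp.
#'
#' @param forward_hits kept forward hits; their `query_id`-free region
#'   identity is taken from a `region_id` column (or `subject_id` when
#'   absent).
#' @param reverse_hits hit table of the reverse search; `query_id` must
#'   match the forward regions' ids and subject coordinates refer to
#'   the original genome.
#' @param family_loci data frame with `chrom`, `start`, `end` (0-based
#'   half-open) of the known family loci in the original genome.
#' @param top_n how many top reverse hits to consider (default 5).
#' @return `forward_hits` with a logical `reciprocal_ok` column;
#'   regions without any reverse record get `FALSE` with a warning.
#' @export
reciprocal_confirm <- function(forward_hits, reverse_hits, family_loci,
                               top_n = 5L) {
  region <- if ("region_id" %in% names(forward_hits))
    forward_hits$region_id else forward_hits$subject_id
  missing <- character(0)
  ok <- vapply(seq_len(nrow(forward_hits)), function(i) {
    rh <- reverse_hits[reverse_hits$query_id == region[i], , drop = FALSE]
    if (nrow(rh) == 0L) { missing <<- c(missing, region[i]); return(FALSE) }
    rh <- rh[order(-rh$bitscore), , drop = FALSE]
    rh <- rh[seq_len(min(top_n, nrow(rh))), , drop = FALSE]
    s0 <- pmin(rh$sstart, rh$send) - 1L   # to 0-based half-open
    e0 <- pmax(rh$sstart, rh$send)
    any(vapply(seq_len(nrow(rh)), function(j)
      any(family_loci$chrom == rh$subject_id[j] &
            family_loci$start < e0[j] & family_loci$end > s0[j]),
      logical(1)))
  }, logical(1))
  if (length(missing))
    warning("no reverse hits for region(s): ",
            paste(unique(missing), collapse = ", "))
  forward_hits$reciprocal_ok <- ok
  forward_hits
}

#' Naive homology scan of a query against subject sequences
#'
#' A deliberately simple seed-and-extend local scanner (exact k-mer
#' seeds, gapless x-drop extension, unit-free +2/-2 scores) producing
#' outfmt-6-shaped hit rows for self-contained fixtures; no E-value
#' model is computed (`evalue` is `NA`). Not a substitute for a real
#' aligner on real genomes.
#'
#' @param query named character vector of length 1.
#' @param subjects named character vector of subject sequences.
#' @param seed_kmer exact seed length (default 14).
#' @param xdrop x-drop threshold (default 10).
#' @param min_len minimum alignment length to report.
#' @return hit data frame in [read_hit_table()] shape.
#' @export
scan_homologs <- function(query, subjects, seed_kmer = 14L, xdrop = 10,
                          min_len = 30L) {
  stopifnot(length(query) == 1L, !is.null(names(query)))
  qid <- names(query)[1L]
  q <- query[[1L]]
  nq <- nchar(q)
  qk <- substring(q, seq_len(nq - seed_kmer + 1L),
                  seq_len(nq - seed_kmer + 1L) + seed_kmer - 1L)
  rows <- list()
  for (sid in names(subjects)) {
    s <- subjects[[sid]]
    ns <- nchar(s)
    if (ns < seed_kmer) next
    joint <- paste0(q, strrep("N", seed_kmer), s)
    chars <- seq_chars(joint)
    sk <- substring(s, seq_len(ns - seed_kmer + 1L),
                    seq_len(ns - seed_kmer + 1L) + seed_kmer - 1L)
    hitpos <- match(sk, qk)             # first query occurrence per subject pos
    found <- which(!is.na(hitpos))
    if (length(found) == 0L) next
    qpos <- hitpos[found]; spos <- found
    diag <- spos - qpos
    for (d in unique(diag)) {
      qs <- sort(qpos[diag == d])
      brk <- c(0L, which(diff(qs) > 200L), length(qs))
      for (ci in seq_len(length(brk) - 1L)) {
        cl <- qs[(brk[ci] + 1L):brk[ci + 1L]]
        a1 <- cl[1L]; a2 <- min(cl[length(cl)] + seed_kmer - 1L, nq, ns - d)
        off <- nq + seed_kmer + d       # joint index offset: s[j] at q[j]+off
        ext_l <- xdrop_extend(chars, a1, a1 + off, -1L, 2, -2, xdrop)
        ext_r <- xdrop_extend(chars, a2, a2 + off, +1L, 2, -2, xdrop)
        a1 <- a1 - ext_l$steps; a2 <- a2 + ext_r$steps
        len <- a2 - a1 + 1L
        if (len < min_len) next
        x <- chars[a1:a2]; y <- chars[(a1 + off):(a2 + off)]
        mm <- sum(x != y | x == "N")
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, subject_id = sid,
          pident = 100 * (len - mm) / len, align_len = len,
          mismatches = mm, gap_opens = 0L, qstart = a1, qend = a2,
          sstart = a1 + d, send = a2 + d, evalue = NA_real_,
          bitscore = 2 * (len - mm) - 2 * mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(stats::setNames(
      data.frame(matrix(ncol = 12L, nrow = 0L)), .hit_cols))
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, -out$bitscore), ]
  rownames(out) <- NULL
  out$strand <- "+"
  out$species <- NA_character_
  out
}
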