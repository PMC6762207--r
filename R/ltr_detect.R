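## Structural de novo detection of full-length LTR retrotransposons:
## seed-and-extend discovery of the LTR pair, TSD refinement, terminal
## TG...CA motif check, PBS screening against a tRNA set, ORF counting
## and overlap resolution. All coordinates 0-based half-open on the
## plus strand of the assembly.

#' Detector parameter set
#'
#' Defaults are the parameterization used throughout: LTR length
#' 100-5000 bp, LTR start-to-start distance 4000-30000 bp, TSD length
#' 3-20 bp, a TSD/motif search vicinity of 80 bp around each boundary,
#' x-drop 7, at most 1 terminal-motif mismatch, PBS searched in a 60 bp
#' window at alignment lengths 8-40 and offsets 0-10, quality filtering
#' on, and no minimum ORF count. `min_ltr_dist`/`max_ltr_dist` are the
#' distance between the starts of the two LTRs.
#'
#' @param min_ltr_len,max_ltr_len LTR length bounds (bp).
#' @param min_ltr_dist,max_ltr_dist bounds on the 5'LTR-start to
#'   3'LTR-start distance (bp).
#' @param min_tsd,max_tsd TSD length bounds (bp).
#' @param vicinity bp searched around each element boundary for TSDs.
#' @param xdrop x-drop score threshold for seed extension and for the
#'   boundary-consistency check during TSD refinement.
#' @param motif_mismatch_max allowed mismatches summed over the TG and
#'   CA termini.
#' @param pbs_radius window size downstream of the 5' LTR searched for
#'   the PBS (bp).
#' @param pbs_align_len allowed PBS alignment length range (bp).
#' @param pbs_offset allowed distance range between the 5' LTR end and
#'   the PBS (bp).
#' @param require_quality_filter if `TRUE`, `quality_pass` demands TSD,
#'   terminal motif and PBS.
#' @param min_orfs minimum ORF count required by the quality filter.
#' @param seed_kmer exact seed length for repeat-pair discovery.
#' @param match_score,mismatch_score,gap_score alignment scores for the
#'   extension stage (the detector itself is gapless; `gap_score` is
#'   kept for the auxiliary local aligners).
#' @param min_pair_identity minimum LTR-pair identity.
#' @param overlaps_mode `"no"` (greedy overlap resolution) or `"all"`.
#' @return a list of class `"detector_params"`.
#' @export
detector_params <- function(min_ltr_len = 100L, max_ltr_len = 5000L,
                            min_ltr_dist = 4000L, max_ltr_dist = 30000L,
                            min_tsd = 3L, max_tsd = 20L, vicinity = 80L,
                            xdrop = 7, motif_mismatch_max = 1L,
                            pbs_radius = 60L, pbs_align_len = c(8L, 40L),
                            pbs_offset = c(0L, 10L),
                            require_quality_filter = TRUE, min_orfs = 0L,
                            seed_kmer = 20L, match_score = 2,
                            mismatch_score = -2, gap_score = -3,
                            min_pair_identity = 0.80,
                            overlaps_mode = c("no", "all")) {
  p <- list(min_ltr_len = min_ltr_len, max_ltr_len = max_ltr_len,
            min_ltr_dist = min_ltr_dist, max_ltr_dist = max_ltr_dist,
            min_tsd = min_tsd, max_tsd = max_tsd, vicinity = vicinity,
            xdrop = xdrop, motif_mismatch_max = motif_mismatch_max,
            pbs_radius = pbs_radius, pbs_align_len = pbs_align_len,
            pbs_offset = pbs_offset,
            require_quality_filter = require_quality_filter,
            min_orfs = min_orfs, seed_kmer = seed_kmer,
            match_score = match_score, mismatch_score = mismatch_score,
            gap_score = gap_score, min_pair_identity = min_pair_identity,
            overlaps_mode = match.arg(overlaps_mode))
  stopifnot(p$min_ltr_len <= p$max_ltr_len,
            p$min_ltr_dist <= p$max_ltr_dist,
            p$min_tsd <= p$max_tsd,
            p$min_pair_identity > 0, p$min_pair_identity <= 1,
            length(p$pbs_align_len) == 2L, length(p$pbs_offset) == 2L)
  class(p) <- "detector_params"
  p
}

#' Find candidate LTR pairs on one sequence
#'
#' Exact `seed_kmer`-mers occurring at two positions whose separation is
#' compatible with the LTR distance constraints seed a gapless x-drop
#' extension along the diagonal; extensions on one diagonal are merged,
#' trimmed to the maximal-scoring segment, and kept when both repeat
#' copies are within the LTR length bounds, their identity reaches
#' `min_pair_identity` and the start-to-start distance lies within
#' `[min_ltr_dist, max_ltr_dist]`.
#'
#' @param seq nucleotide string (one chromosome).
#' @param params a [detector_params()] list.
#' @return data frame with 0-based half-open `start5`, `end5`,
#'   `start3`, `end3` and `identity`; zero rows when nothing is found.
#' @export
find_repeat_pairs <- function(seq, params = detector_params()) {
  empty <- data.frame(start5 = integer(0), end5 = integer(0),
                      start3 = integer(0), end3 = integer(0),
                      identity = numeric(0))
  n <- nchar(seq)
  if (n < params$min_ltr_dist + params$min_ltr_len) return(empty)
  k <- params$seed_kmer
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  dup_vals <- unique(kmers[ok][duplicated(kmers[ok])])
  if (length(dup_vals) == 0L) return(empty)
  idx <- which(ok & kmers %in% dup_vals)
  grp <- split(starts[idx], kmers[idx])

  lo <- max(k, params$min_ltr_dist - params$max_ltr_len)
  hi <- params$max_ltr_dist
  seed_i <- integer(0); seed_d <- integer(0)
  for (pos in grp) {
    if (length(pos) > 50L) next  # low-complexity k-mer, uninformative
    cmb <- utils::combn(sort(pos), 2L)
    sep <- cmb[2L, ] - cmb[1L, ]
    keep <- sep >= lo & sep <= hi
    seed_i <- c(seed_i, cmb[1L, keep])
    seed_d <- c(seed_d, sep[keep])
  }
  if (length(seed_i) == 0L) return(empty)

  chars <- seq_chars(seq)
  out <- empty
  for (d in unique(seed_d)) {
    pos <- sort(unique(seed_i[seed_d == d]))
    brk <- c(0L, which(diff(pos) > params$max_ltr_len), length(pos))
    for (ci in seq_len(length(brk) - 1L)) {
      cl <- pos[(brk[ci] + 1L):brk[ci + 1L]]
      a1 <- cl[1L]; a2 <- cl[length(cl)] + k - 1L
      if (a2 + d > n) a2 <- n - d
      ext_l <- xdrop_extend(chars, a1, a1 + d, -1L,
                            params$match_score, params$mismatch_score,
                            params$xdrop)
      ext_r <- xdrop_extend(chars, a2, a2 + d, +1L,
                            params$match_score, params$mismatch_score,
                            params$xdrop)
      a1 <- a1 - ext_l$steps; a2 <- a2 + ext_r$steps
      len <- a2 - a1 + 1L
      if (len > d) next  # copies would overlap
      if (len < params$min_ltr_len || len > params$max_ltr_len) next
      if (d < params$min_ltr_dist || d > params$max_ltr_dist) next
      x <- chars[a1:a2]; y <- chars[(a1 + d):(a2 + d)]
      identity <- sum(x == y & x != "N") / len
      if (identity < params$min_pair_identity) next
      out <- rbind(out, data.frame(start5 = a1 - 1L, end5 = a1 - 1L + len,
                                   start3 = a1 - 1L + d,
                                   end3 = a1 - 1L + d + len,
                                   identity = identity))
    }
  }
  if (nrow(out) == 0L) return(empty)
  ## collapse near-duplicate candidates (same element seeded on close
  ## diagonals): keep the best-identity one among pairs whose 5' copies
  ## overlap by more than half
  out <- out[order(-out$identity, -(out$end5 - out$start5), out$start5), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) for (j in (i + 1L):nrow(out)) {
      if (!keep[j]) next
      ov5 <- min(out$end5[i], out$end5[j]) - max(out$start5[i], out$start5[j])
      ov3 <- min(out$end3[i], out$end3[j]) - max(out$start3[i], out$start3[j])
      w <- min(out$end5[i] - out$start5[i], out$end5[j] - out$start5[j])
      if (ov5 > w / 2 && ov3 > w / 2) keep[j] <- FALSE
    }
  }
  out <- out[keep, ]
  out <- out[order(out$start5), ]
  rownames(out) <- NULL
  out
}

#' Detect the target site duplication and refine element boundaries
#'
#' Searches all exact duplications of length `min_tsd..max_tsd` between
#' the `vicinity`-bp windows spanning the element's 5' and 3'
#' boundaries, such that the duplication immediately flanks a consistent
#' adjusted element. Consistency demands that (i) the adjusted LTR
#' lengths stay within bounds, (ii) the adjusted termini still carry the
#' TG...CA motif within `motif_mismatch_max` mismatches, and (iii)
#' boundary shifts beyond the TSD length scale (`max_tsd`) do not
#' change the gapless LTR-pair alignment score by more than `xdrop` in
#' the unfavourable direction (extension into non-homologous sequence,
#' or truncation of well-aligned sequence); shifts within `max_tsd`
#' are ordinary boundary noise and always admissible. The longest
#' admissible duplication wins; ties are broken by the smallest total
#' boundary adjustment, then by the leftmost adjusted start.
#'
#' @param seq nucleotide string.
#' @param pair one row of [find_repeat_pairs()] output (or any list
#'   with `start5`, `end5`, `start3`, `end3`).
#' @param params a [detector_params()] list.
#' @return list with `tsd_seq` (empty string when none), `tsd_len`,
#'   and refined 0-based half-open `start`/`end` element boundaries.
#' @export
detect_tsd <- function(seq, pair, params = detector_params()) {
  n <- nchar(seq)
  chars <- seq_chars(seq)
  s <- pair$start5; e <- pair$end3
  d <- pair$start3 - pair$start5
  vh <- params$vicinity %/% 2L
  no_tsd <- list(tsd_seq = "", tsd_len = 0L, start = s, end = e)

  P <- max(params$max_tsd, s - vh):(s + vh)
  Q <- (e - vh):min(n - params$min_tsd, e + vh)
  P <- P[P >= 2L & P + d < n]         # leave room for motif columns
  Q <- Q[Q > d + 2L & Q <= n]
  if (length(P) == 0L || length(Q) == 0L) return(no_tsd)

  motif_ok_start <- vapply(P, function(p)
    (chars[p + 1L] != "T") + (chars[p + 2L] != "G"), numeric(1))
  motif_ok_end <- vapply(Q, function(q)
    (chars[q - 1L] != "C") + (chars[q] != "A"), numeric(1))

  ## boundary shifts within the TSD length scale are ordinary alignment
  ## noise and always admissible; larger shifts must not change the
  ## gapless pair score by more than xdrop in the unfavourable direction
  shift_ok_start <- vapply(P, function(p) {
    if (abs(p - s) <= params$max_tsd) return(TRUE)
    if (p < s) {  # extend LTR5 leftwards: added columns must not tank score
      gapless_score(chars, p + 1L, s, d, params$match_score,
                    params$mismatch_score) >= -params$xdrop
    } else {      # shrink: must not cut strongly matching columns
      gapless_score(chars, s + 1L, p, d, params$match_score,
                    params$mismatch_score) <= params$xdrop
    }
  }, logical(1))
  shift_ok_end <- vapply(Q, function(q) {
    if (abs(q - e) <= params$max_tsd) return(TRUE)
    if (q > e) {
      gapless_score(chars, e + 1L, q, -d, params$match_score,
                    params$mismatch_score) >= -params$xdrop
    } else {
      gapless_score(chars, q + 1L, e, -d, params$match_score,
                    params$mismatch_score) <= params$xdrop
    }
  }, logical(1))

  for (k in params$max_tsd:params$min_tsd) {
    lk <- substring(seq, P - k + 1L, P)
    rk <- substring(seq, Q + 1L, Q + k)
    valid_l <- P - k >= 0L & !grepl("N", lk, fixed = TRUE)
    valid_r <- Q + k <= n & !grepl("N", rk, fixed = TRUE)
    m <- outer(lk, rk, "==")
    m[!valid_l, ] <- FALSE
    m[, !valid_r] <- FALSE
    if (!any(m)) next
    hit <- which(m, arr.ind = TRUE)
    p <- P[hit[, 1L]]; q <- Q[hit[, 2L]]
    ltr_len <- q - d - p
    adm <- ltr_len >= params$min_ltr_len & ltr_len <= params$max_ltr_len &
      (motif_ok_start[hit[, 1L]] + motif_ok_end[hit[, 2L]]) <=
        params$motif_mismatch_max &
      shift_ok_start[hit[, 1L]] & shift_ok_end[hit[, 2L]]
    if (!any(adm)) next
    p <- p[adm]; q <- q[adm]
    adj <- abs(p - s) + abs(q - e)
    best <- order(adj, p)[1L]
    return(list(tsd_seq = substr(seq, p[best] - k + 1L, p[best]),
                tsd_len = k, start = p[best], end = q[best]))
  }
  no_tsd
}

#' Check the terminal TG...CA motif
#'
#' @param seq nucleotide string.
#' @param start,end element boundaries, 0-based half-open.
#' @param params a [detector_params()] list.
#' @return `TRUE` iff the element's first dinucleotide vs `TG` plus its
#'   last dinucleotide vs `CA` differ in at most `motif_mismatch_max`
#'   positions in total.
#' @export
check_terminal_motif <- function(seq, start, end, params = detector_params()) {
  first2 <- substr(seq, start + 1L, start + 2L)
  last2 <- substr(seq, end - 1L, end)
  mism <- hamming(first2, "TG") + hamming(last2, "CA")
  mism <= params$motif_mismatch_max
}

#' Screen for a primer binding site downstream of the 5' LTR
#'
#' The reverse complement of each tRNA's 3'-terminal 40 nt is locally
#' aligned (match +1, mismatch -1, gap -2) against the `pbs_radius`-bp
#' window immediately downstream of the 5' LTR. The best hit with
#' alignment length within `pbs_align_len`, offset from the LTR end
#' within `pbs_offset` and identity >= 0.8 is reported; ties are broken
#' by higher identity, then lower offset, then tRNA id.
#'
#' @param seq nucleotide string.
#' @param ltr5_end 0-based exclusive end of the 5' LTR.
#' @param trnas named character vector of tRNA sequences.
#' @param params a [detector_params()] list.
#' @return list with `trna_id`, `offset`, `align_len`, `identity`,
#'   `trna_segment`, or `NULL` when no admissible hit exists.
#' @export
detect_pbs <- function(seq, ltr5_end, trnas, params = detector_params()) {
  stopifnot(length(trnas) > 0, !is.null(names(trnas)))
  n <- nchar(seq)
  win <- substr(seq, ltr5_end + 1L, min(n, ltr5_end + params$pbs_radius))
  if (nchar(win) < params$pbs_align_len[1L]) return(NULL)
  best <- NULL
  for (id in sort(names(trnas))) {
    tr <- trnas[[id]]
    tail40 <- substr(tr, max(1L, nchar(tr) - 39L), nchar(tr))
    probe <- revcomp(tail40)
    cand <- sw_candidates(probe, win, match = 1, mismatch = -1, gap = -2)
    if (nrow(cand) == 0L) next
    cand$offset <- cand$sub_start - 1L
    cand$identity <- cand$matches / cand$columns
    cand <- cand[cand$columns >= params$pbs_align_len[1L] &
                   cand$columns <= params$pbs_align_len[2L] &
                   cand$offset >= params$pbs_offset[1L] &
                   cand$offset <= params$pbs_offset[2L] &
                   cand$identity >= 0.8, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order(-cand$score, -cand$identity, cand$offset), , drop = FALSE]
    top <- cand[1L, ]
    hit <- list(trna_id = id, offset = top$offset, align_len = top$columns,
                identity = top$identity, score = top$score,
                trna_segment = substr(tail40,
                                      nchar(tail40) - top$q_end + 1L,
                                      nchar(tail40) - top$q_start + 1L))
    if (is.null(best) ||
        hit$score > best$score ||
        (hit$score == best$score && hit$identity > best$identity) ||
        (hit$score == best$score && hit$identity == best$identity &&
           hit$offset < best$offset))
      best <- hit
  }
  best
}

#' Count open reading frames in an element
#'
#' Six-frame ATG-to-stop scan; one ORF is counted per frame and
#' stop-to-stop segment (from the first ATG), when its length including
#' the stop codon reaches `min_len`.
#'
#' @param seq nucleotide string (the element, plus strand).
#' @param min_len minimum ORF length in bp (default 300).
#' @return integer ORF count over all six frames.
#' @export
count_orfs <- function(seq, min_len = 300L) {
  stops <- c("TAA", "TAG", "TGA")
  total <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (frame in 0:2) {
      starts <- seq(1L + frame, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      stop_idx <- which(codons %in% stops)
      atg_idx <- which(codons == "ATG")
      if (length(atg_idx) == 0L || length(stop_idx) == 0L) next
      seg <- findInterval(atg_idx, stop_idx)  # segment = # stops before ATG
      first_atg <- tapply(atg_idx, seg, min)
      next_stop_pos <- stop_idx[as.integer(names(first_atg)) + 1L]
      ok <- !is.na(next_stop_pos)
      len <- (next_stop_pos[ok] - first_atg[ok] + 1L) * 3L
      total <- total + sum(len >= min_len)
    }
  }
  total
}

#' Resolve overlapping elements
#'
#' With `mode = "no"`, among any set of mutually overlapping elements
#' the one with the highest LTR identity is kept greedily (ties: longer
#' element, then leftmost) and all elements overlapping it discarded;
#' `mode = "all"` returns the input. Output is sorted by start.
#'
#' @param elements data frame with `start`, `end`, `ltr_identity`
#'   columns (one chromosome).
#' @param mode `"no"` or `"all"`.
#' @return the retained subset, sorted by `start`.
#' @export
resolve_overlaps <- function(elements, mode = c("no", "all")) {
  mode <- match.arg(mode)
  if (mode == "all" || nrow(elements) <= 1L)
    return(elements[order(elements$start), , drop = FALSE])
  ord <- order(-elements$ltr_identity,
               -(elements$end - elements$start), elements$start)
  kept <- logical(nrow(elements))
  dead <- logical(nrow(elements))
  for (i in ord) {
    if (dead[i]) next
    kept[i] <- TRUE
    ov <- elements$start < elements$end[i] & elements$end > elements$start[i]
    dead[ov] <- TRUE
  }
  out <- elements[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Annotate a genome with full-length LTR retrotransposons
#'
#' Composes [find_repeat_pairs()], [detect_tsd()],
#' [check_terminal_motif()], [detect_pbs()], [count_orfs()] and
#' [resolve_overlaps()] over every chromosome. Because an intact
#' element's LTR pair is a direct repeat on either strand, discovery
#' runs on the plus strand and the strand is assigned from the PBS,
#' which is the structurally asymmetric part: the PBS of a plus-strand
#' element sits just downstream of the left LTR, that of a minus-strand
#' element just upstream of the right LTR (in reverse complement).
#' Elements with no PBS in either orientation are reported on `"+"`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param trnas named character vector of tRNA sequences.
#' @param params a [detector_params()] list.
#' @param domain_table optional data frame of externally produced
#'   protein-domain hits with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `domain`; hits overlapping an element are attached
#'   to it (annotated, never required).
#' @return object of class `"ltr_annotation"`: a list with `elements`
#'   (data frame, one row per element, `quality_pass` flagging elements
#'   with TSD + terminal motif + PBS) and `params`.
#' @export
annotate_genome <- function(genome, trnas, params = detector_params(),
                            domain_table = NULL) {
  stopifnot(is.character(genome))
  rows <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    pairs <- find_repeat_pairs(seq, params)
    if (nrow(pairs) == 0L) next
    chrom_rows <- lapply(seq_len(nrow(pairs)), function(i) {
      pr <- pairs[i, ]
      tsd <- detect_tsd(seq, pr, params)
      start <- tsd$start; end <- tsd$end
      d <- pr$start3 - pr$start5
      ltr_len <- end - d - start
      ltr5 <- c(start, start + ltr_len)
      ltr3 <- c(end - ltr_len, end)
      chars_ok <- seq_chars(substr(seq, start + 1L, start + ltr_len)) ==
        seq_chars(substr(seq, end - ltr_len + 1L, end))
      identity <- mean(chars_ok)
      motif_ok <- check_terminal_motif(seq, start, end, params)
      pbs_plus <- detect_pbs(seq, ltr5[2L], trnas, params)
      rc <- revcomp(substr(seq, start + 1L, end))
      pbs_minus <- detect_pbs(rc, ltr_len, trnas, params)
      if (is.null(pbs_plus) && is.null(pbs_minus)) {
        strand <- "+"; pbs <- NULL
      } else if (is.null(pbs_minus) ||
                 (!is.null(pbs_plus) && pbs_plus$score >= pbs_minus$score)) {
        strand <- "+"; pbs <- pbs_plus
      } else {
        strand <- "-"; pbs <- pbs_minus
      }
      eseq <- substr(seq, start + 1L, end)
      data.frame(
        chrom = chrom, start = start, end = end, strand = strand,
        ltr5_start = ltr5[1L], ltr5_end = ltr5[2L],
        ltr3_start = ltr3[1L], ltr3_end = ltr3[2L],
        ltr_identity = identity,
        tsd_seq = tsd$tsd_seq, tsd_len = tsd$tsd_len,
        motif_ok = motif_ok,
        pbs_trna = if (is.null(pbs)) NA_character_ else pbs$trna_id,
        pbs_offset = if (is.null(pbs)) NA_integer_ else pbs$offset,
        pbs_len = if (is.null(pbs)) NA_integer_ else pbs$align_len,
        pbs_identity = if (is.null(pbs)) NA_real_ else pbs$identity,
        orf_count = count_orfs(eseq),
        stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, chrom_rows)
    df$quality_pass <- if (params$require_quality_filter)
      df$tsd_len > 0L & df$motif_ok & !is.na(df$pbs_trna) &
        df$orf_count >= params$min_orfs
    else rep(TRUE, nrow(df))
    df <- resolve_overlaps(df, params$overlaps_mode)
    rows[[chrom]] <- df
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), ltr5_start = integer(0),
               ltr5_end = integer(0), ltr3_start = integer(0),
               ltr3_end = integer(0), ltr_identity = numeric(0),
               tsd_seq = character(0), tsd_len = integer(0),
               motif_ok = logical(0), pbs_trna = character(0),
               pbs_offset = integer(0), pbs_len = integer(0),
               pbs_identity = numeric(0), orf_count = integer(0),
               quality_pass = logical(0), stringsAsFactors = FALSE)
  rownames(elements) <- NULL
  if (nrow(elements)) {
    rank <- stats::ave(elements$start, elements$chrom,
                       FUN = function(x) rank(x, ties.method = "first"))
    elements$id <- paste0(elements$chrom, "_", as.integer(rank))
  } else elements$id <- character(0)
  elements$n_domains <- rep(0L, nrow(elements))
  elements$domains <- rep("", nrow(elements))
  if (!is.null(domain_table) && nrow(elements)) {
    for (i in seq_len(nrow(elements))) {
      hit <- domain_table$chrom == elements$chrom[i] &
        domain_table$start < elements$end[i] &
        domain_table$end > elements$start[i]
      elements$n_domains[i] <- sum(hit)
      elements$domains[i] <- paste(domain_table$domain[hit], collapse = ",")
    }
  }
  elements <- elements[, c("id", setdiff(names(elements), "id"))]
  structure(list(elements = elements, params = params,
                 genome_lengths = nchar(genome)),
            class = "ltr_annotation")
}

#' @export
print.ltr_annotation <- function(x, ...) {
  el <- x$elements
  cat("LTR retrotransposon annotation\n")
  cat("  chromosomes scanned :", length(x$genome_lengths), "\n")
  cat("  candidate elements  :", nrow(el), "\n")
  cat("  quality-pass        :", sum(el$quality_pass), "\n")
  if (nrow(el)) {
    cat("  LTR identity range  :",
        sprintf("%.3f-%.3f", min(el$ltr_identity), max(el$ltr_identity)), "\n")
  }
  invisible(x)
}

#' @export
summary.ltr_annotation <- function(object, ...) {
  el <- object$elements
  out <- list(
    n = nrow(el),
    n_quality = sum(el$quality_pass),
    by_chrom = table(el$chrom),
    identity = if (nrow(el)) summary(el$ltr_identity) else NULL,
    tsd = table(el$tsd_len),
    pbs = table(el$pbs_trna, useNA = "ifany"))
  class(out) <- "summary.ltr_annotation"
  out
}

#' @export
print.summary.ltr_annotation <- function(x, ...) {
  cat("Elements:", x$n, " (quality-pass:", x$n_quality, ")\n")
  cat("Per chromosome:\n"); print(x$by_chrom)
  if (!is.null(x$identity)) { cat("LTR identity:\n"); print(x$identity) }
  invisible(x)
}

#' Extract element and LTR sequences in element orientation
#'
#' @param annotation an `"ltr_annotation"` object.
#' @param genome the named character vector the annotation was made from.
#' @param what `"element"`, `"ltr5"` or `"ltr3"`, in the element's own
#'   orientation (minus-strand elements are reverse complemented and
#'   their LTR roles swapped accordingly).
#' @return named character vector keyed by element id.
#' @export
element_seqs <- function(annotation, genome,
                         what = c("element", "ltr5", "ltr3")) {
  what <- match.arg(what)
  el <- annotation$elements
  out <- vapply(seq_len(nrow(el)), function(i) {
    seq <- genome[[el$chrom[i]]]
    minus <- el$strand[i] == "-"
    co <- switch(what,
      element = c(el$start[i], el$end[i]),
      ltr5 = if (minus) c(el$ltr3_start[i], el$ltr3_end[i])
             else c(el$ltr5_start[i], el$ltr5_end[i]),
      ltr3 = if (minus) c(el$ltr5_start[i], el$ltr5_end[i])
             else c(el$ltr3_start[i], el$ltr3_end[i]))
    s <- substr(seq, co[1L] + 1L, co[2L])
    if (minus) revcomp(s) else s
  }, character(1))
  names(out) <- el$id
  out
}
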