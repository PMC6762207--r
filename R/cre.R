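## Cis-regulatory element scanning and enrichment testing against
## promoter and strand-matched random backgrounds.

#' Built-in CRE motif catalogue
#'
#' Reads the motif catalogue shipped with the package (or a user YAML
#' of the same shape: a list of `{name, pattern, source}` entries with
#' IUPAC patterns). The MYB-core variants CTGTTG/CTGTTA are literal
#' drought/ABA-responsive core motifs; the CGCG box, ABRE-like, CE3 and
#' CBF/DRE entries are PLACE-style consensus defaults.
#'
#' @param path optional path to a YAML catalogue; default the built-in
#'   one.
#' @return data frame with `name`, `pattern`, `source`.
#' @export
read_motif_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs.yaml", package = "riderscout")
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(y, function(m)
    data.frame(name = m$name, pattern = toupper(m$pattern),
               source = if (is.null(m$source)) "" else m$source,
               stringsAsFactors = FALSE)))
  .check_iupac(out$pattern)
  out
}

.check_iupac <- function(patterns) {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(patterns))
  if (any(bad))
    stop("invalid IUPAC symbol in pattern(s): ",
         paste(patterns[bad], collapse = ", "))
  invisible(TRUE)
}

#' Scan sequences for IUPAC motifs
#'
#' Reports every exact IUPAC match (overlaps allowed) with 1-based
#' inclusive coordinates on the forward sequence. With
#' `strands = "both"`, minus-strand occurrences (matches of the
#' reverse-complemented pattern) are reported at their forward
#' coordinates with strand `"-"`.
#'
#' @param seqs named character vector of sequences.
#' @param motifs data frame with `name` and `pattern` columns (IUPAC),
#'   e.g. from [read_motif_catalogue()].
#' @param strands `"forward_only"` (default; promoter logic is
#'   directional) or `"both"`.
#' @return data frame with `motif_name`, `seq_id`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
scan_motifs <- function(seqs, motifs, strands = c("forward_only", "both")) {
  strands <- match.arg(strands)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  .check_iupac(motifs$pattern)
  rows <- list()
  set <- Biostrings::DNAStringSet(seqs)
  scan1 <- function(pattern, strand) {
    ml <- Biostrings::vmatchPattern(pattern, set,
                                    fixed = c(pattern = FALSE,
                                              subject = TRUE))
    n_hit <- S4Vectors::elementNROWS(ml)
    if (sum(n_hit) == 0L) return(NULL)
    ir <- unlist(ml)
    data.frame(seq_id = rep(names(seqs), n_hit),
               start = BiocGenerics::start(ir),
               end = BiocGenerics::end(ir), strand = strand,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(motifs))) {
    hit <- scan1(motifs$pattern[k], "+")
    if (strands == "both")
      hit <- rbind(hit, scan1(revcomp(motifs$pattern[k]), "-"))
    if (!is.null(hit) && nrow(hit)) {
      hit <- cbind(motif_name = motifs$name[k], hit,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- hit
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif_name = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$motif_name, motifs$name),
                   match(out$seq_id, names(seqs)), out$start), ]
  rownames(out) <- NULL
  out[, c("motif_name", "seq_id", "start", "end", "strand")]
}

#' Extract promoter sequences upstream of gene starts
#'
#' For plus-strand genes the `upstream_len` bp ending just before the
#' gene start; for minus-strand genes the reverse complement of the
#' `upstream_len` bp starting just after the gene end. Candidates
#' truncated below `min_len` bp at chromosome edges are skipped with a
#' warning.
#'
#' @param genes data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (e.g. [read_gff3()] filtered to genes).
#' @param genome named character vector of chromosome sequences.
#' @param upstream_len promoter length (default 400).
#' @param min_len minimum accepted (possibly truncated) length.
#' @return character vector of promoter sequences (named by gene row).
#' @export
promoter_background <- function(genes, genome, upstream_len = 400L,
                                min_len = 50L) {
  if (nrow(genes) == 0L) stop("no gene features supplied")
  out <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    len <- nchar(genome[[chrom]])
    if (genes$strand[i] == "+") {
      from <- max(0L, genes$start[i] - upstream_len)
      to <- genes$start[i]
      s <- substr(genome[[chrom]], from + 1L, to)
    } else {
      from <- genes$end[i]
      to <- min(len, genes$end[i] + upstream_len)
      s <- revcomp(substr(genome[[chrom]], from + 1L, to))
    }
    if (nchar(s) < min_len) { skipped <- skipped + 1L; next }
    nm <- if (!is.null(genes$id) && !is.na(genes$id[i])) genes$id[i]
          else paste0("gene_", i)
    out[nm] <- s
  }
  if (skipped > 0L)
    warning(skipped, " promoter(s) shorter than ", min_len,
            " bp at chromosome edges were skipped")
  if (length(out) == 0L) stop("no usable promoter sequences")
  out
}

## Two-sided Fisher exact p for a 2x2 table [[a, b], [c, d]] by
## minimum-likelihood summation over the hypergeometric support; the
## conventional 1e-7 relative tolerance guards ties against floating
## point.
fisher_p <- function(a, b, c, d) {
  m <- a + b            # foreground size
  n <- c + d            # background size
  k <- a + c            # total with motif
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher-exact motif enrichment of foreground vs background sequences
#'
#' In the default presence mode each sequence counts once per motif
#' (contains at least one hit or not); `count_mode = "occurrence"`
#' instead counts total hits vs scanned positions. For every motif a
#' 2x2 table `[[fg_with, fg_without], [bg_with, bg_without]]` is
#' tested with the two-sided exact test (summing hypergeometric
#' probabilities not exceeding that of the observed table). The odds
#' ratio is the sample odds ratio with a Haldane correction of 0.5 per
#' cell when any cell is zero.
#'
#' @param fg_seqs,bg_seqs named character vectors.
#' @param motifs motif data frame (`name`, `pattern`).
#' @param count_mode `"presence"` or `"occurrence"`.
#' @param strands passed to [scan_motifs()].
#' @return data frame with `motif_name`, `fg_with`, `fg_without`,
#'   `bg_with`, `bg_without`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(fg_seqs, bg_seqs, motifs,
                              count_mode = c("presence", "occurrence"),
                              strands = "forward_only") {
  count_mode <- match.arg(count_mode)
  stopifnot(length(fg_seqs) > 0, length(bg_seqs) > 0)
  if (is.null(names(fg_seqs))) names(fg_seqs) <- paste0("fg_", seq_along(fg_seqs))
  if (is.null(names(bg_seqs))) names(bg_seqs) <- paste0("bg_", seq_along(bg_seqs))
  fg_hits <- scan_motifs(fg_seqs, motifs, strands)
  bg_hits <- scan_motifs(bg_seqs, motifs, strands)
  rows <- lapply(seq_len(nrow(motifs)), function(k) {
    mn <- motifs$name[k]
    if (count_mode == "presence") {
      a <- length(unique(fg_hits$seq_id[fg_hits$motif_name == mn]))
      c_ <- length(unique(bg_hits$seq_id[bg_hits$motif_name == mn]))
      b <- length(fg_seqs) - a
      d <- length(bg_seqs) - c_
    } else {
      w <- nchar(motifs$pattern[k])
      a <- sum(fg_hits$motif_name == mn)
      c_ <- sum(bg_hits$motif_name == mn)
      b <- sum(pmax(nchar(fg_seqs) - w + 1L, 0L)) - a
      d <- sum(pmax(nchar(bg_seqs) - w + 1L, 0L)) - c_
    }
    any0 <- any(c(a, b, c_, d) == 0)
    h <- if (any0) 0.5 else 0
    or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
    data.frame(motif_name = mn, fg_with = a, fg_without = b,
               bg_with = c_, bg_without = d, odds_ratio = or,
               p_value = fisher_p(a, b, c_, d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full two-background enrichment report
#'
#' Runs the enrichment twice: once against gene-promoter sequences
#' ([promoter_background()]) and once against `n_random` random loci
#' of the same length as the foreground elements, sampled genome-wide
#' with the strand vector copied from the elements
#' ([sample_random_loci()]).
#'
#' @param ltr_seqs named character vector of foreground sequences
#'   (typically the elements' 5' LTRs or full elements).
#' @param genome named character vector of chromosome sequences.
#' @param genes gene data frame for the promoter background (or `NULL`
#'   to skip that approach).
#' @param motifs motif data frame.
#' @param element_strands strand vector of the foreground elements
#'   (recycled), used for strand-matched random sampling.
#' @param n_random number of random background loci (default 1000).
#' @param seed integer seed for the random background.
#' @param count_mode passed to [fisher_enrichment()].
#' @return list of class `"cre_enrichment"` with `promoter` and
#'   `random` result tables (`NULL` when skipped) and `presence`
#'   (per-element motif presence matrix).
#' @export
enrichment_report <- function(ltr_seqs, genome, genes, motifs,
                              element_strands = "+", n_random = 1000L,
                              seed = 1L, count_mode = "presence") {
  stopifnot(length(ltr_seqs) > 0)
  if (is.null(names(ltr_seqs)))
    names(ltr_seqs) <- paste0("element_", seq_along(ltr_seqs))
  lens <- nchar(ltr_seqs)
  strands <- rep_len(element_strands, length(ltr_seqs))
  prom <- NULL
  if (!is.null(genes)) {
    prom_seqs <- promoter_background(genes, genome)
    prom <- fisher_enrichment(ltr_seqs, prom_seqs, motifs, count_mode)
    prom$background_type <- "promoters"
  }
  ## random loci share the (modal) foreground length, as when a single
  ## reference length is used for all background draws
  len <- as.integer(stats::median(lens))
  rnd_strands <- rep(strands, length.out = n_random)
  rnd_seqs <- sample_random_loci(genome, n_random, len, rnd_strands, seed)
  names(rnd_seqs) <- paste0("random_", seq_len(n_random))
  rnd <- fisher_enrichment(ltr_seqs, rnd_seqs, motifs, count_mode)
  rnd$background_type <- "random"
  hits <- scan_motifs(ltr_seqs, motifs)
  presence <- vapply(motifs$name, function(mn)
    names(ltr_seqs) %in% hits$seq_id[hits$motif_name == mn],
    logical(length(ltr_seqs)))
  presence <- matrix(presence, nrow = length(ltr_seqs),
                     dimnames = list(names(ltr_seqs), motifs$name))
  structure(list(promoter = prom, random = rnd, presence = presence),
            class = "cre_enrichment")
}

#' @export
print.cre_enrichment <- function(x, ...) {
  cat("CRE enrichment report\n")
  for (nm in c("promoter", "random")) {
    if (is.null(x[[nm]])) next
    cat("-- background:", nm, "--\n")
    df <- x[[nm]]
    df$p_value <- signif(df$p_value, 3)
    df$odds_ratio <- signif(df$odds_ratio, 3)
    print(df[, c("motif_name", "fg_with", "fg_without", "bg_with",
                 "bg_without", "odds_ratio", "p_value")], row.names = FALSE)
  }
  invisible(x)
}
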