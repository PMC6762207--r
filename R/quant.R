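## Per-locus epigenomic and genomic-context summaries, plus in-silico
## PCR copy coverage.

#' Weighted DNA methylation per locus and cytosine context
#'
#' Weighted methylation: per locus and context, 100 * sum(meth_reads) /
#' sum(total_reads) over cytosines inside the locus with
#' `total_reads >= min_coverage` - the read-sum summary that is robust
#' at low coverage. A locus with no qualifying cytosines in a context
#' gets `NA`, never 0.
#'
#' @param records data frame with `chrom`, `pos` (1-based), `strand`,
#'   `context` (`CG`, `CHG`, `CHH`), `meth_reads`, `total_reads`.
#' @param loci data frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_coverage minimum total reads per cytosine (default 1).
#' @return data frame with `id`, `CG`, `CHG`, `CHH` (percentages).
#' @export
methylation_summary <- function(records, loci, min_coverage = 1L) {
  stopifnot(all(records$meth_reads <= records$total_reads),
            all(records$meth_reads >= 0))
  contexts <- c("CG", "CHG", "CHH")
  out <- data.frame(id = loci$id, CG = NA_real_, CHG = NA_real_,
                    CHH = NA_real_, stringsAsFactors = FALSE)
  rec <- records[records$total_reads >= min_coverage, , drop = FALSE]
  for (i in seq_len(nrow(loci))) {
    inside <- rec$chrom == loci$chrom[i] &
      rec$pos - 1L >= loci$start[i] & rec$pos - 1L < loci$end[i]
    for (ctx in contexts) {
      r <- rec[inside & rec$context == ctx, , drop = FALSE]
      if (nrow(r) == 0L) next
      out[[ctx]][i] <- 100 * sum(r$meth_reads) / sum(r$total_reads)
    }
  }
  out
}

#' siRNA abundance per locus and size class, as RPKM
#'
#' Reads per kb of locus per million mapped library reads:
#' `RPKM = count / (locus_len/1000) / (library_total/1e6)` where
#' `count` sums the multiplicities of reads of the class's length(s)
#' overlapping the locus by at least 1 bp.
#'
#' @param reads data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `length_nt` (defaults to `end - start` when missing)
#'   and `count` (defaults to 1).
#' @param loci data frame with `id`, `chrom`, `start`, `end`.
#' @param size_classes named list of read lengths per class
#'   (default `list("21_22" = c(21, 22), "24" = 24)`).
#' @param library_total total mapped reads in the library.
#' @return data frame with `id` and one RPKM column per size class.
#' @export
sirna_rpkm <- function(reads, loci,
                       size_classes = list("21_22" = c(21L, 22L),
                                           "24" = 24L),
                       library_total) {
  stopifnot(library_total > 0)
  if (is.null(reads$length_nt)) reads$length_nt <- reads$end - reads$start
  if (is.null(reads$count)) reads$count <- 1L
  if (any(loci$end <= loci$start)) stop("zero-length locus")
  out <- data.frame(id = loci$id, stringsAsFactors = FALSE)
  for (cls in names(size_classes)) out[[cls]] <- NA_real_
  for (i in seq_len(nrow(loci))) {
    ov <- reads$chrom == loci$chrom[i] &
      reads$start < loci$end[i] & reads$end > loci$start[i]
    kb <- (loci$end[i] - loci$start[i]) / 1000
    for (cls in names(size_classes)) {
      cnt <- sum(reads$count[ov & reads$length_nt %in% size_classes[[cls]]])
      out[[cls]][i] <- cnt / kb / (library_total / 1e6)
    }
  }
  out
}

#' Chromatin-compartment and gene-proximity context per element
#'
#' Each element is assigned the compartment containing its midpoint
#' (compartments must tile each chromosome); `gene_within_2kb` is true
#' when the boundary-to-boundary distance to the nearest gene is at
#' most `window` bp (overlap counts as 0). The summary tables report
#' per-age-class counts and percentages (one decimal, rounded half
#' up): per-compartment counts and total percentages, and per-class
#' gene-proximity / chromosome-arm percentages.
#'
#' @param elements data frame with `id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `age_class` (e.g. merged from
#'   [date_elements()]).
#' @param compartments data frame with `chrom`, `start`, `end`,
#'   `label` in `{"arm", "pericentromere", "centromere"}` (BED-style,
#'   0-based half-open, non-overlapping per chromosome).
#' @param genes gene data frame (`chrom`, `start`, `end`).
#' @param window gene-proximity window in bp (default 2000).
#' @return list of class `"genomic_context"`: `per_element` (with
#'   `compartment` and `gene_within_2kb`), `compartment_table`
#'   (counts by compartment x age class, plus `total_percent`), and
#'   `class_table` (per class: `% gene within 2kb`, `% in arms`).
#' @export
genomic_context <- function(elements, compartments, genes, window = 2000L) {
  mid <- (elements$start + elements$end) %/% 2L
  comp <- vapply(seq_len(nrow(elements)), function(i) {
    hit <- compartments$chrom == elements$chrom[i] &
      compartments$start <= mid[i] & mid[i] < compartments$end
    if (!any(hit)) NA_character_ else compartments$label[which(hit)[1L]]
  }, character(1))
  if (anyNA(comp)) {
    warning(sum(is.na(comp)), " element midpoint(s) outside all ",
            "compartments; labelled 'unassigned'")
    comp[is.na(comp)] <- "unassigned"
  }
  near_gene <- vapply(seq_len(nrow(elements)), function(i) {
    g <- genes[genes$chrom == elements$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(FALSE)
    any(interval_gap(elements$start[i], elements$end[i],
                     g$start, g$end) <= window)
  }, logical(1))
  per_element <- data.frame(id = elements$id, chrom = elements$chrom,
                            start = elements$start, end = elements$end,
                            age_class = elements$age_class,
                            compartment = comp,
                            gene_within_2kb = near_gene,
                            stringsAsFactors = FALSE)
  classes <- c("98-100", "95-98", "85-95")
  comps <- unique(c("arm", "pericentromere",
                    intersect(c("centromere", "unassigned"), comp)))
  compartment_table <- as.data.frame(
    t(vapply(comps, function(cp) {
      vapply(classes, function(cl) sum(comp == cp &
                                         per_element$age_class == cl),
             numeric(1))
    }, numeric(length(classes)))))
  names(compartment_table) <- classes
  compartment_table$total <- rowSums(compartment_table)
  compartment_table$total_percent <-
    round_half_up(100 * compartment_table$total / nrow(per_element), 1)
  class_table <- data.frame(
    age_class = classes,
    n = vapply(classes, function(cl)
      sum(per_element$age_class == cl), numeric(1)),
    gene_within_2kb_percent = vapply(classes, function(cl) {
      n <- sum(per_element$age_class == cl)
      if (n == 0) return(NA_real_)
      round_half_up(100 * sum(near_gene[per_element$age_class == cl]) / n, 1)
    }, numeric(1)),
    arm_percent = vapply(classes, function(cl) {
      n <- sum(per_element$age_class == cl)
      if (n == 0) return(NA_real_)
      round_half_up(100 * sum(comp[per_element$age_class == cl] == "arm") / n,
                    1)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(per_element = per_element,
                 compartment_table = compartment_table,
                 class_table = class_table),
            class = "genomic_context")
}

#' @export
print.genomic_context <- function(x, ...) {
  cat("Genomic context of", nrow(x$per_element), "elements\n")
  cat("Counts by compartment and LTR-identity class:\n")
  print(x$compartment_table)
  cat("Per-class summaries:\n")
  print(x$class_table, row.names = FALSE)
  invisible(x)
}

#' In-silico PCR over a set of target sequences
#'
#' A target is amplifiable when a forward-primer site (at most
#' `max_mismatch` mismatches, no indels) exists on the plus strand and
#' a reverse-primer site on the minus strand downstream of it, with a
#' product no longer than `max_product`. The mismatch budget applies
#' per primer by default; `budget = "total"` applies it to the summed
#' mismatches of the best-compatible site pair.
#'
#' @param target_seqs named character vector.
#' @param fwd_primer,rev_primer primer sequences (>= 15 nt); the
#'   reverse primer is given 5'->3' as ordered, i.e. it anneals to the
#'   plus strand via its reverse complement.
#' @param max_mismatch mismatch budget (default 3).
#' @param max_product maximum product length in bp (default 5000).
#' @param budget `"per_primer"` or `"total"`.
#' @return list with `amplifiable` (named logical) and `n_amplifiable`.
#' @export
insilico_pcr <- function(target_seqs, fwd_primer, rev_primer,
                         max_mismatch = 3L, max_product = 5000L,
                         budget = c("per_primer", "total")) {
  budget <- match.arg(budget)
  stopifnot(nchar(fwd_primer) >= 15L, nchar(rev_primer) >= 15L)
  rev_site <- revcomp(rev_primer)   # as read on the plus strand
  len_f <- nchar(fwd_primer); len_r <- nchar(rev_site)
  limit <- if (budget == "per_primer") max_mismatch else 2L * max_mismatch
  flag <- vapply(target_seqs, function(s) {
    fm <- .primer_mismatches(s, fwd_primer)
    rm_ <- .primer_mismatches(s, rev_site)
    if (length(fm) == 0L || length(rm_) == 0L) return(FALSE)
    fw <- which(fm <= if (budget == "per_primer") max_mismatch else limit)
    rv <- which(rm_ <= if (budget == "per_primer") max_mismatch else limit)
    for (i in fw) {
      ## admissible reverse-site starts: downstream, product within limit
      js <- rv[rv >= i + len_f & rv + len_r - i <= max_product]
      if (length(js) == 0L) next
      if (budget == "per_primer") return(TRUE)
      if (any(fm[i] + rm_[js] <= limit)) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(amplifiable = flag, n_amplifiable = sum(flag))
}

## Mismatch count of `primer` at every start of `s` (vector over
## offsets; positions beyond the end are dropped).
.primer_mismatches <- function(s, primer) {
  ns <- nchar(s); np <- nchar(primer)
  if (ns < np) return(integer(0))
  sc <- seq_chars(s); pc <- seq_chars(primer)
  n_off <- ns - np + 1L
  mm <- integer(n_off)
  for (k in seq_len(np))
    mm <- mm + (sc[k:(k + n_off - 1L)] != pc[k])
  mm
}

#' Read a per-cytosine methylation table
#'
#' TSV with columns `chrom`, `pos`, `strand`, `context`, `meth_reads`,
#' `total_reads` (the per-cytosine dialect of bisulfite callers).
#'
#' @param path TSV path (with header).
#' @return data frame as required by [methylation_summary()].
#' @export
read_cytosine_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$meth_reads > df$total_reads))
    stop("meth_reads > total_reads at line ",
         which(df$meth_reads > df$total_reads)[1L])
  df
}

#' Read small-RNA alignments from BED
#'
#' @param path BED file; read length is `end - start` unless a 7th
#'   numeric column supplies it; a `count` is taken from a numeric
#'   `score` column when present (else 1).
#' @return data frame as required by [sirna_rpkm()].
#' @export
read_srna_bed <- function(path) {
  df <- read_bed(path)
  df$length_nt <- df$end - df$start
  df$count <- if (!is.null(df$score) && is.numeric(df$score) &&
                  all(df$score > 0)) df$score else 1L
  df
}
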