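## GFF3 emission for annotations. Internal coordinates are 0-based
## half-open; GFF3 is 1-based inclusive, converted here and only here.

#' Write an LTR retrotransposon annotation as GFF3
#'
#' Emits one `LTR_retrotransposon` feature per element with
#' `long_terminal_repeat` children for both LTRs and
#' `target_site_duplication` children for both TSD copies (when a TSD
#' was found). Attributes carry `ltr_identity`, `tsd`, `pbs_trna` and
#' `quality`.
#'
#' @param annotation an `"ltr_annotation"` object (or a compatible
#'   element data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  el <- if (inherits(annotation, "ltr_annotation")) annotation$elements
        else annotation
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start0, end0, strand, attrs)
    paste(chrom, "riderscout", type, start0 + 1L, end0, ".", strand, ".",
          attrs, sep = "\t")
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    attrs <- sprintf(
      "ID=%s;ltr_identity=%.4f;tsd=%s;pbs_trna=%s;quality=%s",
      e$id, e$ltr_identity,
      if (nzchar(e$tsd_seq)) e$tsd_seq else ".",
      if (is.na(e$pbs_trna)) "." else e$pbs_trna,
      if (e$quality_pass) "PASS" else "FAIL")
    writeLines(fmt(e$chrom, "LTR_retrotransposon", e$start, e$end,
                   e$strand, attrs), con)
    writeLines(fmt(e$chrom, "long_terminal_repeat", e$ltr5_start, e$ltr5_end,
                   e$strand, sprintf("ID=%s_LTR5;Parent=%s", e$id, e$id)), con)
    writeLines(fmt(e$chrom, "long_terminal_repeat", e$ltr3_start, e$ltr3_end,
                   e$strand, sprintf("ID=%s_LTR3;Parent=%s", e$id, e$id)), con)
    if (e$tsd_len > 0L) {
      writeLines(fmt(e$chrom, "target_site_duplication",
                     e$start - e$tsd_len, e$start, e$strand,
                     sprintf("ID=%s_TSD5;Parent=%s", e$id, e$id)), con)
      writeLines(fmt(e$chrom, "target_site_duplication",
                     e$end, e$end + e$tsd_len, e$strand,
                     sprintf("ID=%s_TSD3;Parent=%s", e$id, e$id)), con)
    }
  }
  invisible(path)
}
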