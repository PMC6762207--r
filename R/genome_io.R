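## Genome input/output, random-locus sampling and assembly statistics.
## A genome is represented as a named character vector of uppercase
## sequences over {A,C,G,T,N}; names are the sequence ids.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on load and any character outside
#' `{A,C,G,T,N}` is mapped to `N` with a warning. Record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector; names are record ids (first
#'   whitespace-delimited token of the header), values the sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGTN characters mapped to N in record(s): ",
            paste(ids[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Sample random loci genome-wide
#'
#' Draws `n` sequences of the requested length, with locus `i` chosen
#' uniformly over all valid start positions in the genome (a chromosome
#' is picked with probability proportional to its number of valid
#' starts). When `strands[i]` is `"-"` the sampled sequence is
#' reverse-complemented, mirroring a background drawn in the annotated
#' strand direction of a foreground element set. Loci whose `N` fraction
#' exceeds `max_n_frac` are resampled (up to `max_attempts` per locus)
#' so that assembly gaps in draft genomes do not leak into backgrounds.
#'
#' @param genome named character vector of chromosome sequences.
#' @param n number of loci.
#' @param length locus length in bp.
#' @param strands character vector of `"+"`/`"-"` of length `n`
#'   (recycled if length 1).
#' @param seed integer seed; the draw is fully reproducible from it.
#' @param max_n_frac maximum tolerated fraction of `N` per locus.
#' @param max_attempts resampling budget per locus.
#' @return character vector of `n` sequences, each `length` bp.
#' @export
sample_random_loci <- function(genome, n, length, strands = "+", seed = NULL,
                               max_n_frac = 0.1, max_attempts = 1000L) {
  stopifnot(n >= 1, length >= 1)
  strands <- rep_len(strands, n)
  stopifnot(all(strands %in% c("+", "-")))
  valid <- nchar(genome) - length + 1L
  valid[valid < 0L] <- 0L
  if (sum(valid) == 0L)
    stop("no chromosome is long enough to hold a ", length, " bp locus")
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      for (att in seq_len(max_attempts)) {
        chrom <- sample.int(base::length(genome), 1L, prob = valid)
        start <- sample.int(valid[chrom], 1L)  # 1-based
        s <- substr(genome[[chrom]], start, start + length - 1L)
        n_frac <- sum(seq_chars(s) == "N") / length
        if (n_frac <= max_n_frac)
          return(if (strands[i] == "-") revcomp(s) else s)
      }
      stop("could not sample a locus with N fraction <= ", max_n_frac,
           " in ", max_attempts, " attempts")
    }, character(1))
  })
}

#' Assembly N50 in megabases
#'
#' Sorts the scaffold/chromosome lengths in decreasing order and returns
#' the first length at which the cumulative sum reaches at least half of
#' the assembly total, divided by 1e6:
#' `len.sorted[cumsum(len.sorted) >= sum(len.sorted) * 0.5][1] / 1e6`.
#'
#' @param lengths positive integer vector of sequence lengths in bp.
#' @return N50 in Mb.
#' @export
#' @examples
#' n50(c(8e6, 5e6, 4e6, 3e6))  # 5
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  stopifnot(is.numeric(lengths), all(lengths > 0))
  len.sorted <- sort(lengths, decreasing = TRUE)
  len.sorted[cumsum(len.sorted) >= sum(len.sorted) * 0.5][1] / 1000000
}

#' Read gene/region features from a GFF3 file
#'
#' Thin wrapper over [rtracklayer::import()] that returns a plain
#' data frame in the package's internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param feature_type optional character vector; keep only these
#'   feature types (e.g. `"gene"`).
#' @return data frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `type`, `id`.
#' @export
read_gff3 <- function(path, feature_type = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  out <- data.frame(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
    type = as.character(df$type),
    id = if ("ID" %in% names(df)) as.character(df$ID) else NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(feature_type)) out <- out[out$type %in% feature_type, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED file (first 3-6 columns)
#'
#' @param path BED file (0-based half-open, as BED always is).
#' @return data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  for (i in seq_len(min(ncol(df) - 3L, 3L))) names(df)[3L + i] <- extra[i]
  df
}
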