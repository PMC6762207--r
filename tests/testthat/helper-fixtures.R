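# Shared fixture builders. Everything is generated in code at test time.

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                 prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                          (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Mutate exactly k positions of s (distinct, substitutions), giving an
# exactly known p-distance.
mutate_exactly <- function(s, k, seed = 1) {
  withr::with_seed(seed, {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[sample.int(3, 1)]
    paste(ch, collapse = "")
  })
}

# Independent two-sided Fisher p oracle: direct enumeration over the
# hypergeometric support using log-factorials (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lchoose2 <- function(x, y) lgamma(x + 1) - lgamma(y + 1) - lgamma(x - y + 1)
  supp <- max(0, k - n):min(k, m)
  logp <- lchoose2(m, supp) + lchoose2(n, k - supp) - lchoose2(m + n, k)
  p <- exp(logp)
  min(1, sum(p[p <= exp(logp[supp == a]) * (1 + 1e-7)]))
}

# A synthetic outfmt-6-style hit table with known random composition.
random_hit_table <- function(n, query_len = 4867, seed = 1) {
  withr::with_seed(seed, {
    qs <- sample.int(query_len - 50L, n, replace = TRUE)
    len <- pmin(sample.int(query_len, n, replace = TRUE) + 20L,
                query_len - qs + 1L)
    minus <- runif(n) < 0.3
    ss <- sample.int(2e6L, n, replace = TRUE)
    data.frame(
      query_id = "ref", subject_id = paste0("scf", sample.int(40, n, TRUE)),
      pident = round(runif(n, 20, 100), 2), align_len = len,
      mismatches = sample.int(200, n, TRUE),
      gap_opens = sample.int(5, n, TRUE) - 1L,
      qstart = qs, qend = qs + len - 1L,
      sstart = ifelse(minus, ss + len - 1L, ss),
      send = ifelse(minus, ss, ss + len - 1L),
      evalue = 10^runif(n, -180, -5), bitscore = round(runif(n, 40, 9000), 1),
      strand = ifelse(minus, "-", "+"), species = NA_character_,
      stringsAsFactors = FALSE)
  })
}

# Build the 71-element compartment fixture mirroring the reference
# per-class counts: arms 5/6/3 and pericentromere 5/23/29 across the
# identity classes 98-100 / 95-98 / 85-95.
table1_fixture <- function() {
  classes <- c("98-100", "95-98", "85-95")
  arm_n <- c(5L, 6L, 3L); peri_n <- c(5L, 23L, 29L)
  rows <- list()
  arm_cursor <- 0L; peri_cursor <- 0L
  for (i in seq_along(classes)) {
    for (j in seq_len(arm_n[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        age_class = classes[i], start = 10000L + arm_cursor * 6000L)
      arm_cursor <- arm_cursor + 1L
    }
    for (j in seq_len(peri_n[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        age_class = classes[i], start = 1100000L + peri_cursor * 6000L)
      peri_cursor <- peri_cursor + 1L
    }
  }
  el <- do.call(rbind, rows)
  el$id <- sprintf("el%02d", seq_len(nrow(el)))
  el$chrom <- "chr1"
  el$end <- el$start + 4800L
  comps <- data.frame(chrom = "chr1",
                      start = c(0L, 1000000L, 2000000L, 2100000L),
                      end = c(1000000L, 2000000L, 2100000L, 3000000L),
                      label = c("arm", "pericentromere", "centromere",
                                "arm"))
  list(elements = el, compartments = comps)
}

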