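# Structural detector: repeat-pair discovery, TSD/motif/PBS calls,
# overlap resolution and the composed annotation pipeline, checked
# against planted truth from the synthetic-genome generator.

test_that("a single planted element is found with tight boundaries", {
  spec <- synth_spec(genome_len = 200000L, n_intact = 1L, n_solo_ltr = 0L,
                     n_truncated = 0L, ltr_len = 400L, internal_len = 5000L,
                     divergences = 0.02, seed = 31L)
  sim <- build_genome(spec)
  truth <- sim$truth
  pairs <- find_repeat_pairs(sim$genome[[1]], detector_params())
  expect_equal(nrow(pairs), 1L)
  expect_lte(abs(pairs$start5 - truth$start), 20L)
  expect_lte(abs(pairs$end3 - truth$end), 20L)
  expect_lt(abs(pairs$identity - truth$pair_identity), 0.01)
})

test_that("random sequence without planted repeats yields nothing", {
  s <- rand_seq(100000, seed = 32)
  expect_equal(nrow(find_repeat_pairs(s, detector_params())), 0L)
  # seed-level exhaustive check on the same fixture: no 20-mer recurs at
  # an admissible separation, so no >=100 bp repeat pair at >=80%
  # identity can exist (such a pair contains a shared 20-mer with
  # overwhelming probability)
  k <- 20L
  km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  dup <- km[duplicated(km)]
  if (length(dup)) {
    seps <- unlist(lapply(unique(dup), function(x) diff(which(km == x))))
    expect_true(all(seps < 3000 | seps > 30000))
  } else succeed()
})

test_that("pairs closer than the minimum LTR distance are rejected", {
  withr::with_seed(33, {
    bg1 <- rand_seq(6000); bg2 <- rand_seq(6000)
    ltr <- rand_seq(400)
    substr(ltr, 1, 2) <- "TG"; substr(ltr, 399, 400) <- "CA"
    near <- paste0(bg1, ltr, rand_seq(2600), ltr, bg2)   # d = 3000 < 4000
    far <- paste0(bg1, ltr, rand_seq(4100), ltr, bg2)    # d = 4500
  })
  expect_equal(nrow(find_repeat_pairs(near, detector_params())), 0L)
  expect_equal(nrow(find_repeat_pairs(far, detector_params())), 1L)
})

test_that("TSD detection returns the flanking duplication exactly", {
  withr::with_seed(34, {
    ltr <- rand_seq(400)
    substr(ltr, 1, 2) <- "TG"; substr(ltr, 399, 400) <- "CA"
    elem <- paste0(ltr, rand_seq(4100), ltr)
    bg1 <- rand_seq(3000); bg2 <- rand_seq(3000)
  })
  s <- paste0(bg1, "ACGTA", elem, "ACGTA", bg2)
  pr <- find_repeat_pairs(s, detector_params())
  expect_equal(nrow(pr), 1L)
  tsd <- detect_tsd(s, pr[1, ], detector_params())
  expect_identical(tsd$tsd_seq, "ACGTA")
  expect_equal(tsd$tsd_len, 5L)
  expect_equal(tsd$start, 3005L)
  expect_equal(tsd$end, 3005L + nchar(elem))
  # no flanking duplication >= 3 bp: the boundary neighbourhoods are
  # engineered to share no k-mer at all (C-homopolymer left, G right)
  withr::with_seed(35, {
    ltr_nd <- paste0("TG", strrep("C", 48), rand_seq(300), strrep("G", 48),
                     "CA")
    elem_nd <- paste0(ltr_nd, rand_seq(4100), ltr_nd)
    s2 <- paste0(rand_seq(2900), strrep("C", 60), elem_nd,
                 strrep("G", 60), rand_seq(2900))
  })
  pr2 <- find_repeat_pairs(s2, detector_params())
  tsd2 <- detect_tsd(s2, pr2[1, ], detector_params())
  expect_identical(tsd2$tsd_seq, "")
  expect_equal(tsd2$tsd_len, 0L)
  # when duplications of length 4 and 9 both flank the element, the
  # 9-bp one wins
  s3 <- paste0(bg1, "GGCCATTAC", elem, "GGCCATTAC", bg2)
  pr3 <- find_repeat_pairs(s3, detector_params())
  tsd3 <- detect_tsd(s3, pr3[1, ], detector_params())
  expect_identical(tsd3$tsd_seq, "GGCCATTAC")
})

test_that("terminal motif counting sums mismatches over both termini", {
  p <- detector_params()
  s1 <- paste0("TG", strrep("A", 96), "CA")
  expect_true(check_terminal_motif(s1, 0L, 100L, p))
  s2 <- paste0("TG", strrep("A", 96), "CT")
  expect_true(check_terminal_motif(s2, 0L, 100L, p))   # 1 mismatch
  s3 <- paste0("AA", strrep("A", 96), "CA")
  expect_false(check_terminal_motif(s3, 0L, 100L, p))  # 2 mismatches
  s4 <- paste0("AG", strrep("A", 96), "CA")
  expect_true(check_terminal_motif(s4, 0L, 100L, p))   # 1 mismatch
})

test_that("PBS screening enforces offset, length and identity bounds", {
  p <- detector_params()
  trnas <- default_trnas(35L)
  probe18 <- revcomp(substr(trnas[[1]], 59, 76))
  withr::with_seed(36, {
    win_hit <- paste0("GT", probe18, rand_seq(60))       # offset 2
    win_far <- paste0(rand_seq(15), probe18, rand_seq(45))  # offset 15 > 10
    win_none <- rand_seq(60)
  })
  hit <- detect_pbs(paste0(strrep("T", 10), win_hit), 10L, trnas, p)
  expect_false(is.null(hit))
  expect_equal(hit$offset, 2L)
  expect_equal(hit$align_len, 18L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$trna_id, names(trnas)[1])
  expect_null(detect_pbs(paste0(strrep("T", 10), win_far), 10L, trnas, p))
  expect_null(detect_pbs(paste0(strrep("T", 10), win_none), 10L, trnas, p))
})

test_that("overlap resolution keeps the best element per conflict set", {
  mk <- function(start, end, id) data.frame(start = start, end = end,
                                            ltr_identity = id)
  two <- rbind(mk(0, 100, 0.9), mk(200, 300, 0.8))
  expect_equal(nrow(resolve_overlaps(two, "no")), 2L)
  ov <- rbind(mk(0, 100, 0.98), mk(50, 150, 0.91))
  kept <- resolve_overlaps(ov, "no")
  expect_equal(kept$ltr_identity, 0.98)
  # chain A-B, B-C overlapping, A and C disjoint: B (0.95) beats both
  chain <- rbind(mk(0, 100, 0.90), mk(80, 180, 0.95), mk(160, 260, 0.92))
  kept <- resolve_overlaps(chain, "no")
  expect_equal(kept$ltr_identity, 0.95)
  expect_equal(nrow(resolve_overlaps(chain, "all")), 3L)
})

test_that("the composed pipeline reports intact elements only", {
  spec <- synth_spec(genome_len = 200000L, n_intact = 12L, n_solo_ltr = 3L,
                     n_truncated = 2L,
                     divergences = c(0.01, 0.03, 0.05, 0.08, 0.1, 0.12),
                     seed = 37L)
  sim <- build_genome(spec)
  ann <- annotate_genome(sim$genome, sim$spec$trnas)
  el <- ann$elements[ann$elements$quality_pass, ]
  truth <- sim$truth
  intact <- truth[truth$kind == "intact", ]
  other <- truth[truth$kind != "intact", ]
  matched <- vapply(seq_len(nrow(intact)), function(i)
    any(el$start < intact$end[i] & el$end > intact$start[i]),
    logical(1))
  expect_gte(sum(matched), 11L)
  # nothing reported over solo LTRs or truncated copies
  false_hit <- vapply(seq_len(nrow(el)), function(j)
    any(other$start < el$end[j] & other$end > el$start[j]), logical(1))
  expect_equal(sum(false_hit), 0L)
  # strands recovered from the PBS orientation
  for (i in which(matched)) {
    j <- which(el$start < intact$end[i] & el$end > intact$start[i])[1]
    expect_identical(el$strand[j], intact$strand[i])
  }
  # every reported element satisfies the detector constraints
  p <- ann$params
  l5 <- el$ltr5_end - el$ltr5_start
  l3 <- el$ltr3_end - el$ltr3_start
  d <- el$ltr3_start - el$ltr5_start
  expect_true(all(l5 >= p$min_ltr_len & l5 <= p$max_ltr_len))
  expect_true(all(l3 >= p$min_ltr_len & l3 <= p$max_ltr_len))
  expect_true(all(d >= p$min_ltr_dist & d <= p$max_ltr_dist))
  expect_true(all(el$ltr_identity >= p$min_pair_identity))
  expect_true(all(el$tsd_len == 0 |
                    (el$tsd_len >= p$min_tsd & el$tsd_len <= p$max_tsd)))
})

test_that("annotation is strand-symmetric under genome reversal", {
  spec <- synth_spec(genome_len = 60000L, n_intact = 2L, n_solo_ltr = 0L,
                     n_truncated = 0L, divergences = c(0.02, 0.06),
                     seed = 38L)
  sim <- build_genome(spec)
  g <- sim$genome
  grc <- setNames(revcomp(g), names(g))
  a1 <- annotate_genome(g, sim$spec$trnas)$elements
  a2 <- annotate_genome(grc, sim$spec$trnas)$elements
  expect_equal(nrow(a1), nrow(a2))
  L <- nchar(g)
  a2m <- a2[order(L - a2$end), ]
  a1 <- a1[order(a1$start), ]
  expect_equal(a1$start, L - a2m$end)
  expect_equal(a1$end, L - a2m$start)
  expect_equal(a1$ltr_identity, a2m$ltr_identity, tolerance = 1e-12)
  expect_identical(a1$strand, chartr("+-", "-+", a2m$strand))
})

test_that("loosening the identity threshold never removes elements", {
  spec <- synth_spec(genome_len = 80000L, n_intact = 3L, n_solo_ltr = 0L,
                     n_truncated = 0L, divergences = c(0.02, 0.1, 0.18),
                     seed = 39L)
  sim <- build_genome(spec)
  strict <- annotate_genome(sim$genome, sim$spec$trnas,
                            detector_params(min_pair_identity = 0.9))
  loose <- annotate_genome(sim$genome, sim$spec$trnas,
                           detector_params(min_pair_identity = 0.8))
  expect_true(all(strict$elements$start %in% loose$elements$start))
  expect_gte(nrow(loose$elements), nrow(strict$elements))
})

test_that("empty input yields an empty annotation and a bare GFF3 header", {
  g <- c(chr1 = rand_seq(5000, seed = 40))
  ann <- annotate_genome(g, default_trnas(1L))
  expect_equal(nrow(ann$elements), 0L)
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, out)
  expect_identical(readLines(out), "##gff-version 3")
})

test_that("GFF3 output is 1-based with LTR and TSD children", {
  sim <- build_genome(synth_spec(seed = 41L, n_intact = 1L, n_solo_ltr = 0L,
                                 n_truncated = 0L, divergences = 0.02))
  ann <- annotate_genome(sim$genome, sim$spec$trnas)
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, out)
  lines <- readLines(out)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[-1], "\t")
  types <- vapply(fields, `[`, "", 3)
  expect_equal(sum(types == "LTR_retrotransposon"), 1L)
  expect_equal(sum(types == "long_terminal_repeat"), 2L)
  expect_equal(sum(types == "target_site_duplication"), 2L)
  main <- fields[[which(types == "LTR_retrotransposon")]]
  expect_equal(as.integer(main[4]), ann$elements$start + 1L)
  expect_equal(as.integer(main[5]), ann$elements$end)
  # re-import through the GFF3 reader round-trips the coordinates
  back <- read_gff3(out, feature_type = "LTR_retrotransposon")
  expect_equal(back$start, ann$elements$start)
  expect_equal(back$end, ann$elements$end)
})

test_that("ORF counting finds long frames in either strand", {
  withr::with_seed(42, {
    orf_start <- 151
    no_orf <- gsub("ATG", "ATT", rand_seq(2000))
    elem <- paste0(substr(no_orf, 1, 150),
                   riderscout:::make_orf(600),
                   substr(no_orf, 800, 2000))
  })
  expect_gte(count_orfs(elem), 1L)
  expect_gte(count_orfs(revcomp(elem)), 1L)
  expect_equal(count_orfs(strrep("TAA", 200)), 0L)
})
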