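test_that("global identity handles matches, mismatches and strands", {
  s <- rand_seq(200, seed = 1)
  expect_equal(global_identity(s, s)$identity, 1.0)
  expect_equal(global_identity("ACGT", "ACGA")$identity, 0.75)
  gi <- global_identity(s, revcomp(s), "both")
  expect_equal(gi$identity, 1.0)
  expect_equal(gi$strand, "-")
  # a short overhang dilutes identity only mildly, never inflates it
  ov <- global_identity(paste0("TTTTTTTTTT", s), s)$identity
  expect_gte(ov, 0.95)
  expect_lte(ov, 1.0)
  # unrelated sequences stay far below the family threshold
  expect_lt(global_identity(s, rand_seq(200, seed = 77), "both")$identity,
            0.7)
})

test_that("greedy clustering groups near-identical copies and splits strangers", {
  base <- rand_seq(1000, seed = 2)
  seqs <- c(a = mutate_exactly(base, 5, seed = 3),
            b = mutate_exactly(base, 8, seed = 4),
            c = mutate_exactly(base, 6, seed = 5),
            u = rand_seq(1000, seed = 6))
  cl <- cluster_greedy(seqs, threshold = 0.85)
  sizes <- sort(table(cl$centroid_id), decreasing = TRUE)
  expect_equal(as.integer(sizes), c(3L, 1L))
  # post hoc: every member is within threshold of its centroid
  for (i in seq_len(nrow(cl))) {
    gi <- global_identity(seqs[[cl$centroid_id[i]]], seqs[[cl$member_id[i]]],
                          "both")
    expect_gte(gi$identity, 0.85)
  }
  # mutually dissimilar sequences give singleton clusters
  alone <- c(x = rand_seq(500, seed = 7), y = rand_seq(500, seed = 8),
             z = rand_seq(500, seed = 9))
  cla <- cluster_greedy(alone)
  expect_equal(nrow(cla), 3L)
  expect_identical(cla$centroid_id, cla$member_id)
  # reverse-complement member joins on the minus strand
  rc <- c(a = base, b = revcomp(base))
  clrc <- cluster_greedy(rc, threshold = 0.85)
  expect_equal(clrc$strand[clrc$member_id == "b"], "-")
  expect_equal(length(unique(clrc$centroid_id)), 1L)
  expect_error(cluster_greedy(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("greedy clustering equals an independent re-implementation", {
  withr::with_seed(10, {
    base1 <- rand_seq(400); base2 <- rand_seq(420)
    seqs <- c(m1 = mutate_exactly(base1, 10, 1), m2 = mutate_exactly(base1, 30, 2),
              m3 = mutate_exactly(base2, 5, 3), m4 = mutate_exactly(base2, 50, 4),
              m5 = rand_seq(380), m6 = mutate_exactly(base1, 20, 5))
  })
  got <- cluster_greedy(seqs, threshold = 0.9)
  # independent greedy over the same rule, written from scratch
  ord <- order(-nchar(seqs))
  cent <- character(0); assign <- character(length(seqs)); names(assign) <- names(seqs)
  for (i in ord) {
    hit <- NA_character_
    for (cid in cent) {
      if (global_identity(seqs[[cid]], seqs[[i]], "both")$identity >= 0.9) {
        hit <- cid; break
      }
    }
    if (is.na(hit)) { cent <- c(cent, names(seqs)[i]); hit <- names(seqs)[i] }
    assign[names(seqs)[i]] <- hit
  }
  expect_identical(setNames(got$centroid_id, got$member_id)[names(seqs)],
                   assign)
})

test_that("family assignment is strict-greater-than the identity threshold", {
  ref <- rand_seq(1000, seed = 11)
  fam <- sapply(1:10, function(i)
    mutate_exactly(ref, sample(20:100, 1), seed = 100 + i))
  names(fam) <- paste0("fam", 1:10)
  other <- setNames(sapply(1:5, function(i) rand_seq(1000, seed = 200 + i)),
                    paste0("other", 1:5))
  got <- assign_family(c(fam, other), ref, threshold = 0.85)
  expect_setequal(got$id, names(fam))
  # exactly 85.0%: excluded by the strict rule
  edge <- c(edge = mutate_exactly(ref, 150, seed = 12))
  expect_equal(global_identity(ref, edge[[1]])$identity, 0.85)
  expect_equal(nrow(assign_family(edge, ref, 0.85)), 0L)
  # the reference itself is a member at identity 1
  expect_equal(assign_family(c(self = ref), ref)$identity, 1.0)
})

test_that("LTR divergence dating follows the molecular clock", {
  l <- rand_seq(400, seed = 13)
  est0 <- date_element(l, l)
  expect_equal(est0$age_years, 0)
  expect_equal(est0$age_class, "98-100")
  # identity 0.98 exactly: the young-class boundary at 1.4 My
  est98 <- date_element(l, mutate_exactly(l, 8, seed = 14))
  expect_equal(est98$ltr_identity, 0.98)
  expect_equal(round(est98$age_my, 1), 1.4)
  # identity 0.95 exactly: 3.59 My
  est95 <- date_element(l, mutate_exactly(l, 20, seed = 15))
  expect_equal(est95$ltr_identity, 0.95)
  expect_equal(round(est95$age_my, 2), 3.59)
  expect_equal(est95$age_my, 0.05 / (2 * 6.96e-9) / 1e6)
  expect_equal(est95$age_class, "95-98")
  # dating is strictly decreasing in identity
  ages <- sapply(c(0, 4, 8, 20, 40, 58), function(k)
    date_element(l, mutate_exactly(l, k, seed = 16))$age_my)
  expect_true(all(diff(ages) > 0))
  # JC correction exceeds the p-distance age for diverged pairs
  expect_gt(date_element(l, mutate_exactly(l, 40, seed = 17),
                         correction = "JC")$age_my,
            date_element(l, mutate_exactly(l, 40, seed = 17))$age_my)
})

test_that("age classes partition [0.85, 1] exhaustively and exclusively", {
  ids <- seq(0.85, 1, by = 0.001)
  cls <- age_class(ids)
  expect_false(anyNA(cls))
  expect_identical(age_class(c(0.98, 0.95, 0.85)),
                   c("98-100", "95-98", "85-95"))
  expect_identical(age_class(c(0.9799, 0.9499, 0.8499)),
                   c("95-98", "85-95", NA))
})

test_that("TN93 distance matches ape and its closed form", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)
  withr::with_seed(18, {
    for (i in 1:6) {
      a <- rand_seq(800, gc = runif(1, 0.3, 0.6))
      b <- mutate_seq(a, runif(1, 0.02, 0.2))
      m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
      oracle <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93"))
      expect_equal(tn93_distance(a, b), oracle, tolerance = 1e-9)
    }
  })
  # transversion-only change at equal base frequencies: d = -log(1-Q)/2
  a <- strrep("ACGT", 100)
  ch <- strsplit(a, "")[[1]]
  idx <- 1:40  # 40 transversions A<->T / C<->G, preserving base counts
  ch[idx] <- chartr("ACGT", "TGCA", ch[idx])
  b <- paste(ch, collapse = "")
  Q <- length(idx) / 400
  expect_equal(tn93_distance(a, b),
               -0.5 * log(1 - Q) - 0.25 * log(1 - 2 * Q),
               tolerance = 1e-12)
  # saturation returns Inf with a flag
  sat <- chartr("ACGT", "TGCA", a)
  d <- tn93_distance(a, sat)
  expect_true(is.infinite(d))
  expect_true(isTRUE(attr(d, "saturated")))
  expect_error(tn93_distance("ACGT", "ACG"), "equal length")
})

test_that("neighbour joining recovers closed forms and additive trees", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nw <- nj_tree(d3)
  P <- patristic_distances(nw)
  expect_equal(P["A", "B"], 2, tolerance = 1e-9)
  expect_equal(P["A", "C"], 4, tolerance = 1e-9)
  expect_equal(P["B", "C"], 4, tolerance = 1e-9)
  # 4-taxon additive matrix: topology and branch lengths recovered
  # tree ((A:1,B:2):1,(C:3,D:4)) as pairwise path lengths
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  P4 <- patristic_distances(nj_tree(d4))
  expect_equal(max(abs(P4[LETTERS[1:4], LETTERS[1:4]] - d4)), 0,
               tolerance = 1e-9)
  # equidistant taxa: patristic distances reproduce the input
  de <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(de) <- 0
  Pe <- patristic_distances(nj_tree(de))
  expect_equal(max(abs(Pe[letters[1:5], letters[1:5]] - de)), 0,
               tolerance = 1e-9)
  bad <- d3; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
})

test_that("nj + patristic is the identity on random additive matrices", {
  withr::with_seed(19, {
    for (n in c(5, 8, 12)) {
      tr <- ape::rtree(n)
      D <- ape::cophenetic.phylo(tr)
      D <- D[order(rownames(D)), order(colnames(D))]
      P <- patristic_distances(nj_tree(D))
      expect_lt(max(abs(P - D)), 1e-9)
    }
  })
})

test_that("patristic distances are path sums and reject bad input", {
  P <- patristic_distances("(A:1,B:1,C:3);")
  expect_equal(P["A", "B"], 2)
  expect_equal(P["A", "C"], 4)
  expect_equal(unname(diag(P)), c(0, 0, 0))
  expect_equal(unname(patristic_distances("(A:0,B:0);")["A", "B"]), 0)
  expect_error(patristic_distances("(A:1,B:1"), "malformed|Newick")
})

test_that("dated elements from an annotation match planted divergences", {
  sim <- build_genome(synth_spec(seed = 21L, n_intact = 3L, n_solo_ltr = 0L,
                                 n_truncated = 0L,
                                 divergences = c(0.01, 0.05, 0.12)))
  ann <- annotate_genome(sim$genome, sim$spec$trnas)
  dt <- date_elements(ann, sim$genome)
  truth <- sim$truth[sim$truth$kind == "intact", ]
  expect_equal(nrow(dt), 3L)
  dt <- dt[order(dt$start), ]; truth <- truth[order(truth$start), ]
  expect_equal(dt$ltr_identity, truth$pair_identity, tolerance = 0.01)
  expect_identical(dt$age_class, age_class(truth$pair_identity))
})
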