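test_that("membership rule handles mismatch and overhang boundaries", {
  set.seed(8)
  centre <- random_seq(24)
  # member 21 nt fully inside: 3-nt total overhang, 3 mismatches allowed
  member <- mutate_at(substr(centre, 2, 22), c(3, 9, 15))
  expect_true(matches_centre(member, centre))
  # a fourth mismatch breaks it (any shift adds overhang beyond budget)
  member4 <- mutate_at(substr(centre, 2, 22), c(3, 9, 15, 18))
  expect_false(matches_centre(member4, centre, max_mismatch = 3))
  # equal length at Hamming distance 4 -> distinct
  s1 <- random_seq(30)
  s2 <- mutate_at(s1, c(2, 10, 18, 26))
  expect_false(matches_centre(s2, s1))
  expect_true(matches_centre(mutate_at(s1, c(2, 10, 18)), s1))
})

test_that("identical sequences collapse to one cluster with summed cardinality", {
  m <- matrix(c(2, 3), 1, 2,
              dimnames = list("ACGTACGTACGTACGTACGTACGT", c("s1", "s2")))
  cs <- greedy_cluster(m)
  expect_equal(length(cs$centres), 1)
  expect_equal(unname(cs$cardinality[1, ]), c(2, 3))
})

test_that("greedy partition matches the brute-force oracle over 20 seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    n_seq <- sample(20:50, 1)
    # families of variants around a few base sequences plus singletons
    base <- replicate(5, random_seq(sample(20:30, 1)))
    seqs <- character(0)
    while (length(seqs) < n_seq) {
      b <- sample(base, 1)
      v <- if (runif(1) < 0.7) {
        nm <- sample(0:4, 1)
        s <- if (nm > 0) mutate_at(b, sample(nchar(b), nm)) else b
        # sometimes trim an end (overhang)
        if (runif(1) < 0.3) s <- substr(s, 1, nchar(s) - sample(1:4, 1))
        s
      } else random_seq(sample(18:30, 1))
      seqs <- unique(c(seqs, v))
    }
    counts <- matrix(rpois(length(seqs) * 2, 5) + 1, ncol = 2,
                     dimnames = list(seqs, c("s1", "s2")))
    got <- greedy_cluster(counts)
    want <- oracle_greedy(counts)
    expect_equal(got$membership[names(want)], want)
  }
})

test_that("cluster partition is invariant to input record order", {
  set.seed(33)
  base <- random_seq(25)
  seqs <- unique(c(base, replicate(15, mutate_at(base, sample(25, sample(1:5, 1)))),
                   replicate(5, random_seq(22))))
  counts <- matrix(rpois(length(seqs) * 3, 4) + 1, ncol = 3,
                   dimnames = list(seqs, paste0("s", 1:3)))
  a <- greedy_cluster(counts)
  perm <- sample(nrow(counts))
  b <- greedy_cluster(counts[perm, ])
  expect_equal(a$membership[seqs], b$membership[seqs])
  expect_equal(a$centres, b$centres)
})

test_that("cluster cardinalities conserve per-sample clustered totals", {
  set.seed(12)
  seqs <- unique(replicate(20, random_seq(sample(20:26, 1))))
  counts <- matrix(rpois(length(seqs) * 4, 6), ncol = 4,
                   dimnames = list(seqs, paste0("s", 1:4)))
  cs <- greedy_cluster(counts)
  cct <- cluster_count_table(cs)
  expect_equal(colSums(cct$counts$counts), colSums(counts))
  expect_equal(dim(cct$correlation), c(4, 4))
  one <- greedy_cluster(counts[, 1, drop = FALSE])
  expect_warning(r1 <- cluster_count_table(one), "single sample")
  expect_equal(dim(r1$correlation), c(0, 0))
})

test_that("cluster counts are more stable across samples than raw sequence counts", {
  # shared backbone expressed as sample-specific variants plus private noise:
  # per-sequence counts decorrelate, cluster cardinalities re-converge
  set.seed(77)
  backbone <- replicate(12, random_seq(26))
  expr <- rpois(12, 60) + 20
  n_samp <- 4
  tabs <- list()
  for (s in seq_len(n_samp)) {
    seqs <- vapply(backbone, function(b) mutate_at(b, sample(26, 2)),
                   character(1))   # sample-private variant of each backbone
    private <- replicate(6, random_seq(24))
    counts <- c(rpois(12, expr), rpois(6, 3) + 1)
    tabs[[s]] <- setNames(counts, c(seqs, private))
  }
  all_seqs <- unique(unlist(lapply(tabs, names)))
  m <- vapply(tabs, function(tb) {
    v <- tb[all_seqs]; v[is.na(v)] <- 0; unname(v)
  }, numeric(length(all_seqs)))
  rownames(m) <- all_seqs
  colnames(m) <- paste0("s", seq_len(n_samp))
  raw_cor <- cor(m, method = "spearman")
  cct <- cluster_count_table(greedy_cluster(m))
  mean_off <- function(x) mean(x[upper.tri(x)])
  expect_gte(mean_off(cct$correlation), mean_off(raw_cor))
})

test_that("TMM factors are 1 for identical or proportional columns", {
  y <- matrix(rep(c(5, 10, 20, 40, 80), 3), ncol = 3,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:3)))
  f <- tmm_factors(count_table(y))
  expect_equal(unname(f$factors), rep(1, 3), tolerance = 1e-12)
  y2 <- cbind(s1 = y[, 1], s2 = 2 * y[, 1])
  f2 <- tmm_factors(count_table(y2))
  expect_equal(unname(f2$factors), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the straight-line oracle and is scale invariant", {
  set.seed(101)
  y <- matrix(rpois(20 * 4, 200), 20, 4,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:4)))
  y[1:4, 2] <- y[1:4, 2] * 8  # perturb 4 features 8-fold in one sample
  ct <- count_table(y)
  got <- tmm_factors(ct)
  want <- oracle_tmm(y, colSums(y))
  expect_equal(got$factors, want, tolerance = 1e-9)
  expect_equal(exp(mean(log(got$factors))), 1, tolerance = 1e-9)

  # multiplying any single column by a positive constant leaves M and A
  # unchanged; only the inverse-variance weights shift, so invariance holds
  # to well under 1%
  y3 <- y; y3[, 3] <- y3[, 3] * 7
  got3 <- tmm_factors(count_table(y3))
  expect_equal(got3$factors, got$factors, tolerance = 1e-2)
})

test_that("apply_factors rescales to mean effective library size", {
  y <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  ct <- count_table(y)
  nf <- structure(list(factors = c(s1 = 1, s2 = 1),
                       reference_sample = "s1",
                       effective_lib_sizes = c(s1 = 60, s2 = 60)),
                  class = "norm_factors")
  out <- apply_factors(ct, nf)
  expect_equal(out$counts, y)
  # doubling one sample's factor halves its normalized values (up to the
  # common mean-effective-library rescaling)
  nf2 <- nf; nf2$factors["s2"] <- 2
  out2 <- apply_factors(ct, nf2)
  ratio <- out2$counts[, "s2"] / out$counts[, "s2"]
  expect_equal(unname(ratio / ratio[1]), rep(1, 3))
  expect_lt(ratio[1], 1)
  nf3 <- nf; names(nf3$factors) <- c("s1", "sX")
  expect_error(apply_factors(ct, nf3), "s2")
})

test_that("normalization recovers unperturbed ratios on a spiked fixture", {
  set.seed(202)
  mu <- rpois(20, 200) + 50
  y <- cbind(case = rpois(20, mu), ctrl = rpois(20, mu))
  rownames(y) <- paste0("f", 1:20)
  y[1:4, "case"] <- y[1:4, "case"] * 8
  ct <- count_table(y)
  nf <- tmm_factors(ct)
  norm <- apply_factors(ct, nf)
  ratios <- norm$counts[5:20, "case"] / norm$counts[5:20, "ctrl"]
  expect_true(all(abs(ratios - 1) < 0.35))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
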