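test_that("pseudocount fold change reproduces reporting conventions", {
  expect_equal(round_half_up(log2fc_pseudo(27.1, 79.7), 2), -1.52)
  expect_equal(round_half_up(log2fc_pseudo(7.9, 0.0), 2), 3.15)
  expect_equal(log2fc_pseudo(13.7, 13.7), 0)
  expect_equal(log2fc_pseudo(0, 0), 0)
  # antisymmetry
  set.seed(4)
  a <- runif(50, 0, 1000); b <- runif(50, 0, 1000)
  expect_equal(log2fc_pseudo(a, b), -log2fc_pseudo(b, a))
  # monotone in the case count
  expect_true(all(diff(log2fc_pseudo(seq(0, 100, 5), 30)) > 0))
  expect_error(log2fc_pseudo(-1, 3), "non-negative")
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5), 3)
})

test_that("Fisher test matches hand-checked tables", {
  expect_equal(fisher_count_test(5, 100, 5, 100), 1.0)
  expect_equal(fisher_count_test(0, 10, 10, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # fractional normalized counts are rounded half-up before testing
  expect_equal(fisher_count_test(4.5, 10, 10, 10),
               fisher_count_test(5, 10, 10, 10))
  expect_error(fisher_count_test(5, 0, 1, 10), "library")
  expect_error(fisher_count_test(11, 10, 1, 10), "exceed")
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  # spot-check a grid here; the exhaustive <= 60 sweep runs in the
  # acceptance suite
  for (n1 in c(8, 15)) for (n2 in c(8, 13)) {
    for (a in seq(0, n1, 3)) for (c_ in seq(0, n2, 4)) {
      expect_equal(
        fisher_count_test(a, n1, c_, n2),
        oracle_fisher(a, n1 - a, c_, n2 - c_),
        tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

make_norm_table <- function(counts, lib = NULL, class = NULL) {
  meta <- if (!is.null(class))
    data.frame(class = class, row.names = rownames(counts),
               stringsAsFactors = FALSE)
  count_table(counts, lib_sizes = lib, feature_meta = meta)
}

test_that("per-sample DE pools controls and flags spiked features", {
  set.seed(10)
  mu <- rep(100, 30)
  y <- cbind(case = rpois(30, mu * c(rep(8, 5), rep(1, 25))),
             c1 = rpois(30, mu), c2 = rpois(30, mu), c3 = rpois(30, mu))
  rownames(y) <- paste0("f", 1:30)
  ct <- make_norm_table(y, lib = setNames(rep(5000, 4), colnames(y)))
  rec <- per_sample_de(ct, "case", c("c1", "c2", "c3"))
  expect_true(all(rec$significant[1:5]))
  expect_equal(rec$group_b_value, unname(rowMeans(y[, 2:4])))
  expect_true(mean(rec$significant[6:30]) <= 0.1)

  # degenerate inputs
  y0 <- rbind(y, zero = 0)
  ct0 <- make_norm_table(y0, lib = setNames(rep(5000, 4), colnames(y0)))
  rec0 <- per_sample_de(ct0, "case", c("c1", "c2", "c3"))
  z <- rec0[rec0$feature == "zero", ]
  expect_equal(z$log2fc, 0)
  expect_equal(z$p_value, 1)
  expect_false(z$significant)
  expect_equal(z$presence, "absent")

  same <- make_norm_table(cbind(a = y[, 2], b = y[, 2], c = y[, 2]),
                          lib = c(a = 5000, b = 5000, c = 5000))
  rec_same <- per_sample_de(same, "a", c("b", "c"))
  expect_equal(sum(rec_same$significant), 0)
  expect_error(per_sample_de(ct, "case", c("case", "c1")), "control pool")
  expect_error(per_sample_de(ct, "nope", "c1"), "unknown sample")
})

test_that("sibling comparison is antisymmetric and summarised per class", {
  set.seed(11)
  y <- cbind(asd = c(rpois(10, 400), rpois(10, 50), 0, 30),
             ctrl = c(rpois(10, 50), rpois(10, 400), 25, 0))
  rownames(y) <- paste0("f", 1:22)
  cls <- rep(c("miRNA", "piRNA"), 11)
  ct <- make_norm_table(y, lib = c(asd = 5000, ctrl = 5000), class = cls)
  fwd <- sibling_compare(ct, "asd", "ctrl")
  rev <- sibling_compare(ct, "ctrl", "asd")
  expect_equal(fwd$records$log2fc, -rev$records$log2fc)
  swap <- c(common = "common", only_a = "only_b", only_b = "only_a",
            absent = "absent")
  expect_equal(unname(swap[fwd$records$presence]), rev$records$presence)
  expect_setequal(fwd$summary$class, c("miRNA", "piRNA"))
  expect_equal(sum(fwd$summary$only_asd), 1)
  expect_equal(sum(fwd$summary$only_ctrl), 1)
  expect_error(sibling_compare(ct, "asd", "asd"), "distinct")

  empty <- make_norm_table(matrix(numeric(0), 0, 2,
                                  dimnames = list(character(0), c("a", "b"))),
                           lib = c(a = 10, b = 10))
  res <- sibling_compare(empty, "a", "b")
  expect_equal(nrow(res$records), 0)
})

test_that("cross-couple intersection demands consistent significant sign", {
  r1 <- data.frame(feature = c("x", "y", "z"),
                   significant = c(TRUE, TRUE, TRUE),
                   log2fc = c(2, -2, 2))
  r2 <- data.frame(feature = c("x", "y", "z"),
                   significant = c(TRUE, TRUE, TRUE),
                   log2fc = c(1.5, -1.2, -3))
  out <- cross_couple_common(list(r1, r2))
  expect_equal(out$up, "x")
  expect_equal(out$down, "y")
  # disjoint significant sets
  r3 <- r2; r3$significant <- c(FALSE, FALSE, FALSE)
  out2 <- cross_couple_common(list(r1, r3))
  expect_equal(out2$up, character(0))
  expect_equal(out2$down, character(0))
  expect_error(cross_couple_common(list(r1)), ">= 2")
})

test_that("type-I error stays controlled on null simulations", {
  fp <- integer(0); n_tests <- integer(0)
  for (seed in 1:20) {
    # the Fisher null is binomial sampling, so the calibration check runs
    # at dispersion 0 (overdispersion robustness is the |lfc| gate's job)
    cfg <- sim_config(seed = seed, de_fraction = 0, dispersion = 0,
                      n_case = 1, n_ctrl = 6, libsize_fold_spread = 2)
    s <- simulate_two_group_counts(cfg, n_features = 100, base_mean = 60)
    ct <- s$counts
    rec <- per_sample_de(ct, "case_1", paste0("ctrl_", 1:6))
    fp <- c(fp, sum(rec$p_value < 0.05))
    n_tests <- c(n_tests, nrow(rec))
  }
  expect_lte(sum(fp) / sum(n_tests), 0.075)
})
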