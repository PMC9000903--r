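fixture_otu <- function() {
  counts <- matrix(c(10, 5, 20, 40, 30, 15), nrow = 3,
                   dimnames = list(c("o1", "o2", "o3"), c("s1", "s2")))
  tax <- data.frame(
    Kingdom = "Bacteria",
    Phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
    Class = "c", Order = "o",
    Family = c("Lachnospiraceae", "Lachnospiraceae", "Bacteroidaceae"),
    Genus = c("g1", "g2", "g3"), Species = "unassigned",
    row.names = c("o1", "o2", "o3"), stringsAsFactors = FALSE)
  otu_table_new(counts, tax, c(s1 = "case", s2 = "control"))
}

test_that("rank aggregation sums lineage groups and conserves totals", {
  ot <- fixture_otu()
  fam <- aggregate_rank(ot, "Family")
  expect_equal(sort(rownames(fam)), c("Bacteroidaceae", "Lachnospiraceae"))
  expect_equal(fam["Lachnospiraceae", ], c(s1 = 15, s2 = 70))
  expect_equal(fam["Bacteroidaceae", ], c(s1 = 20, s2 = 15))
  expect_equal(colSums(fam), colSums(ot$counts))
  expect_equal(nrow(aggregate_rank(ot, "Kingdom")), 1)
  expect_error(aggregate_rank(ot, "Tribe"), "unknown rank")
})

test_that("unassigned ranks pool under the deepest assigned ancestor", {
  ot <- fixture_otu()
  ot$taxonomy$Family[2] <- "unassigned"
  fam <- aggregate_rank(ot, "Family")
  expect_true("unassigned_o" %in% rownames(fam))
  expect_equal(unname(fam["unassigned_o", ]), c(5, 30))
  expect_equal(colSums(fam), colSums(ot$counts))
})

test_that("relative abundances sum to one and average by group", {
  counts <- matrix(c(25, 75, 40, 60), 2,
                   dimnames = list(c("t1", "t2"), c("s1", "s2")))
  ra <- relative_abundance(counts, groups = c(s1 = "case", s2 = "case"))
  expect_equal(unname(ra$fractions[, 1]), c(0.25, 0.75))
  expect_equal(colSums(ra$fractions), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  expect_equal(unname(ra$group_means[, "case"]), c((0.25 + 0.4) / 2,
                                                   (0.75 + 0.6) / 2))
  bad <- cbind(counts, s3 = c(0, 0))
  expect_error(relative_abundance(bad), "s3")
})

test_that("alpha diversity matches closed forms", {
  m <- matrix(c(5, 5, 5, 5, 1, 2, 3, 4, 9, 0, 0, 0), nrow = 4,
              dimnames = list(letters[1:4], c("uniform", "graded", "single")))
  d <- alpha_diversity(m)
  expect_equal(d$observed, c(4, 4, 1))
  expect_equal(d$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(d$simpson[1], 0.75, tolerance = 1e-12)
  p <- (1:4) / 10
  expect_equal(d$shannon[2], -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(d$simpson[2], 1 - sum(p^2), tolerance = 1e-12)
  expect_equal(d$shannon[3], 0)
  expect_equal(d$simpson[3], 0)
  expect_true(all(d$shannon <= log(d$observed) + 1e-12))
  # permutation invariance in taxa; uniform maximises for fixed richness
  expect_equal(alpha_diversity(m[c(3, 1, 4, 2), , drop = FALSE])$shannon,
               d$shannon)
  expect_gte(d$shannon[1], d$shannon[2])
  inv <- alpha_diversity(m, inverse_simpson = TRUE)
  expect_equal(inv$simpson[1], 4, tolerance = 1e-12)
})

test_that("taxon ratios average per sample within groups", {
  counts <- matrix(c(10, 20, 30, 20, 15, 10), nrow = 2, byrow = FALSE,
                   dimnames = list(c("Bacteroidetes", "Firmicutes"),
                                   c("s1", "s2", "s3")))
  tax <- data.frame(Kingdom = "Bacteria",
                    Phylum = c("Bacteroidetes", "Firmicutes"),
                    Class = "c", Order = "o", Family = "f", Genus = "g",
                    Species = "s",
                    row.names = rownames(counts), stringsAsFactors = FALSE)
  ot <- otu_table_new(counts, tax,
                      c(s1 = "case", s2 = "case", s3 = "control"))
  r <- taxon_ratio(ot, "Bacteroidetes", "Firmicutes", "Phylum")
  expect_equal(unname(r$per_sample), c(0.5, 1.5, 1.5))
  expect_equal(unname(r$group_ratio["case"]), 1.0)
  expect_error(taxon_ratio(ot, "Nonexistium", "Firmicutes"), "absent")

  # zero denominator excluded with a warning
  counts2 <- counts; counts2["Firmicutes", "s3"] <- 0
  ot2 <- otu_table_new(counts2, tax, ot$groups)
  expect_warning(r2 <- taxon_ratio(ot2, "Bacteroidetes", "Firmicutes"),
                 "s3")
  expect_equal(r2$excluded_samples, "s3")
})

test_that("prevalence partition splits families by group presence", {
  ot <- simulate_otu_table(
    40, 12, rep(c("case", "control"), each = 6),
    group_exclusive_families = list(control = "Akkermansiaceae",
                                    case = "Sutterellaceae"),
    seed = 9, depth = 20000)
  fam <- aggregate_rank(ot, "Family")
  part <- prevalence_partition(fam)
  expect_true("Akkermansiaceae" %in% part$control_only)
  expect_true("Sutterellaceae" %in% part$case_only)
  expect_true(length(part$both) > 0)

  # swapping group labels swaps case_only and control_only exactly
  swapped <- ifelse(ot$groups == "case", "control", "case")
  names(swapped) <- names(ot$groups)
  fam2 <- fam; attr(fam2, "groups") <- swapped
  part2 <- prevalence_partition(fam2)
  expect_equal(part2$case_only, part$control_only)
  expect_equal(part2$control_only, part$case_only)
  expect_equal(part2$both, part$both)

  # threshold arithmetic: present in 2 of 6 samples is not "mainly present"
  m <- matrix(c(rep(1000, 6), 50, 50, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("base", "rare"), paste0("s", 1:6)))
  g <- setNames(rep("control", 6), paste0("s", 1:6))
  g2 <- c(g, setNames("case", "s7"))
  m2 <- cbind(m, s7 = c(1000, 500))
  part3 <- prevalence_partition(m2, groups = g2)
  expect_false("rare" %in% part3$control_only)
  expect_true("rare" %in% part3$case_only)
  expect_error(prevalence_partition(m, groups = g), "zero samples")
})
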