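#' Differential-expression configuration
#'
#' Significance requires both |log2FC| >= `lfc_threshold` and
#' p < `alpha`; fold changes use a pseudocount, and p-values are adjusted by
#' Benjamini-Hochberg within each comparison.
#'
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param alpha p-value threshold (default 0.05).
#' @param pseudocount added to both counts before the log ratio (default 1).
#' @return list of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 1.0, alpha = 0.05, pseudocount = 1.0) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 pseudocount = pseudocount, fdr_method = "BH"),
            class = "de_config")
}

#' Pseudocount log2 fold change
#'
#' `log2((a + pseudocount) / (b + pseudocount))`. Values are returned at
#' full precision; [round_half_up()] reproduces the 2-decimal reporting
#' convention.
#'
#' @param a,b non-negative (normalized) counts; vectorized.
#' @param pseudocount positive offset (default 1).
#' @return numeric log2 fold change(s).
#' @export
log2fc_pseudo <- function(a, b, pseudocount = 1) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  log2((a + pseudocount) / (b + pseudocount))
}

#' Round half away from zero to a fixed number of decimals
#'
#' R's `round()` rounds half to even; reported fold changes use the
#' conventional half-up rule (half away from zero for negative values).
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fisher's exact test on a count vs library-size contrast
#'
#' Builds the minimal 2x2 table consistent with testing one feature's count
#' against the remainder of each library:
#' `[[round(count_a), round(libsize_a - count_a)],
#'   [round(count_b), round(libsize_b - count_b)]]`
#' (half-up rounding of fractional normalized counts) and returns the
#' two-sided Fisher p-value computed by the point-probability rule (the sum
#' of probabilities of all tables as or less probable than the observed
#' one).
#'
#' @param count_a,count_b feature counts (may be fractional).
#' @param libsize_a,libsize_b positive library sizes, `count <= libsize`.
#' @return two-sided p-value.
#' @export
fisher_count_test <- function(count_a, libsize_a, count_b, libsize_b) {
  if (libsize_a <= 0 || libsize_b <= 0) stop("library sizes must be > 0")
  if (any(c(count_a, count_b) < 0)) stop("counts must be >= 0")
  if (count_a > libsize_a || count_b > libsize_b)
    stop("counts cannot exceed library sizes")
  a <- round_half_up(count_a); b <- round_half_up(count_b)
  m <- matrix(c(a, round_half_up(libsize_a) - a,
                b, round_half_up(libsize_b) - b),
              nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; output in
#' input order.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.presence <- function(a, b) {
  ifelse(a > 0 & b > 0, "common",
         ifelse(a > 0, "only_a",
                ifelse(b > 0, "only_b", "absent")))
}

.de_records <- function(feature, class, a_val, b_val, a_lib, b_lib, cfg) {
  lfc <- log2fc_pseudo(a_val, b_val, cfg$pseudocount)
  p <- vapply(seq_along(a_val), function(i)
    fisher_count_test(a_val[i], a_lib, b_val[i], b_lib), numeric(1))
  fdr <- bh_adjust(p)
  sig <- abs(lfc) >= cfg$lfc_threshold & p < cfg$alpha
  data.frame(
    feature = feature, class = class,
    group_a_value = a_val, group_b_value = b_val,
    log2fc = lfc, p_value = p, fdr = fdr,
    significant = sig, presence = .presence(a_val, b_val),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.feature_classes <- function(ct) {
  if (!is.null(ct$feature_meta) && "class" %in% names(ct$feature_meta))
    ct$feature_meta$class
  else rep(NA_character_, nrow(ct$counts))
}

#' Differential expression of one case sample against a control pool
#'
#' The control value of a feature is its mean normalized count across the
#' control samples; the Fisher test contrasts the case count (vs its
#' effective library size) with the summed control counts (vs the summed
#' control effective library sizes). FDR is adjusted across all features of
#' this comparison.
#'
#' @param ct normalized [count_table()] (library sizes = effective library
#'   sizes).
#' @param case_sample sample id of the case.
#' @param ctrl_samples sample ids of the control pool (case excluded).
#' @param cfg a [de_config()].
#' @return data.frame of per-feature records (feature, class, values,
#'   log2fc, p_value, fdr, significant, presence).
#' @export
per_sample_de <- function(ct, case_sample, ctrl_samples, cfg = de_config()) {
  samples <- colnames(ct$counts)
  unknown <- setdiff(c(case_sample, ctrl_samples), samples)
  if (length(unknown)) stop("unknown sample id(s): ",
                            paste(unknown, collapse = ", "))
  if (case_sample %in% ctrl_samples)
    stop("case sample cannot be part of the control pool")
  if (length(ctrl_samples) < 1) stop("need >= 1 control sample")
  a_val <- ct$counts[, case_sample]
  ctrl_mat <- ct$counts[, ctrl_samples, drop = FALSE]
  b_val <- rowMeans(ctrl_mat)
  a_lib <- ct$lib_sizes[case_sample]
  pool_counts <- rowSums(ctrl_mat)
  pool_lib <- sum(ct$lib_sizes[ctrl_samples])
  lfc <- log2fc_pseudo(a_val, b_val, cfg$pseudocount)
  p <- vapply(seq_along(a_val), function(i)
    fisher_count_test(a_val[i], a_lib, pool_counts[i], pool_lib), numeric(1))
  fdr <- bh_adjust(p)
  sig <- abs(lfc) >= cfg$lfc_threshold & p < cfg$alpha
  data.frame(
    feature = rownames(ct$counts), class = .feature_classes(ct),
    group_a_value = a_val, group_b_value = b_val,
    log2fc = lfc, p_value = p, fdr = fdr, significant = sig,
    presence = .presence(a_val, b_val),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Sibling-pair differential expression with a presence summary
#'
#' Compares two samples feature by feature (no pooling) and summarises, per
#' ncRNA class, how many features were detected in both members, how many of
#' those are significantly up- or down-regulated in the case, and how many
#' were detected only in the case or only in the control.
#'
#' @param ct normalized [count_table()].
#' @param asd_sample,ctrl_sample the two samples (distinct).
#' @param cfg a [de_config()].
#' @return list with `records` (data.frame of per-feature records) and
#'   `summary` (data.frame: class, common_total, up, down, only_asd,
#'   only_ctrl).
#' @export
sibling_compare <- function(ct, asd_sample, ctrl_sample, cfg = de_config()) {
  samples <- colnames(ct$counts)
  unknown <- setdiff(c(asd_sample, ctrl_sample), samples)
  if (length(unknown)) stop("unknown sample id(s): ",
                            paste(unknown, collapse = ", "))
  if (asd_sample == ctrl_sample) stop("the two samples must be distinct")
  rec <- .de_records(rownames(ct$counts), .feature_classes(ct),
                     ct$counts[, asd_sample], ct$counts[, ctrl_sample],
                     ct$lib_sizes[asd_sample], ct$lib_sizes[ctrl_sample],
                     cfg)
  cls <- unique(rec$class)
  summ <- do.call(rbind, lapply(cls, function(k) {
    r <- if (is.na(k)) rec[is.na(rec$class), ]
         else rec[!is.na(rec$class) & rec$class == k, ]
    data.frame(
      class = k,
      common_total = sum(r$presence == "common"),
      up = sum(r$presence == "common" & r$significant & r$log2fc > 0),
      down = sum(r$presence == "common" & r$significant & r$log2fc < 0),
      only_asd = sum(r$presence == "only_a"),
      only_ctrl = sum(r$presence == "only_b"),
      stringsAsFactors = FALSE
    )
  }))
  list(records = rec, summary = summ)
}

#' Features consistently dysregulated across sibling couples
#'
#' Keeps features significant in every supplied comparison with a consistent
#' fold-change sign, split into common-up and common-down lists.
#'
#' @param comparisons list (length >= 2) of record data.frames as produced
#'   by [sibling_compare()] (`$records`) or [per_sample_de()].
#' @return list with `up` and `down` character vectors (alphabetical).
#' @export
cross_couple_common <- function(comparisons) {
  if (length(comparisons) < 2) stop("need >= 2 comparisons")
  sig_up <- lapply(comparisons, function(r)
    r$feature[r$significant & r$log2fc > 0])
  sig_down <- lapply(comparisons, function(r)
    r$feature[r$significant & r$log2fc < 0])
  list(up = sort(Reduce(intersect, sig_up)),
       down = sort(Reduce(intersect, sig_down)))
}
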