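#' Test whether a sequence matches a cluster centre
#'
#' The membership rule of the greedy clustering: slide the two sequences
#' against each other over every ungapped shift; at each shift the overhang
#' is the combined number of unaligned residues at both ends of both
#' sequences, and mismatches are counted over the overlap. The sequence
#' matches when some shift achieves `<= max_mismatch` mismatches and
#' `<= max_overhang` overhanging residues.
#'
#' @param seq,centre nucleotide strings.
#' @param max_mismatch,max_overhang rule parameters (defaults 3 and 3).
#' @param overhang_per_end if `TRUE`, the overhang budget applies to each end
#'   separately instead of to the combined total.
#' @return logical.
#' @export
matches_centre <- function(seq, centre, max_mismatch = 3L, max_overhang = 3L,
                           overhang_per_end = FALSE) {
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(centre, "")[[1]]
  La <- length(a); Lb <- length(b)
  # shift s: position of a[1] relative to b[1] (can be negative)
  for (s in seq(-(La - 1L), Lb - 1L)) {
    lo <- max(1L, s + 1L)           # overlap start on centre
    hi <- min(Lb, s + La)           # overlap end on centre
    ov <- hi - lo + 1L
    if (ov < 1L) next
    left_over <- (lo - 1L) + max(0L, -s)           # unaligned 5' residues
    right_over <- (Lb - hi) + max(0L, s + La - Lb) # unaligned 3' residues
    over <- if (overhang_per_end) max(left_over, right_over)
            else left_over + right_over
    if (over > max_overhang) next
    mism <- sum(a[(lo - s):(hi - s)] != b[lo:hi])
    if (mism <= max_mismatch) return(TRUE)
  }
  FALSE
}

#' Greedy clustering of observed sequences around virtual centres
#'
#' Sequences are processed in decreasing total-abundance order (ties broken
#' lexicographically by sequence). Each sequence joins the first existing
#' cluster whose centre it matches under the mismatch/overhang rule
#' ([matches_centre()]), otherwise it founds a new cluster with itself as
#' centre. Cluster cardinality per sample is the sum of member read counts.
#' The partition is deterministic and independent of input record order.
#'
#' @param seq_counts numeric matrix of per-sample read counts with unique
#'   sequences as row names and samples as columns.
#' @param max_mismatch,max_overhang,overhang_per_end rule parameters, see
#'   [matches_centre()].
#' @return A `cluster_set`: list with `centres` (character), `membership`
#'   (named integer: sequence -> cluster index) and `cardinality` (clusters x
#'   samples matrix).
#' @export
greedy_cluster <- function(seq_counts, max_mismatch = 3L, max_overhang = 3L,
                           overhang_per_end = FALSE) {
  seq_counts <- as.matrix(seq_counts)
  seqs <- rownames(seq_counts)
  if (is.null(seqs) || any(!nzchar(seqs))) stop("sequences must be non-empty row names")
  total <- rowSums(seq_counts)
  ord <- order(-total, seqs)
  centres <- character(0)
  membership <- integer(nrow(seq_counts))
  names(membership) <- seqs
  for (i in ord) {
    s <- seqs[i]
    assigned <- 0L
    for (ci in seq_along(centres)) {
      if (matches_centre(s, centres[ci], max_mismatch, max_overhang,
                         overhang_per_end)) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      centres <- c(centres, s)
      assigned <- length(centres)
    }
    membership[s] <- assigned
  }
  card <- matrix(0, length(centres), ncol(seq_counts),
                 dimnames = list(paste0("cluster_", seq_along(centres)),
                                 colnames(seq_counts)))
  for (s in seqs) {
    card[membership[s], ] <- card[membership[s], ] + seq_counts[s, ]
  }
  structure(list(centres = centres, membership = membership,
                 cardinality = card),
            class = "cluster_set")
}

#' Cluster cardinalities as a count table, with a stability diagnostic
#'
#' Returns the clusters x samples cardinality table and the pairwise
#' between-sample Spearman correlation matrix. The rationale for
#' normalizing on cluster cardinalities rather than raw per-reference counts
#' is that cardinalities are more stable across samples (higher inter-sample
#' correlations), because near-identical sequence variants that scatter
#' reference counts are pooled.
#'
#' @param cs a `cluster_set` from [greedy_cluster()].
#' @return list with `counts` (a [count_table()]) and `correlation`
#'   (samples x samples Spearman matrix; empty with a warning when there is
#'   a single sample).
#' @export
cluster_count_table <- function(cs) {
  card <- cs$cardinality
  if (nrow(card) < 1) stop("need at least one cluster")
  ct <- count_table(card)
  if (ncol(card) < 2) {
    warning("single sample: correlation matrix is empty")
    corr <- matrix(numeric(0), 0, 0)
  } else {
    corr <- stats::cor(card, method = "spearman")
  }
  list(counts = ct, correlation = corr)
}

#' TMM scaling factors (trimmed mean of M-values)
#'
#' The reference sample is the one whose upper quartile of positive
#' counts/library-size is closest to the mean upper quartile. For every
#' other sample, per-feature log-ratios M = log2((y_s/N_s)/(y_r/N_r)) and
#' average intensities A = (1/2) log2((y_s/N_s)(y_r/N_r)) are computed over
#' features positive in both samples; the top and bottom `trim_m` fraction
#' by M and `trim_a` fraction by A are discarded (double trimming, keeping
#' the intersection); the factor is 2 to the weighted mean of the surviving
#' M, with inverse asymptotic binomial variances
#' ((N_s-y_s)/(N_s y_s) + (N_r-y_r)/(N_r y_r))^-1 as weights. Factors are
#' finally divided by their geometric mean, so their geometric mean is 1.
#'
#' @param ct a [count_table()] with >= 2 samples and positive library sizes.
#' @param trim_m,trim_a trim fractions for M and A (defaults 0.30 and 0.05).
#' @return list of class `norm_factors` with `factors` (named, geometric
#'   mean 1), `reference_sample`, and `effective_lib_sizes`
#'   (library size x factor). A sample sharing no positive feature with the
#'   reference gets factor 1 with a warning.
#' @export
tmm_factors <- function(ct, trim_m = 0.30, trim_a = 0.05) {
  y <- ct$counts
  N <- ct$lib_sizes
  if (ncol(y) < 2) stop("need >= 2 samples")
  if (any(N <= 0)) stop("every sample needs a positive library size")
  uq <- vapply(seq_len(ncol(y)), function(j) {
    pos <- y[, j][y[, j] > 0]
    if (!length(pos)) return(NA_real_)
    stats::quantile(pos / N[j], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq, na.rm = TRUE)))
  f <- stats::setNames(rep(1, ncol(y)), colnames(y))
  for (j in seq_len(ncol(y))) {
    if (j == ref) next
    keep <- y[, j] > 0 & y[, ref] > 0
    if (!any(keep)) {
      warning(sprintf("sample %s shares no positive features with reference; factor 1",
                      colnames(y)[j]))
      next
    }
    ys <- y[keep, j]; yr <- y[keep, ref]
    M <- log2((ys / N[j]) / (yr / N[ref]))
    A <- 0.5 * log2((ys / N[j]) * (yr / N[ref]))
    n <- length(M)
    drop_m <- floor(n * trim_m)
    drop_a <- floor(n * trim_a)
    rm_ <- rank(M, ties.method = "first")
    ra_ <- rank(A, ties.method = "first")
    keep2 <- rm_ > drop_m & rm_ <= n - drop_m & ra_ > drop_a & ra_ <= n - drop_a
    if (!any(keep2)) keep2 <- rep(TRUE, n)  # degenerate: fall back to untrimmed
    w <- 1 / ((N[j] - ys) / (N[j] * ys) + (N[ref] - yr) / (N[ref] * yr))
    f[j] <- 2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }
  f <- f / exp(mean(log(f)))
  structure(list(factors = f,
                 reference_sample = colnames(y)[ref],
                 effective_lib_sizes = N * f),
            class = "norm_factors")
}

#' Apply TMM factors to a reference count table
#'
#' Normalized value = raw / (library size x factor) x mean effective library
#' size — counts-per-effective-library rescaled so magnitudes stay
#' comparable to raw counts. The effective library sizes are recorded as the
#' output's library sizes.
#'
#' @param ct a [count_table()] of raw reference counts.
#' @param nf a `norm_factors` from [tmm_factors()]; its sample set must
#'   cover the table's samples.
#' @return A normalized [count_table()].
#' @export
apply_factors <- function(ct, nf) {
  missing <- setdiff(colnames(ct$counts), names(nf$factors))
  if (length(missing))
    stop("no normalization factor for sample(s): ",
         paste(missing, collapse = ", "))
  f <- nf$factors[colnames(ct$counts)]
  eff <- ct$lib_sizes * f
  scale_to <- mean(eff)
  norm <- sweep(ct$counts, 2, eff, "/") * scale_to
  count_table(norm, lib_sizes = eff, feature_meta = ct$feature_meta)
}
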