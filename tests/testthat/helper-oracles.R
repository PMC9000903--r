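# Independent oracle implementations used to cross-check the package.
# These are deliberately naive, loop-based transcriptions kept separate from
# the implementation they verify.

# exhaustive ungapped forward alignment: every reference, every offset
oracle_align <- function(read, refs, max_seed_mm = 1L, max_total_mm = Inf) {
  rb <- strsplit(read, "")[[1]]
  L <- length(rb)
  seed_len <- min(20L, L)
  out <- list()
  for (r in seq_len(nrow(refs))) {
    sb <- strsplit(refs$sequence[r], "")[[1]]
    if (length(sb) < L) next
    for (off in 0:(length(sb) - L)) {
      win <- sb[(off + 1):(off + L)]
      mism <- rb != win
      if (sum(mism[1:seed_len]) <= max_seed_mm && sum(mism) <= max_total_mm) {
        out[[length(out) + 1]] <- data.frame(
          ref_id = refs$id[r], offset = off,
          seed_mismatches = sum(mism[1:seed_len]),
          total_mismatches = sum(mism), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(ref_id = character(0), offset = integer(0),
                      seed_mismatches = integer(0),
                      total_mismatches = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$ref_id, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# membership rule re-derived via explicit string padding at every shift
oracle_matches <- function(seq, centre, max_mm = 3L, max_over = 3L) {
  a <- strsplit(seq, "")[[1]]; b <- strsplit(centre, "")[[1]]
  La <- length(a); Lb <- length(b)
  for (shift in (-La + 1):(Lb - 1)) {
    pos_a <- shift + seq_len(La)        # positions of a on centre coordinates
    both <- intersect(pos_a, seq_len(Lb))
    if (!length(both)) next
    overhang <- (La - length(both)) + (Lb - length(both))
    if (overhang > max_over) next
    mm <- sum(a[both - shift] != b[both])
    if (mm <= max_mm) return(TRUE)
  }
  FALSE
}

# independent greedy clustering using oracle_matches
oracle_greedy <- function(seq_counts, max_mm = 3L, max_over = 3L) {
  seqs <- rownames(seq_counts)
  total <- rowSums(seq_counts)
  ord <- order(-total, seqs)
  centres <- character(0)
  member <- integer(length(seqs)); names(member) <- seqs
  for (i in ord) {
    s <- seqs[i]
    hit <- 0L
    for (ci in seq_along(centres)) {
      if (oracle_matches(s, centres[ci], max_mm, max_over)) { hit <- ci; break }
    }
    if (hit == 0L) { centres <- c(centres, s); hit <- length(centres) }
    member[s] <- hit
  }
  member
}

# two-sided Fisher p by direct hypergeometric enumeration with choose()
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  p_obs <- prob(a)
  sum(vapply(support, function(x) {
    p <- prob(x)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# literal, unoptimized transcription of the trimmed weighted-mean TMM recipe
oracle_tmm <- function(y, N, trim_m = 0.30, trim_a = 0.05) {
  uq <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    pos <- y[, j][y[, j] > 0]
    uq[j] <- quantile(pos / N[j], 0.75, names = FALSE)
  }
  ref <- which.min(abs(uq - mean(uq)))
  f <- rep(1, ncol(y))
  for (j in seq_len(ncol(y))) {
    if (j == ref) next
    M <- c(); A <- c(); w <- c()
    for (i in seq_len(nrow(y))) {
      ys <- y[i, j]; yr <- y[i, ref]
      if (ys > 0 && yr > 0) {
        M <- c(M, log2((ys / N[j]) / (yr / N[ref])))
        A <- c(A, 0.5 * log2((ys / N[j]) * (yr / N[ref])))
        w <- c(w, 1 / ((N[j] - ys) / (N[j] * ys) + (N[ref] - yr) / (N[ref] * yr)))
      }
    }
    n <- length(M)
    dm <- floor(n * trim_m); da <- floor(n * trim_a)
    rm_ <- rank(M, ties.method = "first"); ra_ <- rank(A, ties.method = "first")
    keep <- which(rm_ > dm & rm_ <= n - dm & ra_ > da & ra_ <= n - da)
    f[j] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  f
}

# small random read/reference fixture shared by alignment tests
random_refs <- function(n, len_range, seed) {
  set.seed(seed)
  data.frame(
    id = sprintf("ref%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"),
                   sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = ""), character(1)),
    class = "other", stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_at <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  paste(b, collapse = "")
}
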