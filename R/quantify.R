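#' Length-filter adapter-trimmed small-RNA reads
#'
#' Trimmed small-RNA inserts informative for miRNA/piRNA profiling fall in a
#' 15-51 nt window; anything outside is adapter dimer or longer RNA and is
#' dropped. Adapter trimming itself happens upstream.
#'
#' @param reads data.frame with `id`, `sequence`.
#' @param min_len,max_len inclusive length bounds.
#' @return The retained reads; the number kept/dropped is reported via
#'   `message()`.
#' @export
filter_reads <- function(reads, min_len = 15L, max_len = 51L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  message(sprintf("filter_reads: kept %d/%d reads in [%d, %d] nt",
                  sum(keep), length(keep), min_len, max_len))
  reads[keep, , drop = FALSE]
}

#' Build a k-mer seed index over a reference set
#'
#' Maps every reference k-mer to its (reference, offset) occurrences.
#' Candidate alignment positions for a read are generated by looking up the
#' two disjoint k-mers covering its leftmost 20 nt: with at most one seed
#' mismatch allowed, at least one of them matches the reference exactly, so
#' candidate generation loses no qualifying hit for reads of length >= 2k.
#'
#' @param refs a `reference_set`.
#' @param kmer k-mer size (<= 20; default 10 pairs with the 20-nt seed).
#' @return A `seed_index` (environment-backed hash) with the reference set
#'   attached.
#' @export
build_index <- function(refs, kmer = 10L) {
  if (kmer > 20L) stop("kmer must be <= 20")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(refs))) {
    s <- refs$sequence[r]
    L <- nchar(s)
    if (L < kmer) next
    for (off in seq_len(L - kmer + 1L)) {
      key <- substr(s, off, off + kmer - 1L)
      idx[[key]] <- rbind(idx[[key]], c(r, off))
    }
  }
  structure(list(index = idx, kmer = as.integer(kmer), refs = refs),
            class = "seed_index")
}

.count_mismatches <- function(a, b) {
  # a, b equal-length character vectors of single bases
  sum(a != b)
}

.score_alignment <- function(read_b, ref_b, offset, seed_len) {
  # offset: 1-based start on reference; read fully contained
  L <- length(read_b)
  ref_win <- ref_b[offset:(offset + L - 1L)]
  mism <- read_b != ref_win
  c(seed = sum(mism[seq_len(seed_len)]), total = sum(mism))
}

#' Align one read against the reference set under the seed-mismatch rule
#'
#' Ungapped, forward-strand alignment of the full read inside a reference
#' (no overhang). A hit qualifies when the leftmost `min(20, read length)` nt
#' of the read carry at most `max_seed_mm` mismatches; mismatches beyond the
#' seed are unlimited by default (`max_total_mm`). All qualifying (reference,
#' offset) pairs are returned, sorted by (ref_id, offset); ties are retained
#' and resolved downstream by EM.
#'
#' @param read character, the read sequence (ACGT).
#' @param index a `seed_index` from [build_index()].
#' @param max_seed_mm allowed mismatches in the seed region (default 1).
#' @param max_total_mm optional cap on total mismatches (default `Inf`).
#' @return data.frame with `ref_id`, `offset` (0-based), `seed_mismatches`,
#'   `total_mismatches`; zero rows if the read does not map. Reads with
#'   non-ACGT symbols are skipped with a warning.
#' @export
align_read <- function(read, index, max_seed_mm = 1L, max_total_mm = Inf) {
  refs <- index$refs
  empty <- data.frame(ref_id = character(0), offset = integer(0),
                      seed_mismatches = integer(0), total_mismatches = integer(0))
  if (!grepl("^[ACGT]+$", read)) {
    warning("read contains non-ACGT symbols; skipped")
    return(empty)
  }
  L <- nchar(read)
  if (L < 15L) stop("read length must be >= 15")
  k <- index$kmer
  seed_len <- min(20L, L)
  read_b <- strsplit(read, "")[[1]]
  # candidate (ref, offset) pairs
  cand <- NULL
  if (L >= 2L * k) {
    for (pos in c(1L, k + 1L)) {
      key <- substr(read, pos, pos + k - 1L)
      occ <- index$index[[key]]
      if (!is.null(occ)) {
        cand <- rbind(cand, cbind(occ[, 1], occ[, 2] - pos + 1L))
      }
    }
    cand <- unique(cand)
  } else {
    # short reads: exhaustive offsets (pigeonhole needs two disjoint k-mers)
    for (r in seq_len(nrow(refs))) {
      n_off <- nchar(refs$sequence[r]) - L + 1L
      if (n_off >= 1L) cand <- rbind(cand, cbind(r, seq_len(n_off)))
    }
  }
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  out <- vector("list", nrow(cand))
  n_hit <- 0L
  ref_bases <- attr(index, "ref_bases")
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; off <- cand[i, 2]
    if (off < 1L) next
    refseq <- refs$sequence[r]
    if (off + L - 1L > nchar(refseq)) next
    ref_b <- strsplit(refseq, "")[[1]]
    sc <- .score_alignment(read_b, ref_b, off, seed_len)
    if (sc["seed"] <= max_seed_mm && sc["total"] <= max_total_mm) {
      n_hit <- n_hit + 1L
      out[[n_hit]] <- data.frame(
        ref_id = refs$id[r], offset = off - 1L,
        seed_mismatches = unname(sc["seed"]),
        total_mismatches = unname(sc["total"]),
        stringsAsFactors = FALSE)
    }
  }
  if (n_hit == 0L) return(empty)
  hits <- do.call(rbind, out[seq_len(n_hit)])
  hits[order(hits$ref_id, hits$offset), , drop = FALSE]
}

#' Resolve multireads by expectation-maximization
#'
#' Each read contributes one unit of mass, split across its candidate
#' references in proportion to the current abundance estimates (E-step);
#' abundances are then re-estimated as the summed assigned masses (M-step).
#' Iteration starts from a uniform split and stops when the largest absolute
#' change in expected counts falls below `tol` or after `max_iter` rounds.
#' The multinomial log-likelihood of the allocation is non-decreasing across
#' iterations, and total mass is conserved exactly.
#'
#' @param hits_by_read list, one element per read, each a character vector of
#'   candidate reference ids (every read must have >= 1 hit).
#' @param ref_ids reference universe (ids to report, including zeros).
#' @param tol convergence tolerance on expected counts.
#' @param max_iter iteration cap.
#' @return Named numeric vector of expected counts summing to the number of
#'   reads.
#' @export
em_allocate <- function(hits_by_read, ref_ids, tol = 1e-8, max_iter = 200L) {
  stopifnot(all(lengths(hits_by_read) >= 1))
  n_reads <- length(hits_by_read)
  out <- stats::setNames(numeric(length(ref_ids)), ref_ids)
  if (n_reads == 0) return(out)
  # compress reads into equivalence classes by candidate set
  keys <- vapply(hits_by_read, function(h) paste(sort(unique(h)), collapse = "\r"),
                 character(1))
  tab <- table(keys)
  class_refs <- strsplit(names(tab), "\r", fixed = TRUE)
  class_n <- as.numeric(tab)
  used <- sort(unique(unlist(class_refs)))
  if (!all(used %in% ref_ids)) stop("hits reference unknown ids")
  theta <- stats::setNames(rep(1 / length(used), length(used)), used)
  counts <- stats::setNames(numeric(length(used)), used)
  for (it in seq_len(max_iter)) {
    new_counts <- stats::setNames(numeric(length(used)), used)
    for (c_i in seq_along(class_refs)) {
      rs <- class_refs[[c_i]]
      w <- theta[rs]
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(rs), length(rs))
      new_counts[rs] <- new_counts[rs] + class_n[c_i] * w
    }
    delta <- max(abs(new_counts - counts))
    counts <- new_counts
    theta <- counts / sum(counts)
    if (delta < tol) break
  }
  out[used] <- counts
  out
}

#' Quantify one sample against the reference set
#'
#' Composes [filter_reads()], per-read [align_read()] and [em_allocate()]
#' into one count-table column. The library size is the number of aligned
#' reads; miRNA/piRNA fractions of the allocated mass are reported in the
#' run log.
#'
#' @param reads data.frame with `id`, `sequence`.
#' @param refs a `reference_set`.
#' @param index optional prebuilt [build_index()] (rebuilt if `NULL`).
#' @param max_seed_mm,max_total_mm see [align_read()].
#' @param min_len,max_len see [filter_reads()].
#' @return list with `counts` (named expected counts per reference),
#'   `n_aligned`, `n_filtered`, and `class_fractions`.
#' @export
quantify_sample <- function(reads, refs, index = NULL,
                            max_seed_mm = 1L, max_total_mm = Inf,
                            min_len = 15L, max_len = 51L) {
  if (is.null(index)) index <- build_index(refs)
  reads <- filter_reads(reads, min_len, max_len)
  hits_by_read <- list()
  n_aligned <- 0L
  for (i in seq_len(nrow(reads))) {
    h <- align_read(reads$sequence[i], index,
                    max_seed_mm = max_seed_mm, max_total_mm = max_total_mm)
    if (nrow(h) > 0) {
      n_aligned <- n_aligned + 1L
      hits_by_read[[n_aligned]] <- unique(h$ref_id)
    }
  }
  counts <- em_allocate(hits_by_read, refs$id)
  if (n_aligned == 0L) warning("zero aligned reads")
  cls_tot <- tapply(counts, refs$class[match(names(counts), refs$id)], sum)
  frac <- if (sum(counts) > 0) cls_tot / sum(counts) else cls_tot * 0
  message(sprintf(
    "quantify_sample: %d reads aligned; class fractions: %s",
    n_aligned,
    paste(sprintf("%s=%.3f", names(frac), frac), collapse = " ")))
  list(counts = counts, n_aligned = n_aligned,
       n_filtered = nrow(reads), class_fractions = frac)
}

#' Quantify several samples into a count table
#'
#' @param read_sets named list of read data.frames (one per sample).
#' @param refs a `reference_set`.
#' @param ... passed to [quantify_sample()].
#' @return A [count_table()] with reference class metadata; library sizes are
#'   the per-sample aligned-read counts.
#' @export
quantify_samples <- function(read_sets, refs, ...) {
  index <- build_index(refs)
  cols <- lapply(read_sets, function(rd)
    quantify_sample(rd, refs, index = index, ...))
  counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
  colnames(counts) <- names(read_sets)
  lib <- vapply(cols, `[[`, numeric(1), "n_aligned")
  meta <- data.frame(class = refs$class, row.names = refs$id,
                     stringsAsFactors = FALSE)
  count_table(counts, lib_sizes = lib, feature_meta = meta)
}
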