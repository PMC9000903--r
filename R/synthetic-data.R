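#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. One integer seed
#' drives a single root RNG; each generator derives its own sub-stream from a
#' fixed offset so outputs do not cross-contaminate and identical
#' configurations yield byte-identical files.
#'
#' @param seed integer root seed.
#' @param n_refs number of ncRNA reference sequences.
#' @param ref_length_range integer vector `c(min, max)` of reference lengths
#'   in nucleotides; defaults to the 15-51 nt window of trimmed small-RNA
#'   reads.
#' @param class_mix named fractions over miRNA/piRNA/other, summing to 1.
#'   Defaults reflect a piRNA-dominated faecal sncRNA pool.
#' @param n_reads_per_sample reads simulated per sample.
#' @param per_base_error_rate substitution probability per sequenced base.
#' @param multimap_family_sizes integer vector; each entry f plants a family
#'   of f references sharing an identical internal 20-nt core, so that
#'   seed-constrained mapping produces genuine multireads.
#' @param n_case,n_ctrl group sizes for two-group count simulation.
#' @param de_fraction fraction of features spiked with a true effect.
#' @param effect_log2fc absolute log2 fold change of spiked features (applied
#'   as +effect for half of them, -effect for the other half, in cases).
#' @param dispersion negative-binomial dispersion (gamma-Poisson); 0 means
#'   Poisson.
#' @param libsize_fold_spread max/min ratio of simulated library sizes
#'   (>= 1); defaults to 4, a realistic spread for small-RNA libraries.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_refs = 60L,
                       ref_length_range = c(15L, 51L),
                       class_mix = c(miRNA = 0.3, piRNA = 0.5, other = 0.2),
                       n_reads_per_sample = 2000L,
                       per_base_error_rate = 0.005,
                       multimap_family_sizes = integer(0),
                       n_case = 6L, n_ctrl = 6L,
                       de_fraction = 0.1,
                       effect_log2fc = 3,
                       dispersion = 0.1,
                       libsize_fold_spread = 4) {
  if (length(ref_length_range) != 2 || ref_length_range[1] > ref_length_range[2])
    stop("ref_length_range must be c(min, max) with min <= max")
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1")
  if (!setequal(names(class_mix), c("miRNA", "piRNA", "other")))
    stop("class_mix must be named over miRNA, piRNA, other")
  probs <- c(per_base_error_rate, de_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (libsize_fold_spread < 1) stop("libsize_fold_spread must be >= 1")
  if (n_refs < 1) stop("n_refs must be >= 1")
  structure(list(
    seed = as.integer(seed), n_refs = as.integer(n_refs),
    ref_length_range = as.integer(ref_length_range),
    class_mix = class_mix[c("miRNA", "piRNA", "other")],
    n_reads_per_sample = as.integer(n_reads_per_sample),
    per_base_error_rate = per_base_error_rate,
    multimap_family_sizes = as.integer(multimap_family_sizes),
    n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
    de_fraction = de_fraction, effect_log2fc = effect_log2fc,
    dispersion = dispersion, libsize_fold_spread = libsize_fold_spread
  ), class = "sim_config")
}

# fixed sub-stream offsets per generator (reproducibility without
# cross-contamination between outputs of one config)
.sim_offsets <- c(refs = 101L, reads = 211L, counts = 307L, otu = 401L)

.with_stream <- function(cfg, which, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed + .sim_offsets[[which]])
  force(expr)
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic ncRNA reference set
#'
#' Draws `n_refs` unique sequences over ACGT with lengths uniform in
#' `ref_length_range` and class labels drawn from `class_mix`. Each entry of
#' `multimap_family_sizes` plants a family of references carrying an
#' identical internal 20-nt core (inserted at the start of the sequence), so
#' reads from the core region map to every family member.
#'
#' @param cfg a [sim_config()].
#' @return A `reference_set`: data.frame with columns `id`, `sequence`,
#'   `class`.
#' @export
make_reference_set <- function(cfg) {
  .with_stream(cfg, "refs", {
    lens <- sample(seq(cfg$ref_length_range[1], cfg$ref_length_range[2]),
                   cfg$n_refs, replace = TRUE)
    seqs <- character(cfg$n_refs)
    for (i in seq_len(cfg$n_refs)) {
      repeat {
        s <- .random_seq(lens[i])
        if (!s %in% seqs[seq_len(i - 1)]) break
      }
      seqs[i] <- s
    }
    cls <- sample(names(cfg$class_mix), cfg$n_refs, replace = TRUE,
                  prob = cfg$class_mix)
    # plant shared 20-nt cores for multimap families; cores go at the 5' end
    # so they fall inside the leftmost-20 seed of reads drawn from them
    idx <- 1L
    fam <- 0L
    for (fsize in cfg$multimap_family_sizes) {
      if (idx + fsize - 1L > cfg$n_refs)
        stop("multimap_family_sizes exceed n_refs")
      fam <- fam + 1L
      core <- .random_seq(20L)
      for (j in seq(idx, idx + fsize - 1L)) {
        tail_len <- max(nchar(seqs[j]) - 20L, 1L)
        seqs[j] <- paste0(core, .random_seq(tail_len))
      }
      idx <- idx + fsize
    }
    prefix <- c(miRNA = "mir", piRNA = "pir", other = "onc")
    ids <- sprintf("syn-%s-%04d", prefix[cls], seq_len(cfg$n_refs))
    structure(
      data.frame(id = ids, sequence = seqs, class = cls,
                 stringsAsFactors = FALSE),
      class = c("reference_set", "data.frame")
    )
  })
}

.mutate_seq <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < error_rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    for (i in which(hit)) {
      bases[i] <- sample(setdiff(alt, bases[i]), 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Simulate small-RNA reads from a reference set
#'
#' Reads are whole reference sequences sampled proportional to `abundances`,
#' with independent per-base substitution errors at
#' `cfg$per_base_error_rate`. The true per-reference counts are returned
#' alongside for recovery tests.
#'
#' @param refs a `reference_set` from [make_reference_set()].
#' @param abundances non-negative weights named by reference id (unnamed:
#'   taken in reference order); not all zero.
#' @param cfg a [sim_config()]; `n_reads_per_sample` and
#'   `per_base_error_rate` are used.
#' @param n_reads optional override of the number of reads.
#' @return list with `reads` (data.frame `id`, `sequence`) and `truth`
#'   (named true count per reference).
#' @export
simulate_reads <- function(refs, abundances, cfg, n_reads = cfg$n_reads_per_sample) {
  if (nrow(refs) == 0) stop("empty reference set")
  if (is.null(names(abundances))) names(abundances) <- refs$id
  w <- abundances[refs$id]
  w[is.na(w)] <- 0
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 and not all zero")
  .with_stream(cfg, "reads", {
    pick <- sample.int(nrow(refs), n_reads, replace = TRUE, prob = w)
    seqs <- vapply(refs$sequence[pick],
                   .mutate_seq, character(1),
                   error_rate = cfg$per_base_error_rate,
                   USE.NAMES = FALSE)
    truth <- tabulate(pick, nbins = nrow(refs))
    names(truth) <- refs$id
    list(
      reads = data.frame(
        id = sprintf("read-%06d", seq_len(n_reads)),
        sequence = seqs, stringsAsFactors = FALSE
      ),
      truth = truth
    )
  })
}

#' Simulate a two-group negative-binomial count table
#'
#' Gamma-Poisson counts for `n_case` case and `n_ctrl` control samples. A
#' `de_fraction` of features receives a true effect: their case-sample means
#' are multiplied by `2^effect_log2fc` (half of the spiked features up, half
#' down). Library sizes vary over a `libsize_fold_spread` range. Truth labels
#' (`up`, `down`, `null`) are returned for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param n_features number of features.
#' @param base_mean mean count of an unspiked feature at the reference
#'   library size.
#' @return list with `counts` (a [count_table()]), `truth` (factor per
#'   feature) and `groups` (named `case`/`control` per sample).
#' @export
simulate_two_group_counts <- function(cfg, n_features = 200L, base_mean = 50) {
  if (cfg$n_case < 1 || cfg$n_ctrl < 1) stop("need at least one sample per group")
  .with_stream(cfg, "counts", {
    n_s <- cfg$n_case + cfg$n_ctrl
    samples <- c(sprintf("case_%d", seq_len(cfg$n_case)),
                 sprintf("ctrl_%d", seq_len(cfg$n_ctrl)))
    groups <- stats::setNames(
      rep(c("case", "control"), c(cfg$n_case, cfg$n_ctrl)), samples)
    feats <- sprintf("feat_%04d", seq_len(n_features))
    n_de <- round(cfg$de_fraction * n_features)
    truth <- rep("null", n_features)
    if (n_de > 0) {
      de_idx <- sample.int(n_features, n_de)
      up <- de_idx[seq_len(ceiling(n_de / 2))]
      down <- setdiff(de_idx, up)
      truth[up] <- "up"
      truth[down] <- "down"
    }
    # per-feature baseline means spread around base_mean (half-decade range)
    mu0 <- base_mean * 2^stats::runif(n_features, -0.5, 0.5)
    sf <- 2^stats::runif(n_s, 0, log2(cfg$libsize_fold_spread))
    sf <- sf / mean(sf)
    counts <- matrix(0, n_features, n_s, dimnames = list(feats, samples))
    fc <- rep(1, n_features)
    fc[truth == "up"] <- 2^cfg$effect_log2fc
    fc[truth == "down"] <- 2^(-cfg$effect_log2fc)
    for (s in seq_len(n_s)) {
      mu <- mu0 * sf[s]
      if (groups[s] == "case") mu <- mu * fc
      counts[, s] <- if (cfg$dispersion > 0) {
        stats::rnbinom(n_features, mu = mu, size = 1 / cfg$dispersion)
      } else {
        stats::rpois(n_features, mu)
      }
    }
    list(counts = count_table(counts),
         truth = stats::setNames(factor(truth, c("up", "down", "null")), feats),
         groups = groups)
  })
}

.default_lineages <- function(n_otus, rng_ready = TRUE) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
             "Proteobacteria", "Verrucomicrobia")
  fams <- list(
    Firmicutes = c("Lachnospiraceae", "Ruminococcaceae", "Streptococcaceae"),
    Bacteroidetes = c("Bacteroidaceae", "Prevotellaceae", "Rikenellaceae"),
    Actinobacteria = c("Bifidobacteriaceae", "Coriobacteriaceae"),
    Proteobacteria = c("Sutterellaceae", "Pasteurellaceae"),
    Verrucomicrobia = c("Akkermansiaceae")
  )
  out <- vector("list", n_otus)
  for (i in seq_len(n_otus)) {
    p <- sample(phyla, 1)
    f <- sample(fams[[p]], 1)
    out[[i]] <- c(Kingdom = "Bacteria", Phylum = p,
                  Class = paste0(p, "_class"), Order = paste0(f, "_order"),
                  Family = f, Genus = paste0(sub("aceae$", "", f), "_genus"),
                  Species = "unassigned")
  }
  do.call(rbind, out)
}

#' Simulate a compositional OTU table
#'
#' Dirichlet-multinomial counts per sample over OTUs carrying full 7-rank
#' lineages. Families listed in `group_exclusive_families` have zero expected
#' abundance (and zero counts, by construction) in every sample of the group
#' they are excluded from, emulating group-characteristic families.
#'
#' @param n_otus,n_samples table dimensions.
#' @param group_assignments character vector of `"case"`/`"control"` per
#'   sample (length `n_samples`).
#' @param group_exclusive_families named list: `case` = families present only
#'   in case samples, `control` = families present only in controls.
#' @param seed integer seed.
#' @param depth sequencing depth per sample.
#' @param concentration Dirichlet concentration scaling (smaller = more
#'   sample-to-sample variation).
#' @return An [otu_table_new()] object.
#' @export
simulate_otu_table <- function(n_otus, n_samples, group_assignments,
                               group_exclusive_families = list(),
                               seed = 1L, depth = 10000L,
                               concentration = 50) {
  if (length(group_assignments) != n_samples)
    stop("group_assignments must have one entry per sample")
  if (!all(group_assignments %in% c("case", "control")))
    stop("unknown group label: ",
         paste(setdiff(group_assignments, c("case", "control")), collapse = ", "))
  bad <- setdiff(names(group_exclusive_families), c("case", "control"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  cfg <- sim_config(seed = seed)
  .with_stream(cfg, "otu", {
    lineage <- .default_lineages(n_otus)
    excl <- unlist(group_exclusive_families, use.names = FALSE)
    if (length(excl)) {
      # make sure every requested exclusive family exists in the taxonomy
      missing <- setdiff(excl, lineage[, "Family"])
      for (m in missing) {
        i <- sample.int(n_otus, 1)
        lineage[i, ] <- c("Bacteria", "Firmicutes", "Firmicutes_class",
                          paste0(m, "_order"), m,
                          paste0(sub("aceae$", "", m), "_genus"), "unassigned")
      }
    }
    rownames(lineage) <- sprintf("OTU_%04d", seq_len(n_otus))
    base_alpha <- stats::rgamma(n_otus, shape = 0.8, rate = 1) + 0.05
    samples <- sprintf("%s_%d", ifelse(group_assignments == "case", "asd", "ctrl"),
                       stats::ave(seq_len(n_samples), group_assignments,
                                  FUN = seq_along))
    counts <- matrix(0L, n_otus, n_samples,
                     dimnames = list(rownames(lineage), samples))
    for (s in seq_len(n_samples)) {
      alpha <- base_alpha
      for (g in names(group_exclusive_families)) {
        if (group_assignments[s] != g) {
          alpha[lineage[, "Family"] %in% group_exclusive_families[[g]]] <- 0
        }
      }
      th <- ifelse(alpha > 0,
                   stats::rgamma(n_otus, shape = alpha * concentration, rate = 1),
                   0)
      counts[, s] <- stats::rmultinom(1, depth, th / sum(th))[, 1]
    }
    otu_table_new(counts, as.data.frame(lineage, stringsAsFactors = FALSE),
                  stats::setNames(group_assignments, samples))
  })
}

#' Write references as FASTA / reads as FASTQ
#'
#' Reads get a constant quality string (`I`); quality is not used downstream,
#' where filtering is length-based.
#'
#' @param refs a `reference_set`.
#' @param reads data.frame with `id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(refs$sequence)
  names(x) <- refs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  qual <- Biostrings::BStringSet(vapply(
    nchar(reads$sequence), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a reference FASTA / reads FASTQ
#'
#' Reference sequences are normalized RNA->DNA (U to T) on read-in so
#' RNA-space FASTA files work. Class labels are recovered from id prefixes
#' produced by [make_reference_set()] (`mir`/`pir`), defaulting to `other`.
#'
#' @param path input file.
#' @return `read_reference_fasta`: a `reference_set`; `read_reads_fastq`: a
#'   data.frame with `id`, `sequence`.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("U", "T", as.character(x), fixed = TRUE))
  if (!all(grepl("^[ACGT]+$", seqs))) stop("non-ACGTU symbols in reference")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate reference ids")
  cls <- rep("other", length(ids))
  cls[grepl("mir|miR", ids)] <- "miRNA"
  cls[grepl("pir|piR", ids)] <- "piRNA"
  structure(
    data.frame(id = ids, sequence = unname(seqs), class = cls,
               stringsAsFactors = FALSE),
    class = c("reference_set", "data.frame")
  )
}

#' @rdname read_reference_fasta
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write truth labels next to a simulated dataset
#'
#' @param truth named vector (reference or feature truth).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(
    data.frame(feature = names(truth), truth = as.character(truth)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
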