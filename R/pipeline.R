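#' Load and validate a run configuration
#'
#' The configuration is a single declarative YAML file (or an equivalent R
#' list): reference FASTA, one FASTQ per sample with group and optional
#' sibling-couple id, OTU table and group labels, target-map and GMT paths,
#' stage parameters and an output directory. Validation checks path
#' existence, unique sample ids and that each declared sibling couple has
#' exactly one case and one control — before any computation runs.
#'
#' @param config path to a YAML file, or a list.
#' @return The validated config (list), with defaults filled in.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
}

#' @rdname load_run_config
#' @export
validate_config <- function(cfg) {
  need <- function(x, what) if (is.null(x)) stop("config is missing: ", what)
  need(cfg$reference_fasta, "reference_fasta")
  need(cfg$samples, "samples")
  need(cfg$output_dir, "output_dir")
  ids <- vapply(cfg$samples, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  for (s in cfg$samples) {
    need(s$fastq, sprintf("fastq for sample %s", s$id))
    if (!file.exists(s$fastq)) stop("missing FASTQ: ", s$fastq)
    if (!s$group %in% c("case", "control"))
      stop("sample group must be case/control: ", s$id)
  }
  if (!file.exists(cfg$reference_fasta))
    stop("missing reference FASTA: ", cfg$reference_fasta)
  couples <- vapply(cfg$samples, function(s)
    if (is.null(s$couple)) NA_character_ else as.character(s$couple),
    character(1))
  for (cp in unique(stats::na.omit(couples))) {
    members <- cfg$samples[which(couples == cp)]
    grp <- sort(vapply(members, `[[`, character(1), "group"))
    if (!identical(grp, c("case", "control")))
      stop(sprintf("sibling couple %s must have exactly one case and one control", cp))
  }
  for (p in c(cfg$otu_table, cfg$mirna_targets, cfg$pirna_targets,
              unlist(cfg$gene_sets))) {
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  defaults <- list(
    seed = 1L,
    cluster = list(max_mismatch = 3L, max_overhang = 3L),
    tmm = list(trim_m = 0.30, trim_a = 0.05),
    de = list(lfc_threshold = 1.0, alpha = 0.05, pseudocount = 1.0),
    prevalence = list(presence_threshold = 0.5, detection_floor = 1e-4),
    min_common_samples = 2L
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
    }
  }
  cfg
}

.stage_names <- c("quantify", "cluster", "normalize", "diff", "targets",
                  "microbiome")

.out <- function(cfg, ...) file.path(cfg$output_dir, ...)

.sample_ids <- function(cfg) vapply(cfg$samples, `[[`, character(1), "id")
.sample_groups <- function(cfg)
  stats::setNames(vapply(cfg$samples, `[[`, character(1), "group"),
                  .sample_ids(cfg))

.stage_quantify <- function(cfg) {
  refs <- read_reference_fasta(cfg$reference_fasta)
  read_sets <- lapply(cfg$samples, function(s) read_reads_fastq(s$fastq))
  names(read_sets) <- .sample_ids(cfg)
  ct <- quantify_samples(read_sets, refs)
  write_count_table(ct, .out(cfg, "reference_counts.tsv"))
  # unique observed (length-filtered) sequences per sample, for clustering
  seq_tabs <- lapply(read_sets, function(rd) {
    rd <- filter_reads(rd)
    table(rd$sequence)
  })
  all_seqs <- sort(unique(unlist(lapply(seq_tabs, names))))
  seq_counts <- vapply(seq_tabs, function(tb) {
    v <- as.numeric(tb[all_seqs]); v[is.na(v)] <- 0; v
  }, numeric(length(all_seqs)))
  rownames(seq_counts) <- all_seqs
  utils::write.table(
    data.frame(sequence = all_seqs, seq_counts, check.names = FALSE),
    .out(cfg, "unique_sequences.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = ct, seq_counts = seq_counts)
}

.read_seq_counts <- function(cfg) {
  df <- utils::read.delim(.out(cfg, "unique_sequences.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sequence
  m
}

.stage_cluster <- function(cfg) {
  seq_counts <- .read_seq_counts(cfg)
  cs <- greedy_cluster(seq_counts,
                       max_mismatch = cfg$cluster$max_mismatch,
                       max_overhang = cfg$cluster$max_overhang)
  cct <- cluster_count_table(cs)
  df <- data.frame(cluster = rownames(cs$cardinality),
                   centre = cs$centres,
                   n_members = as.integer(table(cs$membership)[
                     as.character(seq_along(cs$centres))]),
                   cs$cardinality, check.names = FALSE)
  utils::write.table(df, .out(cfg, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_count_table(cct$counts, .out(cfg, "cluster_counts.tsv"))
  message(sprintf("cluster: %d unique sequences -> %d clusters",
                  nrow(seq_counts), length(cs$centres)))
  cct
}

.stage_normalize <- function(cfg) {
  cluster_ct <- read_count_table(.out(cfg, "cluster_counts.tsv"))
  ref_ct <- read_count_table(.out(cfg, "reference_counts.tsv"), n_meta = 1L)
  nf <- tmm_factors(cluster_ct, trim_m = cfg$tmm$trim_m,
                    trim_a = cfg$tmm$trim_a)
  norm <- apply_factors(ref_ct, nf)
  utils::write.table(
    data.frame(sample = names(nf$factors), factor = nf$factors,
               effective_lib_size = nf$effective_lib_sizes),
    .out(cfg, "tmm_factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_count_table(norm, .out(cfg, "normalized_counts.tsv"))
  norm
}

.stage_diff <- function(cfg) {
  norm <- read_count_table(.out(cfg, "normalized_counts.tsv"), n_meta = 1L)
  decfg <- de_config(cfg$de$lfc_threshold, cfg$de$alpha, cfg$de$pseudocount)
  groups <- .sample_groups(cfg)
  cases <- names(groups)[groups == "case"]
  ctrls <- names(groups)[groups == "control"]
  per_sample <- list()
  for (cs in cases) {
    rec <- per_sample_de(norm, cs, ctrls, decfg)
    per_sample[[cs]] <- rec
    utils::write.table(rec, .out(cfg, sprintf("de_%s_vs_ctrlpool.tsv", cs)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  couples <- lapply(cfg$samples, function(s) s$couple)
  names(couples) <- .sample_ids(cfg)
  couple_ids <- unique(unlist(couples))
  sib <- list()
  for (cp in couple_ids) {
    members <- names(couples)[vapply(couples, identical, logical(1), cp)]
    asd <- members[groups[members] == "case"]
    ctl <- members[groups[members] == "control"]
    res <- sibling_compare(norm, asd, ctl, decfg)
    sib[[as.character(cp)]] <- res
    utils::write.table(res$records,
                       .out(cfg, sprintf("sibling_couple_%s.tsv", cp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$summary,
                       .out(cfg, sprintf("sibling_summary_%s.tsv", cp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(sib) >= 2) {
    common <- cross_couple_common(lapply(sib, `[[`, "records"))
    utils::write.table(
      data.frame(feature = c(common$up, common$down),
                 direction = rep(c("up", "down"),
                                 c(length(common$up), length(common$down)))),
      .out(cfg, "cross_couple_common.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(per_sample = per_sample, siblings = sib)
}

.stage_targets <- function(cfg) {
  if (is.null(cfg$mirna_targets) && is.null(cfg$pirna_targets)) {
    message("targets: no target maps configured; stage skipped")
    return(invisible(NULL))
  }
  tmap <- list()
  if (!is.null(cfg$mirna_targets))
    tmap <- c(tmap, unclass(load_target_map(cfg$mirna_targets, "miRNA")))
  if (!is.null(cfg$pirna_targets))
    tmap <- c(tmap, unclass(load_target_map(cfg$pirna_targets, "piRNA")))
  groups <- .sample_groups(cfg)
  cases <- names(groups)[groups == "case"]
  de_by_sample <- lapply(cases, function(cs) {
    utils::read.delim(.out(cfg, sprintf("de_%s_vs_ctrlpool.tsv", cs)),
                      stringsAsFactors = FALSE)
  })
  names(de_by_sample) <- cases
  gene_sets <- dysregulated_targets(de_by_sample, tmap, direction = "up")
  common <- common_targets(gene_sets, min_samples = cfg$min_common_samples)
  utils::write.table(common, .out(cfg, "common_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  annos <- list()
  for (gs in cfg$gene_sets) {
    coll <- read_gmt(gs)
    an <- annotate_gene_sets(common$gene, coll)
    base <- tools::file_path_sans_ext(basename(gs))
    utils::write.table(an, .out(cfg, sprintf("gene_set_hits_%s.tsv", base)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    annos[[base]] <- an
  }
  list(common = common, annotations = annos)
}

.stage_microbiome <- function(cfg) {
  if (is.null(cfg$otu_table)) {
    message("microbiome: no OTU table configured; stage skipped")
    return(invisible(NULL))
  }
  groups <- stats::setNames(unlist(cfg$otu_groups), names(cfg$otu_groups))
  ot <- read_otu_table(cfg$otu_table, groups)
  div <- alpha_diversity(ot)
  utils::write.table(div, .out(cfg, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- aggregate_rank(ot, "Family")
  ra <- relative_abundance(fam)
  utils::write.table(
    data.frame(family = rownames(ra$fractions), ra$fractions,
               check.names = FALSE),
    .out(cfg, "family_relative_abundance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  part <- prevalence_partition(fam,
                               presence_threshold = cfg$prevalence$presence_threshold,
                               detection_floor = cfg$prevalence$detection_floor)
  utils::write.table(
    data.frame(family = unlist(part),
               category = rep(names(part), lengths(part))),
    .out(cfg, "family_prevalence_partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  phyla <- rownames(aggregate_rank(ot, "Phylum"))
  ratio <- NULL
  if (all(c("Bacteroidetes", "Firmicutes") %in% phyla)) {
    ratio <- taxon_ratio(ot, "Bacteroidetes", "Firmicutes", "Phylum")
    utils::write.table(
      data.frame(sample = names(ratio$per_sample),
                 ratio = ratio$per_sample,
                 group = ot$groups[names(ratio$per_sample)]),
      .out(cfg, "bacteroidetes_firmicutes_ratio.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(diversity = div, partition = part, ratio = ratio)
}

#' Run a single pipeline stage
#'
#' Stages: `quantify`, `cluster`, `normalize`, `diff`, `targets`,
#' `microbiome`. Later stages read the TSV outputs of earlier ones from the
#' configured output directory, so they can also be fed externally supplied
#' intermediates.
#'
#' @param config config path or list (see [load_run_config()]).
#' @param stage stage name.
#' @return The stage's in-memory result, invisibly.
#' @export
run_stage <- function(config, stage) {
  cfg <- load_run_config(config)
  if (!stage %in% .stage_names)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(.stage_names, collapse = ", "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(stage,
               quantify = .stage_quantify, cluster = .stage_cluster,
               normalize = .stage_normalize, diff = .stage_diff,
               targets = .stage_targets, microbiome = .stage_microbiome)
  res <- tryCatch(fn(cfg), error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes quantify -> cluster -> normalize -> per-sample and sibling DE ->
#' cross-couple intersection -> target intersection -> microbiome summaries,
#' writing every intermediate TSV plus a JSON manifest (package version,
#' parameters, seed, per-file MD5 checksums). Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config config path or list (see [load_run_config()]).
#' @return The manifest (list), invisibly; written to
#'   `manifest.json` in the output directory.
#' @export
run_full <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in .stage_names) {
    message("== stage: ", stage)
    run_stage(cfg, stage)
  }
  files <- sort(setdiff(list.files(cfg$output_dir), "manifest.json"))
  manifest <- list(
    package = "stoolomics",
    version = as.character(utils::packageVersion("stoolomics")),
    seed = cfg$seed,
    parameters = cfg[c("cluster", "tmm", "de", "prevalence",
                       "min_common_samples")],
    outputs = as.list(tools::md5sum(file.path(cfg$output_dir, files)))
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, .out(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
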