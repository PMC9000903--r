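# Build a complete, small synthetic run directory + config for pipeline tests.
build_demo_run <- function(dir, seed = 1L, n_reads = 200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_sim <- sim_config(seed = seed, n_refs = 20, ref_length_range = c(20, 34),
                        per_base_error_rate = 0.002,
                        multimap_family_sizes = c(2))
  refs <- make_reference_set(cfg_sim)
  fasta <- file.path(dir, "reference.fasta")
  write_reference_fasta(refs, fasta)

  samples <- list(
    list(id = "asd_1", group = "case", couple = 1),
    list(id = "ctrl_1", group = "control", couple = 1),
    list(id = "asd_2", group = "case", couple = 2),
    list(id = "ctrl_2", group = "control", couple = 2)
  )
  set.seed(seed + 5000)
  for (i in seq_along(samples)) {
    ab <- setNames(rexp(nrow(refs)) + 0.2, refs$id)
    if (samples[[i]]$group == "case") ab[1:3] <- ab[1:3] * 8
    cfg_i <- cfg_sim; cfg_i$seed <- cfg_sim$seed + 10L * i
    sim <- simulate_reads(refs, ab, cfg_i, n_reads = n_reads)
    fq <- file.path(dir, paste0(samples[[i]]$id, ".fastq"))
    write_reads_fastq(sim$reads, fq)
    samples[[i]]$fastq <- fq
  }

  ot <- simulate_otu_table(30, 4, c("case", "control", "case", "control"),
                           list(control = "Akkermansiaceae"),
                           seed = seed, depth = 4000)
  names(ot$groups) <- c("asd_1", "ctrl_1", "asd_2", "ctrl_2")
  colnames(ot$counts) <- names(ot$groups)
  otu_path <- file.path(dir, "otu_table.tsv")
  write_otu_table(ot, otu_path)

  tm <- file.path(dir, "mirna_targets.tsv")
  writeLines(c("ncrna_id\tgene\tevidence\talignment_support",
               sprintf("%s\tGENE%d\tvalidated\t0", refs$id[1:6],
                       c(1, 2, 2, 3, 4, 5))), tm)
  pm <- file.path(dir, "pirna_targets.tsv")
  writeLines(c("ncrna_id\tgene\tevidence\talignment_support",
               sprintf("%s\tPGENE%d\tpredicted\t%d", refs$id[7:10],
                       c(1, 1, 2, 3), c(5, 5, 4, 6))), pm)
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("PATHWAY_ONE\tdesc\tGENE1\tGENE2\tPGENE1",
               "PATHWAY_TWO\tdesc\tGENE9"), gmt)

  list(
    reference_fasta = fasta,
    samples = samples,
    otu_table = otu_path,
    otu_groups = as.list(ot$groups),
    mirna_targets = tm,
    pirna_targets = pm,
    gene_sets = list(gmt),
    output_dir = file.path(dir, "out"),
    seed = seed
  )
}
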