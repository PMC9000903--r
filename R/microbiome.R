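.RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")

#' Construct an OTU table
#'
#' OTU x sample integer counts with a 7-rank taxonomy lineage per OTU
#' (Kingdom..Species; gaps marked `"unassigned"` or `NA`) and a
#' case/control group label per sample.
#'
#' @param counts non-negative OTU x sample matrix with dimnames.
#' @param taxonomy data.frame with the 7 rank columns, row names = OTU ids.
#' @param groups named character vector (`"case"`/`"control"`) per sample.
#' @return object of class `otu_tab`.
#' @export
otu_table_new <- function(counts, taxonomy, groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(.RANKS %in% names(taxonomy)))
    stop("taxonomy must have the 7 rank columns Kingdom..Species")
  if (!all(rownames(counts) %in% rownames(taxonomy)))
    stop("taxonomy must cover every OTU")
  taxonomy <- taxonomy[rownames(counts), .RANKS, drop = FALSE]
  taxonomy[] <- lapply(taxonomy, function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unassigned"
    x
  })
  if (!all(colnames(counts) %in% names(groups)))
    stop("every sample needs a group label")
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  structure(list(counts = counts, taxonomy = taxonomy, groups = groups),
            class = "otu_tab")
}

#' Read / write an OTU table TSV
#'
#' Layout: `otu_id`, the 7 lineage columns, then one count column per
#' sample. Group labels are supplied separately (they live in the run
#' configuration, not the table).
#'
#' @param path TSV file.
#' @param groups named group vector per sample.
#' @return an `otu_tab` (read) or `path` (write).
#' @export
read_otu_table <- function(path, groups) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "otu_id") stop("first column must be otu_id")
  tax <- df[, .RANKS, drop = FALSE]
  rownames(tax) <- df$otu_id
  counts <- as.matrix(df[, setdiff(names(df), c("otu_id", .RANKS)), drop = FALSE])
  rownames(counts) <- df$otu_id
  otu_table_new(counts, tax, groups)
}

#' @rdname read_otu_table
#' @param ot an `otu_tab`.
#' @export
write_otu_table <- function(ot, path) {
  df <- cbind(data.frame(otu_id = rownames(ot$counts), stringsAsFactors = FALSE),
              ot$taxonomy, as.data.frame(ot$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Counts are summed over OTUs sharing the taxon name at `rank`. OTUs
#' unassigned at that rank are pooled under `unassigned_<parent>`, keyed by
#' their deepest assigned ancestor, so per-sample totals are conserved
#' exactly.
#'
#' @param ot an `otu_tab`.
#' @param rank one of Kingdom, Phylum, Class, Order, Family, Genus, Species.
#' @return taxa x sample count matrix (groups attached as an attribute).
#' @export
aggregate_rank <- function(ot, rank) {
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  ri <- match(rank, .RANKS)
  labels <- vapply(seq_len(nrow(ot$counts)), function(i) {
    tx <- unlist(ot$taxonomy[i, ])
    if (tx[ri] != "unassigned") return(tx[ri])
    anc <- tx[seq_len(ri - 1)]
    anc <- anc[anc != "unassigned"]
    parent <- if (length(anc)) anc[length(anc)] else "root"
    paste0("unassigned_", parent)
  }, character(1))
  agg <- rowsum(ot$counts, labels)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  attr(agg, "groups") <- ot$groups
  agg
}

#' Relative abundances (per sample, and group means)
#'
#' Each sample column is divided by its total (columns sum to 1); the
#' group-level abundance of a taxon is the mean of its member samples'
#' fractions.
#'
#' @param counts taxa x sample matrix (e.g. from [aggregate_rank()]) or an
#'   `otu_tab`.
#' @param groups optional named group vector (taken from the input when
#'   attached).
#' @return list with `fractions` (matrix) and `group_means` (matrix with one
#'   column per group, `NULL` when no groups are known).
#' @export
relative_abundance <- function(counts, groups = NULL) {
  if (inherits(counts, "otu_tab")) {
    groups <- counts$groups
    counts <- counts$counts
  }
  if (is.null(groups)) groups <- attr(counts, "groups")
  tot <- colSums(counts)
  zero <- tot <= 0
  if (any(zero))
    stop("zero-total sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  frac <- sweep(counts, 2, tot, "/")
  gm <- NULL
  if (!is.null(groups)) {
    groups <- groups[colnames(counts)]
    gm <- vapply(unique(groups), function(g)
      rowMeans(frac[, groups == g, drop = FALSE]), numeric(nrow(frac)))
    if (is.null(dim(gm))) gm <- matrix(gm, ncol = length(unique(groups)),
                                       dimnames = list(rownames(frac), unique(groups)))
  }
  list(fractions = frac, group_means = gm)
}

#' Alpha diversity per sample
#'
#' Observed taxa (count > 0), Shannon entropy (natural log) and the
#' Gini-Simpson index 1 - sum(p^2) (so a single-taxon sample scores 0 on
#' both indices and values lie on a 0-1 axis for Simpson). Inverse Simpson
#' is available behind a flag.
#'
#' @param counts taxa x sample matrix or `otu_tab`.
#' @param inverse_simpson report 1/sum(p^2) instead of 1 - sum(p^2).
#' @return data.frame per sample: `sample`, `observed`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(counts, inverse_simpson = FALSE) {
  if (inherits(counts, "otu_tab")) counts <- counts$counts
  if (any(colSums(counts) <= 0)) stop("every sample needs a positive total")
  m <- t(counts)  # vegan wants samples in rows
  data.frame(
    sample = colnames(counts),
    observed = colSums(counts > 0),
    shannon = as.numeric(vegan::diversity(m, index = "shannon")),
    simpson = as.numeric(vegan::diversity(
      m, index = if (inverse_simpson) "invsimpson" else "simpson")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Ratio of two taxa's relative abundances
#'
#' Per-sample ratio of the two taxa's relative abundances at `rank` (e.g.
#' Bacteroidetes/Firmicutes at Phylum), plus the per-group mean of the
#' per-sample ratios. Samples where the denominator taxon is absent are
#' excluded from the group mean with a warning and reported.
#'
#' @param ot an `otu_tab`.
#' @param numerator_taxon,denominator_taxon taxon names at `rank`.
#' @param rank taxonomic rank.
#' @return list with `per_sample` (named ratios, `NA` where the denominator
#'   is zero), `group_ratio` (named per-group means) and
#'   `excluded_samples`.
#' @export
taxon_ratio <- function(ot, numerator_taxon, denominator_taxon, rank = "Phylum") {
  agg <- aggregate_rank(ot, rank)
  for (tx in c(numerator_taxon, denominator_taxon)) {
    if (!tx %in% rownames(agg))
      stop(sprintf("taxon '%s' absent from the taxonomy at rank %s", tx, rank))
  }
  frac <- relative_abundance(agg)$fractions
  num <- frac[numerator_taxon, ]
  den <- frac[denominator_taxon, ]
  ratio <- ifelse(den > 0, num / den, NA_real_)
  excluded <- colnames(agg)[den == 0]
  if (length(excluded))
    warning("denominator zero in: ", paste(excluded, collapse = ", "))
  groups <- ot$groups
  gr <- vapply(unique(groups), function(g)
    mean(ratio[groups == g], na.rm = TRUE), numeric(1))
  list(per_sample = ratio, group_ratio = gr, excluded_samples = excluded)
}

#' Partition taxa by group prevalence
#'
#' A taxon counts as present in a group when its relative abundance exceeds
#' `detection_floor` in more than `presence_threshold` of that group's
#' samples. Taxa are then partitioned into both / case_only / control_only /
#' neither, each listed alphabetically.
#'
#' @param counts taxa x sample matrix (e.g. a Family aggregation) or
#'   `otu_tab`.
#' @param groups named group vector (needed when not attached to `counts`).
#' @param presence_threshold minimum fraction of group samples (default
#'   0.5).
#' @param detection_floor relative-abundance detection floor (default 1e-4).
#' @return list with `both`, `case_only`, `control_only`, `neither`.
#' @export
prevalence_partition <- function(counts, groups = NULL,
                                 presence_threshold = 0.5,
                                 detection_floor = 1e-4) {
  if (inherits(counts, "otu_tab")) {
    groups <- counts$groups
    counts <- counts$counts
  }
  if (is.null(groups)) groups <- attr(counts, "groups")
  if (is.null(groups)) stop("group labels are required")
  groups <- groups[colnames(counts)]
  for (g in c("case", "control")) {
    if (!any(groups == g)) stop("group with zero samples: ", g)
  }
  frac <- relative_abundance(counts)$fractions
  present_in <- function(g) {
    sub <- frac[, groups == g, drop = FALSE]
    rowMeans(sub > detection_floor) > presence_threshold
  }
  in_case <- present_in("case")
  in_ctrl <- present_in("control")
  taxa <- rownames(counts)
  list(
    both = sort(taxa[in_case & in_ctrl]),
    case_only = sort(taxa[in_case & !in_ctrl]),
    control_only = sort(taxa[!in_case & in_ctrl]),
    neither = sort(taxa[!in_case & !in_ctrl])
  )
}
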