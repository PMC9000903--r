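#' Load an ncRNA -> target-gene map
#'
#' Consumes a TSV snapshot with columns `ncrna_id`, `gene`, `evidence`
#' (`validated`/`predicted`) and `alignment_support` (integer). Filtering
#' follows the class: miRNA maps keep only experimentally validated targets;
#' piRNA maps keep, per ncRNA, only the rows achieving that ncRNA's maximum
#' alignment support. Gene symbols are uppercased; duplicate (ncRNA, gene)
#' pairs collapse.
#'
#' @param path TSV file.
#' @param class `"miRNA"` or `"piRNA"`.
#' @return A `target_map`: named list, ncRNA id -> character vector of gene
#'   symbols.
#' @export
load_target_map <- function(path, class = c("miRNA", "piRNA")) {
  class <- match.arg(class)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("ncrna_id", "gene", "evidence", "alignment_support")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("target map is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(structure(list(), class = "target_map"))
  df$gene <- toupper(df$gene)
  if (class == "miRNA") {
    df <- df[df$evidence == "validated", , drop = FALSE]
  } else {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$ncrna_id), function(i) {
      i[df$alignment_support[i] == max(df$alignment_support[i])]
    }))
    df <- df[sort(keep), , drop = FALSE]
  }
  df <- df[nzchar(df$gene), , drop = FALSE]
  out <- lapply(split(df$gene, df$ncrna_id), function(g) sort(unique(g)))
  structure(out, class = "target_map")
}

#' Target genes of dysregulated ncRNAs, per sample
#'
#' For each sample's DE records, takes the union of target genes of the
#' significant ncRNAs whose fold-change sign matches `direction`.
#'
#' @param de_by_sample named list of DE record data.frames (one per sample,
#'   as from [per_sample_de()]).
#' @param target_map a `target_map` (or plain named list of gene vectors).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return named list: sample -> sorted character vector of genes.
#' @export
dysregulated_targets <- function(de_by_sample, target_map,
                                 direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  lapply(de_by_sample, function(rec) {
    sel <- rec$significant
    if (direction == "up") sel <- sel & rec$log2fc > 0
    if (direction == "down") sel <- sel & rec$log2fc < 0
    ids <- rec$feature[sel]
    sort(unique(unlist(target_map[intersect(ids, names(target_map))],
                       use.names = FALSE)))
  })
}

#' Genes shared by several samples' target sets
#'
#' @param gene_sets named list: sample -> gene vector.
#' @param min_samples minimum number of supporting samples (>= 2).
#' @return data.frame (`gene`, `n_samples`, `samples`) in alphabetical gene
#'   order; empty with a warning when `min_samples` exceeds the number of
#'   samples.
#' @export
common_targets <- function(gene_sets, min_samples = 2L) {
  if (min_samples < 2) stop("min_samples must be >= 2")
  empty <- data.frame(gene = character(0), n_samples = integer(0),
                      samples = character(0), stringsAsFactors = FALSE)
  if (min_samples > length(gene_sets)) {
    warning("min_samples exceeds the number of samples")
    return(empty)
  }
  gene_sets <- lapply(gene_sets, unique)
  genes <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  if (!length(genes)) return(empty)
  support <- lapply(genes, function(g)
    names(gene_sets)[vapply(gene_sets, function(s) g %in% s, logical(1))])
  n <- lengths(support)
  keep <- n >= min_samples
  data.frame(
    gene = genes[keep], n_samples = n[keep],
    samples = vapply(support[keep], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes (tab-separated).
#' Symbols are uppercased.
#'
#' @param path GMT file.
#' @return named list of gene vectors (a `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    out[[f[1]]] <- sort(unique(toupper(f[-(1:2)])))
  }
  if (anyDuplicated(names(out))) stop("duplicate gene-set names")
  structure(out, class = "gene_set_collection")
}

#' Annotate genes against a gene-set collection
#'
#' Pure membership annotation (no enrichment statistic): for each set, the
#' intersection with the query and its size; zero-hit sets are omitted.
#'
#' @param genes character vector of query gene symbols.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame (`set`, `n_hits`, `genes`), descending by `n_hits`
#'   then alphabetical.
#' @export
annotate_gene_sets <- function(genes, collection) {
  genes <- unique(toupper(genes))
  hits <- lapply(collection, function(s) sort(intersect(genes, s)))
  hits <- hits[lengths(hits) > 0]
  if (!length(hits))
    return(data.frame(set = character(0), n_hits = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    set = names(hits), n_hits = lengths(hits),
    genes = vapply(hits, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df[order(-df$n_hits, df$set), , drop = FALSE]
}
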