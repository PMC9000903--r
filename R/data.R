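#' Normalized sncRNA counts for two case-control sibling pairs
#'
#' A reference dataset of 52 miRNAs and piRNAs found consistently
#' dysregulated in both of two case-control sibling pairs profiled from
#' stool small-RNA libraries. For each pair it carries the TMM-normalized
#' counts of the affected (`*_asd`) and neurotypical (`*_ctrl`) sibling, the
#' reported pseudocount-1 log2 fold change (2 decimals) and the reported
#' Fisher's-test p-value. Counts are printed at 1-decimal precision, so
#' fold changes recomputed from them can deviate from the reported values
#' by a unit or two in the second decimal.
#'
#' @return data.frame with columns `feature`, `class`, and per couple
#'   `asd`, `ctrl`, `log2fc`, `fisher_p` (prefixed `couple1_`/`couple2_`).
#' @export
sibling_pair_counts <- function() {
  utils::read.delim(
    system.file("extdata", "sibling_pair_counts.tsv", package = "stoolomics"),
    stringsAsFactors = FALSE
  )
}
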