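#' Drop the obligate endosymbiont from an ASV count matrix
#'
#' Carpenter-ant gut communities are dominated by an obligate intracellular
#' endosymbiont (Blochmannia) that is present in every worker; compositional
#' analyses exclude it. Workers whose remaining read total is zero keep an
#' all-zero profile and are flagged rather than dropped, so worker sets stay
#' aligned across layers.
#'
#' @param counts ASV x worker integer matrix.
#' @param taxonomy Tibble with `asv_id` and logical `endosymbiont` flag;
#'   rows must match `rownames(counts)`.
#' @return A list: `counts` (flagged taxa removed), `taxonomy` (subset), and
#'   `all_zero` (named logical per worker).
#' @export
exclude_endosymbiont <- function(counts, taxonomy) {
  stopifnot(all(rownames(counts) %in% taxonomy$asv_id))
  flag <- setNames(taxonomy$endosymbiont, taxonomy$asv_id)[rownames(counts)]
  if (!any(flag)) abort("no taxon is flagged as the endosymbiont")
  kept <- counts[!flag, , drop = FALSE]
  list(
    counts = kept,
    taxonomy = taxonomy[!taxonomy$endosymbiont, , drop = FALSE],
    all_zero = colSums(kept) == 0
  )
}

#' Convert ASV counts to per-worker relative abundances
#'
#' Column-normalizes each worker's profile to proportions. Workers with zero
#' total (e.g., exclusively endosymbiont reads before exclusion) stay all-zero
#' and are flagged; their pairwise Euclidean distances remain defined.
#'
#' @param counts ASV x worker nonnegative matrix.
#' @return A list: `proportions` (same shape) and `all_zero` (named logical).
#' @export
relative_abundance <- function(counts) {
  stopifnot(all(counts >= 0))
  tot <- colSums(counts)
  props <- sweep(counts, 2, ifelse(tot > 0, tot, 1), `/`)
  list(proportions = props, all_zero = tot == 0)
}
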