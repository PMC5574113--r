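# Consequence classes used throughout: every mutation or variant allele is
# one of missense / nonsense / silent / other (other never enters a subset).
CONSEQUENCE_CLASSES <- c("missense", "nonsense", "silent", "other")

MUTATION_SUBSETS <- c("nonsilent", "missense", "nonsense", "silent")

#' Consequence classes selected by a mutation subset
#'
#' The analysis can be restricted to non-silent (missense + nonsense),
#' missense-only, nonsense-only, or silent-only mutations.  Missense-only
#' runs target oncogenes, nonsense-only runs target tumor suppressors, and
#' silent runs serve as a negative control.
#'
#' @param subset One of `"nonsilent"`, `"missense"`, `"nonsense"`, `"silent"`.
#' @return Character vector of consequence classes included in the subset.
#' @export
#' @examples
#' subset_classes("nonsilent")
subset_classes <- function(subset) {
  subset <- match.arg(subset, MUTATION_SUBSETS)
  switch(subset,
    nonsilent = c("missense", "nonsense"),
    missense  = "missense",
    nonsense  = "nonsense",
    silent    = "silent"
  )
}

# A count matrix is an integer matrix, individuals in rows, genes in columns,
# with unique dimnames.  All cohort-level functions use this layout.
validate_count_matrix <- function(cm, what = "count matrix") {
  if (!is.matrix(cm) || !is.numeric(cm))
    stop(what, " must be a numeric matrix (individuals x genes)")
  if (is.null(colnames(cm)))
    stop(what, " must have gene symbols as column names")
  if (anyDuplicated(colnames(cm)))
    stop(what, " has duplicated gene symbols")
  if (!is.null(rownames(cm)) && anyDuplicated(rownames(cm)))
    stop(what, " has duplicated individual ids")
  if (any(cm < 0) || any(!is.finite(cm)))
    stop(what, " must contain finite non-negative counts")
  invisible(cm)
}

new_count_matrix <- function(individuals, genes) {
  matrix(0L, nrow = length(individuals), ncol = length(genes),
         dimnames = list(individuals, genes))
}

# Error message for mismatched gene universes, listing the symmetric
# difference so the user can see which symbols are missing on which side.
check_same_genes <- function(a, b, what_a = "tumor", what_b = "healthy") {
  ga <- colnames(a)
  gb <- colnames(b)
  if (identical(ga, gb)) return(invisible(TRUE))
  if (setequal(ga, gb)) return(invisible(TRUE))
  only_a <- setdiff(ga, gb)
  only_b <- setdiff(gb, ga)
  stop("gene universes differ: ",
       length(only_a), " genes only in ", what_a,
       ifelse(length(only_a), paste0(" (e.g. ", paste(head(only_a, 5), collapse = ", "), ")"), ""),
       "; ", length(only_b), " genes only in ", what_b,
       ifelse(length(only_b), paste0(" (e.g. ", paste(head(only_b, 5), collapse = ", "), ")"), ""))
}
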