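#' Rank normalize one individual's gene counts
#'
#' Each gene receives the number of genes it has a strictly greater count
#' than, divided by the total number of genes.  Tied counts share a score,
#' all zero-count genes score 0, and the largest possible score is
#' `(G - 1) / G`, so scores lie in `[0, 1)`.  The transform depends only on
#' the ordering of counts, making individuals with very different total
#' mutation burdens directly comparable (hypermutated samples need no
#' special handling).
#'
#' @param counts Non-negative numeric vector of per-gene counts.
#' @return Numeric vector of scores in `[0, 1)`, same length and names.
#' @export
#' @examples
#' rank_normalize(c(5, 0, 0, 2))  # 0.75 0 0 0.5
rank_normalize <- function(counts) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  (rank(counts, ties.method = "min") - 1) / length(counts)
}

#' Rank normalize every individual in a cohort
#'
#' Applies [rank_normalize()] independently to each row (individual) of a
#' count matrix, preserving individual and gene order.
#'
#' @param cm Count matrix (individuals x genes).
#' @return Numeric matrix of scores in `[0, 1)` with the same dimnames.
#' @export
rank_normalize_cohort <- function(cm) {
  validate_count_matrix(cm)
  if (nrow(cm) == 0) return(cm + 0)
  G <- ncol(cm)
  out <- t(apply(cm, 1, function(x) (rank(x, ties.method = "min") - 1) / G))
  dimnames(out) <- dimnames(cm)
  out
}
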