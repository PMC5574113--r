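#' Histogram of rank-normalized scores
#'
#' Bins scores into `nbins` evenly spaced bins on `[0, 1]`: bin index is
#' `min(floor(s * nbins), nbins - 1) + 1`, i.e. half-open bins with the top
#' bin closed so a score of exactly 1 is still counted.  Bin heights are
#' fractions of the cohort, so they sum to 1 for a non-empty cohort.
#'
#' @param scores Numeric vector of scores in `[0, 1]`.
#' @param nbins Number of bins (default 100).
#' @return List with elements `bins` (numeric vector of length `nbins`)
#'   and `n` (number of scores).
#' @export
#' @examples
#' score_histogram(c(0, 0, 0.5), nbins = 100)$bins[c(1, 51)]
score_histogram <- function(scores, nbins = 100) {
  if (nbins < 1) stop("nbins must be >= 1")
  if (any(scores < 0 | scores > 1 | !is.finite(scores)))
    stop("scores must lie in [0, 1]")
  n <- length(scores)
  idx <- pmin(floor(scores * nbins), nbins - 1) + 1
  bins <- tabulate(idx, nbins)
  if (n > 0) bins <- bins / n
  list(bins = as.numeric(bins), n = n)
}

# All per-gene histograms of a rank matrix at once: one tabulate() call
# over linearized (bin, gene) indices.  Returns an nbins x G matrix of
# cohort fractions (all-zero columns if the cohort is empty).
cohort_histograms <- function(rm, nbins = 100) {
  G <- ncol(rm)
  n <- nrow(rm)
  H <- matrix(0, nrow = nbins, ncol = G, dimnames = list(NULL, colnames(rm)))
  if (n == 0 || G == 0) return(H)
  if (any(rm < 0 | rm > 1)) stop("scores must lie in [0, 1]")
  bin <- pmin(floor(rm * nbins), nbins - 1) + 1
  idx <- bin + (col(rm) - 1L) * nbins
  H[] <- tabulate(idx, nbins * G) / n
  H
}

# uEMD for every column of paired histogram matrices (nbins x G): one
# top-down sweep carrying the running surplus per gene and accumulating
# its positive part — nbins row operations of O(G) each, no per-gene
# allocations, so total work is linear in G at fixed nbins.
uemd_from_histograms <- function(MH, NH) {
  nbins <- nrow(MH)
  res <- numeric(ncol(MH))
  carry <- numeric(ncol(MH))
  for (b in nbins:1) {
    carry <- carry + MH[b, ] - NH[b, ]
    pos <- carry > 0
    res[pos] <- res[pos] + carry[pos]
  }
  names(res) <- colnames(MH)
  res
}

#' Unidirectional Earth Mover's Difference between two histograms
#'
#' Measures the total mass-times-distance cost of moving tumor-score
#' histogram mass *downward* to cover the healthy-score histogram, ignoring
#' mass that would have to move upward.  Starting from the highest bin, the
#' surplus of `M` over `N` is carried down bin by bin and every positive
#' running surplus is accumulated:
#' `uEMD = sum over B of max(0, sum over b >= B of (M_b - N_b))`.
#' The result is in units of (probability mass) x (bins moved), between 0
#' and `nbins - 1`.
#'
#' @param M,N Histograms from [score_histogram()] (or bare numeric bin
#'   vectors), with equal bin counts, each summing to 1.
#' @return Non-negative scalar uEMD.
#' @export
#' @examples
#' M <- score_histogram(c(0.05, 0.25), nbins = 10)
#' N <- score_histogram(c(0.05, 0.05), nbins = 10)
#' uemd_score(M, N)  # 0.5 mass moved 2 bins = 1
uemd_score <- function(M, N) {
  m <- if (is.list(M)) M$bins else M
  n <- if (is.list(N)) N$bins else N
  if (length(m) != length(n))
    stop("histograms have different bin counts: ", length(m), " vs ", length(n))
  d <- m - n
  sum(pmax(rev(cumsum(rev(d))), 0))
}

#' uEMD scores for all genes
#'
#' Builds the per-gene tumor and healthy score histograms and computes the
#' uEMD for every gene in one pass; total work is linear in the number of
#' genes for a fixed bin count.  Genes whose tumor scores never exceed
#' their healthy scores get a uEMD of 0.
#'
#' @param tumor,healthy Rank matrices from [rank_normalize_cohort()]
#'   sharing the same gene universe (healthy columns are aligned to the
#'   tumor's order).
#' @param nbins Number of histogram bins (default 100).
#' @return Named numeric vector of per-gene uEMD scores.
#' @export
uemd_all_genes <- function(tumor, healthy, nbins = 100) {
  check_same_genes(tumor, healthy)
  if (!identical(colnames(healthy), colnames(tumor)))
    healthy <- healthy[, colnames(tumor), drop = FALSE]
  MH <- cohort_histograms(tumor, nbins)
  NH <- cohort_histograms(healthy, nbins)
  uemd_from_histograms(MH, NH)
}
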