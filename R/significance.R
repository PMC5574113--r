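#' Permute each individual's rank scores across genes
#'
#' Replaces every individual's score vector with an independent uniform
#' random permutation of its own values, leaving gene labels in place.
#' This destroys any gene-specific structure while exactly preserving each
#' individual's score multiset, and is the randomization underlying the
#' decoy null.
#'
#' @param rm Rank matrix (individuals x genes).
#' @return Rank matrix of the same shape and dimnames.
#' @export
permute_ranks <- function(rm) {
  if (ncol(rm) <= 1 || nrow(rm) == 0) return(rm)
  out <- t(apply(rm, 1, sample))
  dimnames(out) <- dimnames(rm)
  out
}

#' Decoy uEMD scores from permuted tumor ranks
#'
#' For each repeat, permutes every tumor individual's ranks across genes
#' and recomputes all-gene uEMDs against the unchanged healthy histograms.
#' The pooled decoy scores form an empirical null for the real uEMDs.
#'
#' @param tumor,healthy Rank matrices sharing a gene universe.
#' @param repeats Number of randomization repeats (default 5).
#' @param nbins Number of histogram bins (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"decoy_set"`: a list with `decoys` (repeats x
#'   genes matrix), `repeats` and `seed`.
#' @export
decoy_uemds <- function(tumor, healthy, repeats = 5, nbins = 100,
                        seed = NULL) {
  check_same_genes(tumor, healthy)
  if (!identical(colnames(healthy), colnames(tumor)))
    healthy <- healthy[, colnames(tumor), drop = FALSE]
  if (repeats < 0) stop("repeats must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  NH <- cohort_histograms(healthy, nbins)
  decoys <- matrix(NA_real_, nrow = repeats, ncol = ncol(tumor),
                   dimnames = list(NULL, colnames(tumor)))
  for (r in seq_len(repeats)) {
    MH <- cohort_histograms(permute_ranks(tumor), nbins)
    decoys[r, ] <- uemd_from_histograms(MH, NH)
  }
  structure(list(decoys = decoys, repeats = repeats, seed = seed),
            class = "decoy_set")
}

# #{x >= u} for each u, exact under ties, via one sort + findInterval:
# findInterval(u, sorted, left.open = TRUE) counts values strictly below u.
count_at_least <- function(u, values) {
  s <- sort(values)
  length(s) - findInterval(u, s, left.open = TRUE)
}

#' Empirical FDR and q-values from real and decoy uEMD scores
#'
#' For each randomization repeat, the FDR at a gene's score `u` is the
#' number of decoy uEMDs at least `u` divided by the number of real gene
#' uEMDs at least `u`, capped at 1; per-gene FDRs are then averaged over
#' repeats.  The q-value of a gene is the minimum averaged FDR over all
#' genes with a score at most its own, which makes q-values non-increasing
#' in uEMD — a conservative empirical FDR control.
#'
#' @param real Named numeric vector of per-gene uEMD scores.
#' @param decoys A `"decoy_set"` from [decoy_uemds()] (or a repeats x genes
#'   matrix) over the same gene universe.
#' @return Data.frame with columns `gene`, `uemd`, `fdr`, `qvalue`, sorted
#'   by decreasing uEMD (ties broken alphabetically by gene).
#' @export
fdr_qvalues <- function(real, decoys) {
  dm <- if (inherits(decoys, "decoy_set")) decoys$decoys else decoys
  if (is.null(dim(dm))) dm <- matrix(dm, nrow = 1)
  if (nrow(dm) < 1)
    stop("at least one decoy repeat is required to estimate the FDR")
  if (ncol(dm) != length(real))
    stop("decoy set covers ", ncol(dm), " genes but ", length(real),
         " real uEMDs were given")
  n_real_ge <- count_at_least(real, real)  # >= 1 always: the gene itself
  fdr_by_rep <- vapply(seq_len(nrow(dm)), function(r) {
    pmin(count_at_least(real, dm[r, ]) / n_real_ge, 1)
  }, numeric(length(real)))
  if (is.null(dim(fdr_by_rep)))
    fdr_by_rep <- matrix(fdr_by_rep, nrow = length(real))
  fdr <- rowMeans(fdr_by_rep)
  # q(g) = min FDR over genes with uEMD <= uEMD(g): running min upward
  asc <- order(real)
  q <- numeric(length(real))
  q[asc] <- cummin(fdr[asc])
  out <- data.frame(gene = names(real), uemd = unname(real),
                    fdr = unname(fdr), qvalue = unname(q),
                    stringsAsFactors = FALSE)
  out[order(-out$uemd, out$gene), , drop = FALSE]
}
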