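#' Differential mutation analysis of a tumor and a healthy cohort
#'
#' Fits the differential-mutation model to paired cohorts of per-individual
#' gene counts: somatic mutation counts from a tumor cohort and summed
#' germline variant scores from a healthy cohort.  Both cohorts share the
#' premise that a gene's propensity for neutral mutation (driven by length,
#' replication timing, expression, ...) is similar in somatic and germline
#' cells, so the germline profile serves as the background against which
#' somatic excess is measured — no covariates and no parameter fitting.
#'
#' Each individual's counts are rank normalized to `[0, 1)`; per gene, the
#' two cohorts' score histograms (`nbins` evenly spaced bins) are compared
#' with a unidirectional Earth Mover's Difference ([uemd_score()]).  Genes
#' whose tumor scores systematically exceed their germline scores get high
#' uEMDs and are candidate drivers.  Significance comes from decoy uEMDs
#' computed after permuting each tumor individual's ranks across genes
#' ([decoy_uemds()]), converted to empirical FDRs and monotone q-values
#' ([fdr_qvalues()]).
#'
#' @param tumor Integer matrix of somatic mutation counts, tumor samples in
#'   rows, genes in columns (see [build_mutation_counts()]).
#' @param healthy Integer matrix of summed germline variant scores, healthy
#'   individuals in rows, genes in columns (see [build_variant_counts()]).
#'   Must share the tumor's gene universe.
#' @param nbins Number of histogram bins (default 100).
#' @param permutations Number of decoy randomization repeats (default 5).
#' @param seed Optional integer seed controlling the decoy permutations.
#' @param q_threshold q-value below which a gene is flagged significant
#'   (default 0.1).
#' @return An object of class `"diffmut"`: a list with `results` (a
#'   data.frame of gene, uemd, fdr, qvalue, rank, significant, sorted by
#'   decreasing uEMD), the per-gene histogram matrices `tumor_hist` and
#'   `healthy_hist`, cohort sizes, and the call parameters.
#' @seealso [run_diffmut()] for the MAF/VCF file interface,
#'   [simulate_counts()] for synthetic cohorts.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, n_tumor = 40,
#'                                   n_healthy = 60, n_drivers = 5),
#'                        seed = 1)
#' fit <- diffmut(subset_counts(sim$tumor, "nonsilent"),
#'                subset_counts(sim$healthy, "nonsilent"), seed = 1)
#' head(fit$results)
diffmut <- function(tumor, healthy, nbins = 100, permutations = 5,
                    seed = NULL, q_threshold = 0.1) {
  validate_count_matrix(tumor, "tumor count matrix")
  validate_count_matrix(healthy, "healthy count matrix")
  check_same_genes(tumor, healthy)
  if (nrow(tumor) == 0) stop("tumor cohort is empty")
  if (nrow(healthy) == 0) stop("healthy cohort is empty")
  if (nbins < 1) stop("nbins must be >= 1")
  if (permutations < 1) stop("at least one permutation repeat is required")
  if (!identical(colnames(healthy), colnames(tumor)))
    healthy <- healthy[, colnames(tumor), drop = FALSE]

  tumor_rm <- rank_normalize_cohort(tumor)
  healthy_rm <- rank_normalize_cohort(healthy)
  MH <- cohort_histograms(tumor_rm, nbins)
  NH <- cohort_histograms(healthy_rm, nbins)
  uemd <- uemd_from_histograms(MH, NH)
  decoys <- decoy_uemds(tumor_rm, healthy_rm, repeats = permutations,
                        nbins = nbins, seed = seed)
  results <- fdr_qvalues(uemd, decoys)
  results$rank <- seq_len(nrow(results))
  results$significant <- results$qvalue < q_threshold
  rownames(results) <- NULL

  structure(list(results = results,
                 tumor_hist = MH, healthy_hist = NH,
                 n_tumor = nrow(tumor), n_healthy = nrow(healthy),
                 n_genes = ncol(tumor), nbins = nbins,
                 permutations = permutations, seed = seed,
                 q_threshold = q_threshold,
                 call = match.call()),
            class = "diffmut")
}

#' @export
print.diffmut <- function(x, n = 10, ...) {
  cat("Differential mutation analysis\n")
  cat(sprintf("  %d genes; %d tumor samples vs %d healthy individuals\n",
              x$n_genes, x$n_tumor, x$n_healthy))
  cat(sprintf("  %d bins, %d decoy permutation(s)%s\n", x$nbins,
              x$permutations,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  %d gene(s) significant at q < %g\n",
              sum(x$results$significant), x$q_threshold))
  cat(sprintf("\nTop %d genes by uEMD:\n", min(n, nrow(x$results))))
  print(head(x$results, n), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.diffmut <- function(object, ...) {
  res <- object$results
  structure(list(n_genes = object$n_genes, n_tumor = object$n_tumor,
                 n_healthy = object$n_healthy,
                 q_threshold = object$q_threshold,
                 n_significant = sum(res$significant),
                 n_nonzero = sum(res$uemd > 0),
                 uemd_quantiles = stats::quantile(res$uemd),
                 top = head(res, 10)),
            class = "summary.diffmut")
}

#' @export
print.summary.diffmut <- function(x, ...) {
  cat("Differential mutation analysis summary\n")
  cat(sprintf("  genes: %d (uEMD > 0 for %d)\n", x$n_genes, x$n_nonzero))
  cat(sprintf("  cohorts: %d tumor / %d healthy\n", x$n_tumor, x$n_healthy))
  cat(sprintf("  significant at q < %g: %d\n", x$q_threshold, x$n_significant))
  cat("  uEMD quantiles:\n")
  print(signif(x$uemd_quantiles, 4))
  cat("\nTop genes:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Extract per-gene uEMD scores from a fit
#'
#' @param object A `"diffmut"` fit.
#' @param ... Unused.
#' @return Named numeric vector of uEMD scores in decreasing order.
#' @export
coef.diffmut <- function(object, ...) {
  setNames(object$results$uemd, object$results$gene)
}

#' @export
as.data.frame.diffmut <- function(x, ...) x$results

#' Genes called significantly differentially mutated
#'
#' @param fit A `"diffmut"` fit.
#' @param q_threshold q-value cutoff; defaults to the fit's own threshold.
#' @return Character vector of gene symbols with q below the threshold.
#' @export
significant_genes <- function(fit, q_threshold = fit$q_threshold) {
  fit$results$gene[fit$results$qvalue < q_threshold]
}

#' Plot a differential mutation fit
#'
#' `which = "uemd"` draws the ranked uEMD curve with the significant genes
#' marked; `which = "gene"` overlays the tumor and healthy score histograms
#' for one gene so the mass the uEMD has to move is visible.
#'
#' @param x A `"diffmut"` fit.
#' @param which `"uemd"` or `"gene"`.
#' @param gene Gene symbol (required for `which = "gene"`; defaults to the
#'   top-ranked gene).
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.diffmut <- function(x, which = c("uemd", "gene"), gene = NULL, ...) {
  which <- match.arg(which)
  res <- x$results
  if (which == "uemd") {
    plot(res$rank, res$uemd, type = "l", log = "x",
         xlab = "gene rank", ylab = "uEMD",
         main = "Per-gene differential mutation", ...)
    sig <- res$significant
    if (any(sig)) points(res$rank[sig], res$uemd[sig], pch = 16, col = 2)
    legend("topright", legend = sprintf("q < %g", x$q_threshold),
           pch = 16, col = 2, bty = "n")
  } else {
    if (is.null(gene)) gene <- res$gene[1]
    if (!gene %in% colnames(x$tumor_hist)) stop("unknown gene: ", gene)
    mids <- (seq_len(x$nbins) - 0.5) / x$nbins
    m <- x$tumor_hist[, gene]
    n <- x$healthy_hist[, gene]
    u <- res$uemd[match(gene, res$gene)]
    plot(mids, n, type = "h", col = "grey60", lwd = 2,
         xlab = "rank-normalized score", ylab = "cohort fraction",
         main = sprintf("%s (uEMD = %.3g)", gene, u),
         ylim = c(0, max(m, n)), ...)
    lines(mids + 0.15 / x$nbins, m, type = "h", col = 2, lwd = 2)
    legend("topright", legend = c("tumor", "healthy"), col = c(2, "grey60"),
           lwd = 2, bty = "n")
  }
  invisible(x)
}
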