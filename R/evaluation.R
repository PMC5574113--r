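#' Read a curated gene list
#'
#' Plain text, one gene symbol per line, with an optional second
#' (tab-separated) column giving the gene's role: `oncogene`, `tsg` or
#' `other-cancer`.
#'
#' @param path File path.
#' @return Data.frame with columns `gene` and `role` (`NA` when absent).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  data.frame(gene = vapply(parts, `[[`, character(1), 1),
             role = vapply(parts, function(p)
               if (length(p) >= 2) p[[2]] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' Positives and exclusions for an evaluation mode
#'
#' Builds the evaluation sets from an annotated cancer-gene table.  Role
#' `oncogene`/`tsg` marks genes implicated through somatic point mutation;
#' `other-cancer` marks cancer genes implicated for other reasons, which
#' are never counted as negatives.  In `"tsg"` mode the oncogenes are also
#' excluded from the negatives (and symmetrically for `"oncogene"` mode),
#' since both groups are real drivers that the other-mode analysis is not
#' expected to find.
#'
#' @param table Data.frame with columns `gene` and `role`.
#' @param mode `"all"`, `"oncogene"` or `"tsg"`.
#' @return List with character vectors `positives` and `exclusions`.
#' @export
split_eval_lists <- function(table, mode = c("all", "oncogene", "tsg")) {
  mode <- match.arg(mode)
  ok <- c("oncogene", "tsg", "other-cancer")
  bad <- setdiff(unique(table$role), ok)
  if (length(bad) > 0)
    stop("unknown role value(s) in gene table: ", paste(bad, collapse = ", "))
  gene_with <- function(roles) unique(table$gene[table$role %in% roles])
  sets <- switch(mode,
    all = list(positives = gene_with(c("oncogene", "tsg")),
               exclusions = gene_with("other-cancer")),
    oncogene = list(positives = gene_with("oncogene"),
                    exclusions = gene_with(c("tsg", "other-cancer"))),
    tsg = list(positives = gene_with("tsg"),
               exclusions = gene_with(c("oncogene", "other-cancer"))))
  if (length(sets$positives) == 0)
    stop("no positive genes for mode '", mode, "'")
  sets$exclusions <- setdiff(sets$exclusions, sets$positives)
  sets
}

#' Fraction of known genes among the top of a ranking
#'
#' @param ranking Character vector of genes, best first.
#' @param positives Character vector of known genes.
#' @param ks Integer cutoffs (each between 1 and `length(ranking)`).
#' @return Named numeric vector: for each k, `|top-k intersect positives| / k`.
#' @export
top_fraction <- function(ranking, positives, ks) {
  if (any(ks <= 0)) stop("cutoffs must be positive")
  if (any(ks > length(ranking)))
    stop("cutoff exceeds ranking length (", length(ranking), ")")
  hits <- cumsum(ranking %in% positives)
  setNames(hits[ks] / ks, ks)
}

#' Area under the precision-recall curve with exclusion-aware negatives
#'
#' Negatives are the universe minus positives minus exclusions; excluded
#' genes are dropped from the evaluation entirely.  The curve is traced
#' over descending score thresholds, processing tied scores as one group,
#' and the area is the step-wise sum `sum (recall_i - recall_{i-1}) *
#' precision_i` (average-precision style).  Invariant under any strictly
#' monotone transform of the scores.
#'
#' @param scores Named numeric vector: the gene universe with scores.
#' @param positives Character vector of positive genes.
#' @param exclusions Character vector of genes removed from the negatives.
#' @return Scalar AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, positives, exclusions = character(0)) {
  genes <- names(scores)
  if (is.null(genes)) stop("scores must be a named vector")
  drop <- genes %in% setdiff(exclusions, positives)
  scores <- scores[!drop]
  lab <- names(scores) %in% positives
  P <- sum(lab)
  if (P == 0) stop("no positive genes in the scored universe")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  lab <- lab[o]
  grp_end <- cumsum(rle(unname(s))$lengths)  # last index of each tie group
  tp <- cumsum(lab)[grp_end]
  n_pred <- grp_end
  recall <- tp / P
  precision <- tp / n_pred
  sum(diff(c(0, recall)) * precision)
}

#' log2 fold change between two AUPRC values
#'
#' Used to compare the same ranking task under two settings, e.g.
#' non-silent vs silent mutations.
#'
#' @param a,b Positive AUPRC values (`a` the setting of interest, `b` the
#'   baseline).
#' @return `log2(a / b)`.
#' @export
log2_fold_change_auprc <- function(a, b) {
  if (b <= 0) stop("baseline AUPRC must be positive")
  if (a <= 0) stop("AUPRC must be positive")
  log2(a / b)
}

#' Spearman correlation between uEMD scores and a per-gene covariate
#'
#' Checks whether differential-mutation scores track a known mutation-rate
#' covariate (gene length, replication time, expression, chromatin state)
#' over the mutated genes; the method's premise is that they should not,
#' because the germline background already absorbs those effects.
#'
#' @param uemds Named numeric vector of per-gene uEMD scores.
#' @param covariate Named numeric vector of per-gene covariate values.
#' @param mutated Character vector of mutated genes over which to test.
#' @return List with `estimate` (Spearman rho), `p.value` and `n`.
#' @export
covariate_correlation <- function(uemds, covariate, mutated) {
  genes <- intersect(intersect(names(uemds), names(covariate)), mutated)
  if (length(genes) < 3)
    stop("need at least 3 mutated genes present in both maps, got ",
         length(genes))
  ct <- suppressWarnings(
    cor.test(uemds[genes], covariate[genes], method = "spearman"))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(genes))
}
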