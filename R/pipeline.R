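#' Run the full differential mutation pipeline from MAF and VCF files
#'
#' Reads a somatic MAF and a multi-sample germline VCF, builds the two
#' count matrices for the chosen mutation subset, and fits [diffmut()].
#' The gene universe defaults to the union of genes seen in both inputs;
#' supply `gene_universe` to fix it externally.
#'
#' @param maf Path to the somatic MAF file.
#' @param vcf Path to the germline multi-sample VCF.
#' @param subset Mutation subset: `"nonsilent"` (default), `"missense"`,
#'   `"nonsense"` or `"silent"`.
#' @param gene_field,gene_bed,class_field Gene and consequence annotation
#'   sources for the VCF; see [read_vcf()].  `gene_bed` may be a file path.
#' @param sex_table Optional path to a two-column sex TSV (see
#'   [read_sex_table()]).
#' @param gene_universe Optional character vector, or path to a one-symbol-
#'   per-line file, fixing the gene universe.
#' @param match_consequence Restrict the germline side to the same
#'   consequence classes as the somatic subset (default `TRUE`; requires
#'   `class_field`).
#' @param normalize_case Uppercase all gene symbols before matching.
#' @param out Optional path for a tab-separated results file (gene, uemd,
#'   fdr, qvalue, rank, significant).  Written atomically: to a temporary
#'   name first, renamed on success.
#' @param nbins,permutations,seed,q_threshold Passed to [diffmut()].
#' @return The `"diffmut"` fit (invisibly if `out` is given).
#' @export
run_diffmut <- function(maf, vcf, subset = "nonsilent",
                        gene_field = "GENE", gene_bed = NULL,
                        class_field = NULL, sex_table = NULL,
                        gene_universe = NULL, match_consequence = TRUE,
                        normalize_case = FALSE, out = NULL,
                        nbins = 100, permutations = 5, seed = NULL,
                        q_threshold = 0.1) {
  subset <- match.arg(subset, MUTATION_SUBSETS)
  if (is.character(gene_bed) && length(gene_bed) == 1 && file.exists(gene_bed))
    gene_bed <- read_gene_bed(gene_bed)
  if (!is.null(gene_bed)) gene_field <- NULL
  sex <- if (!is.null(sex_table)) read_sex_table(sex_table) else NULL
  if (is.character(gene_universe) && length(gene_universe) == 1 &&
      file.exists(gene_universe))
    gene_universe <- readLines(gene_universe)

  records <- read_maf(maf)
  sites <- read_vcf(vcf, gene_field = gene_field, gene_bed = gene_bed,
                    class_field = class_field)
  if (normalize_case) {
    records$gene <- toupper(records$gene)
    for (i in seq_along(sites)) sites[[i]]$gene <- toupper(sites[[i]]$gene)
    if (!is.null(gene_universe)) gene_universe <- toupper(gene_universe)
  }
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(c(records$gene,
                                   vapply(sites, `[[`, character(1), "gene"))))
  }
  if (length(gene_universe) == 0) stop("empty gene universe")

  message("parsed ", nrow(records), " mutation records and ",
          length(sites), " variant sites over ", length(gene_universe),
          " genes")
  tumor <- build_mutation_counts(records, subset, gene_universe)
  healthy <- build_variant_counts(sites, subset, gene_universe, sex = sex,
                                  match_consequence = match_consequence)
  if (nrow(tumor) == 0) stop("no tumor samples found in MAF")
  if (nrow(healthy) == 0) stop("no individuals found in VCF")

  fit <- diffmut(tumor, healthy, nbins = nbins, permutations = permutations,
                 seed = seed, q_threshold = q_threshold)
  if (!is.null(out)) {
    tmp <- paste0(out, ".tmp")
    write.table(fit$results, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    file.rename(tmp, out)
    message("results written to ", out)
    return(invisible(fit))
  }
  fit
}
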