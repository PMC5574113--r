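#' Default mapping from MAF Variant_Classification values to consequence classes
#'
#' Only single-nucleotide point-mutation classes are distinguished:
#' `Missense_Mutation`, `Nonsense_Mutation` and `Silent`.  Every other
#' classification (splice sites, indels, UTR variants, ...) maps to
#' `"other"` and never contributes to any analysis subset.
#'
#' @return Named character vector mapping classification strings to
#'   consequence classes.
#' @export
maf_class_map <- function() {
  c(Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Silent = "silent")
}

#' Read somatic mutations from a MAF file
#'
#' Parses a Mutation Annotation Format (tab-separated, `#` comment lines)
#' file into one record per mutation, classifying each mutation as
#' missense, nonsense, silent, or other.  Each MAF data row is one
#' mutation event; duplicate rows are kept.
#'
#' @param path Path to a MAF file.
#' @param col_gene,col_sample,col_class Column names holding the gene
#'   symbol, tumor sample barcode and variant classification.  Defaults are
#'   the standard MAF headers.
#' @param class_map Named character vector mapping classification values to
#'   consequence classes; unmapped values become `"other"`.
#' @return A data.frame with columns `sample`, `gene`, `consequence`.
#' @export
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
#'              "TP53\tT01\tMissense_Mutation"), maf)
#' read_maf(maf)
read_maf <- function(path,
                     col_gene = "Hugo_Symbol",
                     col_sample = "Tumor_Sample_Barcode",
                     col_class = "Variant_Classification",
                     class_map = maf_class_map()) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  tab <- tryCatch(
    read.delim(path, sep = "\t", comment.char = "#", quote = "",
               check.names = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse MAF file ", path, ": ",
                             conditionMessage(e)))
  for (col in c(col_gene, col_sample, col_class)) {
    if (!col %in% names(tab))
      stop("MAF file ", path, " is missing required column '", col, "'")
  }
  consequence <- unname(class_map[tab[[col_class]]])
  consequence[is.na(consequence)] <- "other"
  out <- data.frame(sample = tab[[col_sample]],
                    gene = tab[[col_gene]],
                    consequence = consequence,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0 && any(!nzchar(out$gene)))
    stop("MAF file contains rows with an empty gene symbol")
  out
}

#' Build the tumor-cohort count matrix from mutation records
#'
#' Counts, per individual and gene, the mutations whose consequence class
#' falls in the chosen subset.  Records for genes outside the gene universe
#' are dropped (with a message).  Every distinct sample id observed in the
#' records appears as a row, even if all of its retained counts are zero:
#' hypermutated or mutation-free samples are never removed.
#'
#' @param records Data.frame as returned by [read_maf()].
#' @param subset One of `"nonsilent"`, `"missense"`, `"nonsense"`, `"silent"`.
#' @param gene_universe Ordered character vector of gene symbols defining
#'   the analysis universe.
#' @return Integer matrix, individuals in rows, `gene_universe` in columns.
#' @export
build_mutation_counts <- function(records, subset = "nonsilent",
                                  gene_universe) {
  classes <- subset_classes(subset)
  if (length(gene_universe) == 0) stop("gene_universe must be non-empty")
  if (anyDuplicated(gene_universe)) stop("gene_universe has duplicates")
  individuals <- unique(records$sample)
  keep_class <- records$consequence %in% classes
  in_universe <- records$gene %in% gene_universe
  n_dropped <- sum(keep_class & !in_universe)
  if (n_dropped > 0)
    message(n_dropped, " mutation record(s) in genes outside the gene universe dropped")
  kept <- records[keep_class & in_universe, , drop = FALSE]
  cm <- new_count_matrix(individuals, gene_universe)
  if (nrow(kept) > 0) {
    tab <- table(factor(kept$sample, levels = individuals),
                 factor(kept$gene, levels = gene_universe))
    cm[] <- as.integer(tab)
  }
  cm
}
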