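#' Read a gene interval map from a BED file
#'
#' BED uses 0-based, half-open intervals; they are converted to 1-based
#' closed intervals internally so they can be compared directly with VCF
#' positions.
#'
#' @param path Path to a BED file with at least columns chrom, start, end,
#'   name (the gene symbol).
#' @return Data.frame with columns `chrom`, `start`, `end` (1-based closed)
#'   and `gene`.
#' @export
read_gene_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4)
    stop("gene BED file must have at least 4 columns (chrom, start, end, gene)")
  data.frame(chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]),
             gene = as.character(bed[[4]]),
             stringsAsFactors = FALSE)
}

#' Read a per-individual sex table
#'
#' @param path Path to a two-column TSV (individual id, sex).  Sex values
#'   are matched case-insensitively against male/female (also m/f);
#'   anything else becomes `"unknown"`.
#' @return Named character vector mapping individual id to
#'   `"male"`/`"female"`/`"unknown"`.
#' @export
read_sex_table <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("sex table must have two columns: id, sex")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("sex table has duplicated individual ids")
  sex <- tolower(as.character(tab[[2]]))
  sex[sex == "m"] <- "male"
  sex[sex == "f"] <- "female"
  sex[!sex %in% c("male", "female")] <- "unknown"
  setNames(sex, ids)
}

# Parse one genotype string into 0-based allele indices; missing calls
# ('.', './.', or NA from the VCF reader) yield integer(0) and are treated
# as homozygous-major.
parse_gt <- function(gt) {
  gt[is.na(gt)] <- "."
  lapply(strsplit(gt, "[/|]"), function(a) {
    a <- a[!is.na(a) & a != "." & nzchar(a)]
    as.integer(a)
  })
}

#' Read germline variant sites from a multi-sample VCF
#'
#' Each VCF record becomes one variant site per overlapping gene.  Gene
#' assignment comes either from an INFO key or from a gene-interval BED
#' map; sites assignable to no gene are dropped with a message, as are all
#' chromosome Y records.  Per-alternate-allele consequence classes can be
#' read from a second INFO key (comma-separated, one value per ALT allele).
#'
#' @param path Path to a VCF 4.x file (optionally bgzipped).
#' @param gene_field INFO key holding the gene symbol, or `NULL` to use
#'   `gene_bed`.
#' @param gene_bed Gene interval map from [read_gene_bed()]; used when
#'   `gene_field` is `NULL`.  A site overlapping several genes is emitted
#'   once per gene.
#' @param class_field Optional INFO key holding per-ALT consequence classes
#'   (`missense`/`nonsense`/`silent`/`other`).  When absent, classes are
#'   `"unknown"` and germline consequence matching must be disabled
#'   downstream.
#' @return List of variant sites; each is a list with elements `chrom`,
#'   `pos`, `gene`, `alleles` (REF first), `gt` (named genotype strings) and
#'   `classes` (per-ALT-index consequence classes).
#' @export
read_vcf <- function(path, gene_field = "GENE", gene_bed = NULL,
                     class_field = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) return(list())
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec,
                                     dimnames = list(NULL, names(gt)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])

  # gene assignment: INFO key, or BED interval overlap (possibly 1-to-many)
  if (!is.null(gene_field)) {
    genes <- vcfR::extract.info(vcf, element = gene_field)
    rec_idx <- seq_len(n_rec)
    drop_na <- is.na(genes) | genes == "."
    n_no_gene <- sum(drop_na)
    rec_idx <- rec_idx[!drop_na]
    genes <- genes[!drop_na]
  } else {
    if (is.null(gene_bed))
      stop("either gene_field or gene_bed must be supplied for gene assignment")
    gr_genes <- GenomicRanges::GRanges(
      gene_bed$chrom, IRanges::IRanges(gene_bed$start, gene_bed$end))
    gr_sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
    rec_idx <- S4Vectors::queryHits(hits)
    genes <- gene_bed$gene[S4Vectors::subjectHits(hits)]
    n_no_gene <- sum(!seq_len(n_rec) %in% rec_idx)
  }
  if (!is.null(class_field)) {
    class_of <- vcfR::extract.info(vcf, element = class_field)
  } else {
    class_of <- rep(NA_character_, n_rec)
  }

  on_y <- chrom[rec_idx] %in% c("Y", "chrY")
  n_y <- sum(on_y)
  rec_idx <- rec_idx[!on_y]
  genes <- genes[!on_y]
  if (n_no_gene > 0)
    message(n_no_gene, " VCF record(s) without gene assignment dropped")
  if (n_y > 0)
    message(n_y, " chromosome Y record(s) dropped")

  sites <- vector("list", length(rec_idx))
  for (k in seq_along(rec_idx)) {
    i <- rec_idx[k]
    alts <- if (is.na(alt[i]) || alt[i] == ".") character(0)
            else strsplit(alt[i], ",", fixed = TRUE)[[1]]
    cls <- if (is.na(class_of[i])) rep("unknown", length(alts))
           else strsplit(class_of[i], ",", fixed = TRUE)[[1]]
    if (length(cls) < length(alts))
      cls <- c(cls, rep("unknown", length(alts) - length(cls)))
    sites[[k]] <- list(chrom = chrom[i], pos = pos[i], gene = genes[k],
                       alleles = c(ref[i], alts),
                       gt = gt[i, ],
                       classes = setNames(cls[seq_along(alts)],
                                          as.character(seq_along(alts))))
  }
  sites
}

#' Cohort-major allele of a variant site
#'
#' The major allele is the allele with the highest total count over all
#' called genotypes in the cohort (the reference allele has no special
#' status).  Ties break to the lowest allele index, so an exact 50/50 split
#' resolves to the reference.
#'
#' @param site A variant site from [read_vcf()].
#' @return 0-based index of the major allele.
#' @export
major_allele <- function(site) {
  idx <- unlist(parse_gt(site$gt))
  if (length(idx) == 0)
    stop("site ", site$chrom, ":", site$pos, " has no called genotypes")
  counts <- tabulate(idx + 1L, nbins = length(site$alleles))
  which.max(counts) - 1L  # which.max takes the first (lowest) on ties
}

#' Per-individual variant scores at one site
#'
#' Each individual scores the number of non-major alleles in their
#' genotype: 0 (absent), 1 (heterozygous) or 2 (homozygous for a non-major
#' allele).  On chromosome X, males are always scored as homozygous (any
#' non-major call scores 2).  Missing genotypes score 0.  Individuals of
#' unknown sex are treated as autosomal on X, with a warning.
#'
#' @param site A variant site from [read_vcf()].
#' @param sex Optional named sex vector from [read_sex_table()].
#' @param major Optional precomputed major allele index.
#' @return Named integer vector of scores in `{0, 1, 2}`.
#' @export
site_scores <- function(site, sex = NULL, major = NULL) {
  if (is.null(major)) major <- major_allele(site)
  alleles <- parse_gt(site$gt)
  score <- vapply(alleles, function(a) sum(a != major), integer(1))
  score <- pmin(score, 2L)
  on_x <- site$chrom %in% c("X", "chrX")
  if (on_x) {
    ids <- names(site$gt)
    s <- if (is.null(sex)) rep("unknown", length(ids)) else {
      out <- sex[ids]
      out[is.na(out)] <- "unknown"
      out
    }
    if (any(s == "unknown"))
      warning("chrX site ", site$chrom, ":", site$pos, ": ",
              sum(s == "unknown"),
              " individual(s) of unknown sex treated as autosomal")
    male <- s == "male"
    score[male & score > 0] <- 2L
  }
  setNames(as.integer(score), names(site$gt))
}

#' Build the healthy-cohort count matrix from variant sites
#'
#' Sums per-site variant scores within each gene.  When consequence
#' matching is on, a site is retained iff any of its non-major alleles has
#' a consequence class inside the subset; sites whose classes are unknown
#' are then dropped.  With matching off every site is retained.
#'
#' @param sites List of variant sites from [read_vcf()].
#' @param subset One of `"nonsilent"`, `"missense"`, `"nonsense"`, `"silent"`.
#' @param gene_universe Optional ordered gene universe; defaults to the
#'   genes observed in `sites`.  Sites in other genes are dropped with a
#'   message.
#' @param sex Optional named sex vector from [read_sex_table()].
#' @param match_consequence Apply the subset's consequence filter to the
#'   germline side (default `TRUE`).
#' @return Integer matrix, individuals in rows, genes in columns.
#' @export
build_variant_counts <- function(sites, subset = "nonsilent",
                                 gene_universe = NULL, sex = NULL,
                                 match_consequence = TRUE) {
  classes <- subset_classes(subset)
  if (length(sites) == 0) {
    return(new_count_matrix(character(0),
                            if (is.null(gene_universe)) character(0)
                            else gene_universe))
  }
  individuals <- names(sites[[1]]$gt)
  site_genes <- vapply(sites, `[[`, character(1), "gene")
  if (is.null(gene_universe)) {
    gene_universe <- unique(site_genes)
  } else {
    n_out <- sum(!site_genes %in% gene_universe)
    if (n_out > 0)
      message(n_out, " variant site(s) in genes outside the gene universe dropped")
  }
  cm <- new_count_matrix(individuals, gene_universe)
  for (site in sites) {
    if (!site$gene %in% gene_universe) next
    major <- major_allele(site)
    if (match_consequence) {
      nonmajor <- setdiff(seq_along(site$alleles) - 1L, major)
      cls <- site$classes[as.character(nonmajor)]
      cls[is.na(cls)] <- "unknown"  # the REF allele when an ALT is major
      if (!any(cls %in% classes)) next
    }
    sc <- site_scores(site, sex = sex, major = major)
    cm[, site$gene] <- cm[, site$gene] + sc[individuals]
  }
  cm
}
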