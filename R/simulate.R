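#' Configuration for the synthetic paired-cohort generator
#'
#' The generator emulates the structural premise of differential mutation
#' analysis: every gene has a latent count propensity `lambda_g` (standing
#' in for length, replication timing and expression effects) that is shared
#' between the tumor and healthy cohorts, while a planted set of driver
#' genes carries a somatic-only rate excess `beta` in its boosted
#' consequence classes.  Per-class counts are Poisson:
#' `tumor count ~ Pois(lambda_g * t_j * mix_c * beta_gc)` and
#' `healthy count ~ Pois(lambda_g * d_i * mix_c)`, with per-individual
#' exposures `t_j`, `d_i` log-normal around 1.
#'
#' @param n_genes,n_tumor,n_healthy Cohort dimensions.
#' @param n_drivers Number of planted driver genes.
#' @param beta Somatic rate multiplier for drivers in boosted classes.
#' @param driver_classes Consequence classes carrying the driver excess
#'   (default missense + nonsense; set to `"missense"` only to emulate
#'   oncogene-style drivers, `"nonsense"` for TSG-style ones).
#' @param driver_sets Optional list of lists with elements `n`, `beta`,
#'   `classes` to plant several disjoint driver sets with different
#'   boosted classes; overrides `n_drivers`/`beta`/`driver_classes`.
#' @param lambda_meanlog,lambda_sdlog Log-normal parameters of the shared
#'   per-gene propensity (default `meanlog = log(0.5)`, `sdlog = 1`).
#' @param exposure_sdlog Log-normal sd of per-individual exposures
#'   (meanlog 0).
#' @param mix Probabilities of missense/nonsense/silent consequences
#'   (must sum to 1).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_tumor = 200, n_healthy = 500,
                       n_drivers = 25, beta = 5,
                       driver_classes = c("missense", "nonsense"),
                       driver_sets = NULL,
                       lambda_meanlog = log(0.5), lambda_sdlog = 1,
                       exposure_sdlog = 0.3,
                       mix = c(missense = 0.6, nonsense = 0.1,
                               silent = 0.3)) {
  mix <- mix[c("missense", "nonsense", "silent")]
  if (any(is.na(mix)) || abs(sum(mix) - 1) > 1e-9 || any(mix < 0))
    stop("mix must give non-negative missense/nonsense/silent probabilities summing to 1")
  if (is.null(driver_sets)) {
    driver_sets <- if (n_drivers > 0)
      list(list(n = n_drivers, beta = beta, classes = driver_classes))
    else list()
  }
  total_drivers <- sum(vapply(driver_sets, `[[`, numeric(1), "n"))
  if (total_drivers > n_genes) stop("more drivers than genes")
  for (ds in driver_sets) {
    if (ds$beta <= 0) stop("driver beta must be positive")
    if (!all(ds$classes %in% c("missense", "nonsense", "silent")))
      stop("driver classes must be missense/nonsense/silent")
  }
  structure(list(n_genes = n_genes, n_tumor = n_tumor,
                 n_healthy = n_healthy, driver_sets = driver_sets,
                 lambda_meanlog = lambda_meanlog,
                 lambda_sdlog = lambda_sdlog,
                 exposure_sdlog = exposure_sdlog, mix = mix),
            class = "sim_config")
}

#' Simulate paired tumor/healthy per-class count matrices
#'
#' Draws the latent propensities, exposures and per-class Poisson counts of
#' a paired cohort (see [sim_config()]), without touching the file system.
#' Driver genes are sampled uniformly (disjointly across driver sets).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical config + seed gives identical draws.
#' @return List with `tumor` and `healthy` (each a list of
#'   individuals x genes count matrices named missense/nonsense/silent),
#'   `truth` (data.frame gene, driver, driver_set, boosted_classes),
#'   `lambda`, `tumor_exposure`, `healthy_exposure`, `config`.
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  tumor_ids <- sprintf("T%04d", seq_len(config$n_tumor))
  healthy_ids <- sprintf("H%04d", seq_len(config$n_healthy))
  lambda <- setNames(rlnorm(config$n_genes, config$lambda_meanlog,
                            config$lambda_sdlog), genes)
  t_exp <- setNames(rlnorm(config$n_tumor, 0, config$exposure_sdlog),
                    tumor_ids)
  d_exp <- setNames(rlnorm(config$n_healthy, 0, config$exposure_sdlog),
                    healthy_ids)

  truth <- data.frame(gene = genes, driver = FALSE,
                      driver_set = NA_integer_,
                      boosted_classes = NA_character_,
                      stringsAsFactors = FALSE)
  pool <- genes
  boost <- sapply(names(config$mix), function(cl)
    setNames(rep(1, config$n_genes), genes))  # genes x classes
  for (k in seq_along(config$driver_sets)) {
    ds <- config$driver_sets[[k]]
    chosen <- sample(pool, ds$n)
    pool <- setdiff(pool, chosen)
    truth$driver[truth$gene %in% chosen] <- TRUE
    truth$driver_set[truth$gene %in% chosen] <- k
    truth$boosted_classes[truth$gene %in% chosen] <-
      paste(ds$classes, collapse = "+")
    boost[chosen, ds$classes] <- ds$beta
  }

  draw <- function(ids, exposure, boost_col) {
    out <- list()
    for (cl in names(config$mix)) {
      rate <- outer(exposure, lambda * config$mix[[cl]] *
                      (if (boost_col) boost[, cl] else 1))
      m <- matrix(rpois(length(rate), rate), nrow = length(ids),
                  ncol = length(genes), dimnames = list(ids, genes))
      out[[cl]] <- m
    }
    out
  }
  tumor <- draw(tumor_ids, t_exp, boost_col = TRUE)
  healthy <- draw(healthy_ids, d_exp, boost_col = FALSE)
  list(tumor = tumor, healthy = healthy, truth = truth, lambda = lambda,
       tumor_exposure = t_exp, healthy_exposure = d_exp, config = config)
}

#' Collapse per-class count matrices into one subset count matrix
#'
#' @param class_counts List of per-class count matrices (as in the `tumor`
#'   or `healthy` component of [simulate_counts()]).
#' @param subset One of `"nonsilent"`, `"missense"`, `"nonsense"`, `"silent"`.
#' @return Single count matrix, the sum over the subset's classes.
#' @export
subset_counts <- function(class_counts, subset = "nonsilent") {
  classes <- intersect(subset_classes(subset), names(class_counts))
  if (length(classes) == 0) stop("no matching classes in class_counts")
  Reduce(`+`, class_counts[classes])
}

# Inverse of maf_class_map(), for writing synthetic MAF rows.
class_to_maf <- c(missense = "Missense_Mutation",
                  nonsense = "Nonsense_Mutation",
                  silent = "Silent")

write_synthetic_maf <- function(tumor_counts, path) {
  rows <- list()
  for (cl in names(tumor_counts)) {
    m <- tumor_counts[[cl]]
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    reps <- m[nz]
    rows[[cl]] <- data.frame(
      Hugo_Symbol = rep(colnames(m)[nz[, 2]], reps),
      Tumor_Sample_Barcode = rep(rownames(m)[nz[, 1]], reps),
      Variant_Classification = class_to_maf[[cl]],
      stringsAsFactors = FALSE)
  }
  maf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Hugo_Symbol = character(0),
               Tumor_Sample_Barcode = character(0),
               Variant_Classification = character(0))
  maf <- maf[order(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode,
                   maf$Variant_Classification), , drop = FALSE]
  con <- file(path, "wb")  # binary mode: fixed '\n' endings for determinism
  on.exit(close(con))
  writeLines(paste(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                     "Variant_Classification"), collapse = "\t"), con)
  if (nrow(maf) > 0)
    writeLines(paste(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode,
                     maf$Variant_Classification, sep = "\t"), con)
  invisible(path)
}

# Realize a vector of per-individual summed dosages as biallelic sites:
# enough sites that no individual needs more than 2 alleles per site, and
# each unit allocated round-robin (offset by individual) so no site's
# cohort alt count can exceed the ref count (the reference stays major).
dosage_sites <- function(cnt) {
  n <- length(cnt)
  total <- sum(cnt)
  if (total == 0) return(matrix(0L, nrow = 0, ncol = n))
  S <- max(1, ceiling(max(cnt) / 2), ceiling(total / n))
  repeat {
    dos <- matrix(0L, nrow = S, ncol = n)
    for (i in which(cnt > 0)) {
      slots <- ((i - 1 + seq_len(cnt[i]) - 1) %% S) + 1
      dos[, i] <- tabulate(slots, S)
    }
    if (all(rowSums(dos) <= n)) return(dos)
    S <- S + 1
  }
}

write_synthetic_vcf <- function(healthy_counts, paths) {
  ids <- rownames(healthy_counts[[1]])
  genes <- colnames(healthy_counts[[1]])
  gt_str <- c("0|0", "0|1", "1|1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=VC,Number=A,Type=String,Description=\"Consequence class per ALT allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- character(0)
  bed <- character(0)
  pos_next <- 1000L
  for (g in genes) {
    first <- pos_next
    last <- first
    for (cl in names(healthy_counts)) {
      dos <- dosage_sites(healthy_counts[[cl]][, g])
      if (nrow(dos) == 0) next
      for (s in seq_len(nrow(dos))) {
        body <- c(body, paste(c(
          "1", pos_next, ".", "A", "C", ".", "PASS",
          sprintf("GENE=%s;VC=%s", g, cl), "GT",
          gt_str[dos[s, ] + 1L]), collapse = "\t"))
        last <- pos_next
        pos_next <- pos_next + 10L
      }
    }
    bed <- c(bed, paste("1", first - 1L, max(last, first), g, sep = "\t"))
    pos_next <- max(pos_next, first + 10L)
  }
  con <- file(paths$vcf, "wb")
  writeLines(c(header, body), con)
  close(con)
  con <- file(paths$bed, "wb")
  writeLines(bed, con)
  close(con)
  invisible(paths)
}

#' Simulate a paired cohort and write it as standard files
#'
#' Runs [simulate_counts()] and realizes the draws as a somatic MAF
#' (tumor), a multi-sample VCF 4.2 with `GENE`/`VC` INFO annotations
#' (healthy; biallelic sites whose summed 0/1/2 dosages reproduce the
#' drawn counts exactly, with the reference always the cohort-major
#' allele), a gene-interval BED map, a sex table and a truth-label TSV.
#' Output is byte-identical for identical config + seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List with file paths (`maf`, `vcf`, `gene_bed`, `sex_table`,
#'   `truth`) and the underlying `sim` draws from [simulate_counts()].
#' @export
simulate_cohorts <- function(config, seed, dir) {
  sim <- simulate_counts(config, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(maf = file.path(dir, "tumor.maf"),
                vcf = file.path(dir, "healthy.vcf"),
                bed = file.path(dir, "genes.bed"),
                sex_table = file.path(dir, "sex.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_synthetic_maf(sim$tumor, paths$maf)
  write_synthetic_vcf(sim$healthy, paths)
  ids <- rownames(sim$healthy[[1]])
  con <- file(paths$sex_table, "wb")
  writeLines(paste(ids, rep(c("male", "female"), length.out = length(ids)),
                   sep = "\t"), con)
  close(con)
  con <- file(paths$truth, "wb")
  writeLines(c(paste(names(sim$truth), collapse = "\t"),
               do.call(paste, c(lapply(sim$truth, as.character),
                                sep = "\t"))), con)
  close(con)
  c(list(gene_bed = paths$bed), paths[c("maf", "vcf", "sex_table", "truth")],
    list(sim = sim))
}

#' Evaluate a fit against planted driver truth
#'
#' @param results A `"diffmut"` fit or its `results` data.frame.
#' @param truth Truth data.frame from [simulate_counts()] (columns `gene`,
#'   `driver`).
#' @param ks Top-k cutoffs for [top_fraction()]; defaults to the number of
#'   planted drivers.
#' @return List with `auprc`, `top_fraction` and `n_drivers`.
#' @export
truth_eval <- function(results, truth, ks = NULL) {
  res <- if (inherits(results, "diffmut")) results$results else results
  if (!setequal(res$gene, truth$gene))
    stop("results and truth cover different gene universes")
  positives <- truth$gene[truth$driver]
  if (is.null(ks)) ks <- length(positives)
  scores <- setNames(res$uemd, res$gene)
  list(auprc = auprc(scores, positives),
       top_fraction = top_fraction(res$gene[order(-res$uemd, res$gene)],
                                   positives, ks),
       n_drivers = length(positives))
}
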