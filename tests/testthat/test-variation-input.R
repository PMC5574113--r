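toy_sites <- function() {
  ids <- c("I1", "I2", "I3")
  records <- data.frame(
    chrom = c("1", "1", "Y", "X"),
    pos = c(100, 200, 300, 400),
    ref = "A", alt = "C",
    info = c("GENE=A;VC=missense", "GENE=B;VC=silent",
             "GENE=C;VC=missense", "GENE=D;VC=missense"))
  gts <- rbind(c("0|0", "0|1", "1|1"),
               c("1|1", "1|1", "0|1"),
               c("0|1", "0|0", "0|0"),
               c("1", "0|1", "0|0"))
  list(path = write_toy_vcf(records, gts, ids), ids = ids)
}

test_that("VCF parsing drops chromosome Y and keeps invariant sites", {
  sites <- suppressMessages(read_vcf(toy_sites()$path, gene_field = "GENE",
                    class_field = "VC"))
  expect_equal(vapply(sites, `[[`, character(1), "gene"),
               c("A", "B", "D"))  # the chrY site is gone
  flat <- write_toy_vcf(
    data.frame(chrom = "1", pos = 1, ref = "A", alt = "C",
               info = "GENE=E;VC=silent"),
    matrix(c("0|0", "0|0"), nrow = 1), c("I1", "I2"))
  sites_flat <- read_vcf(flat, gene_field = "GENE", class_field = "VC")
  expect_length(sites_flat, 1)  # retained even though nobody carries it
  expect_equal(unname(site_scores(sites_flat[[1]])), c(0L, 0L))
})

test_that("major allele is the cohort-wide most common, ties to lowest index", {
  sites <- suppressMessages(read_vcf(toy_sites()$path, gene_field = "GENE",
                    class_field = "VC"))
  # {0|0, 0|1, 1|1}: ref 3 vs alt 3, tie resolves to the reference
  expect_equal(major_allele(sites[[1]]), 0L)
  # {1|1, 1|1, 0|1}: alt 5 vs ref 1
  expect_equal(major_allele(sites[[2]]), 1L)
  s <- sites[[1]]
  s$gt[] <- "0|0"
  expect_equal(major_allele(s), 0L)
  s$gt[] <- "."
  expect_error(major_allele(s), "no called genotypes")
})

test_that("site scores count non-major alleles with sex-chromosome rules", {
  sites <- suppressMessages(read_vcf(toy_sites()$path, gene_field = "GENE",
                    class_field = "VC"))
  # major = ref: absent / het / hom -> 0 / 1 / 2
  expect_equal(unname(site_scores(sites[[1]])), c(0L, 1L, 2L))
  # major = alt: 1|1 -> 0, 0|1 -> 1, 0|0 -> 2
  expect_equal(unname(site_scores(sites[[2]])), c(0L, 0L, 1L))
  s22 <- sites[[2]]
  s22$gt <- c(I1 = "0|0", I2 = "1|1", I3 = "1|1")
  expect_equal(unname(site_scores(s22)), c(2L, 0L, 0L))
  # male hemizygous non-major on chrX scores as homozygous
  sex <- c(I1 = "male", I2 = "female", I3 = "female")
  x <- sites[[3]]
  expect_equal(x$chrom, "X")
  expect_equal(unname(site_scores(x, sex = sex)), c(2L, 1L, 0L))
  # unknown sex on chrX warns and falls back to autosomal counting
  expect_warning(sc <- site_scores(x), "unknown sex")
  expect_equal(unname(sc), c(1L, 1L, 0L))
})

test_that("variant counts sum filtered site scores per gene", {
  ids <- c("I1", "I2")
  records <- data.frame(
    chrom = "1", pos = c(10, 20, 30), ref = "A", alt = "C",
    info = c("GENE=A;VC=missense", "GENE=A;VC=missense",
             "GENE=A;VC=silent"))
  gts <- rbind(c("0|1", "0|0"), c("1|1", "0|1"), c("0|1", "0|1"))
  sites <- read_vcf(write_toy_vcf(records, gts, ids),
                    gene_field = "GENE", class_field = "VC")
  # site 2's ALT is the cohort-major allele, so its "variant" is the REF
  # allele, whose class is unknown -> dropped under consequence matching
  cm <- build_variant_counts(sites, "missense")
  expect_equal(unname(cm[, "A"]), c(1L, 0L))
  cm_sil <- build_variant_counts(sites, "silent")
  expect_equal(unname(cm_sil[, "A"]), c(1L, 1L))
  cm_all <- build_variant_counts(sites, "missense", match_consequence = FALSE)
  expect_equal(unname(cm_all[, "A"]), c(2L, 2L))
  expect_equal(dim(build_variant_counts(list(), "missense")), c(0, 0))
  # gene count can never exceed twice the number of sites in the gene
  expect_true(all(cm_all <= 2 * length(sites)))
})

test_that("BED gene maps assign sites to every overlapping gene", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t150\tA", "1\t50\t300\tB"), bed)
  records <- data.frame(chrom = "1", pos = c(100, 200), ref = "A",
                        alt = "C", info = c(".", "."))
  gts <- rbind(c("0|1", "0|0"), c("0|1", "0|1"))
  sites <- read_vcf(write_toy_vcf(records, gts, c("I1", "I2")),
                    gene_field = NULL, gene_bed = read_gene_bed(bed))
  # pos 100 overlaps A and B; pos 200 only B
  expect_equal(sort(vapply(sites, `[[`, character(1), "gene")),
               c("A", "B", "B"))
  # unknown-class sites are kept only when matching is disabled
  cm <- build_variant_counts(sites, "missense", match_consequence = FALSE)
  expect_equal(unname(cm[, "B"]), c(2L, 1L))
  expect_equal(sum(build_variant_counts(sites, "missense")), 0)
})

test_that("missing genotypes are scored as homozygous-major", {
  records <- data.frame(chrom = "1", pos = 10, ref = "A", alt = "C",
                        info = "GENE=A;VC=missense")
  sites <- read_vcf(write_toy_vcf(records, matrix(c("./.", "0|1"), 1),
                                  c("I1", "I2")),
                    gene_field = "GENE", class_field = "VC")
  expect_equal(unname(site_scores(sites[[1]])), c(0L, 1L))
})
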