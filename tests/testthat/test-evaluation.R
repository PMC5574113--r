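test_that("top-k fractions count known genes among the leaders", {
  ranking <- c("A", "B", "C", "D", "E", "F")
  expect_equal(unname(top_fraction(ranking, c("A", "C"), 4)), 0.5)
  expect_equal(unname(top_fraction(ranking, ranking, c(1, 3, 6))),
               c(1, 1, 1))
  expect_equal(unname(top_fraction(ranking, c("X", "Y"), c(2, 6))), c(0, 0))
  # at k = universe size the fraction is the prevalence
  expect_equal(unname(top_fraction(ranking, c("A", "F"), 6)), 2 / 6)
  expect_error(top_fraction(ranking, "A", 0), "positive")
  expect_error(top_fraction(ranking, "A", 7), "exceeds")
})

test_that("AUPRC handles perfect, flat, and interleaved rankings", {
  s <- setNames(c(4, 3, 2, 1), c("p1", "n1", "p2", "n2"))
  perfect <- setNames(c(4, 3, 2, 1), c("p1", "p2", "n1", "n2"))
  expect_equal(auprc(perfect, c("p1", "p2")), 1)
  flat <- setNames(rep(1, 10), paste0("g", 1:10))
  expect_equal(auprc(flat, paste0("g", 1:3)), 0.3)  # prevalence
  # + - + - : precision 1 at recall .5, 2/3 at recall 1
  expect_equal(auprc(s, c("p1", "p2")), 0.5 * 1 + 0.5 * (2 / 3))
  expect_error(auprc(s, c("zz")), "no positive")
})

test_that("AUPRC is invariant under monotone transforms and exclusion-aware", {
  set.seed(13)
  s <- setNames(runif(40), paste0("g", 1:40))
  pos <- paste0("g", sample(40, 8))
  expect_equal(auprc(exp(5 * s), pos), auprc(s, pos))
  expect_equal(auprc(rank(s), pos), auprc(s, pos))
  # excluding a top-scoring non-positive can only help
  top_neg <- names(sort(s[setdiff(names(s), pos)], decreasing = TRUE))[1]
  expect_gte(auprc(s, pos, exclusions = top_neg), auprc(s, pos))
  # genes both positive and excluded stay positive
  expect_equal(auprc(s, pos, exclusions = pos[1]), auprc(s, pos))
})

test_that("log2 AUPRC fold change", {
  expect_equal(log2_fold_change_auprc(0.3, 0.3), 0)
  expect_equal(log2_fold_change_auprc(0.8, 0.2), 2)
  expect_equal(log2_fold_change_auprc(0.2, 0.05), 2)
  expect_error(log2_fold_change_auprc(0.2, 0), "positive")
})

test_that("covariate correlation is Spearman over mutated genes only", {
  u <- setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  expect_equal(covariate_correlation(u, u, names(u))$estimate, 1)
  expect_equal(covariate_correlation(u, -u, names(u))$estimate, -1)
  cv <- setNames(c(2, 1, 4, 3), names(u))
  expect_equal(covariate_correlation(u, cv, names(u))$estimate, 0.6)
  # restriction to mutated genes: drop d, recompute on 3 genes
  res <- covariate_correlation(u, cv, c("a", "b", "c"))
  expect_equal(res$n, 3)
  expect_error(covariate_correlation(u, cv, c("a", "b")), "at least 3")
})

test_that("evaluation lists split by driver role with symmetric exclusions", {
  tab <- data.frame(gene = c("A", "B", "C"),
                    role = c("oncogene", "tsg", "other-cancer"))
  tsg <- split_eval_lists(tab, "tsg")
  expect_equal(tsg$positives, "B")
  expect_equal(sort(tsg$exclusions), c("A", "C"))
  onc <- split_eval_lists(tab, "oncogene")
  expect_equal(onc$positives, "A")
  expect_equal(sort(onc$exclusions), c("B", "C"))
  all_mode <- split_eval_lists(tab, "all")
  expect_equal(sort(all_mode$positives), c("A", "B"))
  expect_equal(all_mode$exclusions, "C")
  no_other <- split_eval_lists(tab[1:2, ], "all")
  expect_equal(no_other$exclusions, character(0))
  expect_error(split_eval_lists(data.frame(gene = "A", role = "driver"),
                                "all"), "unknown role")
  expect_error(split_eval_lists(tab[0, ], "all"), "no positive")
})

test_that("gene lists read symbols with optional roles", {
  f <- tempfile()
  writeLines(c("# a comment", "TP53\ttsg", "KRAS\toncogene", "MYC", ""), f)
  gl <- read_gene_list(f)
  expect_equal(gl$gene, c("TP53", "KRAS", "MYC"))
  expect_equal(gl$role, c("tsg", "oncogene", NA))
})
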