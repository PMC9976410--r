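# Divergence score, 25/50/25 classification, fold-change correlations,
# species dendrogram and functional-group comparisons.

test_that("divergence score evaluates the displayed formula", {
  expect_equal(divergence_score(1.0, 0.5, 0.0), log(0.625))
  expect_equal(round(divergence_score(1.0, 0.5, 0.0), 4), -0.47)
  # symmetric in mouse and rat
  expect_equal(divergence_score(1.0, 0.0, 0.5), divergence_score(1.0, 0.5, 0.0))
  # zero discrepancy hits the floor
  expect_equal(divergence_score(2.2, 2.2, 2.2), log(1e-12))
  expect_equal(divergence_score(0, 0, 0, floor = 1e-6), log(1e-6))
  expect_error(divergence_score(Inf, 0, 0), class = "crossmac_bad_input")
})

test_that("divergence score matches a naive independent evaluation on 1000 random triples", {
  set.seed(99)
  for (i in 1:1000) {
    l <- rnorm(3, 0, 2)
    expect_equal(divergence_score(l[1], l[2], l[3]),
                 oracle_divergence(l[1], l[2], l[3]), tolerance = 1e-9)
  }
})

test_that("classification splits floor(n/4) / rest / floor(n/4)", {
  rec <- tibble::tibble(gene = sprintf("g%02d", 1:8), divergence = 1:8)
  got <- classify_divergence(rec)
  expect_setequal(got$gene[got$group == "high"], c("g07", "g08"))
  expect_setequal(got$gene[got$group == "low"], c("g01", "g02"))
  expect_setequal(got$gene[got$group == "medium"], c("g03", "g04", "g05", "g06"))

  rec636 <- tibble::tibble(gene = sprintf("g%04d", 1:636),
                           divergence = rnorm(636))
  tab <- table(classify_divergence(rec636)$group)
  expect_equal(unname(tab[c("high", "medium", "low")]),
               c(159L, 318L, 159L), ignore_attr = TRUE)
})

test_that("ties are resolved by gene identifier and the partition is exact", {
  rec <- tibble::tibble(gene = sprintf("g%02d", 1:10), divergence = rep(1, 10))
  got <- classify_divergence(rec)
  expect_setequal(got$gene[got$group == "high"], c("g01", "g02"))
  expect_setequal(got$gene[got$group == "low"], c("g09", "g10"))
  expect_equal(sum(table(got$group)), 10)
  expect_error(classify_divergence(rec[1:3, ]), class = "crossmac_bad_input")
})

test_that("Spearman rho hits the exact endpoints and a 5-point oracle", {
  x <- c(0.2, 1.4, -0.3, 2.2, 0.9)
  up <- fc_correlation(x, 2 * x + 1)
  expect_equal(up$rho[1], 1)
  down <- fc_correlation(x, -x)
  expect_equal(down$rho[1], -1)
  y <- c(1.0, 0.1, 0.7, -0.5, 2.0)
  # independent oracle: Pearson correlation of the rank vectors
  expect_equal(fc_correlation(x, y)$rho[1], cor(rank(x), rank(y)))
  expect_error(fc_correlation(rep(1, 5), x), class = "crossmac_constant_input")
})

test_that("fold-change triples join three species and flag DEGs", {
  orth <- tibble::tibble(human = c("A", "B", "C"), mouse = c("a", "b", "c"),
                         rat = c("ra", "rb", "rc"))
  de <- function(genes, lfc, padj) {
    tibble::tibble(gene = genes, log_fc = lfc, pct_in_group = 1,
                   pct_out_group = 1, p_value = padj, p_adjusted = padj)
  }
  tr <- fold_change_triples(de(c("A", "B"), c(1, 2), c(0.01, 0.2)),
                            de(c("a", "b"), c(1.1, 2.1), c(0.2, 0.2)),
                            de(c("ra", "rb", "rc"), c(0.9, 1.9, 1), c(0.01, 0.01, 0.01)),
                            orth)
  expect_equal(tr$gene, c("A", "B"))   # C is absent from two tables
  expect_equal(tr$de_any, c(TRUE, TRUE))
  expect_equal(tr$de_mouse, c(FALSE, FALSE))
  dup <- tibble::tibble(human = c("A", "A"), mouse = c("a", "a2"),
                        rat = c("ra", "ra2"))
  expect_error(fold_change_triples(de("A", 1, 1), de("a", 1, 1),
                                   de("ra", 1, 1), dup),
               class = "crossmac_bad_input")
})

test_that("duplicating the mouse column joins the rodents at distance zero", {
  set.seed(4)
  fc <- cbind(human = rnorm(30), mouse = rnorm(30))
  fc <- cbind(fc, rat = fc[, "mouse"])
  tree <- species_dendrogram(fc)
  expect_equal(first_join(tree), c("mouse", "rat"))
  expect_equal(tree$hclust$height[1], 0, tolerance = 1e-12)
})

test_that("the dendrogram is invariant to row permutation", {
  set.seed(5)
  fc <- cbind(human = rnorm(40), mouse = rnorm(40), rat = rnorm(40))
  t1 <- species_dendrogram(fc)
  t2 <- species_dendrogram(fc[sample(40), ])
  expect_equal(t1$newick, t2$newick)
  expect_equal(t1$distances, t2$distances)
})

test_that("small within-clade noise recovers the ((mouse,rat),human) topology", {
  cfg <- simulation_config(n_genes = 300L,
                           n_cells_per_subtype_per_species = 10L,
                           frac_de = 1, divergence_noise_sd_clade = 0.5,
                           divergence_noise_sd_within = 0.05, seed = 21L)
  gt <- generate_dataset(cfg)$ground_truth
  fc <- cbind(human = gt$lfc_human, mouse = gt$lfc_mouse, rat = gt$lfc_rat)
  expect_equal(first_join(species_dendrogram(fc)), c("mouse", "rat"))
})

test_that("functional-group comparison matches exact enumeration and skips degenerate input", {
  rec <- tibble::tibble(gene = paste0("g", 1:6),
                        divergence = c(5, 4, 6, 1, 2, 3))
  cats <- tibble::tibble(gene = paste0("g", 1:3), category = "cytokine")
  got <- group_divergence_comparison(rec, cats)
  expect_equal(got$p_value,
               oracle_mw_exact(c(5, 4, 6), c(1, 2, 3), "greater"))
  all_cat <- tibble::tibble(gene = paste0("g", 1:6), category = "everything")
  expect_warning(skipped <- group_divergence_comparison(rec, all_cat),
                 class = "crossmac_skipped_test")
  expect_true(skipped$skipped)
})

test_that("a stochastically larger category is detected at n = 50 and shift 1 sd", {
  set.seed(31)
  rec <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                        divergence = c(rnorm(50, 1), rnorm(50, 0)))
  cats <- tibble::tibble(gene = sprintf("g%03d", 1:50), category = "tf")
  expect_lt(group_divergence_comparison(rec, cats)$p_value, 0.05)
})
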