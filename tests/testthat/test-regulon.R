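# Regulon analytics: AUC scoring, binarization, selectivity, entropy,
# correlation filtering, enrichment, cross-species mapping and clustering.

test_that("AUC hits its exact endpoints and matches the step-curve oracle", {
  set.seed(20)
  genes <- sprintf("g%03d", 1:100)
  expr <- matrix(0, nrow = 100, ncol = 1, dimnames = list(genes, "cell1"))
  expr[, 1] <- seq(100, 1)          # g001 highest ... g100 lowest
  # top fraction 0.05 of 100 genes = top 5 ranks
  expect_equal(activity_auc(expr, genes[1:3], top_fraction = 0.05), c(cell1 = 1))
  expect_equal(activity_auc(expr, genes[50:55], top_fraction = 0.05),
               c(cell1 = 0))
  for (i in 1:20) {
    targets <- sample(genes, 5)
    v <- rnorm(100)
    expr[, 1] <- v
    got <- activity_auc(expr, targets, top_fraction = 0.1)
    expect_equal(unname(got), oracle_auc(v, genes, targets, 0.1))
  }
})

test_that("AUC breaks expression ties by gene identifier and validates targets", {
  genes <- c("a", "b", "c", "d")
  expr <- matrix(1, nrow = 4, ncol = 1, dimnames = list(genes, "cell1"))
  # all tied: ranking is a,b,c,d; top 1 rank (ceiling(0.25*4))
  expect_equal(unname(activity_auc(expr, c("a"), top_fraction = 0.25)), 1)
  expect_equal(unname(activity_auc(expr, c("d"), top_fraction = 0.25)), 0)
  expect_error(activity_auc(expr, list(r1 = "zz")),
               class = "crossmac_no_targets")
})

test_that("binarization separates a clean bimodal mixture and handles degenerates", {
  set.seed(22)
  auc <- rbind(bimodal = c(rnorm(150, 0.1, 0.02), rnorm(150, 0.8, 0.02)),
               flat = rep(0, 300))
  colnames(auc) <- paste0("c", 1:300)
  expect_warning(got <- binarize_activity(auc), class = "crossmac_constant_auc")
  th <- got$thresholds$threshold[got$thresholds$regulon == "bimodal"]
  expect_gt(th, 0.2); expect_lt(th, 0.7)
  expect_equal(unname(got$activity["bimodal", ]),
               rep(c(0L, 1L), each = 150))
  expect_true(all(got$activity["flat", ] == 0))
  # invariant to regulon ordering
  got2 <- suppressWarnings(binarize_activity(auc[c("flat", "bimodal"), ]))
  expect_equal(got$activity["bimodal", ], got2$activity["bimodal", ])
})

test_that("selectivity is exact set arithmetic", {
  expect_equal(selectivity(c("A", "B", "C", "D"), c("A", "B", "X")), 0.5)
  expect_equal(selectivity(c("A", "B"), c("X", "Y")), 0)
  expect_equal(selectivity(c("A", "B"), c("A", "B", "C")), 1)
  expect_error(selectivity(character(0), "A"), class = "crossmac_bad_input")
  set.seed(23)
  universe <- sprintf("g%03d", 1:50)
  for (i in 1:200) {
    targets <- sample(universe, sample(1:20, 1))
    degs <- sample(universe, sample(1:30, 1))
    expect_identical(selectivity(targets, degs),
                     sum(targets %in% degs) / length(targets))
  }
})

test_that("cumulative coverage is monotone, ordered by selectivity, and finds min k", {
  degs <- sprintf("d%02d", 1:10)
  regs <- list(all_of_them = degs,
               half = degs[1:5],
               none = c("x1", "x2"))
  got <- cumulative_deg_coverage(regs, degs)
  expect_equal(got$regulon[1], "all_of_them")
  expect_equal(attr(got, "min_k"), 1L)
  expect_true(all(diff(got$coverage) >= 0))
  two <- list(a = degs[1:4], b = degs[5:8], c = "x")
  got2 <- cumulative_deg_coverage(two, degs)
  expect_equal(got2$coverage, c(0.4, 0.8, 0.8))
  expect_equal(attr(got2, "min_k"), 2L)
  never <- cumulative_deg_coverage(list(a = degs[1]), degs)
  expect_true(is.na(attr(never, "min_k")))
  expect_error(cumulative_deg_coverage(two, character(0)),
               class = "crossmac_bad_input")
})

test_that("binary entropy matches its closed form and is symmetric", {
  expect_identical(binary_entropy(0.5, 0.5), 1)
  expect_identical(binary_entropy(0.2, 0), 0)
  expect_equal(binary_entropy(0.30, 0.10),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(round(binary_entropy(0.30, 0.10), 4), 0.8113)
  set.seed(24)
  for (i in 1:200) {
    a <- runif(1); b <- runif(1)
    expect_equal(binary_entropy(a, b), binary_entropy(b, a))
    p <- a / (a + b)
    naive <- sum(vapply(c(p, 1 - p), function(q)
      if (q == 0) 0 else -q * log(q, base = 2), numeric(1)))
    expect_equal(binary_entropy(a, b), naive, tolerance = 1e-12)
  }
  expect_warning(out <- binary_entropy(0, 0),
                 class = "crossmac_undefined_entropy")
  expect_true(is.na(out))
})

test_that("correlation filter keeps duplicated and complementary rows, not noise", {
  set.seed(25)
  base <- rbinom(1000, 1, 0.5)
  act <- rbind(r1 = base, r2 = base, r3 = 1 - base,
               noise1 = rbinom(1000, 1, 0.5),
               noise2 = rbinom(1000, 1, 0.5))
  colnames(act) <- paste0("c", 1:1000)
  got <- regulon_correlation_filter(act)
  expect_setequal(got$correlated, c("r1", "r2", "r3"))
  expect_equal(got$pairs$r[got$pairs$regulon1 == "r1" &
                             got$pairs$regulon2 == "r2"], 1)
  expect_equal(got$pairs$r[got$pairs$regulon1 == "r1" &
                             got$pairs$regulon2 == "r3"], -1)
  const <- rbind(act, allon = 1)
  expect_warning(regulon_correlation_filter(const),
                 class = "crossmac_constant_rows")
})

test_that("subtype enrichment p equals the hypergeometric oracle on a clean split", {
  ann <- tibble::tibble(cell_id = paste0("c", 1:40), species = "human",
                        subtype = rep(c("infiltrated", "resident"), each = 20))
  act <- rbind(specific = rep(c(1L, 0L), each = 20),
               allon = rep(1L, 40))
  colnames(act) <- ann$cell_id
  got <- subtype_enrichment(act, ann)
  sp <- got[got$regulon == "specific", ]
  expect_equal(sp$p_value, oracle_fisher_2x2(20, 0, 0, 20), tolerance = 1e-9)
  expect_equal(sp$direction, "infiltrated")
  expect_true(!is.na(got$note[got$regulon == "allon"]))
  expect_equal(got$p_adjusted, p.adjust(got$p_value, "BH"))
})

test_that("regulon mapping converts TFs and targets, drops the unmappable, and round-trips", {
  orth <- tibble::tibble(human = c("FOS", "JUN", "IL1B"),
                         mouse = c("Fos", "Jun", "Il1b"),
                         rat = c("fos", "jun", "il1b"))
  regs <- list(Fos = c("Jun", "Il1b"), Zzz = c("Jun"), Jun = c("Notagene"))
  got <- map_regulons_across_species(regs, orth, "mouse", "human")
  expect_equal(got$regulons, list(FOS = c("JUN", "IL1B")))
  rep_ <- got$report
  expect_false(rep_$kept[rep_$regulon_from == "Zzz"])
  expect_equal(rep_$reason[rep_$regulon_from == "Jun"], "no mappable targets")
  expect_true(all(unlist(got$regulons) %in% orth$human))
  back <- map_regulons_across_species(got$regulons, orth, "human", "mouse")
  expect_equal(back$regulons, list(Fos = c("Jun", "Il1b")))
  expect_error(map_regulons_across_species(regs, orth, "mouse", "dog"),
               class = "crossmac_bad_input")
})

test_that("joint clustering merges identical profiles first and is permutation invariant", {
  set.seed(26)
  act <- matrix(rbinom(10 * 30, 1, 0.5), nrow = 10,
                dimnames = list(paste0("r", 1:10), paste0("c", 1:30)))
  act[, 2] <- act[, 1]  # identical profiles
  jc <- joint_cluster(act, k = 2)
  d <- crossmac:::spearman_cell_distance(act)
  expect_equal(d["c1", "c2"], 0)
  expect_equal(unname(jc$clusters["c1"]), unname(jc$clusters["c2"]))
  perm <- sample(30)
  jc2 <- joint_cluster(act[, perm], k = 2)
  tab <- table(jc$clusters[colnames(act)], jc2$clusters[colnames(act)])
  expect_equal(sum(tab > 0), 2)  # a pure relabelling
  expect_error(joint_cluster(act[1, , drop = FALSE]),
               class = "crossmac_bad_input")
})

test_that("single-matrix joint clustering reduces to Ward clustering of its cells", {
  set.seed(27)
  act <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8,
                dimnames = list(paste0("r", 1:8), paste0("c", 1:20)))
  jc <- joint_cluster(act, k = 3)
  ranks <- apply(act, 2, rank)
  rho <- suppressWarnings(cor(ranks)); rho[is.na(rho)] <- 0
  d <- 1 - rho
  key <- apply(act, 2, paste, collapse = ",")
  d[outer(key, key, "==")] <- 0
  ref <- hclust(as.dist(d), method = "ward.D2")
  expect_equal(jc$hclust$height, ref$height)
  expect_equal(cutree(ref, 3)[names(jc$clusters)], jc$clusters)
})

test_that("conservation partition scores phi 1 / -1 / ~0 and splits at the median", {
  set.seed(28)
  ann <- tibble::tibble(cell_id = paste0("c", 1:100), species = "human",
                        subtype = rep(c("infiltrated", "resident"), 50))
  nat <- matrix(rbinom(4 * 100, 1, 0.5), nrow = 4,
                dimnames = list(c("same", "flip", "rand", "extra"),
                                ann$cell_id))
  cross <- nat
  cross["flip", ] <- 1 - nat["flip", ]
  cross["rand", ] <- rbinom(100, 1, 0.5)
  cross <- cross[c("same", "flip", "rand"), ]
  expect_warning(got <- conservation_partition(nat, cross, ann),
                 class = "crossmac_excluded_regulons")
  expect_equal(got$phi[got$regulon == "same"], 1)
  expect_equal(got$phi[got$regulon == "flip"], -1)
  expect_lt(abs(got$phi[got$regulon == "rand"]), 0.5)
  expect_equal(got$group[got$regulon == "same"], "more_conserved")
  expect_equal(got$group[got$regulon == "flip"], "less_conserved")
})

test_that("entropy-selectivity correlation endpoints and guards", {
  scores <- tibble::tibble(regulon = paste0("r", 1:10),
                           entropy = seq(0, 1, length.out = 10))
  scores$selectivity <- 1 - scores$entropy
  got <- entropy_selectivity_correlation(scores)
  expect_equal(got$r, -1)
  expect_error(entropy_selectivity_correlation(scores[1:2, ]),
               class = "crossmac_bad_input")
  expect_error(entropy_selectivity_correlation(
    dplyr::mutate(scores, selectivity = 0.5)),
    class = "crossmac_constant_input")
})

test_that("multi-TF regulation test matches the hand-computed pooled z", {
  regs <- list(tf1 = c("A", "B", "C"), tf2 = c("A", "B"), tf3 = c("A", "X"))
  universe <- c("A", "B", "C", "X", "Y", "Z")
  degs <- c("A", "B")
  got <- multi_tf_regulation_test(regs, degs, universe)
  # A in 3 regulons, B in 2, C in 1, X in 1: multi = {A, B}
  expect_equal(got$multi_deg, 2)
  expect_equal(got$multi_non_deg, 0)
  ref <- two_proportion_test(2, 2, 0, 4, alternative = "greater")
  expect_equal(got$statistic, ref$statistic)
  expect_equal(got$p_value, ref$p_value)
  expect_error(multi_tf_regulation_test(regs, universe, universe),
               class = "crossmac_bad_input")
  # equal proportions by construction -> p ~ 1
  eq <- multi_tf_regulation_test(list(tf1 = c("A", "X"), tf2 = c("A", "X")),
                                 c("A", "B"), c("A", "B", "X", "Y"))
  expect_gt(eq$p_value, 0.5)
})
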