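# Distance-to-median variability statistic and its association tests.

test_that("identical mean/variance across genes gives dm = 0 everywhere", {
  # cyclic shifts of one vector: every gene has the same mean and variance
  # and all library sizes are equal, so log10 CV^2 is constant and the
  # running median removes it exactly
  v <- c(1L, 3L, 5L, 7L, 9L)
  m <- t(vapply(0:4, function(s) v[(seq_along(v) + s - 1) %% 5 + 1],
                integer(5)))
  dimnames(m) <- list(paste0("g", 1:5), paste0("c", 1:5))
  got <- dm_statistic(m, window = 3)
  expect_equal(got$dm, rep(0, 5))
})

test_that("dm equals the naive running-median oracle on random fixtures", {
  set.seed(8)
  for (i in 1:25) {
    m <- make_counts(100, 20, mu = runif(1, 1, 20), size = runif(1, 0.3, 3),
                     seed = i)
    got <- dm_statistic(m, window = 15)
    ref <- oracle_dm(m, 15)
    expect_equal(got$gene, ref$gene)
    expect_equal(got$dm, ref$dm, tolerance = 1e-12)
  }
})

test_that("dm is invariant to per-cell count scaling", {
  m <- make_counts(120, 15, mu = 8, seed = 3)
  base <- dm_statistic(m, window = 21)
  doubled <- dm_statistic(m * 2L, window = 21)
  expect_equal(base$dm, doubled$dm, tolerance = 1e-12)
  m2 <- m
  m2[, 4] <- m2[, 4] * 5L
  one_cell <- dm_statistic(m2, window = 21)
  shared <- intersect(base$gene, one_cell$gene)
  # CV^2 is computed on size-factor normalized counts, so inflating one
  # cell's library leaves the statistic untouched
  expect_equal(base$dm[match(shared, base$gene)],
               one_cell$dm[match(shared, one_cell$gene)], tolerance = 1e-12)
})

test_that("window validation and gene dropping behave as documented", {
  m <- make_counts(60, 10, seed = 5)
  expect_error(dm_statistic(m, window = 10), "odd",
               class = "crossmac_bad_input")
  expect_error(dm_statistic(m, window = 101), class = "crossmac_bad_input")
  # equal library sizes so normalization keeps the planted rows degenerate:
  # g1 has zero mean, g2 zero variance
  m2 <- rbind(g1 = c(0L, 0L, 0L, 0L), g2 = c(5L, 5L, 5L, 5L),
              g3 = c(1L, 2L, 3L, 4L), g4 = c(4L, 3L, 2L, 1L),
              g5 = c(2L, 4L, 1L, 3L), g6 = c(3L, 1L, 4L, 2L))
  colnames(m2) <- paste0("c", 1:4)
  got <- dm_statistic(m2, window = 3)
  expect_setequal(attr(got, "dropped"), c("g1", "g2"))
  expect_setequal(got$gene, c("g3", "g4", "g5", "g6"))
})

test_that("group test detects injected extra dispersion and matches exact U on 3v3", {
  set.seed(13)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  # high-divergence genes get overdispersed counts (NB size 0.5 vs 2)
  grp <- rep(c("high", "low"), each = n / 2)
  m <- rbind(
    matrix(rnbinom(n / 2 * 60, mu = 10, size = 0.5), ncol = 60),
    matrix(rnbinom(n / 2 * 60, mu = 10, size = 2), ncol = 60))
  dimnames(m) <- list(genes, paste0("c", 1:60))
  dm <- dm_statistic(m, window = 51)
  div <- tibble::tibble(gene = genes, group = grp)
  got <- dm_group_test(dm, div)
  expect_lt(got$p_value, 0.01)
  expect_gt(got$median_a, got$median_b)

  tiny <- tibble::tibble(gene = paste0("t", 1:6),
                         mean_expression = 1, log10_cv2 = 0,
                         dm = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3))
  tiny_div <- tibble::tibble(gene = paste0("t", 1:6),
                             group = rep(c("high", "low"), each = 3))
  got_tiny <- dm_group_test(tiny, tiny_div)
  expect_equal(got_tiny$p_value,
               oracle_mw_exact(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3), "greater"))
  expect_error(dm_group_test(dm, tibble::tibble(gene = "zz", group = "high")),
               class = "crossmac_bad_input")
})

test_that("element test skips single-stratum input and detects planted coupling", {
  dmr <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                        mean_expression = 1, log10_cv2 = 0,
                        dm = c(rnorm(50, 0.5), rnorm(50, -0.5)))
  flags <- tibble::tibble(gene = dmr$gene,
                          tata = rep(c(TRUE, FALSE), each = 50))
  got <- dm_element_test(dmr, flags, "tata")
  expect_lt(got$p_value, 0.01)
  expect_warning(sk <- dm_element_test(dmr, dplyr::mutate(flags, tata = TRUE),
                                       "tata"),
                 class = "crossmac_skipped_test")
  expect_true(sk$skipped)
})

test_that("expression bins are equal-sized with the remainder in the lowest bins", {
  mk_records <- function(n) {
    tibble::tibble(gene = sprintf("g%04d", 1:n),
                   mean_expression = seq_len(n), log10_cv2 = 0,
                   dm = rnorm(n))
  }
  div636 <- tibble::tibble(gene = sprintf("g%04d", 1:636),
                           group = rep(c("high", "low"), length.out = 636))
  got <- expression_binned_control(mk_records(636), div636, n_bins = 5)
  expect_equal(attr(got, "bin_sizes"), c(128L, 127L, 127L, 127L, 127L))
  expect_equal(sum(got$n), 636)

  div10 <- tibble::tibble(gene = sprintf("g%04d", 1:10), group = "high")
  got10 <- expression_binned_control(mk_records(10), div10, n_bins = 5)
  expect_equal(attr(got10, "bin_sizes"), rep(2L, 5))
  expect_error(expression_binned_control(mk_records(10), div10, n_bins = 1),
               class = "crossmac_bad_input")
})

test_that("per-bin group medians stay flat on null data after DM correction", {
  set.seed(17)
  n <- 400
  genes <- sprintf("g%03d", 1:n)
  m <- matrix(rnbinom(n * 50, mu = rep(exp(runif(n, 0, 3)), 50), size = 1),
              nrow = n, dimnames = list(genes, paste0("c", 1:50)))
  dm <- dm_statistic(m, window = 51)
  div <- tibble::tibble(gene = dm$gene,
                        group = rep(c("high", "low"),
                                    length.out = nrow(dm)))
  got <- expression_binned_control(dm, div, n_bins = 5)
  spread <- tapply(got$median_dm, got$bin, function(v) diff(range(v)))
  expect_true(all(spread < 0.5))
})
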