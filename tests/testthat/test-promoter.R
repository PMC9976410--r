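# TATA scan, CGI detection, conservation profiles and element tests.

test_that("a TATA motif planted at -50 is found there, outside the core window is not", {
  s <- strrep("C", 500)
  hit <- tata_scan(sub_plant(s, "TATAAAAG", 451))  # TSS-relative -50
  expect_true(hit$hit)
  expect_equal(hit$positions, -50)
  miss <- tata_scan(sub_plant(s, "TATAAAAG", 301)) # TSS-relative -200
  expect_false(miss$hit)
  expect_length(miss$positions, 0)
  expect_false(tata_scan(s)$hit)
})

test_that("the consensus covers W and R degeneracy and overlapping matches", {
  for (m in c("TATAAAAA", "TATATATG", "TATAAATA", "TATATAAG")) {
    expect_true(tata_scan(sub_plant(strrep("C", 500), m, 460))$hit)
  }
  expect_false(tata_scan(sub_plant(strrep("C", 500), "TATACAAG", 460))$hit)
  # TATATATAAG contains overlapping TATAWAWR matches at -60 and -58
  s2 <- sub_plant(strrep("C", 500), "TATATATAAG", 441)
  expect_equal(tata_scan(s2)$positions, c(-60, -58))
})

test_that("tata_scan validates its input", {
  expect_error(tata_scan("TATA"), class = "crossmac_bad_input")
  expect_error(tata_scan(strrep("X", 500)), class = "crossmac_bad_input")
})

test_that("CGI detection: CpG-dense sequences qualify, AT-only never", {
  cg <- paste0(strrep("AT", 100), strrep("CG", 150))
  got <- cgi_detect(cg)
  expect_true(got$cgi)
  expect_gt(nrow(got$islands), 0)
  expect_false(cgi_detect(strrep("AT", 250))$cgi)
})

test_that("CGI criteria are >= at both boundaries exactly", {
  # window of 200: 50 CpG dinucleotides then AT filler gives GC exactly 0.5;
  # obs/exp = 50*200/(50*50) = 4 >= 0.6
  s1 <- paste0(strrep("CG", 50), strrep("AT", 50))
  expect_equal(nchar(s1), 200)
  chars <- strsplit(s1, "")[[1]]
  expect_equal(mean(chars %in% c("C", "G")), 0.5)
  expect_true(cgi_detect(s1)$cgi)

  # boundary on obs/exp: 15 CpGs with C and G spread apart; nC = nG = 50
  # -> obs/exp = 15*200/2500 = 1.2; dilute CpGs to hit 0.6: nCpG such that
  # nCpG*200/(50*50) = 0.6  => nCpG = 7.5, so 8 CpGs is just above, 7 below
  mk <- function(n_cpg) {
    body <- paste0(strrep("CG", n_cpg),
                   strrep("CA", 50 - n_cpg), strrep("GT", 50 - n_cpg),
                   strrep("AT", n_cpg))
    stopifnot(nchar(body) == 200)
    body
  }
  expect_true(cgi_detect(mk(8))$cgi)    # obs/exp = 0.64
  expect_false(cgi_detect(mk(7))$cgi)   # obs/exp = 0.56
})

test_that("mostly-N sequences are flagged indeterminate", {
  s <- paste0(strrep("N", 300), strrep("A", 200))
  expect_warning(got <- cgi_detect(s), class = "crossmac_indeterminate")
  expect_true(is.na(got$cgi))
  expect_true(got$indeterminate)
})

test_that("conservation profile means equal hand-computed averages", {
  prom <- tibble::tibble(
    gene = c("A", "B", "C"),
    conservation = list(rep(0.7, 500), seq(0, 1, length.out = 500),
                        rep(0.2, 500)))
  groups <- tibble::tibble(gene = c("A", "B", "C"),
                           group = c("high", "high", "low"))
  prof <- conservation_profile(prom, groups)
  hi <- prof[prof$group == "high", ]
  expect_equal(hi$mean, (rep(0.7, 500) + seq(0, 1, length.out = 500)) / 2)
  lo <- prof[prof$group == "low", ]
  expect_equal(lo$mean, rep(0.2, 500))      # single gene: its own vector
  expect_equal(lo$smooth, rep(0.2, 500), tolerance = 1e-9) # flat profile
  expect_equal(prof$position[1:500], seq(-500, -1))
})

test_that("groups with no promoter records are omitted with a warning", {
  prom <- tibble::tibble(gene = c("A", "B"),
                         conservation = list(rep(0.5, 500), rep(0.6, 500)))
  groups <- tibble::tibble(gene = c("A", "B", "Z"),
                           group = c("high", "high", "low"))
  expect_warning(prof <- conservation_profile(prom, groups),
                 class = "crossmac_skipped_group")
  expect_setequal(unique(prof$group), "high")
})

test_that("one-sided KS statistic equals the hand-computed ECDF gap on a 4-point fixture", {
  a <- c(0.1, 0.2, 0.3, 0.6)
  b <- c(0.4, 0.5, 0.7, 0.8)
  got <- conservation_group_test(
    tibble::tibble(gene = paste0("g", 1:8),
                   conservation = lapply(c(a, b), function(v) rep(v, 500))),
    tibble::tibble(gene = paste0("g", 1:8),
                   group = rep(c("low_set", "high_set"), each = 4)),
    "low_set", "high_set")
  # max_t (ECDF_a(t) - ECDF_b(t)): at t = 0.3, 3/4 - 0/4 = 0.75
  expect_equal(got$statistic, 0.75)
  # identical groups -> p near 1; reversed direction of a strong shift -> p near 1
  same <- conservation_group_test(
    tibble::tibble(gene = paste0("g", 1:8),
                   conservation = lapply(rep(a, 2), function(v) rep(v, 500))),
    tibble::tibble(gene = paste0("g", 1:8),
                   group = rep(c("x", "y"), each = 4)), "x", "y")
  expect_gt(same$p_value, 0.5)
  rev <- conservation_group_test(
    tibble::tibble(gene = paste0("g", 1:8),
                   conservation = lapply(c(b + 1, a), function(v) rep(v, 500))),
    tibble::tibble(gene = paste0("g", 1:8),
                   group = rep(c("x", "y"), each = 4)), "x", "y")
  expect_gt(rev$p_value, 0.5)
})

test_that("element-divergence test reports MW and Fisher, skipping degenerate strata", {
  set.seed(12)
  n <- 200
  div <- classify_divergence(
    tibble::tibble(gene = sprintf("g%03d", 1:n), divergence = rnorm(n)))
  prom <- tibble::tibble(gene = div$gene,
                         tata = rep(c(TRUE, FALSE), each = n / 2),
                         cgi = FALSE)
  got <- element_divergence_test(prom, div, "tata")
  expect_false(got$skipped)
  expect_equal(got$n_present, 100)
  # against a manual Fisher on the same 2x2
  a <- sum(div$group == "high" & prom$tata)
  b <- sum(div$group == "high" & !prom$tata)
  c_ <- sum(div$group == "low" & prom$tata)
  d <- sum(div$group == "low" & !prom$tata)
  ref <- fisher.test(matrix(c(a, c_, b, d), 2), alternative = "greater")
  expect_equal(got$fisher_p, ref$p.value)
  all_pos <- dplyr::mutate(prom, tata = TRUE)
  expect_true(element_divergence_test(all_pos, div, "tata")$skipped)
})
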