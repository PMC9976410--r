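# Core two-sample tests used throughout the package.
#
# The Mann-Whitney implementation is hand-rolled so that small samples get a
# deterministic exact-enumeration p-value even in the presence of ties
# (midranks), which stats::wilcox.test does not provide. Larger samples use
# the tie-corrected normal approximation with continuity correction.

#' Mann-Whitney U (Wilcoxon rank-sum) test with an exact small-sample path
#'
#' Computes the Mann-Whitney U statistic for `x` relative to `y` using
#' midranks. When both groups have at most `exact_max` observations the
#' p-value is obtained by exact enumeration of all group assignments of the
#' pooled values (valid with ties); otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param alternative `"two.sided"`, `"greater"` (x stochastically larger) or
#'   `"less"`.
#' @param exact_max Largest per-group size for which exact enumeration is
#'   used (default 8).
#' @return A one-row tibble with columns `test`, `alternative`, `n1`, `n2`,
#'   `statistic` (U), `p_value` and `method` (`"exact"` or `"normal"`).
#' @examples
#' mw_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
mw_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    exact_max = 8L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    xm_abort("both groups must be non-empty", "bad_input")
  }
  if (anyNA(x) || anyNA(y)) xm_abort("NA values in test input", "bad_input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(N, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    p_ge <- mean(u_all >= u_obs - 1e-12)
    p_le <- mean(u_all <= u_obs + 1e-12)
    p <- switch(alternative,
                greater   = p_ge,
                less      = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        greater   = stats::pnorm((u_obs - mu - 0.5) / sigma, lower.tail = FALSE),
        less      = stats::pnorm((u_obs - mu + 0.5) / sigma),
        two.sided = {
          z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma
          min(1, 2 * stats::pnorm(-abs(z)))
        })
    }
    method <- "normal"
  }
  tibble::tibble(test = "mann_whitney", alternative = alternative,
                 n1 = n1, n2 = n2, statistic = u_obs, p_value = p,
                 method = method)
}

#' Two-proportion z-test with continuity correction
#'
#' Pooled-proportion z-test for `x1/n1` versus `x2/n2` with the Yates
#' continuity correction, computed from the textbook formula (the squared
#' two-sided z equals the Yates-corrected chi-square of
#' [stats::prop.test()]).
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A one-row tibble with `estimate1`, `estimate2`, `statistic` (z),
#'   `p_value` and bookkeeping columns.
#' @export
two_proportion_test <- function(x1, n1, x2, n2,
                                alternative = c("two.sided", "greater", "less"),
                                correct = TRUE) {
  alternative <- match.arg(alternative)
  if (n1 < 1 || n2 < 1) xm_abort("empty group in proportion test", "bad_input")
  p1 <- x1 / n1; p2 <- x2 / n2
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  d <- p1 - p2
  cc <- if (correct) 0.5 * (1 / n1 + 1 / n2) else 0
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    d_adj <- switch(alternative,
                    two.sided = sign(d) * max(0, abs(d) - cc),
                    greater   = d - cc,
                    less      = d + cc)
    z <- d_adj / se
    p <- switch(alternative,
                two.sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater   = stats::pnorm(z, lower.tail = FALSE),
                less      = stats::pnorm(z))
  }
  tibble::tibble(test = "two_proportion", alternative = alternative,
                 n1 = n1, n2 = n2, estimate1 = p1, estimate2 = p2,
                 statistic = z, p_value = p)
}

# One-sided two-sample KS for "x stochastically lower than y".
# R's ks.test(x, y, alternative = "greater") tests that the CDF of x lies
# above that of y, i.e. x is the smaller distribution.
ks_lower_test <- function(x, y) {
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "greater"))
  tibble::tibble(test = "ks_one_sided", alternative = "x_lower",
                 n1 = length(x), n2 = length(y),
                 statistic = unname(kt$statistic), p_value = kt$p.value)
}

# Fisher's exact test on a 2x2 table given as four counts
# (rows: condition present/absent, cols: outcome present/absent).
fisher_2x2 <- function(a, b, c, d,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- matrix(c(a, c, b, d), nrow = 2)
  ft <- stats::fisher.test(tab, alternative = alternative)
  tibble::tibble(test = "fisher_exact", alternative = alternative,
                 a = a, b = b, c = c, d = d,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
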