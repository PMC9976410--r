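# Distance-to-median (DM) cell-to-cell variability.
#
# For each gene, CV^2 = variance / mean^2 is computed on size-factor
# normalized counts; genes are ordered by log10 mean expression and DM is
# the residual of log10(CV^2) from a running median over that order, which
# removes the mean-variability trend so that variability can be compared
# across expression levels.

#' Distance-to-median variability statistic
#'
#' Computes per-gene DM on a raw count matrix for one cell group: counts are
#' scaled by per-cell size factors (total counts divided by the mean library
#' size), CV^2 is taken on the normalized values, and DM is
#' `log10(CV^2)` minus its running median in a centered window of `window`
#' genes ordered by `log10(mean)` (the window shrinks symmetrically at the
#' edges). Genes with zero mean or zero variance are dropped before trend
#' fitting and reported in the `dropped` attribute.
#'
#' @param counts Gene x cell count matrix.
#' @param cells Optional character vector of cell ids to use (e.g. one
#'   subtype); default all cells.
#' @param window Odd running-median window size (default 51).
#' @return Tibble in input gene order (retained genes only): `gene`,
#'   `mean_expression`, `log10_cv2`, `dm`. Attribute `dropped` lists the
#'   excluded genes.
#' @export
dm_statistic <- function(counts, cells = NULL, window = 51L) {
  assert_count_matrix(counts)
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(counts))
    if (length(missing) > 0) {
      xm_abort(sprintf("unknown cells: %s", paste(utils::head(missing, 3),
                                                  collapse = ", ")),
               "bad_input")
    }
    counts <- counts[, cells, drop = FALSE]
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) xm_abort("window must be odd", "bad_input")
  m <- as_dense(counts)
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    xm_abort(sprintf("cell '%s' has zero total counts",
                     colnames(m)[which(libsize == 0)[1]]), "zero_library")
  }
  sf <- libsize / mean(libsize)
  norm <- sweep(m, 2, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  keep <- mu > 0 & v > 0
  dropped <- rownames(m)[!keep]
  if (sum(keep) < window) {
    xm_abort("window larger than the number of genes with positive mean and variance",
             "bad_input")
  }
  mu <- mu[keep]; v <- v[keep]
  genes <- rownames(m)[keep]
  log10_cv2 <- log10(v / mu^2)
  ord <- order(log10(mu), genes, method = "radix")
  trend <- running_median(log10_cv2[ord], window)
  dm <- numeric(length(mu))
  dm[ord] <- log10_cv2[ord] - trend
  out <- tibble::tibble(gene = genes, mean_expression = mu,
                        log10_cv2 = log10_cv2, dm = dm)
  attr(out, "dropped") <- dropped
  attr(out, "window") <- window
  out
}

# Centered running median with symmetric shrinkage at the edges: at index i
# the half-width is min((w-1)/2, i-1, n-i).
running_median <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    stats::median(x[(i - hi):(i + hi)])
  }, numeric(1))
}

#' Compare DM between divergence groups
#'
#' One-sided Mann-Whitney test of the hypothesis that `group_a` (default
#' `"high"`) has higher DM than `group_b` (default `"low"`), joined on gene
#' identifier.
#'
#' @param dm_records Output of [dm_statistic()].
#' @param divergence Divergence tibble (`gene`, `group`).
#' @param group_a,group_b Divergence groups compared.
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `statistic`, `p_value`.
#' @export
dm_group_test <- function(dm_records, divergence, group_a = "high",
                          group_b = "low") {
  joined <- dplyr::inner_join(dm_records, divergence, by = "gene")
  x <- joined$dm[joined$group == group_a]
  y <- joined$dm[joined$group == group_b]
  if (length(x) == 0 || length(y) == 0) {
    xm_abort("empty divergence group after join", "bad_input")
  }
  mw <- mw_core(x, y, alternative = "greater")
  tibble::tibble(group_a = group_a, group_b = group_b,
                 n_a = length(x), n_b = length(y),
                 median_a = stats::median(x), median_b = stats::median(y),
                 statistic = mw$u, p_value = mw$p)
}

#' Compare DM between element-positive and element-negative genes
#'
#' One-sided Mann-Whitney test of the hypothesis that genes carrying the
#' promoter element have higher DM.
#'
#' @param dm_records Output of [dm_statistic()].
#' @param promoter_flags Tibble with `gene` and logical flag columns.
#' @param element Name of the flag column (`"tata"` or `"cgi"`).
#' @return One-row tibble like [dm_group_test()], plus `skipped`/`reason`
#'   when all genes share the same flag.
#' @export
dm_element_test <- function(dm_records, promoter_flags, element = "tata") {
  if (!element %in% names(promoter_flags)) {
    xm_abort(sprintf("no column '%s' in promoter_flags", element), "bad_input")
  }
  joined <- dplyr::inner_join(dm_records, promoter_flags, by = "gene")
  flag <- joined[[element]]
  if (all(flag) || !any(flag)) {
    xm_warn("all genes share the same element flag; test skipped",
            "skipped_test")
    return(tibble::tibble(element = element, n_present = sum(flag),
                          n_absent = sum(!flag), median_present = NA_real_,
                          median_absent = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, skipped = TRUE,
                          reason = "single stratum"))
  }
  x <- joined$dm[flag]; y <- joined$dm[!flag]
  mw <- mw_core(x, y, alternative = "greater")
  tibble::tibble(element = element, n_present = length(x),
                 n_absent = length(y), median_present = stats::median(x),
                 median_absent = stats::median(y), statistic = mw$u,
                 p_value = mw$p, skipped = FALSE, reason = NA_character_)
}

#' Expression-binned DM control
#'
#' Ranks genes by mean expression, splits them into `n_bins` equal-sized
#' bins (sizes `floor(n/b)`, with the remainder distributed one gene each to
#' the lowest-expression bins) and summarises DM per divergence group within
#' each bin — the control showing that group differences in DM are not
#' driven by expression level.
#'
#' @param dm_records Output of [dm_statistic()].
#' @param divergence Divergence tibble (`gene`, `group`).
#' @param n_bins Number of bins (default 5).
#' @return Tibble: `bin` (1 = lowest expression), `group`, `n`, `median_dm`.
#'   Attribute `bin_sizes` gives the per-bin gene counts.
#' @export
expression_binned_control <- function(dm_records, divergence, n_bins = 5L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) xm_abort("n_bins must be >= 2", "bad_input")
  joined <- dplyr::inner_join(dm_records, divergence, by = "gene")
  n <- nrow(joined)
  if (n < n_bins) xm_abort("fewer genes than bins", "bad_input")
  base <- n %/% n_bins
  rem <- n - base * n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  ord <- order(joined$mean_expression, joined$gene, method = "radix")
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  out <- joined |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(.data$bin, .data$group) |>
    dplyr::summarise(n = dplyr::n(), median_dm = stats::median(.data$dm),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin, .data$group)
  attr(out, "bin_sizes") <- sizes
  out
}
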