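# QC filtering, log-normalization and per-species differential expression
# between resident and infiltrated macrophages.

#' Quality-control filter for a count matrix
#'
#' Applies, in order: (1) remove genes detected (count > 0) in at most 3
#' cells; (2) remove cells whose detected-gene count (computed on the
#' gene-filtered matrix) is below 200 or above 2500; (3) remove cells whose
#' mitochondrial count fraction exceeds 5% (strict inequality, so exactly 5%
#' is retained). Row and column order of the retained entries is preserved.
#'
#' @param counts Gene x cell integer matrix with dimnames.
#' @param mito_gene_ids Character vector of mitochondrial gene ids (may be
#'   empty, in which case the mito rule removes nothing).
#' @param min_cells_per_gene Genes detected in `<= min_cells_per_gene` cells
#'   are dropped (default 3).
#' @param min_genes_per_cell,max_genes_per_cell Inclusive bounds on the
#'   per-cell detected-gene count (defaults 200 and 2500).
#' @param max_mito_fraction Cells above this mitochondrial fraction are
#'   dropped (default 0.05).
#' @return The filtered count matrix.
#' @export
qc_filter <- function(counts, mito_gene_ids = character(),
                      min_cells_per_gene = 3L,
                      min_genes_per_cell = 200L,
                      max_genes_per_cell = 2500L,
                      max_mito_fraction = 0.05) {
  assert_count_matrix(counts)
  detected_cells <- rowSums(counts > 0)
  keep_genes <- detected_cells > min_cells_per_gene
  m <- counts[keep_genes, , drop = FALSE]
  if (nrow(m) == 0) xm_abort("no genes survive QC filtering", "empty_result")

  genes_per_cell <- colSums(m > 0)
  keep_cells <- genes_per_cell >= min_genes_per_cell &
    genes_per_cell <= max_genes_per_cell
  mito <- intersect(mito_gene_ids, rownames(m))
  if (length(mito) > 0) {
    tot <- colSums(m)
    mito_frac <- ifelse(tot > 0, colSums(m[mito, , drop = FALSE]) / tot, 0)
    keep_cells <- keep_cells & mito_frac <= max_mito_fraction
  }
  m <- m[, keep_cells, drop = FALSE]
  if (ncol(m) == 0) xm_abort("no cells survive QC filtering", "empty_result")
  m
}

#' Library-size log-normalization
#'
#' Scales each cell to `scale` total counts and applies `log1p`, the
#' standard log-normalization for droplet scRNA-seq.
#'
#' @param counts Gene x cell count matrix.
#' @param scale Target library size (default 1e4).
#' @return Matrix of the same shape with values `log1p(count / libsize * scale)`.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  assert_count_matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[which(libsize == 0)[1]]
    xm_abort(sprintf("cell '%s' has zero total counts", bad), "zero_library")
  }
  m <- sweep(as_dense(counts), 2, libsize / scale, "/")
  log1p(m)
}

# Shared numeric core of the Mann-Whitney test (no tibble allocation), so
# find_markers can loop it over thousands of genes.
mw_core <- function(x, y, alternative = "two.sided", exact_max = 8L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_ge <- mean(u_all >= u - 1e-12)
    p_le <- mean(u_all <= u + 1e-12)
    p <- switch(alternative, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(u = u, p = p))
  }
  mu <- n1 * n2 / 2
  ties <- tabulate(match(r, unique(r)))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1))
  sigma <- sqrt(sigma2)
  p <- switch(alternative,
    greater = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((u - mu + 0.5) / sigma),
    two.sided = min(1, 2 * stats::pnorm(-abs((u - mu - sign(u - mu) * 0.5) /
                                               sigma))))
  list(u = u, p = p)
}

#' Wilcoxon rank-sum differential expression between subtypes
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized expression
#' between two cell groups, with the log-fold-change and detection-fraction
#' prefilters of the Seurat v3 `FindMarkers` contract: the log fold change is
#' the difference of `log(mean(expm1(x)) + 1)` (natural log, pseudocount 1)
#' between groups; genes detected in fewer than `min_pct` of cells in both
#' groups, or with `|log_fc| < logfc_threshold`, are excluded before
#' testing. Benjamini-Hochberg adjustment is applied over the tested genes.
#'
#' @param norm Log-normalized gene x cell matrix (see [log_normalize()]).
#' @param annotation Cell annotation with columns `cell_id` and `subtype`.
#' @param group1,group2 Subtype labels contrasted (log_fc > 0 means higher in
#'   `group1`); defaults `"resident"` vs `"infiltrated"`.
#' @param min_pct Minimum detection fraction in at least one group (0.1).
#' @param logfc_threshold Minimum absolute log fold change (0.25).
#' @return Tibble with columns `gene`, `log_fc`, `pct_in_group`,
#'   `pct_out_group`, `p_value`, `p_adjusted`, in input gene order
#'   (tested genes only). Attribute `log_base` records the natural-log
#'   convention.
#' @export
find_markers <- function(norm, annotation, group1 = "resident",
                         group2 = "infiltrated", min_pct = 0.1,
                         logfc_threshold = 0.25) {
  if (!is.matrix(norm)) norm <- as_dense(norm)
  if (!all(c("cell_id", "subtype") %in% names(annotation))) {
    xm_abort("annotation needs cell_id and subtype columns", "bad_input")
  }
  cells1 <- annotation$cell_id[annotation$subtype == group1]
  cells2 <- annotation$cell_id[annotation$subtype == group2]
  cells1 <- intersect(cells1, colnames(norm))
  cells2 <- intersect(cells2, colnames(norm))
  if (length(cells1) < 3 || length(cells2) < 3) {
    xm_abort(sprintf("need >= 3 cells in each of '%s' and '%s'",
                     group1, group2), "bad_input")
  }
  m1 <- norm[, cells1, drop = FALSE]
  m2 <- norm[, cells2, drop = FALSE]
  pct1 <- rowMeans(m1 > 0)
  pct2 <- rowMeans(m2 > 0)
  log_fc <- log(rowMeans(expm1(m1)) + 1) - log(rowMeans(expm1(m2)) + 1)
  keep <- (pmax(pct1, pct2) >= min_pct) & (abs(log_fc) >= logfc_threshold)
  idx <- which(keep)
  p <- vapply(idx, function(i) mw_core(m1[i, ], m2[i, ])$p, numeric(1))
  out <- tibble::tibble(gene = rownames(norm)[idx],
                        log_fc = unname(log_fc[idx]),
                        pct_in_group = unname(pct1[idx]),
                        pct_out_group = unname(pct2[idx]),
                        p_value = unname(p),
                        p_adjusted = unname(stats::p.adjust(p, method = "BH")))
  attr(out, "log_base") <- "natural"
  attr(out, "pseudocount") <- 1
  out
}
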