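# Regulon analytics: rank-recovery activity scoring, mixture binarization,
# selectivity, normalized binary entropy, correlation filtering, subtype
# enrichment, cross-species mapping and joint Ward/Spearman clustering.

#' Rank-recovery regulon activity (AUC) per cell
#'
#' For each cell, genes are ranked by expression in descending order (ties
#' broken by gene identifier) and the regulon's activity is the area under
#' its target-recovery curve within the top `ceiling(top_fraction * G)`
#' ranks, normalized so that 1 means all targets occupy the very top ranks
#' and 0 means no target enters the top fraction.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param regulons Named list of target-gene character vectors (one regulon
#'   per element), or a single character vector (treated as one regulon).
#' @param top_fraction Fraction of the ranking used (default 0.05).
#' @return Regulon x cell numeric matrix of AUC values in `[0, 1]` (a named
#'   vector when a single character vector was supplied).
#' @export
activity_auc <- function(norm, regulons, top_fraction = 0.05) {
  single <- is.character(regulons)
  if (single) regulons <- list(regulon = regulons)
  if (is.null(names(regulons)) || any(names(regulons) == "")) {
    xm_abort("regulons must be a named list", "bad_input")
  }
  norm <- as_dense(norm)
  genes <- rownames(norm)
  g <- length(genes)
  m_top <- ceiling(top_fraction * g)
  target_idx <- lapply(names(regulons), function(tf) {
    ix <- which(genes %in% regulons[[tf]])
    if (length(ix) == 0) {
      xm_abort(sprintf("regulon '%s' has no targets in the gene universe", tf),
               "no_targets")
    }
    ix
  })
  names(target_idx) <- names(regulons)
  max_area <- vapply(target_idx, function(ix) {
    k <- length(ix)
    if (k >= m_top) m_top * (m_top + 1) / 2
    else k * (k + 1) / 2 + (m_top - k) * k
  }, numeric(1))

  out <- matrix(0, nrow = length(regulons), ncol = ncol(norm),
                dimnames = list(names(regulons), colnames(norm)))
  pos <- integer(g)
  for (j in seq_len(ncol(norm))) {
    ord <- order(-norm[, j], genes, method = "radix")
    pos[ord] <- seq_len(g)
    for (r in seq_along(target_idx)) {
      tr <- pos[target_idx[[r]]]
      tr <- tr[tr <= m_top]
      out[r, j] <- sum(m_top - tr + 1) / max_area[r]
    }
  }
  if (single) stats::setNames(out[1, ], colnames(out)) else out
}

#' Binarize regulon activity with a Gaussian-mixture valley threshold
#'
#' Per regulon, fits 1- and 2-component Gaussian mixtures (unequal
#' variances) to the AUC distribution. If the 2-component model is preferred
#' by BIC the threshold is the density minimum between the two component
#' means; otherwise (unimodal) the fallback threshold is the 95th percentile
#' of the single fitted Gaussian. Cells with AUC above the threshold are
#' active. Constant AUC rows become all-inactive with a warning.
#'
#' @param auc_matrix Regulon x cell AUC matrix (values in `[0, 1]`).
#' @return Object of class `regulon_activity`: list with `activity` (binary
#'   matrix) and `thresholds` (tibble: `regulon`, `threshold`, `rule`).
#' @export
binarize_activity <- function(auc_matrix) {
  if (is.null(rownames(auc_matrix))) {
    xm_abort("auc_matrix needs regulon rownames", "bad_input")
  }
  act <- matrix(0L, nrow(auc_matrix), ncol(auc_matrix),
                dimnames = dimnames(auc_matrix))
  th <- numeric(nrow(auc_matrix))
  rule <- character(nrow(auc_matrix))
  for (i in seq_len(nrow(auc_matrix))) {
    x <- auc_matrix[i, ]
    if (stats::sd(x) == 0) {
      xm_warn(sprintf("regulon '%s' has constant AUC; set inactive",
                      rownames(auc_matrix)[i]), "constant_auc")
      th[i] <- NA_real_; rule[i] <- "constant"
      next
    }
    # fixed internal seed: mclust initialization subsamples for large n
    fit <- with_seed(0L, tryCatch(
      Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL))
    if (!is.null(fit) && fit$G == 2) {
      mu <- fit$parameters$mean
      sg <- sqrt(fit$parameters$variance$sigmasq)
      if (length(sg) == 1) sg <- rep(sg, 2)
      pro <- fit$parameters$pro
      o <- order(mu)
      grid <- seq(mu[o[1]], mu[o[2]], length.out = 512)
      dens <- pro[1] * stats::dnorm(grid, mu[1], sg[1]) +
        pro[2] * stats::dnorm(grid, mu[2], sg[2])
      th[i] <- grid[which.min(dens)]
      rule[i] <- "mixture_valley"
    } else {
      mu1 <- mean(x); s1 <- stats::sd(x)
      if (!is.null(fit) && fit$G == 1) {
        mu1 <- fit$parameters$mean
        s1 <- sqrt(fit$parameters$variance$sigmasq)
      }
      th[i] <- mu1 + stats::qnorm(0.95) * s1
      rule[i] <- "unimodal_q95"
    }
    act[i, ] <- as.integer(x > th[i])
  }
  structure(list(activity = act,
                 thresholds = tibble::tibble(regulon = rownames(auc_matrix),
                                             threshold = th, rule = rule)),
            class = "regulon_activity")
}

#' Regulon selectivity for DEGs
#'
#' Fraction of a regulon's target genes that are DEGs:
#' `|DEG intersect targets| / |targets|`.
#'
#' @param targets Character vector of target genes (non-empty).
#' @param deg_set Character vector of DEG identifiers.
#' @return A fraction in `[0, 1]`.
#' @export
selectivity <- function(targets, deg_set) {
  if (length(targets) == 0) xm_abort("empty target set", "bad_input")
  length(intersect(unique(targets), deg_set)) / length(unique(targets))
}

#' Selectivity table for a regulon set
#'
#' @param regulons Named list TF -> target vector.
#' @param deg_set Character vector of DEGs.
#' @return Tibble: `regulon`, `n_targets`, `n_deg_targets`, `selectivity`.
#' @export
regulon_selectivity <- function(regulons, deg_set) {
  tibble::tibble(
    regulon = names(regulons),
    n_targets = vapply(regulons, function(t) length(unique(t)), integer(1)),
    n_deg_targets = vapply(regulons, function(t)
      length(intersect(unique(t), deg_set)), integer(1))) |>
    dplyr::mutate(selectivity = .data$n_deg_targets / .data$n_targets)
}

#' Cumulative DEG coverage by selectivity-ranked TFs
#'
#' Sorts TFs by selectivity (descending, ties by TF identifier), then
#' reports the fraction of the DEG set covered by the union of the top-k
#' target sets, and the smallest k reaching `coverage_threshold`.
#'
#' @param regulons Named list TF -> target vector.
#' @param deg_set Non-empty DEG set.
#' @param coverage_threshold Coverage level of interest (default 0.8).
#' @return Tibble: `k`, `regulon`, `selectivity`, `coverage`; attribute
#'   `min_k` is the smallest k with coverage `>= coverage_threshold` (NA if
#'   never reached).
#' @export
cumulative_deg_coverage <- function(regulons, deg_set,
                                    coverage_threshold = 0.8) {
  if (length(deg_set) == 0) xm_abort("empty DEG set", "bad_input")
  if (length(regulons) == 0) xm_abort("no regulons", "bad_input")
  sel <- regulon_selectivity(regulons, deg_set)
  ord <- order(-sel$selectivity, sel$regulon, method = "radix")
  covered <- character(0)
  cov <- numeric(length(ord))
  for (i in seq_along(ord)) {
    covered <- union(covered,
                     intersect(regulons[[sel$regulon[ord[i]]]], deg_set))
    cov[i] <- length(covered) / length(unique(deg_set))
  }
  out <- tibble::tibble(k = seq_along(ord), regulon = sel$regulon[ord],
                        selectivity = sel$selectivity[ord], coverage = cov)
  hit <- which(cov >= coverage_threshold)
  attr(out, "min_k") <- if (length(hit)) hit[1] else NA_integer_
  class(out) <- c("crossmac_coverage", class(out))
  out
}

#' Normalized binary entropy of regulon subtype activity
#'
#' With `p = pct_res / (pct_res + pct_inf)` the normalized fraction of a
#' regulon's activity in resident cells, the score is
#' `-p log2 p - (1 - p) log2(1 - p)` (with `0 log 0 = 0`), ranging from 0
#' (fully subtype-specific) to 1 (equally active in both subtypes).
#'
#' @param pct_res,pct_inf Fractions of active cells in resident and
#'   infiltrated macrophages (vectorized).
#' @return Numeric entropy in `[0, 1]`; `NA` with a warning where both
#'   fractions are zero (undefined).
#' @examples
#' binary_entropy(0.3, 0.1) # p = 0.75 -> ~0.8113
#' @export
binary_entropy <- function(pct_res, pct_inf) {
  if (any(pct_res < 0 | pct_inf < 0, na.rm = TRUE)) {
    xm_abort("activity fractions must be non-negative", "bad_input")
  }
  tot <- pct_res + pct_inf
  undef <- tot == 0
  if (any(undef, na.rm = TRUE)) {
    xm_warn("entropy undefined where both activity fractions are zero",
            "undefined_entropy")
  }
  p <- ifelse(undef, NA_real_, pct_res / tot)
  term <- function(q) ifelse(is.na(q) | q == 0, 0, -q * log2(q))
  out <- term(p) + term(1 - p)
  ifelse(undef, NA_real_, out)
}

#' Per-regulon subtype activity summary
#'
#' Fraction of active cells per subtype, the normalized resident fraction p
#' and the binary entropy, per regulon.
#'
#' @param activity Binary regulon x cell matrix.
#' @param annotation Tibble with `cell_id`, `subtype`.
#' @return Tibble: `regulon`, `pct_active_resident`, `pct_active_infiltrated`,
#'   `p`, `entropy`.
#' @export
regulon_subtype_activity <- function(activity, annotation) {
  assert_annotation(annotation)
  res_cells <- intersect(colnames(activity),
                         annotation$cell_id[annotation$subtype == "resident"])
  inf_cells <- intersect(colnames(activity),
                         annotation$cell_id[annotation$subtype == "infiltrated"])
  if (length(res_cells) == 0 || length(inf_cells) == 0) {
    xm_abort("both subtypes must have cells in the activity matrix",
             "bad_input")
  }
  pr <- rowMeans(activity[, res_cells, drop = FALSE])
  pi_ <- rowMeans(activity[, inf_cells, drop = FALSE])
  tibble::tibble(regulon = rownames(activity),
                 pct_active_resident = pr,
                 pct_active_infiltrated = pi_,
                 p = ifelse(pr + pi_ > 0, pr / (pr + pi_), NA_real_),
                 entropy = suppressWarnings(binary_entropy(pr, pi_)))
}

#' Regulons correlated with at least one other regulon
#'
#' Pairwise Pearson correlation between binary activity rows; regulons with
#' at least one partner at `|r| > r_threshold` are returned together with
#' the qualifying pair list. Constant rows are excluded with a warning.
#'
#' @param activity Binary regulon x cell matrix (>= 2 regulons).
#' @param r_threshold Absolute correlation threshold (default 0.3).
#' @return List with `correlated` (character vector) and `pairs` (tibble:
#'   `regulon1`, `regulon2`, `r`).
#' @export
regulon_correlation_filter <- function(activity, r_threshold = 0.3) {
  if (nrow(activity) < 2) xm_abort("need >= 2 regulons", "bad_input")
  sds <- apply(activity, 1, stats::sd)
  if (any(sds == 0)) {
    xm_warn(sprintf("%d constant regulon row(s) excluded from correlation",
                    sum(sds == 0)), "constant_rows")
  }
  keep <- which(sds > 0)
  if (length(keep) < 2) {
    return(list(correlated = character(0),
                pairs = tibble::tibble(regulon1 = character(0),
                                       regulon2 = character(0),
                                       r = numeric(0))))
  }
  r <- stats::cor(t(activity[keep, , drop = FALSE]))
  idx <- which(upper.tri(r) & abs(r) > r_threshold, arr.ind = TRUE)
  pairs <- tibble::tibble(regulon1 = rownames(r)[idx[, 1]],
                          regulon2 = rownames(r)[idx[, 2]],
                          r = r[idx])
  list(correlated = sort(unique(c(pairs$regulon1, pairs$regulon2))),
       pairs = pairs)
}

#' Subtype enrichment of regulon activity
#'
#' Per regulon, Fisher's exact test on the 2x2 table of (active/inactive) x
#' (infiltrated/resident), BH-adjusted across regulons. An odds ratio above
#' 1 means activity is enriched in infiltrated macrophages.
#'
#' @param activity Binary regulon x cell matrix.
#' @param annotation Tibble with `cell_id`, `subtype` (both subtypes must be
#'   present among the matrix columns).
#' @return Tibble: `regulon`, the four table counts, `odds_ratio`,
#'   `direction`, `p_value`, `p_adjusted`, `note` (flags degenerate tables).
#' @export
subtype_enrichment <- function(activity, annotation) {
  assert_annotation(annotation)
  ann <- annotation[match(colnames(activity), annotation$cell_id), ]
  if (anyNA(ann$subtype)) {
    xm_abort("all activity cells must be annotated", "bad_input")
  }
  is_inf <- ann$subtype == "infiltrated"
  if (!any(is_inf) || all(is_inf)) {
    xm_abort("both subtypes must have cells", "bad_input")
  }
  rows <- purrr::map_dfr(seq_len(nrow(activity)), function(i) {
    act <- activity[i, ] == 1
    a <- sum(act & is_inf); b <- sum(act & !is_inf)
    c_ <- sum(!act & is_inf); d <- sum(!act & !is_inf)
    ft <- fisher_2x2(a, b, c_, d)
    note <- if ((a + b) == length(act) || (c_ + d) == length(act))
      "degenerate: single activity level" else NA_character_
    tibble::tibble(regulon = rownames(activity)[i],
                   active_infiltrated = a, active_resident = b,
                   inactive_infiltrated = c_, inactive_resident = d,
                   odds_ratio = ft$odds_ratio,
                   direction = dplyr::case_when(
                     !is.na(note) ~ NA_character_,
                     ft$odds_ratio > 1 ~ "infiltrated",
                     TRUE ~ "resident"),
                   p_value = ft$p_value, note = note)
  })
  dplyr::mutate(rows, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
}

#' Map a regulon set into another species through one-to-one orthologs
#'
#' Converts the TF name and every target through the ortholog table.
#' Targets without an ortholog are dropped; regulons whose TF lacks an
#' ortholog, or whose target set becomes empty, are dropped. A per-regulon
#' attrition report is returned.
#'
#' @param regulons Named list TF -> targets, in `from`-species identifiers.
#' @param orthologs Ortholog tibble with `human`, `mouse`, `rat` columns.
#' @param from,to Source and target species (column names of `orthologs`).
#' @return List with `regulons` (mapped named list) and `report` (tibble:
#'   `regulon_from`, `regulon_to`, `n_targets`, `n_mapped`, `kept`,
#'   `reason`).
#' @export
map_regulons_across_species <- function(regulons, orthologs, from, to) {
  for (sp in c(from, to)) {
    if (!sp %in% names(orthologs)) {
      xm_abort(sprintf("unknown species '%s' in ortholog table", sp),
               "bad_input")
    }
  }
  mapped <- list()
  report <- purrr::map_dfr(names(regulons), function(tf) {
    tf_to <- orthologs[[to]][match(tf, orthologs[[from]])]
    targets <- regulons[[tf]]
    t_to <- orthologs[[to]][match(targets, orthologs[[from]])]
    t_to <- t_to[!is.na(t_to)]
    if (is.na(tf_to)) {
      return(tibble::tibble(regulon_from = tf, regulon_to = NA_character_,
                            n_targets = length(targets), n_mapped = length(t_to),
                            kept = FALSE, reason = "TF has no ortholog"))
    }
    if (length(t_to) == 0) {
      return(tibble::tibble(regulon_from = tf, regulon_to = tf_to,
                            n_targets = length(targets), n_mapped = 0L,
                            kept = FALSE, reason = "no mappable targets"))
    }
    mapped[[tf_to]] <<- t_to
    tibble::tibble(regulon_from = tf, regulon_to = tf_to,
                   n_targets = length(targets), n_mapped = length(t_to),
                   kept = TRUE, reason = NA_character_)
  })
  list(regulons = mapped, report = report)
}

# Spearman distance between cells (columns) of a merged binary matrix.
# Convention for degenerate profiles: identical columns (including identical
# constant columns) are at distance 0; a constant column against any
# differing column has rho defined as 0, hence distance 1.
spearman_cell_distance <- function(m) {
  ranks <- apply(m, 2, rank)
  rho <- suppressWarnings(stats::cor(ranks))
  rho[is.na(rho)] <- 0
  d <- 1 - rho
  key <- apply(m, 2, paste, collapse = ",")
  same <- outer(key, key, "==")
  d[same] <- 0
  diag(d) <- 0
  d
}

#' Joint clustering of cells on merged binary regulon activity
#'
#' Merges activity matrices (e.g. one per species, already in a common
#' regulon namespace after ortholog mapping) on their shared regulons and
#' clusters cells with Ward linkage on Spearman distance
#' (`1 - Spearman rho` between binary activity profiles).
#'
#' @param matrices List of binary regulon x cell matrices (or a single
#'   matrix) sharing at least 2 regulon rownames.
#' @param k Number of flat clusters to cut (default 2).
#' @return Object of class `joint_clustering`: list with `hclust`,
#'   `clusters` (named integer vector), `shared_regulons`, `k`.
#' @export
joint_cluster <- function(matrices, k = 2L) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) < 2) {
    xm_abort("fewer than 2 regulons shared across matrices", "bad_input")
  }
  merged <- do.call(cbind, lapply(matrices, function(m)
    m[shared, , drop = FALSE]))
  if (anyDuplicated(colnames(merged))) {
    xm_abort("duplicate cell identifiers across matrices", "bad_input")
  }
  d <- spearman_cell_distance(merged)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, clusters = cl, shared_regulons = shared,
                 k = as.integer(k)),
            class = "joint_clustering")
}

#' Partition TFs by cross-species conservation of regulon activity
#'
#' For each regulon scored on the same cells both natively and through the
#' cross-species-mapped regulon set, the conservation score is the phi
#' coefficient (Pearson correlation of the binary vectors) between the two
#' activity rows restricted to one subtype's cells. TFs are split at the
#' median score (ties upward) into "more conserved" and "less conserved".
#'
#' @param activity_native,activity_cross Binary regulon x cell matrices over
#'   the same cells.
#' @param annotation Tibble with `cell_id`, `subtype`.
#' @param subtype Subtype whose cells are scored (default `"infiltrated"`).
#' @return Tibble: `regulon`, `phi`, `group`; attribute `threshold` holds
#'   the median split point. Regulons absent from either matrix, or with a
#'   constant activity vector, are excluded with a warning.
#' @export
conservation_partition <- function(activity_native, activity_cross,
                                   annotation, subtype = "infiltrated") {
  assert_annotation(annotation)
  cells <- intersect(colnames(activity_native),
                     annotation$cell_id[annotation$subtype == subtype])
  if (length(cells) < 2) {
    xm_abort(sprintf("fewer than 2 '%s' cells shared", subtype), "bad_input")
  }
  shared <- intersect(rownames(activity_native), rownames(activity_cross))
  missing <- setdiff(union(rownames(activity_native),
                           rownames(activity_cross)), shared)
  if (length(missing) > 0) {
    xm_warn(sprintf("%d regulon(s) absent from one matrix; excluded",
                    length(missing)), "excluded_regulons")
  }
  phi <- vapply(shared, function(tf) {
    x <- activity_native[tf, cells]
    y <- activity_cross[tf, cells]
    if (all(x == y)) return(1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  usable <- !is.na(phi)
  if (any(!usable)) {
    xm_warn(sprintf("%d regulon(s) with constant activity excluded",
                    sum(!usable)), "excluded_regulons")
  }
  phi <- phi[usable]
  med <- stats::median(phi)
  out <- tibble::tibble(regulon = names(phi), phi = unname(phi),
                        group = ifelse(phi >= med, "more_conserved",
                                       "less_conserved"))
  attr(out, "threshold") <- med
  out
}

#' Correlation between regulon entropy and selectivity
#'
#' Pearson correlation (two-sided) between the normalized binary entropy and
#' the DEG selectivity across regulons.
#'
#' @param scores Tibble with columns `regulon`, `entropy`, `selectivity`
#'   (e.g. a join of [regulon_subtype_activity()] and
#'   [regulon_selectivity()]).
#' @return One-row tibble: `n`, `r`, `p_value`.
#' @export
entropy_selectivity_correlation <- function(scores) {
  ok <- stats::complete.cases(scores[, c("entropy", "selectivity")])
  x <- scores$entropy[ok]; y <- scores$selectivity[ok]
  if (length(x) < 3) xm_abort("need >= 3 regulons with both scores",
                              "bad_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    xm_abort("correlation undefined for a constant score", "constant_input")
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(n = length(x), r = unname(ct$estimate), p_value = ct$p.value)
}

#' Multi-TF regulation of DEGs versus non-DEGs
#'
#' Counts, per gene in `universe`, the number of regulons containing it, and
#' compares the proportion of genes regulated by at least `min_regulons`
#' TFs between DEGs and non-DEGs with a one-sided two-proportion z-test
#' (continuity-corrected; DEGs hypothesised higher).
#'
#' @param regulons Named list TF -> targets.
#' @param deg_set DEG identifiers (subset of `universe`).
#' @param universe All gene identifiers considered.
#' @param min_regulons Threshold defining "multiple TFs" (default 2).
#' @return One-row tibble: counts, the two proportions, `statistic` (z) and
#'   `p_value`; attribute `regulon_counts` holds the per-gene counts.
#' @export
multi_tf_regulation_test <- function(regulons, deg_set, universe,
                                     min_regulons = 2L) {
  if (!all(deg_set %in% universe)) {
    xm_abort("deg_set must be a subset of universe", "bad_input")
  }
  non_deg <- setdiff(universe, deg_set)
  if (length(non_deg) == 0) xm_abort("empty non-DEG complement", "bad_input")
  counts <- table(factor(unlist(lapply(regulons, unique)), levels = universe))
  counts <- as.integer(counts)
  names(counts) <- universe
  multi <- counts >= min_regulons
  x1 <- sum(multi[deg_set]); n1 <- length(deg_set)
  x2 <- sum(multi[non_deg]); n2 <- length(non_deg)
  zt <- two_proportion_test(x1, n1, x2, n2, alternative = "greater")
  out <- tibble::tibble(n_deg = n1, n_non_deg = n2,
                        multi_deg = x1, multi_non_deg = x2,
                        prop_deg = zt$estimate1, prop_non_deg = zt$estimate2,
                        statistic = zt$statistic, p_value = zt$p_value)
  attr(out, "regulon_counts") <- counts
  out
}
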