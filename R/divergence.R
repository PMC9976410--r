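# Cross-species transcriptional divergence over one-to-one orthologs.
#
# For each ortholog triple with subtype log-fold-changes Lh (human), Lm
# (mouse), Lr (rat), divergence is
#     D = log( 1/2 * [ (Lh - Lm)^2 + (Lh - Lr)^2 ] )
# i.e. the log mean squared human-vs-rodent fold-change discrepancy
# (natural log). Genes are classified into the top 25% (high), bottom 25%
# (low) and middle 50% (medium) of the D distribution.

#' Transcriptional divergence score
#'
#' Vectorized over triples of per-species subtype log-fold-changes. Returns
#' `log(max(floor, 0.5 * ((Lh - Lm)^2 + (Lh - Lr)^2)))`; the floor guards
#' `log(0)` for exactly tied fold changes. Symmetric in mouse and rat.
#'
#' @param lfc_human,lfc_mouse,lfc_rat Numeric vectors of log-fold-changes.
#' @param floor Positive lower bound on the mean squared discrepancy
#'   (default 1e-12).
#' @return Numeric vector of divergence values (natural-log scale).
#' @examples
#' divergence_score(1, 0.5, 0) # log(0.625)
#' @export
divergence_score <- function(lfc_human, lfc_mouse, lfc_rat, floor = 1e-12) {
  if (!all(is.finite(lfc_human), is.finite(lfc_mouse), is.finite(lfc_rat))) {
    xm_abort("log fold changes must be finite", "bad_input")
  }
  if (floor <= 0) xm_abort("floor must be positive", "bad_input")
  msd <- 0.5 * ((lfc_human - lfc_mouse)^2 + (lfc_human - lfc_rat)^2)
  log(pmax(floor, msd))
}

#' Classify genes into high/medium/low divergence groups
#'
#' Labels exactly `floor(n/4)` genes with the largest divergence `high`,
#' `floor(n/4)` with the smallest `low`, and the remainder `medium`. Ties
#' are broken deterministically by lexicographic gene identifier.
#'
#' @param records Tibble with columns `gene` and `divergence`.
#' @param lower,upper Quantile boundaries of the split (defaults 0.25 and
#'   0.75, i.e. the 25/50/25 classification); `floor(n * lower)` genes are
#'   labelled low and `floor(n * (1 - upper))` high.
#' @return The input with a `group` column added (`"high"`, `"medium"`,
#'   `"low"`).
#' @export
classify_divergence <- function(records, lower = 0.25, upper = 0.75) {
  if (!all(c("gene", "divergence") %in% names(records))) {
    xm_abort("records need columns gene and divergence", "bad_input")
  }
  n <- nrow(records)
  if (n < 4) xm_abort("need at least 4 records to classify", "bad_input")
  if (anyNA(records$divergence)) {
    xm_abort("divergence values must not be NA", "bad_input")
  }
  if (!(lower > 0 && upper < 1 && lower < upper)) {
    xm_abort("need 0 < lower < upper < 1", "bad_input")
  }
  k_high <- floor(n * (1 - upper))
  k_low <- floor(n * lower)
  ord <- order_desc_ties_by_id(records$divergence, records$gene)
  group <- character(n)
  group[ord[seq_len(k_high)]] <- "high"
  group[ord[seq(n - k_low + 1L, n)]] <- "low"
  group[group == ""] <- "medium"
  dplyr::mutate(records, group = group)
}

#' Join per-species DE tables into fold-change triples
#'
#' Restricts to complete one-to-one ortholog triples present in all three DE
#' tables and records per-species DEG flags (`p_adjusted < fdr_alpha`).
#' Genes are keyed by their human identifier.
#'
#' @param de_human,de_mouse,de_rat DE tibbles from [find_markers()].
#' @param orthologs Tibble with columns `human`, `mouse`, `rat` (one-to-one).
#' @param fdr_alpha DEG threshold on the BH-adjusted p-value (default 0.05).
#' @return Tibble: `gene`, `log_fc_human/mouse/rat`, `de_human/mouse/rat`,
#'   `de_any`.
#' @export
fold_change_triples <- function(de_human, de_mouse, de_rat, orthologs,
                                fdr_alpha = 0.05) {
  if (!all(c("human", "mouse", "rat") %in% names(orthologs))) {
    xm_abort("ortholog table needs human, mouse, rat columns", "bad_input")
  }
  if (anyDuplicated(orthologs$human) || anyDuplicated(orthologs$mouse) ||
      anyDuplicated(orthologs$rat)) {
    xm_abort("ortholog table is not one-to-one", "bad_input")
  }
  pick <- function(de, sp_col) {
    tibble::tibble(!!sp_col := de$gene,
                   !!paste0("log_fc_", sp_col) := de$log_fc,
                   !!paste0("padj_", sp_col) := de$p_adjusted)
  }
  out <- orthologs |>
    dplyr::inner_join(pick(de_human, "human"), by = "human") |>
    dplyr::inner_join(pick(de_mouse, "mouse"), by = "mouse") |>
    dplyr::inner_join(pick(de_rat, "rat"), by = "rat") |>
    dplyr::transmute(
      gene = .data$human,
      log_fc_human = .data$log_fc_human,
      log_fc_mouse = .data$log_fc_mouse,
      log_fc_rat = .data$log_fc_rat,
      de_human = .data$padj_human < fdr_alpha,
      de_mouse = .data$padj_mouse < fdr_alpha,
      de_rat = .data$padj_rat < fdr_alpha,
      de_any = .data$de_human | .data$de_mouse | .data$de_rat)
  out
}

#' Divergence table over the cross-species DEG universe
#'
#' Computes the divergence score for ortholog triples and classifies them
#' 25/50/25. By default the universe is restricted to genes called DE in at
#' least one species (the cross-species DEG set).
#'
#' @param triples Output of [fold_change_triples()].
#' @param deg_only Restrict to `de_any` genes (default `TRUE`).
#' @param floor Passed to [divergence_score()].
#' @return Tibble: `gene`, `divergence`, `group`.
#' @export
divergence_table <- function(triples, deg_only = TRUE, floor = 1e-12) {
  d <- if (deg_only) dplyr::filter(triples, .data$de_any) else triples
  if (nrow(d) < 4) {
    xm_abort("fewer than 4 genes in the divergence universe", "bad_input")
  }
  rec <- tibble::tibble(
    gene = d$gene,
    divergence = divergence_score(d$log_fc_human, d$log_fc_mouse,
                                  d$log_fc_rat, floor = floor))
  classify_divergence(rec)
}

#' Cross-species fold-change correlation
#'
#' Spearman correlation between two species' log-fold-change vectors over
#' all shared orthologs and over the subset flagged DE in both species.
#'
#' @param fc_a,fc_b Numeric log-fold-change vectors (aligned by ortholog).
#' @param de_both Logical vector: DE in both species.
#' @return Tibble with rows `all` and `de_both`: `subset`, `n`, `rho`,
#'   `p_value` (two-sided). The `de_both` row is `NA` when fewer than 3
#'   genes qualify.
#' @export
fc_correlation <- function(fc_a, fc_b, de_both = NULL) {
  if (length(fc_a) != length(fc_b) || length(fc_a) < 3) {
    xm_abort("need >= 3 aligned fold changes", "bad_input")
  }
  if (stats::sd(fc_a) == 0 || stats::sd(fc_b) == 0) {
    xm_abort("Spearman correlation undefined for a constant vector",
             "constant_input")
  }
  one <- function(x, y, label) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(subset = label, n = length(x), rho = NA_real_,
                            p_value = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    tibble::tibble(subset = label, n = length(x),
                   rho = unname(ct$estimate), p_value = ct$p.value)
  }
  out <- one(fc_a, fc_b, "all")
  if (!is.null(de_both)) {
    out <- dplyr::bind_rows(out, one(fc_a[de_both], fc_b[de_both], "de_both"))
  }
  out
}

#' Species dendrogram from subtype fold changes
#'
#' Hierarchical clustering of species using distance
#' `1 - Spearman rho` between their per-gene log-fold-change vectors
#' (complete rows only) with average linkage.
#'
#' @param fc_matrix Numeric genes x species matrix with species colnames.
#' @return An object of class `species_tree`: list with `hclust`, the
#'   `distances` matrix and a `newick` string.
#' @export
species_dendrogram <- function(fc_matrix) {
  if (is.data.frame(fc_matrix)) {
    fc_matrix <- as.matrix(tibble::column_to_rownames(
      as.data.frame(fc_matrix[c("gene", setdiff(names(fc_matrix), "gene"))]),
      "gene"))
  }
  if (is.null(colnames(fc_matrix)) || ncol(fc_matrix) < 2) {
    xm_abort("fc_matrix needs >= 2 named species columns", "bad_input")
  }
  fc_matrix <- fc_matrix[stats::complete.cases(fc_matrix), , drop = FALSE]
  if (nrow(fc_matrix) < 2) {
    xm_abort("need >= 2 complete ortholog rows", "bad_input")
  }
  rho <- stats::cor(fc_matrix, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, distances = as.matrix(d), newick = newick),
            class = "species_tree")
}

#' First-joined pair of a species tree
#'
#' @param tree A `species_tree`.
#' @return Character vector of the two leaf labels merged first (sorted).
#' @export
first_join <- function(tree) {
  stopifnot(inherits(tree, "species_tree"))
  m <- tree$hclust$merge[1, ]
  sort(tree$hclust$labels[-m])
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species dendrogram (1 - Spearman rho, average linkage)\n")
  cat("  newick:", x$newick, "\n")
  cat("  first join:", paste(first_join(x), collapse = " + "), "\n")
  invisible(x)
}

#' Compare divergence of a functional category against all other DEGs
#'
#' One-sided Mann-Whitney test per category: are the category's divergence
#' values stochastically larger than those of the remaining DEGs?
#'
#' @param records Divergence tibble (`gene`, `divergence`).
#' @param categories Tibble with columns `gene`, `category` (a gene may
#'   appear in several categories).
#' @return Tibble per category: `category`, `n_category`, `n_rest`,
#'   `statistic`, `p_value`, `skipped`, `reason`. Categories with an empty
#'   membership or empty complement are skipped with a warning.
#' @export
group_divergence_comparison <- function(records, categories) {
  if (!all(c("gene", "category") %in% names(categories))) {
    xm_abort("categories need columns gene and category", "bad_input")
  }
  purrr::map_dfr(unique(categories$category), function(cat_name) {
    members <- unique(categories$gene[categories$category == cat_name])
    in_cat <- records$gene %in% members
    x <- records$divergence[in_cat]
    y <- records$divergence[!in_cat]
    if (length(x) == 0 || length(y) == 0) {
      reason <- if (length(x) == 0) "empty category" else "empty complement"
      xm_warn(sprintf("category '%s' skipped: %s", cat_name, reason),
              "skipped_test")
      return(tibble::tibble(category = cat_name, n_category = length(x),
                            n_rest = length(y), statistic = NA_real_,
                            p_value = NA_real_, skipped = TRUE,
                            reason = reason))
    }
    mw <- mw_core(x, y, alternative = "greater")
    tibble::tibble(category = cat_name, n_category = length(x),
                   n_rest = length(y), statistic = mw$u, p_value = mw$p,
                   skipped = FALSE, reason = NA_character_)
  })
}
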