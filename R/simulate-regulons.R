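# Synthetic regulons and binary activity matrices.
#
# Binary activity is generated directly (Bernoulli per cell per regulon)
# rather than through the AUC scorer, so the scorer can be tested
# independently. Subtype-specific regulons are active in a configurably
# higher fraction of their preferred subtype's cells; their target sets are
# enriched for genes with a true subtype effect so that selectivity and
# subtype specificity are coupled, as in real regulatory programs.

#' Generate synthetic regulons and binary activity matrices
#'
#' Samples `n_regulons` transcription factors and target sets from the
#' simulated gene universe, translates both into each species' namespace
#' through the ortholog table, and draws per-cell binary activity. A
#' fraction `frac_subtype_specific_regulons` of regulons is subtype-specific
#' (activation probability `activity_high` in the preferred subtype,
#' `activity_low` in the other, preference alternating
#' resident/infiltrated); the rest are active with probability
#' `activity_neutral` in both subtypes. Subtype-specific regulons draw 70%
#' of their targets from genes with a true subtype effect (when enough
#' exist).
#'
#' @param dataset Output of [generate_dataset()] (uses `ground_truth`,
#'   `orthologs`, `annotation`).
#' @param config The [simulation_config()] used to generate it.
#' @return A list with `regulons` (named list per species: TF -> character
#'   vector of targets), `activity` (named list per species: binary regulons
#'   x cells matrix) and `truth` (tibble: regulon id in human namespace,
#'   preferred subtype or `"none"`).
#' @export
generate_regulons <- function(dataset, config) {
  validate_simulation_config(config)
  gt <- dataset$ground_truth
  orth <- dataset$orthologs
  if (config$targets_per_regulon > nrow(gt) - 1L) {
    xm_abort("targets_per_regulon exceeds the gene universe", "bad_config")
  }
  with_seed(config$seed + 2L, {
    n_reg <- config$n_regulons
    n_spec <- round(config$frac_subtype_specific_regulons * n_reg)
    tf_idx <- sample.int(nrow(gt), n_reg)
    pref <- c(rep(c("resident", "infiltrated"), length.out = n_spec),
              rep("none", n_reg - n_spec))

    de_pool <- which(gt$is_de)
    all_pool <- seq_len(nrow(gt))
    target_idx <- vector("list", n_reg)
    for (j in seq_len(n_reg)) {
      pool <- setdiff(all_pool, tf_idx[j])
      k <- config$targets_per_regulon
      if (pref[j] != "none" && length(de_pool) > 0) {
        k_de <- min(round(0.7 * k), length(setdiff(de_pool, tf_idx[j])))
        picked_de <- sample(setdiff(de_pool, tf_idx[j]), k_de)
        picked_bg <- sample(setdiff(pool, picked_de), k - k_de)
        target_idx[[j]] <- sort(c(picked_de, picked_bg))
      } else {
        target_idx[[j]] <- sort(sample(pool, k))
      }
    }

    species <- c("human", "mouse", "rat")
    regulons <- lapply(stats::setNames(species, species), function(sp) {
      tfs <- orth[[sp]][tf_idx]
      stats::setNames(lapply(target_idx, function(ix) orth[[sp]][ix]), tfs)
    })

    ann <- dataset$annotation
    activity <- lapply(stats::setNames(species, species), function(sp) {
      cells <- ann$cell_id[ann$species == sp]
      subt <- ann$subtype[ann$species == sp]
      m <- matrix(0L, nrow = n_reg, ncol = length(cells),
                  dimnames = list(orth[[sp]][tf_idx], cells))
      for (j in seq_len(n_reg)) {
        p <- if (pref[j] == "none") rep(config$activity_neutral, length(cells))
             else ifelse(subt == pref[j], config$activity_high,
                         config$activity_low)
        m[j, ] <- stats::rbinom(length(cells), 1L, p)
      }
      m
    })

    list(regulons = regulons, activity = activity,
         truth = tibble::tibble(regulon = orth$human[tf_idx],
                                preferred_subtype = pref))
  })
}
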