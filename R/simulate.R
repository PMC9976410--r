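# Synthetic three-species single-cell generator with recorded ground truth.
#
# The generator emulates the statistical structure of a resident-vs-infiltrated
# macrophage comparison in human, mouse and rat: negative-binomial counts,
# subtype log-fold-changes shared across species up to clade-level noise
# (human vs rodents) and within-clade noise (mouse vs rat), promoter elements
# coupled to divergence, and subtype-specific binary regulon activity.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic-data generator. Counts
#' are negative binomial with gene means drawn log-normal around
#' `baseline_mean` and gene-level NB size drawn uniform in
#' `dispersion_range`. A fraction `frac_de` of genes receives a subtype
#' log-fold-change (natural log) drawn `N(0, logfc_scale)`; per species the
#' realised log-fold-change adds clade noise (human only, sd
#' `divergence_noise_sd_clade`) or within-clade noise (mouse and rat
#' independently, sd `divergence_noise_sd_within`), so the injected
#' cross-species divergence is recoverable downstream. TATA/CGI promoter
#' flags are drawn per gene; a flagged gene's clade-noise sd is multiplied by
#' `exp(tata_effect)` (resp. `exp(cgi_effect)`), shifting its log-scale
#' divergence by about twice the effect.
#'
#' @param n_genes Number of genes (>= 40 so the 25/50/25 divergence split is
#'   non-degenerate).
#' @param n_cells_per_subtype_per_species Cells per subtype per species.
#' @param baseline_mean Median expected counts per cell per gene.
#' @param dispersion_range Length-2 positive range for the NB size parameter
#'   (smaller size = more dispersion).
#' @param frac_de Fraction of genes with a true subtype effect.
#' @param logfc_scale SD of the base subtype log-fold-change (natural log).
#' @param divergence_noise_sd_clade SD of human-vs-rodent decorrelation noise.
#' @param divergence_noise_sd_within SD of mouse/rat decorrelation noise.
#' @param tata_effect,cgi_effect Log-multipliers of the clade-noise sd for
#'   TATA/CGI-flagged genes (positive = more divergent).
#' @param tata_rate,cgi_rate Marginal flag probabilities.
#' @param cons_means Named per-group mean conservation (high/medium/low
#'   divergence) used by [generate_promoters()].
#' @param n_regulons,targets_per_regulon Regulon count and size.
#' @param frac_subtype_specific_regulons Fraction of regulons active
#'   preferentially in one subtype.
#' @param activity_high,activity_low Per-cell activation probabilities of a
#'   subtype-specific regulon in its preferred / non-preferred subtype.
#' @param activity_neutral Activation probability of subtype-agnostic
#'   regulons in both subtypes.
#' @param seed Integer seed (< 2^31 - 16; the promoter and regulon
#'   generators use small fixed offsets of it).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_cells_per_subtype_per_species = 300L,
                              baseline_mean = 1,
                              dispersion_range = c(0.5, 2),
                              frac_de = 0.25,
                              logfc_scale = 1,
                              divergence_noise_sd_clade = 0.5,
                              divergence_noise_sd_within = 0.1,
                              tata_effect = 0.5,
                              cgi_effect = -0.5,
                              tata_rate = 0.15,
                              cgi_rate = 0.5,
                              cons_means = c(high = 0.5, medium = 0.6, low = 0.7),
                              n_regulons = 50L,
                              targets_per_regulon = 30L,
                              frac_subtype_specific_regulons = 0.5,
                              activity_high = 0.9,
                              activity_low = 0.1,
                              activity_neutral = 0.4,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_subtype_per_species =
                as.integer(n_cells_per_subtype_per_species),
              baseline_mean = baseline_mean,
              dispersion_range = as.numeric(dispersion_range),
              frac_de = frac_de, logfc_scale = logfc_scale,
              divergence_noise_sd_clade = divergence_noise_sd_clade,
              divergence_noise_sd_within = divergence_noise_sd_within,
              tata_effect = tata_effect, cgi_effect = cgi_effect,
              tata_rate = tata_rate, cgi_rate = cgi_rate,
              cons_means = cons_means,
              n_regulons = as.integer(n_regulons),
              targets_per_regulon = as.integer(targets_per_regulon),
              frac_subtype_specific_regulons = frac_subtype_specific_regulons,
              activity_high = activity_high, activity_low = activity_low,
              activity_neutral = activity_neutral,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_genes < 40L) {
    xm_abort("n_genes must be >= 40 for a non-degenerate 25/50/25 split",
             "bad_config")
  }
  if (cfg$n_cells_per_subtype_per_species < 1L) {
    xm_abort("need at least one cell per subtype per species", "bad_config")
  }
  if (cfg$baseline_mean <= 0) xm_abort("baseline_mean must be > 0", "bad_config")
  if (length(cfg$dispersion_range) != 2L || cfg$dispersion_range[1] <= 0 ||
      diff(cfg$dispersion_range) < 0) {
    xm_abort("dispersion_range must be an increasing positive pair",
             "bad_config")
  }
  for (f in c("frac_de", "tata_rate", "cgi_rate",
              "frac_subtype_specific_regulons", "activity_high",
              "activity_low", "activity_neutral")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      xm_abort(sprintf("%s must lie in [0, 1]", f), "bad_config")
    }
  }
  if (cfg$logfc_scale <= 0) xm_abort("logfc_scale must be > 0", "bad_config")
  if (cfg$divergence_noise_sd_clade < 0 || cfg$divergence_noise_sd_within < 0) {
    xm_abort("noise sds must be >= 0", "bad_config")
  }
  if (!all(c("high", "medium", "low") %in% names(cfg$cons_means))) {
    xm_abort("cons_means needs named entries high, medium, low", "bad_config")
  }
  if (cfg$targets_per_regulon > cfg$n_genes - 1L) {
    xm_abort("targets_per_regulon exceeds the number of available genes",
             "bad_config")
  }
  if (abs(cfg$seed) > 2^31 - 16) xm_abort("seed out of range", "bad_config")
  invisible(cfg)
}

species_gene_names <- function(n) {
  base <- sprintf("g%04d", seq_len(n))
  list(human = toupper(sprintf("GENE%04d", seq_len(n))),
       mouse = sprintf("Gene%04d", seq_len(n)),
       rat   = sprintf("gene%04d", seq_len(n)),
       base  = base)
}

#' Generate a three-species synthetic single-cell dataset
#'
#' Produces one integer count matrix per species (genes x cells, both
#' subtypes), a cell annotation table, a one-to-one ortholog table (species
#' use distinct naming conventions so ortholog mapping is exercised) and a
#' per-gene ground-truth table recording injected log-fold-changes,
#' dispersion, promoter flags and the true divergence value/class (computed
#' from the injected log-fold-changes; `NA` for genes without a subtype
#' effect).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `counts` (named list human/mouse/rat of
#'   integer matrices), `annotation` (tibble: cell_id, species, subtype),
#'   `orthologs` (tibble: human, mouse, rat) and `ground_truth` (tibble).
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  with_seed(config$seed, {
    n <- config$n_genes
    nm <- species_gene_names(n)
    mu <- stats::rlnorm(n, meanlog = log(config$baseline_mean), sdlog = 1)
    size <- stats::runif(n, config$dispersion_range[1], config$dispersion_range[2])
    tata <- stats::rbinom(n, 1L, config$tata_rate) == 1L
    cgi <- stats::rbinom(n, 1L, config$cgi_rate) == 1L

    n_de <- round(config$frac_de * n)
    is_de <- logical(n)
    if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE

    base_fc <- ifelse(is_de, stats::rnorm(n, 0, config$logfc_scale), 0)
    clade_sd <- config$divergence_noise_sd_clade *
      exp(config$tata_effect * tata + config$cgi_effect * cgi)
    eps_h <- ifelse(is_de, stats::rnorm(n, 0, 1) * clade_sd, 0)
    eps_m <- ifelse(is_de, stats::rnorm(n, 0, config$divergence_noise_sd_within), 0)
    eps_r <- ifelse(is_de, stats::rnorm(n, 0, config$divergence_noise_sd_within), 0)
    lfc <- list(human = base_fc + eps_h,
                mouse = base_fc + eps_m,
                rat   = base_fc + eps_r)

    d_true <- ifelse(
      is_de,
      log(pmax(1e-12, 0.5 * ((lfc$human - lfc$mouse)^2 +
                               (lfc$human - lfc$rat)^2))),
      NA_real_)
    class_true <- rep(NA_character_, n)
    if (sum(is_de) >= 4L) {
      de_idx <- which(is_de)
      cls <- classify_divergence(
        tibble::tibble(gene = nm$human[de_idx], divergence = d_true[de_idx]))
      class_true[de_idx] <- cls$group[match(nm$human[de_idx], cls$gene)]
    }

    nc <- config$n_cells_per_subtype_per_species
    counts <- list()
    ann <- list()
    for (sp in c("human", "mouse", "rat")) {
      cells_res <- sprintf("%s_res_%04d", sp, seq_len(nc))
      cells_inf <- sprintf("%s_inf_%04d", sp, seq_len(nc))
      mu_res <- mu
      mu_inf <- mu * exp(lfc[[sp]])
      m_res <- matrix(stats::rnbinom(n * nc, mu = rep(mu_res, nc),
                                     size = rep(size, nc)), nrow = n)
      m_inf <- matrix(stats::rnbinom(n * nc, mu = rep(mu_inf, nc),
                                     size = rep(size, nc)), nrow = n)
      m <- cbind(m_res, m_inf)
      rownames(m) <- nm[[sp]]
      colnames(m) <- c(cells_res, cells_inf)
      counts[[sp]] <- m
      ann[[sp]] <- tibble::tibble(
        cell_id = c(cells_res, cells_inf),
        species = sp,
        subtype = rep(c("resident", "infiltrated"), each = nc))
    }

    ground_truth <- tibble::tibble(
      gene = nm$base,
      human = nm$human, mouse = nm$mouse, rat = nm$rat,
      mean_expression = mu, dispersion = size,
      is_de = is_de,
      lfc_human = lfc$human, lfc_mouse = lfc$mouse, lfc_rat = lfc$rat,
      divergence_true = d_true, divergence_class = class_true,
      tata = tata, cgi = cgi)

    list(counts = counts,
         annotation = dplyr::bind_rows(ann),
         orthologs = tibble::tibble(human = nm$human, mouse = nm$mouse,
                                    rat = nm$rat),
         ground_truth = ground_truth)
  })
}
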