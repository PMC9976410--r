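# End-to-end pipeline orchestration. Stages communicate through files
# (TSV/MTX/FASTA/JSON) under the output directory so that any stage can be
# re-run or substituted; a manifest records parameters and per-stage row
# counts (no timestamps, so identical config + seed reproduces all outputs
# byte-identically).

PIPELINE_STAGES <- c("simulate", "qc", "de", "divergence", "promoter",
                     "dm", "regulon")

#' Pipeline configuration
#'
#' @param outdir Output directory for all stage files.
#' @param simulation A [simulation_config()] (used by the `simulate` stage;
#'   ignored when `input_paths` supplies user data).
#' @param input_paths Optional named list overriding raw inputs instead of
#'   simulating: `counts` (named character vector of MTX directories per
#'   species), `annotation`, `orthologs` (TSV paths), `promoters_dir`,
#'   `regulons` and `activity` (named vectors per species). Only the stages
#'   you run need their inputs present.
#' @param min_pct,logfc_threshold DE prefilters (defaults 0.1, 0.25).
#' @param fdr_alpha DEG threshold on BH-adjusted p (default 0.05).
#' @param divergence_quantiles Lower/upper split quantiles (0.25, 0.75).
#' @param r_threshold Regulon correlation threshold (default 0.3).
#' @param dm_window DM running-median window (odd, default 51).
#' @param top_fraction AUC top fraction (default 0.05).
#' @param k_clusters Flat cluster count for joint clustering (default 2).
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulation = simulation_config(),
                            input_paths = NULL,
                            min_pct = 0.1,
                            logfc_threshold = 0.25,
                            fdr_alpha = 0.05,
                            divergence_quantiles = c(0.25, 0.75),
                            r_threshold = 0.3,
                            dm_window = 51L,
                            top_fraction = 0.05,
                            k_clusters = 2L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    xm_abort("fdr_alpha must lie in (0, 1)", "bad_config")
  }
  q <- divergence_quantiles
  if (length(q) != 2 || !(q[1] > 0 && q[2] < 1 && q[1] < q[2])) {
    xm_abort("divergence_quantiles must be an ordered pair in (0, 1)",
             "bad_config")
  }
  structure(list(outdir = outdir, simulation = simulation,
                 input_paths = input_paths, min_pct = min_pct,
                 logfc_threshold = logfc_threshold, fdr_alpha = fdr_alpha,
                 divergence_quantiles = q, r_threshold = r_threshold,
                 dm_window = as.integer(dm_window),
                 top_fraction = top_fraction,
                 k_clusters = as.integer(k_clusters),
                 log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, ...) {
  if (config$log_level == "info") message("[crossmac] ", ...)
}

pipe_need <- function(path, stage) {
  miss <- path[!file.exists(path)]
  if (length(miss) > 0) {
    xm_abort(sprintf("stage '%s' is missing input: %s", stage,
                     paste(miss, collapse = ", ")), "missing_input")
  }
  invisible(path)
}

SPECIES <- c("human", "mouse", "rat")

# Resolve where each artifact lives: outdir by default, input_paths override
# for raw inputs.
pipeline_paths <- function(config) {
  o <- config$outdir
  ip <- config$input_paths %||% list()
  counts_dirs <- ip$counts %||%
    stats::setNames(file.path(o, "counts", SPECIES), SPECIES)
  list(
    counts = counts_dirs,
    qc_counts = stats::setNames(file.path(o, "qc", SPECIES), SPECIES),
    annotation = ip$annotation %||% file.path(o, "annotation.tsv"),
    orthologs = ip$orthologs %||% file.path(o, "orthologs.tsv"),
    ground_truth = file.path(o, "ground_truth.json"),
    promoters_dir = ip$promoters_dir %||% file.path(o, "promoters"),
    regulons = ip$regulons %||%
      stats::setNames(file.path(o, "regulons",
                                paste0("regulons_", SPECIES, ".json")),
                      SPECIES),
    activity = ip$activity %||%
      stats::setNames(file.path(o, "regulons",
                                paste0("activity_", SPECIES, ".tsv")),
                      SPECIES),
    de = stats::setNames(file.path(o, "de", paste0("de_", SPECIES, ".tsv")),
                         SPECIES),
    divergence = file.path(o, "divergence", "divergence.tsv"),
    triples = file.path(o, "divergence", "fc_triples.tsv"),
    tree = file.path(o, "divergence", "species_tree.nwk"),
    fc_cor = file.path(o, "divergence", "fc_correlations.tsv"),
    promoter_tests = file.path(o, "promoter", "element_tests.tsv"),
    cons_profile = file.path(o, "promoter", "conservation_profile.tsv"),
    cons_tests = file.path(o, "promoter", "conservation_ks.tsv"),
    dm_dir = file.path(o, "dm"),
    regulon_dir = file.path(o, "regulon_analytics"),
    manifest = file.path(o, "manifest.json"))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order: `simulate` (synthetic data with
#' ground truth), `qc` (count filtering), `de` (per-species normalization +
#' Wilcoxon markers), `divergence` (ortholog fold-change triples, divergence
#' classification, species tree, cross-species correlations), `promoter`
#' (element-divergence tests, conservation profiles and KS tests), `dm`
#' (distance-to-median variability with group/element tests and the
#' expression-binned control) and `regulon` (selectivity, coverage, entropy,
#' correlation filtering, subtype enrichment, cross-species mapping, joint
#' clustering, conservation partition, multi-TF test). All outputs are
#' files under `config$outdir`; a manifest with parameters and per-stage
#' row counts is written last. Re-running with an identical config
#' reproduces every output byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param stages `"all"` or a subset of
#'   `c("simulate","qc","de","divergence","promoter","dm","regulon")`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0) {
    xm_abort(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")),
             "bad_config")
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  p <- pipeline_paths(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "crossmac",
                   version = as.character(utils::packageVersion("crossmac")),
                   parameters = config[setdiff(names(config),
                                               c("simulation", "input_paths",
                                                 "outdir"))],
                   simulation = unclass(config$simulation),
                   seed = config$simulation$seed,
                   stages = list())
  for (st in stages) {
    pipe_log(config, "stage: ", st)
    manifest$stages[[st]] <- switch(st,
      simulate = stage_simulate(config, p),
      qc = stage_qc(config, p),
      de = stage_de(config, p),
      divergence = stage_divergence(config, p),
      promoter = stage_promoter(config, p),
      dm = stage_dm(config, p),
      regulon = stage_regulon(config, p))
  }
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(config, p) {
  ds <- generate_dataset(config$simulation)
  for (sp in SPECIES) write_count_matrix(ds$counts[[sp]], p$counts[[sp]])
  readr::write_tsv(ds$annotation, p$annotation)
  readr::write_tsv(ds$orthologs, p$orthologs)
  jsonlite::write_json(ds$ground_truth, p$ground_truth, auto_unbox = FALSE,
                       digits = NA, na = "null")
  prom <- generate_promoters(ds$ground_truth, config$simulation)
  write_promoters(prom, p$promoters_dir)
  reg <- generate_regulons(ds, config$simulation)
  dir.create(dirname(p$regulons[["human"]]), recursive = TRUE,
             showWarnings = FALSE)
  for (sp in SPECIES) {
    write_regulons_json(reg$regulons[[sp]], p$regulons[[sp]])
    write_activity_tsv(reg$activity[[sp]], p$activity[[sp]])
  }
  readr::write_tsv(reg$truth, file.path(dirname(p$regulons[["human"]]),
                                        "regulon_truth.tsv"))
  list(n_genes = nrow(ds$ground_truth), n_cells = nrow(ds$annotation),
       n_regulons = length(reg$regulons$human))
}

stage_qc <- function(config, p) {
  out <- list()
  for (sp in SPECIES) {
    pipe_need(file.path(p$counts[[sp]], "matrix.mtx"), "qc")
    m <- read_count_matrix(p$counts[[sp]])
    # synthetic data carries no mitochondrial genes; the bounds rules apply
    f <- qc_filter(m, mito_gene_ids = character(),
                   min_genes_per_cell = min(200L, nrow(m)))
    write_count_matrix(f, p$qc_counts[[sp]])
    out[[sp]] <- list(genes = nrow(f), cells = ncol(f))
  }
  out
}

stage_de <- function(config, p) {
  pipe_need(p$annotation, "de")
  ann <- readr::read_tsv(p$annotation, show_col_types = FALSE)
  out <- list()
  dir.create(dirname(p$de[["human"]]), recursive = TRUE, showWarnings = FALSE)
  for (sp in SPECIES) {
    pipe_need(file.path(p$qc_counts[[sp]], "matrix.mtx"), "de")
    m <- read_count_matrix(p$qc_counts[[sp]])
    norm <- log_normalize(m)
    de <- find_markers(norm, ann[ann$species == sp, ],
                       min_pct = config$min_pct,
                       logfc_threshold = config$logfc_threshold)
    write_de_tsv(de, p$de[[sp]])
    out[[sp]] <- list(tested = nrow(de),
                      deg = sum(de$p_adjusted < config$fdr_alpha))
  }
  out
}

stage_divergence <- function(config, p) {
  pipe_need(c(p$de, p$orthologs), "divergence")
  orth <- readr::read_tsv(p$orthologs, show_col_types = FALSE)
  de <- lapply(p$de, read_de_tsv)
  triples <- fold_change_triples(de$human, de$mouse, de$rat, orth,
                                 fdr_alpha = config$fdr_alpha)
  dir.create(dirname(p$divergence), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(triples, p$triples)
  div <- divergence_table(triples)
  div <- classify_divergence(div[, c("gene", "divergence")],
                             lower = config$divergence_quantiles[1],
                             upper = config$divergence_quantiles[2])
  readr::write_tsv(div, p$divergence)
  fc <- as.matrix(triples[, c("log_fc_human", "log_fc_mouse", "log_fc_rat")])
  colnames(fc) <- SPECIES
  tree <- species_dendrogram(fc)
  writeLines(tree$newick, p$tree)
  cors <- dplyr::bind_rows(
    dplyr::mutate(fc_correlation(triples$log_fc_human, triples$log_fc_mouse,
                                 triples$de_human & triples$de_mouse),
                  pair = "human_mouse"),
    dplyr::mutate(fc_correlation(triples$log_fc_human, triples$log_fc_rat,
                                 triples$de_human & triples$de_rat),
                  pair = "human_rat"),
    dplyr::mutate(fc_correlation(triples$log_fc_mouse, triples$log_fc_rat,
                                 triples$de_mouse & triples$de_rat),
                  pair = "mouse_rat"))
  readr::write_tsv(cors, p$fc_cor)
  list(n_triples = nrow(triples), n_deg = nrow(div),
       first_join = paste(first_join(tree), collapse = "+"))
}

stage_promoter <- function(config, p) {
  pipe_need(c(file.path(p$promoters_dir, "promoter_flags.tsv"),
              p$divergence), "promoter")
  prom <- read_promoters(p$promoters_dir)
  div <- readr::read_tsv(p$divergence, show_col_types = FALSE)
  dir.create(dirname(p$promoter_tests), recursive = TRUE, showWarnings = FALSE)
  tests <- dplyr::bind_rows(
    element_divergence_test(prom, div, "tata", alternative = "greater"),
    element_divergence_test(prom, div, "cgi", alternative = "less"),
    element_divergence_test(prom, div, "tata_and_cgi",
                            alternative = "greater"))
  readr::write_tsv(tests, p$promoter_tests)
  prof <- conservation_profile(prom, div[, c("gene", "group")])
  readr::write_tsv(prof, p$cons_profile)
  ks <- dplyr::bind_rows(
    conservation_group_test(prom, div[, c("gene", "group")], "high", "medium"),
    conservation_group_test(prom, div[, c("gene", "group")], "high", "low"))
  readr::write_tsv(ks, p$cons_tests)
  list(n_promoters = nrow(prom), n_tests = nrow(tests))
}

stage_dm <- function(config, p) {
  pipe_need(c(file.path(p$qc_counts[["human"]], "matrix.mtx"),
              p$annotation, p$divergence), "dm")
  ann <- readr::read_tsv(p$annotation, show_col_types = FALSE)
  div <- readr::read_tsv(p$divergence, show_col_types = FALSE)
  prom_flags_path <- file.path(p$promoters_dir, "promoter_flags.tsv")
  dir.create(p$dm_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  m <- read_count_matrix(p$qc_counts[["human"]])
  for (subt in c("resident", "infiltrated")) {
    cells <- intersect(colnames(m),
                       ann$cell_id[ann$species == "human" &
                                     ann$subtype == subt])
    dm <- dm_statistic(m, cells = cells, window = config$dm_window)
    readr::write_tsv(dm, file.path(p$dm_dir, paste0("dm_human_", subt, ".tsv")))
    reports <- list(dm_group_test(dm, div))
    if (file.exists(prom_flags_path)) {
      flags <- readr::read_tsv(prom_flags_path, show_col_types = FALSE)
      reports <- c(reports, list(dm_element_test(dm, flags, "tata")))
    }
    binned <- expression_binned_control(dm, div)
    readr::write_tsv(binned,
                     file.path(p$dm_dir, paste0("dm_binned_", subt, ".tsv")))
    readr::write_tsv(dplyr::bind_rows(reports),
                     file.path(p$dm_dir, paste0("dm_tests_", subt, ".tsv")))
    out[[subt]] <- list(n_genes = nrow(dm))
  }
  out
}

stage_regulon <- function(config, p) {
  pipe_need(c(p$regulons[["human"]], p$regulons[["mouse"]],
              p$activity[["human"]], p$activity[["mouse"]],
              p$annotation, p$orthologs, p$divergence), "regulon")
  ann <- readr::read_tsv(p$annotation, show_col_types = FALSE)
  orth <- readr::read_tsv(p$orthologs, show_col_types = FALSE)
  div <- readr::read_tsv(p$divergence, show_col_types = FALSE)
  deg <- list(human = div$gene,
              mouse = orth$mouse[match(div$gene, orth$human)])
  dir.create(p$regulon_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  summaries <- list()
  for (sp in c("human", "mouse")) {
    regs <- read_regulons_json(p$regulons[[sp]])
    act <- read_activity_tsv(p$activity[[sp]])
    sel <- regulon_selectivity(regs, deg[[sp]])
    cov <- cumulative_deg_coverage(regs, deg[[sp]])
    sub_act <- regulon_subtype_activity(act, ann)
    enr <- subtype_enrichment(act, ann)
    corr <- regulon_correlation_filter(act, r_threshold = config$r_threshold)
    scores <- dplyr::inner_join(sub_act, sel, by = "regulon")
    es_cor <- entropy_selectivity_correlation(scores)
    mt <- multi_tf_regulation_test(regs, deg[[sp]],
                                   universe = orth[[sp]])
    readr::write_tsv(scores, file.path(p$regulon_dir,
                                       paste0("regulon_scores_", sp, ".tsv")))
    readr::write_tsv(cov, file.path(p$regulon_dir,
                                    paste0("deg_coverage_", sp, ".tsv")))
    readr::write_tsv(enr, file.path(p$regulon_dir,
                                    paste0("subtype_enrichment_", sp, ".tsv")))
    readr::write_tsv(corr$pairs, file.path(p$regulon_dir,
                                           paste0("correlated_pairs_", sp,
                                                  ".tsv")))
    readr::write_tsv(dplyr::bind_rows(
      dplyr::mutate(es_cor, report = "entropy_selectivity"),
      dplyr::mutate(mt, report = "multi_tf")),
      file.path(p$regulon_dir, paste0("regulon_tests_", sp, ".tsv")))
    summaries[[sp]] <- list(regs = regs, act = act)
    out[[sp]] <- list(n_regulons = length(regs),
                      coverage_k80 = attr(cov, "min_k"),
                      entropy_selectivity_r = es_cor$r)
  }
  mapping <- map_regulons_across_species(summaries$mouse$regs, orth,
                                         from = "mouse", to = "human")
  readr::write_tsv(mapping$report,
                   file.path(p$regulon_dir, "mouse_to_human_mapping.tsv"))
  mouse_act <- summaries$mouse$act
  mapped_names <- mapping$report$regulon_to[
    match(rownames(mouse_act), mapping$report$regulon_from)]
  keep <- !is.na(mapped_names) & mapping$report$kept[
    match(rownames(mouse_act), mapping$report$regulon_from)]
  mouse_act_mapped <- mouse_act[keep, , drop = FALSE]
  rownames(mouse_act_mapped) <- mapped_names[keep]
  jc <- joint_cluster(list(summaries$human$act, mouse_act_mapped),
                      k = config$k_clusters)
  readr::write_tsv(tidy(jc), file.path(p$regulon_dir, "joint_clusters.tsv"))
  out$joint <- list(n_shared = length(jc$shared_regulons),
                    k = jc$k)
  out
}
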