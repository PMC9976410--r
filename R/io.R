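# Readers and writers for the pipeline's on-disk formats: MTX + TSV count
# matrices, annotation/ortholog TSVs, promoter FASTA + flag/conservation
# TSVs, regulon JSON and binary activity TSVs.

#' Write a count matrix as MTX plus gene/barcode TSVs
#'
#' @param counts Gene x cell matrix.
#' @param dir Output directory (created if needed).
#' @param prefix File prefix (`<prefix>matrix.mtx`, `<prefix>genes.tsv`,
#'   `<prefix>barcodes.tsv`).
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(counts, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::Matrix(as_dense(counts), sparse = TRUE),
                    "generalMatrix")
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "genes.tsv",
                                           "barcodes.tsv")))
  Matrix::writeMM(sp, paths[1])
  readr::write_tsv(tibble::tibble(gene = rownames(counts)), paths[2],
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(counts)), paths[3],
                   col_names = FALSE)
  invisible(paths)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding the three files.
#' @param prefix File prefix used when writing.
#' @return Dense integer gene x cell matrix with dimnames.
#' @export
read_count_matrix <- function(dir, prefix = "") {
  m <- as.matrix(Matrix::readMM(file.path(dir, paste0(prefix, "matrix.mtx"))))
  genes <- readr::read_tsv(file.path(dir, paste0(prefix, "genes.tsv")),
                           col_names = "gene", show_col_types = FALSE)$gene
  cells <- readr::read_tsv(file.path(dir, paste0(prefix, "barcodes.tsv")),
                           col_names = "barcode", show_col_types = FALSE)$barcode
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  m
}

#' Write promoter records as FASTA plus flag and conservation TSVs
#'
#' Sequences go to `<prefix>promoters.fasta` (header = gene id), flags and
#' strand to `<prefix>promoter_flags.tsv`, and conservation to a long
#' `<prefix>conservation.tsv` (gene, pos 1..L upstream-to-TSS, score).
#'
#' @param promoters Promoter tibble (see [generate_promoters()]).
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Invisibly, the paths written.
#' @export
write_promoters <- function(promoters, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("promoters.fasta",
                                           "promoter_flags.tsv",
                                           "conservation.tsv")))
  seqs <- Biostrings::DNAStringSet(stats::setNames(promoters$sequence,
                                                   promoters$gene))
  Biostrings::writeXStringSet(seqs, paths[1])
  readr::write_tsv(promoters[, c("gene", "strand", "tata", "cgi")], paths[2])
  cons <- tidyr::unnest(
    dplyr::mutate(promoters[, c("gene", "conservation")],
                  pos = purrr::map(.data$conservation, seq_along)),
    c("conservation", "pos"))
  readr::write_tsv(cons[, c("gene", "pos", "conservation")], paths[3])
  invisible(paths)
}

#' Read promoter records written by [write_promoters()]
#'
#' @param dir Directory holding the files.
#' @param prefix File prefix used when writing.
#' @return Promoter tibble with `gene`, `strand`, `sequence`, `tata`, `cgi`,
#'   `conservation` list-column.
#' @export
read_promoters <- function(dir, prefix = "") {
  seqs <- Biostrings::readDNAStringSet(
    file.path(dir, paste0(prefix, "promoters.fasta")))
  flags <- readr::read_tsv(file.path(dir, paste0(prefix, "promoter_flags.tsv")),
                           show_col_types = FALSE)
  cons <- readr::read_tsv(file.path(dir, paste0(prefix, "conservation.tsv")),
                          show_col_types = FALSE)
  cons_list <- split(cons$conservation, cons$gene)[flags$gene]
  tibble::tibble(gene = flags$gene, strand = flags$strand,
                 sequence = unname(as.character(seqs[flags$gene])),
                 tata = flags$tata, cgi = flags$cgi,
                 conservation = unname(cons_list))
}

#' Write regulons as JSON (`{tf: [targets, ...]}`)
#'
#' @param regulons Named list TF -> targets.
#' @param path Output path.
#' @export
write_regulons_json <- function(regulons, path) {
  jsonlite::write_json(regulons, path, auto_unbox = FALSE, pretty = FALSE)
  invisible(path)
}

#' Read regulons from JSON
#'
#' @param path JSON path (`{tf: [targets, ...]}`).
#' @return Named list TF -> character vector of targets.
#' @export
read_regulons_json <- function(path) {
  lapply(jsonlite::read_json(path), function(x) unlist(x, use.names = FALSE))
}

#' Write a binary activity matrix as TSV (regulons x cells)
#'
#' @param activity Binary matrix with regulon rownames and cell colnames.
#' @param path Output path.
#' @export
write_activity_tsv <- function(activity, path) {
  df <- tibble::as_tibble(as.data.frame(activity), rownames = "regulon")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a binary activity matrix written by [write_activity_tsv()]
#'
#' @param path TSV path.
#' @return Integer matrix regulons x cells.
#' @export
read_activity_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a DE result table as TSV with Seurat-style column names
#'
#' @param de DE tibble from [find_markers()].
#' @param path Output path.
#' @export
write_de_tsv <- function(de, path) {
  readr::write_tsv(
    tibble::tibble(gene = de$gene, log_fc = de$log_fc,
                   pct.1 = de$pct_in_group, pct.2 = de$pct_out_group,
                   p_val = de$p_value, p_val_adj = de$p_adjusted),
    path)
  invisible(path)
}

#' Read a DE TSV written by [write_de_tsv()]
#'
#' @param path TSV path.
#' @return DE tibble with the package's column names.
#' @export
read_de_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(gene = df$gene, log_fc = df$log_fc,
                 pct_in_group = df$pct.1, pct_out_group = df$pct.2,
                 p_value = df$p_val, p_adjusted = df$p_val_adj)
}
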