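# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can catch precisely.
xm_abort <- function(msg, class) {
  rlang::abort(msg, class = paste0("crossmac_", class))
}

xm_warn <- function(msg, class) {
  rlang::warn(msg, class = paste0("crossmac_", class))
}

assert_count_matrix <- function(counts, arg = "counts") {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix"))) {
    xm_abort(sprintf("`%s` must be a matrix of gene x cell counts", arg),
             "bad_input")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    xm_abort(sprintf("`%s` must have gene rownames and cell colnames", arg),
             "bad_input")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    xm_abort(sprintf("`%s` has duplicated gene or cell identifiers", arg),
             "bad_input")
  }
  if (min(counts) < 0) {
    xm_abort(sprintf("`%s` contains negative values", arg), "bad_input")
  }
  invisible(TRUE)
}

assert_annotation <- function(annotation) {
  req <- c("cell_id", "species", "subtype")
  if (!is.data.frame(annotation) || !all(req %in% names(annotation))) {
    xm_abort("cell annotation needs columns cell_id, species, subtype",
             "bad_input")
  }
  invisible(TRUE)
}

# Dense numeric matrix view (counts may come in sparse).
as_dense <- function(m) {
  if (methods::is(m, "Matrix")) as.matrix(m) else m
}

# Deterministic order: numeric key descending, gene id ascending for ties.
order_desc_ties_by_id <- function(values, ids) {
  order(-values, ids, method = "radix")
}
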