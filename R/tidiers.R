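# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a species tree
#'
#' @param x A `species_tree` from [species_dendrogram()].
#' @param ... Unused.
#' @return Tibble of merge steps: `step`, `height`, `members`.
#' @export
tidy.species_tree <- function(x, ...) {
  hc <- x$hclust
  members <- vapply(seq_len(nrow(hc$merge)), function(i) {
    leaves <- function(node) {
      if (node < 0) return(hc$labels[-node])
      unlist(lapply(hc$merge[node, ], leaves))
    }
    paste(sort(unlist(lapply(hc$merge[i, ], leaves))), collapse = "+")
  }, character(1))
  tibble::tibble(step = seq_along(hc$height), height = hc$height,
                 members = members)
}

#' One-row summary of a species tree
#'
#' @param x A `species_tree`.
#' @param ... Unused.
#' @return Tibble: `n_species`, `first_join`, `newick`.
#' @export
glance.species_tree <- function(x, ...) {
  tibble::tibble(n_species = length(x$hclust$labels),
                 first_join = paste(first_join(x), collapse = "+"),
                 newick = x$newick)
}

#' Tidy a joint clustering
#'
#' @param x A `joint_clustering` from [joint_cluster()].
#' @param ... Unused.
#' @return Tibble: `cell_id`, `cluster`.
#' @export
tidy.joint_clustering <- function(x, ...) {
  tibble::tibble(cell_id = names(x$clusters),
                 cluster = unname(x$clusters))
}

#' One-row summary of a joint clustering
#'
#' @param x A `joint_clustering`.
#' @param ... Unused.
#' @return Tibble: `n_cells`, `n_shared_regulons`, `k`.
#' @export
glance.joint_clustering <- function(x, ...) {
  tibble::tibble(n_cells = length(x$clusters),
                 n_shared_regulons = length(x$shared_regulons),
                 k = x$k)
}

#' Tidy binarized regulon activity
#'
#' @param x A `regulon_activity` from [binarize_activity()].
#' @param ... Unused.
#' @return The per-regulon threshold tibble with the active-cell fraction.
#' @export
tidy.regulon_activity <- function(x, ...) {
  dplyr::mutate(x$thresholds,
                frac_active = rowMeans(x$activity))
}

#' One-row summary of binarized regulon activity
#'
#' @param x A `regulon_activity`.
#' @param ... Unused.
#' @return Tibble: `n_regulons`, `n_cells`, `frac_active`.
#' @export
glance.regulon_activity <- function(x, ...) {
  tibble::tibble(n_regulons = nrow(x$activity),
                 n_cells = ncol(x$activity),
                 frac_active = mean(x$activity))
}

#' @export
print.joint_clustering <- function(x, ...) {
  cat("Joint clustering (Ward linkage, Spearman distance)\n")
  cat(sprintf("  %d cells, %d shared regulons, k = %d\n",
              length(x$clusters), length(x$shared_regulons), x$k))
  print(table(cluster = x$clusters))
  invisible(x)
}
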