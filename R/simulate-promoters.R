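# Synthetic promoter sequences and conservation profiles.
#
# Sequences are i.i.d. uniform nucleotides outside planted elements. Genes
# flagged TATA get a TATAWAWR match planted inside the core promoter
# (positions -100..-1 relative to the TSS); genes flagged CGI get a 250-nt
# GC/CpG-rich island that satisfies the Gardiner-Garden--Frommer criteria
# (verified against cgi_detect at generation time). Per-base conservation is
# beta-distributed with divergence-group-specific means.

PROMOTER_LEN <- 500L

random_seq <- function(len, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

plant_at <- function(seq, insert, start) {
  # start is a 1-based string index
  substr(seq, start, start + nchar(insert) - 1L) <- insert
  seq
}

random_tata_motif <- function() {
  w <- function() sample(c("A", "T"), 1)
  r <- function() sample(c("A", "G"), 1)
  paste0("TATA", w(), "A", w(), r())
}

#' Generate synthetic promoter records
#'
#' Builds one 500-nt upstream sequence (positions -500..-1 relative to the
#' TSS, stored 5'->3' on the gene's strand) and one 500-length conservation
#' vector per gene in `ground_truth`. TATA-flagged genes are guaranteed a
#' consensus match in the core promoter; CGI-flagged genes are guaranteed a
#' detectable island. Conservation means follow the gene's true divergence
#' class (`cons_means` in the config); unclassified genes get the medium
#' mean.
#'
#' @param ground_truth Ground-truth tibble from [generate_dataset()].
#' @param config The [simulation_config()] used to generate it.
#' @return A tibble with columns `gene` (human id), `strand`, `sequence`,
#'   `tata`, `cgi` and a list-column `conservation` of numeric(500).
#' @export
generate_promoters <- function(ground_truth, config) {
  validate_simulation_config(config)
  if (!all(c("human", "tata", "cgi", "divergence_class") %in%
             names(ground_truth))) {
    xm_abort("ground_truth lacks required columns", "bad_input")
  }
  with_seed(config$seed + 1L, {
    n <- nrow(ground_truth)
    cons_conc <- 30
    seqs <- character(n)
    cons <- vector("list", n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      s <- random_seq(PROMOTER_LEN)
      if (ground_truth$cgi[i]) {
        # island end <= position 400 when a TATA motif will also be planted,
        # so the two elements never overwrite each other
        max_start <- if (ground_truth$tata[i]) 150L else 251L
        for (try in 1:25) {
          island <- random_seq(250L, prob = c(0.10, 0.40, 0.40, 0.10))
          cand <- plant_at(s, island, sample.int(max_start, 1))
          if (isTRUE(cgi_detect_seq(cand)$cgi)) { s <- cand; break }
        }
      }
      if (ground_truth$tata[i]) {
        # string index 401..493 <=> TSS-relative start -100..-8
        s <- plant_at(s, random_tata_motif(), sample(401:493, 1))
      }
      seqs[i] <- s
      grp <- ground_truth$divergence_class[i]
      m <- if (is.na(grp)) config$cons_means[["medium"]] else
        config$cons_means[[grp]]
      cons[[i]] <- stats::rbeta(PROMOTER_LEN, m * cons_conc,
                                (1 - m) * cons_conc)
    }
    tibble::tibble(gene = ground_truth$human, strand = strand,
                   sequence = seqs, tata = ground_truth$tata,
                   cgi = ground_truth$cgi, conservation = cons)
  })
}
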