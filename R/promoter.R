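# Promoter architecture: TATA-box scan, CpG-island detection, upstream
# conservation profiles and element-divergence association tests.
#
# Coordinates are TSS-relative: a 500-nt upstream sequence covers positions
# -500..-1 (stored 5'->3' on the gene's strand), with -1 the base
# immediately upstream of the TSS.

TATA_REGEX <- "TATA[AT]A[AT][AG]"

#' Scan a promoter sequence for a core TATA-box
#'
#' Matches the consensus TATAWAWR (W = A/T, R = A/G) and reports whether any
#' match starts within the core promoter (the `core_window` bases
#' immediately upstream of the TSS, default 100).
#'
#' @param sequence A single upstream sequence (5'->3', ending at position -1).
#' @param core_window Width of the core promoter window (default 100).
#' @return List with `hit` (logical) and `positions` (TSS-relative start
#'   positions of matches inside the core window; -1 is the base immediately
#'   upstream of the TSS).
#' @examples
#' tata_scan(paste0(strrep("C", 450), "TATAAAAG", strrep("C", 42)))
#' @export
tata_scan <- function(sequence, core_window = 100L) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    xm_abort("sequence must be a single string", "bad_input")
  }
  len <- nchar(sequence)
  if (len < core_window) {
    xm_abort("sequence shorter than the core window", "bad_input")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    xm_abort("sequence must be over the alphabet {A,C,G,T,N}", "bad_input")
  }
  starts <- integer(0)
  offset <- 0L
  s <- sequence
  repeat { # gregexpr misses overlapping matches; rescan after each hit
    m <- regexpr(TATA_REGEX, s)
    if (m == -1L) break
    starts <- c(starts, offset + as.integer(m))
    offset <- offset + as.integer(m)
    s <- substr(s, as.integer(m) + 1L, nchar(s))
  }
  rel <- starts - (len + 1L)
  rel <- rel[rel >= -core_window]
  list(hit = length(rel) > 0, positions = rel)
}

# Sequence-level CGI detector shared by cgi_detect and the generator.
cgi_detect_seq <- function(sequence, min_len = 200L, gc_min = 0.5,
                           obsexp_min = 0.6) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  n_frac <- mean(chars == "N")
  if (n_frac > 0.5) {
    xm_warn("sequence is more than 50% N; CGI call indeterminate",
            "indeterminate")
    return(list(cgi = NA, islands = tibble::tibble(start = integer(0),
                                                   end = integer(0)),
                indeterminate = TRUE))
  }
  if (len < min_len) {
    return(list(cgi = FALSE, islands = tibble::tibble(start = integer(0),
                                                      end = integer(0)),
                indeterminate = FALSE))
  }
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_cpg <- c(is_c[-len] & is_g[-1], FALSE) # CpG dinucleotide starts
  cum_c <- cumsum(is_c); cum_g <- cumsum(is_g); cum_cpg <- cumsum(is_cpg)
  win_sum <- function(cum, from, to) cum[to] - c(0, cum)[from]
  starts <- seq_len(len - min_len + 1L)
  ends <- starts + min_len - 1L
  n_c <- win_sum(cum_c, starts, ends)
  n_g <- win_sum(cum_g, starts, ends)
  n_cpg <- win_sum(cum_cpg, starts, ends - 1L)
  gc <- (n_c + n_g) / min_len
  obsexp <- ifelse(n_c * n_g > 0, n_cpg * min_len / (n_c * n_g), 0)
  ok <- gc >= gc_min & obsexp >= obsexp_min
  if (!any(ok)) {
    return(list(cgi = FALSE, islands = tibble::tibble(start = integer(0),
                                                      end = integer(0)),
                indeterminate = FALSE))
  }
  # merge overlapping qualifying windows into islands
  run <- rle(ok)
  stops <- cumsum(run$lengths)
  begins <- stops - run$lengths + 1L
  isl_start <- starts[begins[run$values]]
  isl_end <- ends[stops[run$values]]
  list(cgi = TRUE,
       islands = tibble::tibble(start = isl_start - (len + 1L),
                                end = isl_end - (len + 1L)),
       indeterminate = FALSE)
}

#' Detect CpG islands in a promoter sequence
#'
#' Gardiner-Garden--Frommer-style detector: slides a `min_len` window (step
#' 1) and calls a window qualifying when its GC fraction is `>= gc_min` and
#' its observed/expected CpG ratio (`nCpG * L / (nC * nG)`) is
#' `>= obsexp_min`; overlapping qualifying windows are merged into islands.
#' Sequences that are more than 50% N are indeterminate (`cgi = NA`, with a
#' warning).
#'
#' @param sequence A single promoter sequence.
#' @param min_len Minimum island/window length (default 200).
#' @param gc_min Minimum GC fraction (default 0.5).
#' @param obsexp_min Minimum observed/expected CpG ratio (default 0.6).
#' @return List with `cgi` (logical or NA), `islands` (tibble of
#'   TSS-relative `start`/`end`) and `indeterminate`.
#' @export
cgi_detect <- function(sequence, min_len = 200L, gc_min = 0.5,
                       obsexp_min = 0.6) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    xm_abort("sequence must be a single string", "bad_input")
  }
  cgi_detect_seq(sequence, min_len, gc_min, obsexp_min)
}

#' Run both element detectors over a promoter table
#'
#' @param promoters Tibble with columns `gene`, `sequence`.
#' @param core_window Passed to [tata_scan()].
#' @return Tibble: `gene`, `detected_tata`, `detected_cgi`.
#' @export
detect_promoter_elements <- function(promoters, core_window = 100L) {
  tibble::tibble(
    gene = promoters$gene,
    detected_tata = vapply(promoters$sequence, function(s)
      tata_scan(s, core_window)$hit, logical(1), USE.NAMES = FALSE),
    detected_cgi = vapply(promoters$sequence, function(s)
      isTRUE(cgi_detect_seq(s)$cgi), logical(1), USE.NAMES = FALSE))
}

#' Per-group upstream conservation profile
#'
#' Position-wise mean conservation per divergence group over the 500 bases
#' upstream of the TSS, with a loess smoother (span 0.3) and a pointwise
#' normal-approximation 95% band.
#'
#' @param promoters Tibble with `gene` and list-column `conservation`
#'   (numeric, one value per upstream position).
#' @param groups Tibble with `gene`, `group`.
#' @param span Loess span (default 0.3).
#' @return Tibble of class `crossmac_profile`: `group`, `position`
#'   (TSS-relative, -500..-1), `mean`, `smooth`, `lo`, `hi`. Empty groups
#'   are omitted with a warning.
#' @export
conservation_profile <- function(promoters, groups, span = 0.3) {
  joined <- dplyr::inner_join(promoters, groups, by = "gene")
  out <- purrr::map_dfr(unique(groups$group), function(g) {
    rows <- which(joined$group == g)
    if (length(rows) == 0) {
      xm_warn(sprintf("group '%s' is empty; omitted", g), "skipped_group")
      return(NULL)
    }
    mat <- do.call(rbind, joined$conservation[rows])
    len <- ncol(mat)
    pos <- seq(-len, -1L)
    mu <- colMeans(mat)
    fit <- stats::loess(mu ~ pos, span = span, degree = 2)
    pr <- stats::predict(fit, se = TRUE)
    tibble::tibble(group = g, position = pos, mean = mu,
                   smooth = as.numeric(pr$fit),
                   lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
                   hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  })
  class(out) <- c("crossmac_profile", class(out))
  out
}

#' One-sided conservation comparison between divergence groups
#'
#' Summarises each gene by the mean of its upstream conservation vector and
#' applies a one-sided two-sample Kolmogorov-Smirnov test of the hypothesis
#' that `group_a`'s summaries are stochastically lower than `group_b`'s.
#'
#' @param promoters Tibble with `gene` and `conservation` list-column.
#' @param groups Tibble with `gene`, `group`.
#' @param group_a,group_b Group labels compared (`group_a` hypothesised
#'   lower).
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `statistic`,
#'   `p_value`.
#' @export
conservation_group_test <- function(promoters, groups, group_a, group_b) {
  joined <- dplyr::inner_join(promoters, groups, by = "gene")
  summ <- vapply(joined$conservation, mean, numeric(1))
  x <- summ[joined$group == group_a]
  y <- summ[joined$group == group_b]
  if (length(x) < 2 || length(y) < 2) {
    xm_abort("each group needs >= 2 genes", "bad_input")
  }
  kt <- ks_lower_test(x, y)
  tibble::tibble(group_a = group_a, group_b = group_b,
                 n_a = length(x), n_b = length(y),
                 statistic = kt$statistic, p_value = kt$p_value)
}

#' Association between a promoter element and transcriptional divergence
#'
#' Two complementary tests, reported together: a one-sided Mann-Whitney
#' test comparing divergence values of element-positive vs element-negative
#' genes, and a Fisher exact test on the 2x2 table (high vs low divergence
#' group) x (element present vs absent). `alternative = "greater"` (the
#' default) tests for higher divergence / enrichment in the high group.
#'
#' @param promoters Tibble with `gene`, `tata`, `cgi` flag columns.
#' @param divergence Divergence tibble (`gene`, `divergence`, `group`).
#' @param element `"tata"`, `"cgi"` or `"tata_and_cgi"`.
#' @param alternative Direction of both tests.
#' @return One-row tibble: `element`, `n_present`, `n_absent`, `mw_statistic`,
#'   `mw_p`, `fisher_odds_ratio`, `fisher_p`, `direction`, `skipped`,
#'   `reason`. When a stratum is empty both tests are skipped with the
#'   reason recorded.
#' @export
element_divergence_test <- function(promoters, divergence,
                                    element = c("tata", "cgi", "tata_and_cgi"),
                                    alternative = c("greater", "less",
                                                    "two.sided")) {
  element <- match.arg(element)
  alternative <- match.arg(alternative)
  joined <- dplyr::inner_join(divergence, promoters, by = "gene")
  flag <- switch(element,
                 tata = joined$tata,
                 cgi = joined$cgi,
                 tata_and_cgi = joined$tata & joined$cgi)
  skip_row <- function(reason) {
    tibble::tibble(element = element, n_present = sum(flag),
                   n_absent = sum(!flag), mw_statistic = NA_real_,
                   mw_p = NA_real_, fisher_odds_ratio = NA_real_,
                   fisher_p = NA_real_, direction = NA_character_,
                   skipped = TRUE, reason = reason)
  }
  if (all(flag)) return(skip_row("all genes element-positive"))
  if (!any(flag)) return(skip_row("no element-positive genes"))
  mw <- mw_core(joined$divergence[flag], joined$divergence[!flag],
                alternative = alternative)
  a <- sum(joined$group == "high" & flag)
  b <- sum(joined$group == "high" & !flag)
  c_ <- sum(joined$group == "low" & flag)
  d <- sum(joined$group == "low" & !flag)
  ft <- fisher_2x2(a, b, c_, d, alternative = alternative)
  dir_label <- if (median(joined$divergence[flag]) >=
                     median(joined$divergence[!flag]))
    "element_higher" else "element_lower"
  tibble::tibble(element = element, n_present = sum(flag),
                 n_absent = sum(!flag), mw_statistic = mw$u, mw_p = mw$p,
                 fisher_odds_ratio = ft$odds_ratio, fisher_p = ft$p_value,
                 direction = dir_label, skipped = FALSE, reason = NA_character_)
}
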