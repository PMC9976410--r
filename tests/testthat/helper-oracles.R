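# Independent brute-force oracles used to validate the package's
# implementations. These deliberately recompute everything from first
# principles (explicit enumeration, naive loops) and share no code with R/.

# Exact Mann-Whitney p by enumerating every assignment of the pooled values
# to the two groups; U computed from scratch by pairwise comparison
# (#{x > y} + 0.5 #{x == y}), not from rank sums.
oracle_mw_exact <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  sets <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(sets, function(ix) u_of(pooled[ix], pooled[-ix]), numeric(1))
  p_ge <- mean(us >= u_obs - 1e-12)
  p_le <- mean(us <= u_obs + 1e-12)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Naive running median with symmetric edge shrinkage.
oracle_running_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i] <- median(x[(i - hi):(i + hi)])
  }
  out
}

# Naive DM: normalize, CV^2, order by log10 mean (ties by gene id), running
# median, residual.
oracle_dm <- function(counts, window) {
  sf <- colSums(counts) / mean(colSums(counts))
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  keep <- mu > 0 & v > 0
  mu <- mu[keep]; v <- v[keep]
  genes <- rownames(counts)[keep]
  lcv2 <- log10(v / mu^2)
  ord <- order(log10(mu), genes, method = "radix")
  trend <- oracle_running_median(lcv2[ord], window)
  dm <- numeric(length(mu))
  dm[ord] <- lcv2[ord] - trend
  data.frame(gene = genes, dm = dm)
}

# Recovery-curve AUC by explicitly building the step curve: hits(x) =
# number of targets among the top-x ranked genes, area = sum_{x=1..m}
# hits(x), normalized by the ideal curve's area.
oracle_auc <- function(expr, gene_ids, targets, top_fraction) {
  g <- length(expr)
  m <- ceiling(top_fraction * g)
  ranking <- gene_ids[order(-expr, gene_ids, method = "radix")]
  hits <- vapply(seq_len(m), function(x)
    length(intersect(ranking[seq_len(x)], targets)), numeric(1))
  k <- length(intersect(targets, gene_ids))
  ideal <- vapply(seq_len(m), function(x) min(x, k), numeric(1))
  sum(hits) / sum(ideal)
}

# Naive divergence: log of the mean over rodents of the squared difference
# to the human log fold change.
oracle_divergence <- function(lh, lm, lr, floor = 1e-12) {
  log(max(floor, mean(c((lh - lm)^2, (lh - lr)^2))))
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small NB count fixture with named genes/cells.
make_counts <- function(n_genes, n_cells, mu = 5, size = 2, seed = 1,
                        prefix = "g") {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  m
}

# Plant a motif at a 1-based string index.
sub_plant <- function(s, insert, at) {
  substr(s, at, at + nchar(insert) - 1) <- insert
  s
}
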