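# Shared fixtures and reference implementations used as oracles.

# Named sample -> group vector with nA "A" samples then nB "B" samples.
make_groups <- function(nA = 4, nB = 4) {
  stats::setNames(rep(c("A", "B"), c(nA, nB)),
                  c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB))))
}

# Small deterministic dataset: `n_genes` genes, each with `n_ps` probe-sets
# of `ppp` probes, 4+4 samples, reproducible noise.
toy_dataset <- function(n_genes = 3, n_ps = 4, ppp = 3, nA = 4, nB = 4,
                        seed = 42, noise_sd = 0.2) {
  set.seed(seed)
  groups <- make_groups(nA, nB)
  rows <- list(); ann <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%02d", g)
    np <- n_ps * ppp
    mu <- 6 + g
    a <- stats::rnorm(np, 0, 0.5)
    y <- outer(mu + a, rep(0, nA + nB), "+") +
      matrix(stats::rnorm(np * (nA + nB), 0, noise_sd), np)
    rownames(y) <- sprintf("%s_ps%02d_p%d", gid, rep(seq_len(n_ps), each = ppp),
                           rep(seq_len(ppp), n_ps))
    colnames(y) <- names(groups)
    rows[[g]] <- y
    ann[[g]] <- data.frame(probe_id = rownames(y), gene_id = gid,
                           probeset_id = sprintf("%s_ps%02d", gid,
                                                 rep(seq_len(n_ps), each = ppp)),
                           genomic_index = seq_len(np),
                           stringsAsFactors = FALSE)
  }
  design <- data.frame(sample_id = names(groups), group = unname(groups),
                       stringsAsFactors = FALSE)
  aeu_dataset(do.call(rbind, rows), do.call(rbind, ann), design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force MUF: enumerate every prefix sum.
brute_muf <- function(d) {
  best <- 0
  for (k in seq_along(d)) best <- max(best, abs(sum(d[seq_len(k)])))
  best
}

# Brute-force Benjamini-Hochberg step-up adjusted values.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1)
    for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
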