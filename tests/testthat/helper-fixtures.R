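# Shared fixtures: all test data is generated in code.

# unlinked binomial genotypes on n_chrom pseudo-chromosomes
sim_binomial_geno <- function(N, k, n_chrom = 2L, p_range = c(0.1, 0.9)) {
  p <- runif(k, p_range[1], p_range[2])
  cnt <- vapply(p, function(pp) rbinom(N, 2L, pp), numeric(N))
  per <- table(rep(seq_len(n_chrom), length.out = k))
  map <- data.frame(
    chrom = sprintf("chr%02d", rep(seq_len(n_chrom), per)),
    pos = unlist(lapply(per, function(m) seq_len(m) * 1000L)),
    id = paste0("s", seq_len(k)),
    stringsAsFactors = FALSE
  )
  genotype_matrix(cnt, map)
}

# polymorphic standardized fixture plus its full-rank merged SVD
std_fixture <- function(N, k, n_chrom = 2L, frac = 1) {
  g <- filter_maf(sim_binomial_geno(N, k, n_chrom), 0.01)
  xs <- standardize(g)
  list(g = g, xs = xs, msvd = svd_genotypes(xs, frac = frac))
}

# materialize the blockwise V of a merged_svd as one dense k x m matrix
dense_V <- function(msvd) {
  V <- matrix(0, msvd$k, msvd$m)
  for (bl in msvd$blocks) V[bl$rows, bl$cols] <- bl$v
  V
}

# dense multivariate-normal log-density with mean zero (oracle helper)
dmvnorm_log0 <- function(y, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# a small desk-style simulation config that runs in a few seconds
tiny_sim_config <- function(...) {
  sim_config("desk", ne_hist = 50L, n_hist_gen = 400L, n_ref = 150L,
             ne_forward = 40L, n_forward_gen = 4L, n_qtl_per_chrom = 10L,
             ...)
}
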