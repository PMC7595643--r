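# Shared fixture builders. Everything is generated in code at test time.

# A small deterministic layout: `n_chrom` chromosomes of `len` bp with
# fixed-width windows and supplied (recycled) rates.
fixture_layout <- function(n_chrom = 2, len = 1e6, window = 2.5e5,
                           rates = c(10, 20, 5, 40)) {
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length = len)
  wins <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    s <- seq(0, len - 1, by = window)
    data.frame(chrom = chroms$chrom[i], start = s,
               end = pmin(s + window, len),
               rate = rep_len(rates, length(s)))
  }))
  genome_layout(chroms, wins)
}

# A small k_model with mid-range alphas (negligible MVN truncation).
fixture_kmodel <- function(P = 6, var = 0.004, rho = 0.4, seed = 99) {
  set.seed(seed)
  alpha <- seq(0.3, 0.7, length.out = P)
  corr <- rho^abs(outer(seq_len(P), seq_len(P), "-"))
  K <- corr * var
  f <- matrix(rnorm(50 * P), 50) %*% chol(K) +
    matrix(alpha, 50, P, byrow = TRUE)
  km <- compute_K(pmin(pmax(f, 0), 1), alpha)
  km$K <- K  # exact construction K for simulation tests
  km
}

# Population ancestry frequencies generated from a shared logistic cline
# plus iid noise, for per-SNP fitting tests.
fixture_cline_freqs <- function(L, lat, b, c, noise_sd = 0, M = 1,
                                seed = 1) {
  set.seed(seed)
  b <- rep_len(b, L)
  f <- t(vapply(seq_len(L), function(l)
    logistic_cline(lat, M, b[l], c) + rnorm(length(lat), 0, noise_sd),
    numeric(length(lat))))
  pmin(pmax(f, 0), 1)
}
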