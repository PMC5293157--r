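# Small fixtures built in code, shared across test files.

# tiny noise-free study with no metabolite couplings (pure global regulation)
tiny_constitutive_truth <- function(seed = 11, n_conditions = 8,
                                    n_promoters = 6) {
  generate_truth(sim_config(n_conditions = n_conditions,
                            n_promoters = n_promoters, n_metabolites = 4,
                            n_coupled = 0, noise_sd_ln = 0,
                            n_blocks = 1, block_size = 2),
                 seed = seed)
}

# normalized matrix wrapper around an arbitrary z-like matrix
as_norm <- function(X, growth_rates = NULL,
                    row_means = rep(0, nrow(X)), row_sds = rep(1, nrow(X))) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("P%02d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("C%02d", seq_len(ncol(X)))
  if (is.null(growth_rates)) {
    growth_rates <- stats::setNames(seq(0.1, 1.5, length.out = ncol(X)),
                                    colnames(X))
  }
  names(row_means) <- rownames(X); names(row_sds) <- rownames(X)
  structure(list(X = X, row_means = row_means, row_sds = row_sds,
                 promoters = rownames(X), conditions = colnames(X),
                 growth_rates = growth_rates),
            class = "normalized_matrix")
}

# exhaustive hypergeometric upper-tail probability by enumeration over all
# draws of size n from a universe of size N with K successes
enumerate_hyper_p <- function(N, K, n, observed) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= observed)
}

# analytic plate well: exponential OD, exact GFP integral
make_well_series <- function(pa, mu, times, od0 = 0.01, gfp0 = 0,
                             background = 0) {
  od <- od0 * exp(mu * times)
  rate <- pa + background
  gfp <- if (abs(mu) < 1e-12) gfp0 + rate * od0 * times else
    gfp0 + rate * od0 * (exp(mu * times) - 1) / mu
  list(time = times, od = od, gfp = gfp)
}
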