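# Shared fixtures. Free-parameter order is documented in the package as:
# free loadings column-major, then structure parameters, then uniquenesses —
# so a loading-value matrix indexed by is.na(pattern) yields the loading
# block of theta directly.

# Ground-truth config for the modified CHC model (published loading set).
truth_config <- function(n_obs = 1000L, seed = 1L) {
  spec <- build_catalog()$modified_chc
  vals <- modified_chc_loadings()
  theta <- c(vals[is.na(spec$pattern)], rep(0.5, nrow(spec$pattern)))
  synthetic_config(spec, theta, n_obs = n_obs, seed = seed)
}

# Truth = modified CHC plus one extra loading `value` at (subtest, factor);
# returns the restricted spec (without the cell), the true spec (with it),
# and the exact population matrix of the truth.
planted_fixture <- function(value, subtest = "Coding", factor = "F3",
                            n_obs = 1000L) {
  spec <- build_catalog()$modified_chc
  stopifnot(!is.na(spec$pattern[subtest, factor]))
  pat_t <- spec$pattern
  pat_t[subtest, factor] <- NA_real_
  spec_true <- fm_spec(pat_t, "nested", name = "modified CHC + cell")
  vals <- modified_chc_loadings()
  vals[subtest, factor] <- value
  theta <- c(vals[is.na(pat_t)], rep(0.5, nrow(pat_t)))
  cfg <- synthetic_config(spec_true, theta, n_obs = n_obs)
  list(restricted = spec, true_spec = spec_true, theta = cfg$true_params,
       pop = exact_population_matrix(cfg))
}

# Tiny one-factor spec over `p` variables.
one_factor_spec <- function(p = 3L, names = paste0("V", seq_len(p))) {
  pat <- matrix(NA_real_, p, 1L, dimnames = list(names, "F1"))
  fm_spec(pat, "orthonormal", name = "one factor")
}

# Agreement with a table value at its printed precision (absolute
# comparison: within half a unit of the last printed digit, allowing for
# round-half behavior).
expect_printed <- function(actual, printed, digits = 4) {
  expect_lt(abs(actual - printed), 0.55 * 10^(-digits))
}

# A small well-conditioned PD correlation matrix sample.
small_sample <- function(n_obs = 200L) {
  R <- matrix(c(1, .5, .4,
                .5, 1, .3,
                .4, .3, 1), 3, 3)
  corr_sample(R, n_obs = n_obs, names = c("a", "b", "c"))
}
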