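test_that("implied matrix closed forms", {
  # free loadings evaluated at 0 with unit uniquenesses: pure-noise identity
  spec <- one_factor_spec(3)
  expect_equal(implied_matrix(spec, c(0, 0, 0, 1, 1, 1)), diag(3),
               ignore_attr = TRUE)
  # one factor, lambda = (a, b), Theta = I - diag(a^2, b^2): off-diagonal ab
  a <- 0.6; b <- 0.3
  spec2 <- one_factor_spec(2)
  Sig <- implied_matrix(spec2, c(a, b, 1 - a^2, 1 - b^2))
  expect_equal(Sig[1, 2], a * b)
  expect_equal(diag(Sig), c(1, 1), ignore_attr = TRUE)
  # published-table cross product: (Block Design, Visual Puzzles) entry
  pop <- exact_population_matrix(truth_config())
  expect_equal(pop$R["Block Design", "Visual Puzzles"],
               0.6474 * 0.6571 + (-0.4970) * (-0.4815), tolerance = 1e-12)
  expect_equal(pop$R["Block Design", "Visual Puzzles"], 0.66472,
               tolerance = 1e-4)
  # wrong length / non-finite theta
  expect_error(implied_matrix(spec2, c(1, 2, 3)), "length")
  expect_error(implied_matrix(spec2, c(NA, 1, 1, 1)), "non-finite")
})

test_that("ML discrepancy closed forms and permutation invariance", {
  S <- matrix(c(1, .5, .5, 1), 2)
  expect_lt(abs(ml_discrepancy(S, S)), 1e-12)
  expect_equal(ml_discrepancy(S, diag(2)), -log(0.75), tolerance = 1e-12)
  set.seed(3)
  A <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  B <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  pi <- sample(5)
  expect_equal(ml_discrepancy(A[pi, pi], B[pi, pi]), ml_discrepancy(A, B))
  expect_error(ml_discrepancy(S, matrix(c(1, 1, 1, 1), 2)), "decomposition")
})

test_that("fitting a spec to its own implied matrix recovers parameters", {
  cfg <- truth_config()
  pop <- exact_population_matrix(cfg)
  fit <- fit_model(cfg$spec, pop)
  expect_true(fit$converged)
  expect_lt(fit$F_min, 1e-8)
  est <- sign_normalize(loading_matrix(fit))$Lambda
  tru <- sign_normalize(modified_chc_loadings())$Lambda
  expect_lt(max(abs(est - tru)), 1e-3)
})

test_that("null fit equals the diagonal closed form", {
  s <- sample_matrix(truth_config(n_obs = 300L, seed = 11L))
  nf <- null_model_fit(s)
  expect_equal(nf$chi2, -(s$n_obs - 1) * as.numeric(determinant(s$R)$modulus),
               tolerance = 1e-6)
  expect_equal(unname(diag(nf$Sigma_hat)), rep(1, 15), tolerance = 1e-6)
  expect_identical(nf$df, 105L)
  # independence truth: chi2 = 0
  ident <- corr_sample(diag(3), 100, names = c("a", "b", "c"))
  expect_lt(null_model_fit(ident)$chi2, 1e-8)
})

test_that("chi-squared is monotone under nesting", {
  s <- sample_matrix(truth_config(n_obs = 500L, seed = 21L))
  cl <- build_catalog()
  sub <- fit_model(cl$modified_chc, s)
  fx <- planted_fixture(0.2)
  super <- fit_model(fx$true_spec, s)   # one extra free cell
  expect_lte(super$chi2, sub$chi2 + 1e-6)
  k4 <- fit_model(cl$k_orthogonal[["4"]], s)
  k5 <- fit_model(cl$k_orthogonal[["5"]], s)
  expect_lte(k5$chi2, k4$chi2 + 1e-6)
})

test_that("information matrix matches a finite-difference oracle of F", {
  spec <- one_factor_spec(3)
  theta <- c(0.7, 0.6, 0.5, 1 - 0.49, 1 - 0.36, 1 - 0.25)
  S <- implied_matrix(spec, theta)
  s <- corr_sample(S, 500, names = rownames(S))
  fit <- fit_model(spec, s, start = theta)
  I <- information_matrix(fit)
  # oracle: central second differences of F itself (not of the gradient)
  h <- 1e-4
  q <- length(fit$theta_hat)
  Fv <- function(th) ml_discrepancy(S, implied_matrix(spec, th))
  H0 <- matrix(0, q, q)
  th <- unname(fit$theta_hat)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    ei <- ej <- numeric(q); ei[i] <- h; ej[j] <- h
    H0[i, j] <- (Fv(th + ei + ej) - Fv(th + ei - ej) -
                 Fv(th - ei + ej) + Fv(th - ei - ej)) / (4 * h^2)
  }
  H0 <- (s$n_obs - 1) / 2 * (H0 + t(H0)) / 2
  expect_equal(unname(I), H0, tolerance = 1e-4)
  # information is linear in N - 1: scaling N by 4 (N-1 by 4) scales it by 4
  s4 <- corr_sample(S, 4 * 500 - 3, names = rownames(S))
  fit4 <- fit_model(spec, s4, start = theta)
  expect_equal(unname(information_matrix(fit4)), unname(I) * (s4$n_obs - 1) / 499,
               tolerance = 1e-8)
})

test_that("stochastic recovery: estimates within 3 standard errors at N = 5000", {
  cfg <- truth_config(n_obs = 5000L, seed = 77L)
  s <- sample_matrix(cfg)
  fit <- fit_model(cfg$spec, s)
  expect_true(fit$converged)
  I <- information_matrix(fit)
  se <- sqrt(diag(solve(I)))
  est <- sign_normalize(loading_matrix(fit))$Lambda
  tru <- sign_normalize(modified_chc_loadings())$Lambda
  dev <- abs(est - tru)[is.na(cfg$spec$pattern)]
  se_l <- se[seq_len(sum(is.na(cfg$spec$pattern)))]
  expect_true(all(dev <= 3 * se_l))
})

test_that("jittered starts reach the same minimum", {
  s <- sample_matrix(truth_config(n_obs = 1000L, seed = 31L))
  cl <- build_catalog()
  for (spec in cl[c("modified_chc", "nested_chc")]) {
    base <- fit_model(spec, s)
    set.seed(99)
    for (r in 1:5) {
      st <- fit_model(spec, s,
                      start = pmax(base$param_table$start +
                                     rnorm(length(base$theta_hat), 0, 0.05),
                                   base$param_table$lower + 0.01))
      expect_equal(st$F_min, base$F_min, tolerance = 1e-6)
    }
  }
})

test_that("Heywood guard: variances bounded at zero and reported", {
  s <- sample_matrix(truth_config(n_obs = 1000L, seed = 42L))
  cl <- build_catalog()
  fit <- fit_model(cl$benson_2010, s)
  # the fluid-factor disturbance collapses to its bound on these surrogates
  expect_true("psi[Gf]" %in% fit$active_bounds)
  expect_gte(min(fit$theta_hat[fit$param_table$type %in% c("psi", "theta")]), 0)
})
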