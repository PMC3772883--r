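test_that("LM projections are nonnegative and vanish on the true model", {
  pop <- exact_population_matrix(truth_config())
  fit <- fit_model(build_catalog()$modified_chc, pop)
  lr <- suppressWarnings(lagrange_rank(fit))
  expect_true(all(lr$projected_dchi2 >= 0))
  expect_lt(max(lr$projected_dchi2), 1e-6)
})

test_that("a planted cross-loading ranks first and LM tracks the refit", {
  fx <- planted_fixture(0.1)
  fit <- fit_model(fx$restricted, fx$pop)
  lr <- suppressWarnings(lagrange_rank(fit))
  expect_identical(lr$subtest[1], "Coding")
  expect_identical(lr$factor[1], "F3")
  refit <- fit_model(fx$true_spec, fx$pop)
  actual <- fit$chi2 - refit$chi2
  expect_lt(abs(lr$projected_dchi2[1] - actual) / actual, 0.25)
})

test_that("Wald ranks a truly-zero loading first under sampling noise", {
  fx <- planted_fixture(0)        # the extra cell's true value is exactly 0
  cfg <- synthetic_config(fx$true_spec, fx$theta, n_obs = 1000L, seed = 13L)
  s <- sample_matrix(cfg)
  fit <- fit_model(fx$true_spec, s)
  wd <- suppressWarnings(wald_rank(fit))
  expect_identical(wd$subtest[1], "Coding")
  expect_identical(wd$factor[1], "F3")
})

test_that("Wald statistics scale linearly in N - 1", {
  fx <- planted_fixture(0.1)
  s1 <- corr_sample(fx$pop$R, 400, names = fx$pop$names)
  s2 <- corr_sample(fx$pop$R, 799, names = fx$pop$names)  # N2-1 = 2 (N1-1)
  f1 <- fit_model(fx$true_spec, s1)
  f2 <- fit_model(fx$true_spec, s2)
  w1 <- suppressWarnings(wald_rank(f1))
  w2 <- suppressWarnings(wald_rank(f2))
  key <- function(w) paste(w$subtest, w$factor)
  m <- match(key(w1), key(w2))
  expect_equal(w2$projected_dchi2[m], 2 * w1$projected_dchi2,
               tolerance = 1e-4)
})

test_that("Wald projection tracks the refit for a small free loading", {
  fx <- planted_fixture(0.1)
  fit <- fit_model(fx$true_spec, fx$pop)
  wd <- suppressWarnings(wald_rank(fit))
  cell <- wd[wd$subtest == "Coding" & wd$factor == "F3", ]
  drop_fit <- fit_model(fx$restricted, fx$pop)
  actual <- drop_fit$chi2 - fit$chi2
  expect_lt(abs(cell$projected_dchi2 - actual) / actual, 0.25)
})

test_that("stepwise search is a no-op on the true model", {
  pop <- exact_population_matrix(truth_config())
  sw <- stepwise_modify(build_catalog()$modified_chc, pop)
  expect_identical(nrow(sw$log), 0L)
  expect_identical(sw$spec$pattern, build_catalog()$modified_chc$pattern)
})

test_that("stepwise search restores a single omitted loading", {
  fx <- planted_fixture(0.4)
  sw <- stepwise_modify(fx$restricted, fx$pop)
  adds <- sw$log[sw$log$action == "ADD" & sw$log$accepted, ]
  expect_identical(nrow(adds), 1L)
  expect_identical(adds$subtest, "Coding")
  expect_identical(adds$factor, "F3")
  expect_true(is.na(sw$spec$pattern["Coding", "F3"]))
  # accepted ADD strictly decreases chi2 by at least the criterion
  expect_gte(adds$actual_dchi2, qchisq(0.95, 1))
})

test_that("stepwise search drops a single spurious loading", {
  fx <- planted_fixture(0)        # truth has 0 in the extra free cell
  pop0 <- exact_population_matrix(
    synthetic_config(fx$true_spec, fx$theta, n_obs = 1000L))
  sw <- stepwise_modify(fx$true_spec, pop0)
  drops <- sw$log[sw$log$action == "DROP" & sw$log$accepted, ]
  expect_identical(nrow(drops), 1L)
  expect_identical(drops$subtest, "Coding")
  expect_identical(drops$factor, "F3")
  expect_lt(drops$actual_dchi2, qchisq(0.95, 1))
})

test_that("modification log df bookkeeping holds", {
  fx <- planted_fixture(0.4)
  sw <- stepwise_modify(fx$restricted, fx$pop)
  n_add <- sum(sw$log$action == "ADD" & sw$log$accepted)
  n_drop <- sum(sw$log$action == "DROP" & sw$log$accepted)
  expect_identical(model_df(sw$spec),
                   model_df(fx$restricted) - n_add + n_drop)
})

test_that("general-factor loadings survive modification on nested surrogates", {
  # the general column's loadings are large in truth; the search must not
  # remove them (reduced replicate count; the full sweep is a slow check)
  cl <- build_catalog()
  for (seed in c(101L, 202L, 303L)) {
    s <- sample_matrix(truth_config(n_obs = 1000L, seed = seed))
    sw <- stepwise_modify(cl$modified_chc, s)
    dropped_g <- sw$log$action == "DROP" & sw$log$accepted &
      sw$log$factor == "F1"
    expect_false(any(dropped_g))
  }
})
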