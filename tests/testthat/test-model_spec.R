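test_that("free-parameter counts match construction", {
  cl <- build_catalog()
  # 6 factors x 15 subtests all free: 90 loadings + 15 uniquenesses
  expect_identical(count_free_parameters(cl$k_orthogonal[["6"]]), 105L)
  expect_identical(count_free_parameters(null_spec()), 15L)
  # published modified-CHC pattern: 43 nonblank cells + 15 uniquenesses
  expect_identical(count_free_parameters(cl$modified_chc), 58L)
  expect_identical(sum(modified_chc_loadings() != 0), 43L)
})

test_that("model df accounting", {
  cl <- build_catalog()
  expect_identical(model_df(null_spec()), 105L)
  expect_identical(model_df(cl$k_orthogonal[["6"]]), 15L)
  # saturated: df 0
  pat <- matrix(NA_real_, 15, 7)
  rownames(pat) <- wais_subtests()
  expect_identical(model_df(fm_spec(pat, "orthonormal")), 0L)
  # over-parameterized: error
  pat8 <- matrix(NA_real_, 15, 8)
  rownames(pat8) <- wais_subtests()
  expect_error(model_df(fm_spec(pat8, "orthonormal")), "over-parameterized")
  # k-orthogonal family: df = 120 - 15(k+1)
  for (k in 1:6)
    expect_identical(model_df(cl$k_orthogonal[[k]]), 120L - 15L * (k + 1L))
})

test_that("oblique partition count", {
  expect_identical(oblique_partition_count(5), 15L)
  expect_identical(oblique_partition_count(2), 3L)
  expect_identical(oblique_partition_count(6), 21L)
  expect_error(oblique_partition_count(1), "m must be")
})

test_that("catalog structure is as published where reconcilable", {
  cl <- build_catalog()
  expect_identical(model_df(cl$modified_chc), 62L)
  expect_identical(model_df(cl$k_orthogonal[["4"]]), 45L)
  expect_identical(model_df(cl$wechsler_2008), 80L)
  expect_identical(model_df(cl$nested_chc), 74L)
  # nested model: exactly one more factor column than the Benson group level
  expect_identical(ncol(cl$nested_chc$pattern),
                   ncol(cl$benson_2010$pattern) + 1L)
  # flagged entries where the published df cannot be reconciled
  expect_true(isTRUE(attr(cl$benson_2010, "df_unverified")))
  expect_true(isTRUE(attr(cl$ward_2011, "df_unverified")))
  expect_true(isTRUE(attr(cl$modified_6indep, "df_unverified")))
  # subtest order fixed to the published row order
  for (s in c(cl[c("wechsler_2008", "benson_2010", "modified_chc")],
              cl$k_orthogonal[6]))
    expect_identical(rownames(s$pattern), wais_subtests())
})

test_that("every catalog spec passes estimator pre-checks on exact data", {
  cl <- build_catalog()
  specs <- c(cl[c("wechsler_2008", "benson_2010", "ward_2011", "nested_chc",
                  "modified_chc", "modified_6indep")], cl$k_orthogonal)
  pop <- exact_population_matrix(truth_config())
  for (s in specs) {
    expect_true(model_df(s) >= 0L)
    fit <- suppressWarnings(fit_model(s, pop, maxit = 500L))
    expect_s3_class(fit, "fm_fit")
  }
})

test_that("spec config serialization round-trips pattern and structure", {
  cl <- build_catalog()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  for (s in cl[c("benson_2010", "ward_2011", "modified_chc")]) {
    write_model_spec(s, tmp)
    back <- read_model_spec(tmp)
    expect_identical(back$pattern, s$pattern)
    expect_identical(back$structure, s$structure)
    expect_identical(back$uniqueness_bounds, s$uniqueness_bounds)
    expect_identical(back$name, s$name)
  }
})

test_that("sign normalization flips whole columns and preserves the model", {
  vals <- modified_chc_loadings()
  flipped <- vals %*% diag(c(1, -1, 1, -1, 1, 1))
  sn <- sign_normalize(flipped)
  expect_equal(unname(sn$Lambda), unname(sign_normalize(vals)$Lambda))
  expect_identical(sn$flips, c(1, -1, 1, -1, 1, 1) *
                     sign_normalize(vals)$flips)
  # oblique flip keeps Lambda Phi Lambda' invariant
  Phi <- diag(6); Phi[lower.tri(Phi)] <- 0.3; Phi <- (Phi + t(Phi)); diag(Phi) <- 1
  sn2 <- sign_normalize(flipped, Phi = Phi)
  expect_equal(sn2$Lambda %*% sn2$Phi %*% t(sn2$Lambda),
               flipped %*% Phi %*% t(flipped))
})
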