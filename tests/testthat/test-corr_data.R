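test_that("corr_sample validates symmetry, diagonal, bounds and definiteness", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  s <- corr_sample(R, n_obs = 100, names = c("a", "b", "c"))
  expect_s3_class(s, "corr_sample")
  expect_identical(s$R["a", "b"], 0.5)

  Rbad <- R; Rbad[1, 2] <- 0.51
  expect_error(corr_sample(Rbad, 100), "asymmetric")
  Rbad <- R; diag(Rbad) <- c(1, 1, 1.001)
  expect_error(corr_sample(Rbad, 100), "diagonal")
  Rind <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)
  expect_error(corr_sample(Rind, 100), "smallest eigenvalue")
  expect_error(corr_sample(R, 3), "n_obs")
})

test_that("matrix files round-trip in both dialects", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.5
  s <- corr_sample(R, n_obs = 100, names = c("x", "y"), label = "toy")
  for (d in c("full", "lower_triangle")) {
    write_correlation_matrix(s, tmp, dialect = d)
    back <- read_correlation_matrix(tmp, dialect = d)
    expect_equal(back$R[1, 2], 0.5)
    expect_identical(back$n_obs, 100L)
    expect_identical(back$label, "toy")
  }

  # identity matrix, any N
  write_correlation_matrix(corr_sample(diag(4), 50), tmp)
  ident <- read_correlation_matrix(tmp)
  expect_true(all(ident$R[lower.tri(ident$R)] == 0))

  # 15x15 lower-triangle file: write -> read -> write is byte-identical
  big <- exact_population_matrix(truth_config())
  write_correlation_matrix(big, tmp, dialect = "lower_triangle")
  first <- readLines(tmp)
  back <- read_correlation_matrix(tmp, dialect = "lower_triangle")
  tmp2 <- withr::local_tempfile(fileext = ".txt")
  write_correlation_matrix(back, tmp2, dialect = "lower_triangle")
  expect_identical(readLines(tmp2), first)
})

test_that("matrix file errors are specific", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# N=100", "a b", "a 1 0.5", "b 0.4 1"), tmp)
  expect_error(read_correlation_matrix(tmp, "full"), "asymmetric")
  writeLines(c("a b", "a 1 0.5", "b 0.5 1"), tmp)
  expect_error(read_correlation_matrix(tmp, "full"), "N=")
  writeLines(c("# N=100", "a b", "a 1 0.9", "b 0.9 1"), tmp)
  Rind <- read_correlation_matrix(tmp, "full")  # PD, fine
  expect_s3_class(Rind, "corr_sample")
})

test_that("Fisher-z pooling matches hand values and fixed points", {
  mk <- function(r) corr_sample(matrix(c(1, r, r, 1), 2), 200,
                                names = c("a", "b"))
  expect_equal(pool_correlations(list(mk(.5), mk(.5)), 400)$R[1, 2], 0.5)
  expect_equal(pool_correlations(list(mk(0), mk(0)), 400)$R[1, 2], 0)
  # tanh((atanh .3 + atanh .7)/2), hand-evaluated
  expect_equal(pool_correlations(list(mk(.3), mk(.7)), 400)$R[1, 2],
               0.5287511, tolerance = 1e-6)
  # an exact |r| = 1 cannot pass sample validation (singular), so exercise
  # the pooling guard on a hand-corrupted object
  s1 <- mk(.5)
  s1$R[1, 2] <- s1$R[2, 1] <- 1
  expect_error(pool_correlations(list(s1, mk(.5)), 400), "transform-domain")
  bad <- corr_sample(matrix(c(1, .5, .5, 1), 2), 200, names = c("a", "z"))
  expect_error(pool_correlations(list(mk(.5), bad), 400), "alignment")
})

test_that("pooling properties: bounds, identity, order invariance", {
  set.seed(7)
  samples <- lapply(1:4, function(i) {
    cfg <- truth_config(n_obs = 200L, seed = 100L + i)
    sample_matrix(cfg)
  })
  pooled <- pool_correlations(samples, 800)
  off <- lower.tri(pooled$R)
  lo <- pmin(samples[[1]]$R, samples[[2]]$R, samples[[3]]$R, samples[[4]]$R)
  hi <- pmax(samples[[1]]$R, samples[[2]]$R, samples[[3]]$R, samples[[4]]$R)
  expect_true(all(pooled$R[off] > lo[off] - 1e-12 &
                  pooled$R[off] < hi[off] + 1e-12))

  single <- pool_correlations(list(samples[[1]]), 200)
  expect_equal(max(abs(single$R - samples[[1]]$R)), 0, tolerance = 1e-15)

  perm <- pool_correlations(samples[c(3, 1, 4, 2)], 800)
  expect_equal(perm$R, pooled$R, tolerance = 1e-12)
})
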