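# Synthetic inputs with known ground truth: exact implied population
# matrices, finite-N sample correlation matrices from multivariate-normal
# draws, and WAIS-like multi-population surrogate batteries. The real
# standardization correlation tables are proprietary, so every pipeline
# exercise in this package runs on these surrogates.

# Run expr with a private RNG stream: seed explicitly, restore the caller's
# generator state afterwards, so no operation leaks global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Replace the uniqueness block of a parameter vector so the implied diagonal
# is exactly 1. Errors if any structural diagonal entry reaches 1.
complete_uniquenesses <- function(spec, theta, info = param_info(spec)) {
  u <- unpack_theta(spec, theta, info)
  comm <- if (u$m > 0L) diag(u$Lambda %*% u$Phi %*% t(u$Lambda)) else
    rep(0, u$p)
  if (any(comm >= 1))
    stop(sprintf(
      "infeasible parameters: structural variance >= 1 for %s",
      paste(rownames(spec$pattern)[comm >= 1], collapse = ", ")))
  theta[info$type == "theta"] <- 1 - comm
  theta
}

#' Synthetic-data configuration
#'
#' Binds a model specification to ground-truth parameter values and sampling
#' conditions. The uniqueness block of `true_params` is always re-completed
#' so the implied population matrix has unit diagonal, and the result must
#' be positive definite.
#'
#' @param spec an [fm_spec()].
#' @param true_params parameter vector in canonical order (the uniqueness
#'   entries may be anything; they are recomputed).
#' @param n_obs sample size per generated matrix.
#' @param perturbation_sd standard deviation of additive Gaussian
#'   perturbations applied to free loadings when emulating additional
#'   populations (unitless, >= 0).
#' @param seed integer seed for all sampling from this config.
#' @return object of class `synth_config`.
#' @export
synthetic_config <- function(spec, true_params, n_obs, perturbation_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(spec, "fm_spec"))
  info <- param_info(spec)
  if (length(true_params) != nrow(info))
    stop(sprintf("true_params has length %d, expected %d",
                 length(true_params), nrow(info)))
  if (perturbation_sd < 0) stop("perturbation_sd must be >= 0")
  true_params <- complete_uniquenesses(spec, true_params, info)
  Sigma <- implied_matrix(spec, true_params)
  if (max(abs(diag(Sigma) - 1)) > 1e-9)
    stop("internal error: implied diagonal not 1 after completion")
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("infeasible parameters: implied population matrix not positive definite")
  structure(list(spec = spec, true_params = true_params,
                 n_obs = as.integer(n_obs),
                 perturbation_sd = perturbation_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Exact population matrix of a synthetic configuration
#'
#' Returns the implied matrix itself as a noise-free "sample" carrying the
#' configured N — the fixture for parameter-recovery and self-consistency
#' checks (fitting the generating spec to it reaches F_min ~ 0).
#'
#' @param config a [synthetic_config()].
#' @param label population label.
#' @return a [corr_sample()].
#' @export
exact_population_matrix <- function(config, label = "population") {
  stopifnot(inherits(config, "synth_config"))
  Sigma <- implied_matrix(config$spec, config$true_params)
  corr_sample(Sigma, n_obs = config$n_obs,
              names = rownames(config$spec$pattern), label = label)
}

#' Sample correlation matrix from a synthetic configuration
#'
#' Pearson correlation matrix of `n_obs` multivariate-normal draws from the
#' configured population matrix; reproducible for a given seed and free of
#' global RNG side effects.
#'
#' @param config a [synthetic_config()].
#' @param seed seed override (default: the config's seed).
#' @param label population label.
#' @return a [corr_sample()].
#' @export
sample_matrix <- function(config, seed = config$seed, label = "sample") {
  stopifnot(inherits(config, "synth_config"))
  Sigma <- implied_matrix(config$spec, config$true_params)
  p <- nrow(Sigma)
  if (config$n_obs <= p)
    stop("degenerate sample: n_obs must exceed the number of variables")
  R <- with_seed(seed, {
    Z <- matrix(stats::rnorm(config$n_obs * p), config$n_obs, p)
    stats::cor(Z %*% chol(Sigma))
  })
  corr_sample(R, n_obs = config$n_obs,
              names = rownames(config$spec$pattern), label = label)
}

#' WAIS-like three-population surrogate battery
#'
#' Emulates the three age-band samples of the WAIS-IV standardization
#' analysis: an estimation band "ages 20-54" (N = 1000) and two
#' generalization bands "ages 16-19" and "ages 55-69" (N = 400 each), over
#' the 15 subtests. Ground truth is the modified CHC parameter set
#' ([modified_chc_loadings()], the study's most completely published
#' values); for the two outer bands each free loading is perturbed by
#' additive Gaussian noise (sd `perturbation_sd`, default 0.03) and the
#' uniquenesses are re-completed, emulating the moderate cross-population
#' drift visible in the published generalization tables.
#'
#' @param seed integer seed.
#' @param perturbation_sd per-loading perturbation sd for the outer bands
#'   (0 makes all three bands draws from one population).
#' @param n_obs sample sizes of the three bands.
#' @param exact if `TRUE` return exact population matrices (no sampling
#'   noise) instead of finite-N sample matrices.
#' @return named list of three [corr_sample()] objects
#'   (`"ages 20-54"`, `"ages 16-19"`, `"ages 55-69"`), with the generating
#'   `synth_config` of the estimation band attached as attribute `truth`.
#' @export
wais_like_battery <- function(seed, perturbation_sd = 0.03,
                              n_obs = c(1000L, 400L, 400L), exact = FALSE) {
  catalog <- build_catalog()
  spec <- catalog$modified_chc
  info <- param_info(spec)
  vals <- modified_chc_loadings()
  theta <- info$start
  il <- info$type == "lambda"
  theta[il] <- vals[cbind(info$row[il], info$col[il])]
  labels <- c("ages 20-54", "ages 16-19", "ages 55-69")

  bands <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 6L)
    out <- vector("list", 3L)
    for (b in 1:3) {
      th_b <- theta
      if (b > 1L && perturbation_sd > 0) {
        # Rejection draw: the perturbation distribution is truncated to the
        # feasible region (every structural variance below 1), so a band
        # population is always a valid correlation structure.
        th_b[il] <- with_seed(sub_seeds[3L + b], {
          for (try in 1:100) {
            cand <- theta[il] + stats::rnorm(sum(il), 0, perturbation_sd)
            th_try <- theta; th_try[il] <- cand
            ok <- tryCatch({
              complete_uniquenesses(spec, th_try, info); TRUE
            }, error = function(e) FALSE)
            if (ok) break
          }
          if (!ok) stop("could not draw a feasible loading perturbation")
          cand
        })
      }
      cfg <- synthetic_config(spec, th_b, n_obs = n_obs[b],
                              seed = sub_seeds[b])
      out[[b]] <- if (exact) exact_population_matrix(cfg, label = labels[b])
                  else sample_matrix(cfg, label = labels[b])
    }
    out
  })
  names(bands) <- labels
  attr(bands, "truth") <- synthetic_config(spec, theta, n_obs = n_obs[1],
                                           perturbation_sd = perturbation_sd,
                                           seed = seed)
  bands
}

#' Six-equal-orthogonal-factor simulation
#'
#' Population with six orthogonal factors, every factor loading equally and
#' positively on all tests: all off-diagonal correlations equal
#' `6 loading^2`, all uniquenesses `1 - 6 loading^2`. Used to probe how a
#' fitted full six-factor model absorbs variance into one general factor
#' and mixed-sign secondary factors even when no factor dominates in truth.
#'
#' @param n_tests number of tests (default 15).
#' @param loading the common loading; requires `6 loading^2 < 1`.
#' @param n_obs sample size.
#' @param seed integer seed.
#' @param exact if `TRUE` return the exact population matrix.
#' @return a [corr_sample()], with the generating `synth_config` attached as
#'   attribute `truth`.
#' @export
six_equal_factor_sim <- function(n_tests = 15L, loading, n_obs, seed = 1L,
                                 exact = FALSE) {
  if (6 * loading^2 >= 1)
    stop("infeasible loading: 6 * loading^2 must be below 1")
  subtests <- paste0("T", seq_len(n_tests))
  pat <- matrix(NA_real_, n_tests, 6L,
                dimnames = list(subtests, paste0("F", 1:6)))
  spec <- fm_spec(pat, "orthonormal", name = "6 equal orthogonal")
  info <- param_info(spec)
  theta <- info$start
  theta[info$type == "lambda"] <- loading
  cfg <- synthetic_config(spec, theta, n_obs = n_obs, seed = seed)
  out <- if (exact) exact_population_matrix(cfg, label = "six equal factors")
         else sample_matrix(cfg, label = "six equal factors")
  attr(out, "truth") <- cfg
  out
}
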