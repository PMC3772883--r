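# Fixed-loading cross-validation: a fitted measurement structure is carried
# to a new population sample with every structural parameter frozen; only
# the p subtest-specific uniquenesses are re-estimated. Every cross-validated
# model therefore has df = p(p+1)/2 - p (105 for p = 15), the same as the
# null model, so all fit indices rank the models identically within a table.

#' Cross-validate a fitted model on a new sample
#'
#' Freezes all loadings and factor-covariance parameters at the fitted
#' values and refits only the uniquenesses on `new_sample`. Internally the
#' frozen structural part Lambda Phi Lambda' is carried as a fully fixed
#' loading matrix `Lambda chol(Phi)'` with orthonormal factors, which leaves
#' the implied matrix identical and is invariant to factor sign flips of the
#' source fit. The chi-squared uses the new sample's N.
#'
#' @param fit a converged `fm_fit`.
#' @param new_sample a [corr_sample()] with identical variable names.
#' @return an `fm_fit` with df = p(p+1)/2 - p.
#' @export
cross_validate <- function(fit, new_sample) {
  stopifnot(inherits(fit, "fm_fit"), inherits(new_sample, "corr_sample"))
  if (!identical(fit$sample$names, new_sample$names))
    stop("alignment error: new sample has different variable names")
  u <- unpack_theta(fit$spec, fit$theta_hat, fit$param_table)
  if (u$m == 0L) return(fit_model(null_spec(new_sample$names), new_sample))
  cv_name <- fit$spec$name
  L_fixed <- u$Lambda %*% t(chol(u$Phi))
  colnames(L_fixed) <- colnames(fit$spec$pattern)
  cv_spec <- fm_spec(L_fixed, "orthonormal",
                     uniqueness_bounds = fit$spec$uniqueness_bounds,
                     name = cv_name)
  fit_model(cv_spec, new_sample)
}

#' Generalization table for a set of fitted models
#'
#' Cross-validates each fit to `new_sample` and assembles one fit-index row
#' per model, plus the null-model row (whose "cross-validation" is simply
#' the null fit on the new sample, its only parameters being uniquenesses).
#' All rows share the same df, so rank order by any one index equals rank
#' order by chi-squared.
#'
#' @param fits list of `fm_fit` objects sharing variable names.
#' @param new_sample the generalization [corr_sample()].
#' @return data.frame in the Model/df/X2/GFI/AGFI/CFI/RMSEA/Akaike layout.
#' @export
generalization_table <- function(fits, new_sample) {
  if (inherits(fits, "fm_fit")) fits <- list(fits)
  cv_fits <- lapply(fits, cross_validate, new_sample = new_sample)
  null_fit <- null_model_fit(new_sample)
  index_table(cv_fits, null_fit = null_fit)
}
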