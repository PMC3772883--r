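# The six fit indices reported for every model: chi-squared, GFI, AGFI,
# CFI, RMSEA, and the legacy CALIS "Akaike's" column, which table arithmetic
# identifies as chi2 - 2 df (not the -2lnL + 2k textbook AIC); it is named
# aic_calis throughout to avoid ambiguity.

#' Component fit-index formulas
#'
#' Small pure functions used by [compute_indices()] and directly testable
#' against published table cells:
#' `cfi_from_chisq(chi2, df, chi2_null, df_null)`,
#' `rmsea_from_chisq(chi2, df, n)` (= sqrt(max(chi2 - df, 0) / (df (N-1)))),
#' `agfi_from_gfi(gfi, df, p)` (= 1 - (q/df)(1 - GFI), q = p(p+1)/2),
#' and `aic_calis(chi2, df)` (= chi2 - 2 df).
#'
#' @param chi2,df,chi2_null,df_null,n,gfi,p scalars.
#' @return scalar index value.
#' @name index_formulas
NULL

#' @rdname index_formulas
#' @export
cfi_from_chisq <- function(chi2, df, chi2_null, df_null) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_null - df_null, chi2 - df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' @rdname index_formulas
#' @export
rmsea_from_chisq <- function(chi2, df, n) {
  if (df <= 0) return(NA_real_)
  sqrt(max(chi2 - df, 0) / (df * (n - 1)))
}

#' @rdname index_formulas
#' @export
agfi_from_gfi <- function(gfi, df, p) {
  if (df <= 0) return(NA_real_)
  q <- p * (p + 1) / 2
  1 - (q / df) * (1 - gfi)
}

#' @rdname index_formulas
#' @export
aic_calis <- function(chi2, df) chi2 - 2 * df

# ML-metric goodness of fit: 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2].
gfi_ml <- function(S, Sigma) {
  A <- solve(Sigma, S)
  num <- sum(diag((A - diag(nrow(A))) %*% (A - diag(nrow(A)))))
  den <- sum(diag(A %*% A))
  1 - num / den
}

#' Fit-index set for one fitted model
#'
#' Computes chi2, GFI, AGFI, CFI, RMSEA and the CALIS Akaike variant from a
#' fitted model, the uniqueness-only null fit on the same sample, and the
#' observed matrix. Anomalies (a model worse than its df, or a null better
#' than the model) are absorbed by the max() clamps in CFI and RMSEA; with
#' df = 0 AGFI and RMSEA are undefined and reported as `NA`.
#'
#' @param fit an `fm_fit`.
#' @param null_fit the null-model `fm_fit` on the same sample (see
#'   [null_model_fit()]).
#' @param S observed matrix (defaults to the fit's sample matrix).
#' @return object of class `fit_index_set`: list with `model`, `chi2`, `df`,
#'   `gfi`, `agfi`, `cfi`, `rmsea`, `aic_calis`, `n_obs`.
#' @export
compute_indices <- function(fit, null_fit, S = fit$sample$R) {
  stopifnot(inherits(fit, "fm_fit"), inherits(null_fit, "fm_fit"))
  if (fit$n_obs != null_fit$n_obs)
    stop("fit and null fit must be on the same sample (N differs)")
  gfi <- gfi_ml(S, fit$Sigma_hat)
  structure(list(
    model = fit$spec$name,
    chi2 = fit$chi2,
    df = fit$df,
    gfi = gfi,
    agfi = agfi_from_gfi(gfi, fit$df, nrow(S)),
    cfi = cfi_from_chisq(fit$chi2, fit$df, null_fit$chi2, null_fit$df),
    rmsea = rmsea_from_chisq(fit$chi2, fit$df, fit$n_obs),
    aic_calis = aic_calis(fit$chi2, fit$df),
    n_obs = fit$n_obs
  ), class = "fit_index_set")
}

#' @export
print.fit_index_set <- function(x, ...) {
  cat(sprintf(
    "%s: df=%d X2=%.2f GFI=%.4f AGFI=%s CFI=%.4f RMSEA=%s Akaike=%.2f\n",
    x$model, x$df, x$chi2, x$gfi,
    ifelse(is.na(x$agfi), "NA", sprintf("%.4f", x$agfi)),
    x$cfi,
    ifelse(is.na(x$rmsea), "NA", sprintf("%.4f", x$rmsea)),
    x$aic_calis))
  invisible(x)
}

#' Assemble an index table for several fitted models
#'
#' One row per fit (the null model first), in the layout of the published
#' model-comparison tables: Model, df, X2, GFI, AGFI, CFI, RMSEA, Akaike's.
#'
#' @param fits list of `fm_fit` objects on one sample.
#' @param null_fit the null fit on that sample; computed if missing.
#' @return data.frame, full precision (round for display).
#' @export
index_table <- function(fits, null_fit = NULL) {
  if (inherits(fits, "fm_fit")) fits <- list(fits)
  if (is.null(null_fit)) null_fit <- null_model_fit(fits[[1]]$sample)
  rows <- lapply(c(list(null_fit), fits), function(f) {
    ix <- compute_indices(f, null_fit)
    data.frame(Model = ix$model, df = ix$df, X2 = ix$chi2, GFI = ix$gfi,
               AGFI = ix$agfi, CFI = ix$cfi, RMSEA = ix$rmsea,
               Akaike = ix$aic_calis, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
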