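# Maximum-likelihood covariance-structure estimation.
#
# The model-implied matrix is Sigma = Lambda Phi Lambda' + Theta with Theta
# diagonal; under a second-order structure Phi = Gamma Gamma' + diag(Psi).
# The discrepancy is the Wishart ML form
#   F(S, Sigma) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p,
# minimized under lower bounds by L-BFGS-B with the analytic gradient
#   dF/dSigma = W = Sigma^-1 (Sigma - S) Sigma^-1,
#   dF/dLambda = 2 W Lambda Phi,   dF/dphi_jk = 2 (L' W L)_jk,
#   dF/dgamma = 2 L' W L Gamma,    dF/dpsi_j = (L' W L)_jj,
#   dF/dtheta_i = W_ii.
# chi2 = (N - 1) * F_min: the correlation matrix is analyzed as a covariance
# matrix, the convention of SAS CALIS for matrix input.

# Value returned when Sigma (or an oblique Phi) leaves the positive-definite
# cone during a line search; large enough that any such step is rejected.
PENALTY_F <- 1e10

# Build Lambda, Phi, Theta (diagonal vector) from a free-parameter vector.
unpack_theta <- function(spec, theta, info = param_info(spec)) {
  pat <- spec$pattern
  p <- nrow(pat); m <- ncol(pat)
  Lambda <- pat
  il <- info$type == "lambda"
  if (any(il)) Lambda[cbind(info$row[il], info$col[il])] <- theta[il]
  Gamma <- NULL; Psi <- NULL
  if (spec$structure == "oblique" && m >= 2L) {
    Phi <- diag(m)
    ip <- info$type == "phi"
    Phi[cbind(info$row[ip], info$col[ip])] <- theta[ip]
    Phi[cbind(info$col[ip], info$row[ip])] <- theta[ip]
  } else if (spec$structure == "second_order") {
    Gamma <- theta[info$type == "gamma"]
    Psi <- theta[info$type == "psi"]
    Phi <- tcrossprod(Gamma) + diag(Psi, m)
  } else {
    Phi <- diag(m)
  }
  uniq <- theta[info$type == "theta"]
  list(Lambda = Lambda, Phi = Phi, Gamma = Gamma, Psi = Psi,
       uniquenesses = uniq, p = p, m = m)
}

#' Model-implied covariance matrix
#'
#' Evaluates Sigma(theta) = Lambda Phi Lambda' + Theta for a specification
#' and a free-parameter vector in canonical order (free loadings
#' column-major, then structure parameters, then uniquenesses).
#'
#' @param spec an [fm_spec()].
#' @param theta numeric vector, length [count_free_parameters()].
#' @return symmetric p x p matrix with the spec's subtest dimnames.
#' @export
implied_matrix <- function(spec, theta) {
  stopifnot(inherits(spec, "fm_spec"))
  info <- param_info(spec)
  if (length(theta) != nrow(info))
    stop(sprintf("theta has length %d, expected %d", length(theta), nrow(info)))
  if (any(!is.finite(theta))) stop("non-finite parameter value")
  u <- unpack_theta(spec, theta, info)
  Sigma <- if (u$m > 0L) u$Lambda %*% u$Phi %*% t(u$Lambda) else
    matrix(0, u$p, u$p)
  Sigma <- (Sigma + t(Sigma)) / 2 + diag(u$uniquenesses, u$p)
  dimnames(Sigma) <- list(rownames(spec$pattern), rownames(spec$pattern))
  Sigma
}

#' Wishart maximum-likelihood discrepancy
#'
#' `F(S, Sigma) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p`; nonnegative, and
#' zero exactly when `S == Sigma`.
#'
#' @param S,Sigma symmetric positive-definite matrices of equal order.
#' @return scalar discrepancy (unitless).
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S)
  stopifnot(nrow(Sigma) == p, ncol(S) == p, ncol(Sigma) == p)
  cS <- chol(S)
  cSig <- tryCatch(chol(Sigma), error = function(e)
    stop("decomposition error: implied matrix is singular or indefinite"))
  Siginv <- chol2inv(cSig)
  2 * sum(log(diag(cSig))) - 2 * sum(log(diag(cS))) + sum(Siginv * S) - p
}

# Discrepancy and analytic gradient in one pass. Returns F = PENALTY_F with
# a zero gradient outside the positive-definite cone (large enough that the
# line search backs off).
fml_grad <- function(spec, theta, S, info, ldetS) {
  u <- unpack_theta(spec, theta, info)
  p <- u$p; m <- u$m
  if (spec$structure == "oblique" && m >= 2L) {
    ok <- tryCatch({ chol(u$Phi); TRUE }, error = function(e) FALSE)
    if (!ok) return(list(F = PENALTY_F, grad = numeric(nrow(info))))
  }
  Sigma <- if (m > 0L) u$Lambda %*% u$Phi %*% t(u$Lambda) else matrix(0, p, p)
  Sigma <- (Sigma + t(Sigma)) / 2 + diag(u$uniquenesses, p)
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cSig)) return(list(F = PENALTY_F, grad = numeric(nrow(info))))
  Siginv <- chol2inv(cSig)
  Fval <- 2 * sum(log(diag(cSig))) - ldetS + sum(Siginv * S) - p
  W <- Siginv - Siginv %*% S %*% Siginv
  W <- (W + t(W)) / 2
  grad <- numeric(nrow(info))
  if (m > 0L) {
    GL <- 2 * W %*% u$Lambda %*% u$Phi
    il <- info$type == "lambda"
    grad[il] <- GL[cbind(info$row[il], info$col[il])]
    if (spec$structure == "oblique" && m >= 2L) {
      A <- t(u$Lambda) %*% W %*% u$Lambda
      ip <- info$type == "phi"
      grad[ip] <- 2 * A[cbind(info$row[ip], info$col[ip])]
    } else if (spec$structure == "second_order") {
      A <- t(u$Lambda) %*% W %*% u$Lambda
      grad[info$type == "gamma"] <- 2 * as.vector(A %*% u$Gamma)
      grad[info$type == "psi"] <- diag(A)
    }
  }
  grad[info$type == "theta"] <- diag(W)
  list(F = Fval, grad = grad)
}

#' Fit a factor model by maximum likelihood
#'
#' Minimizes the Wishart discrepancy between the sample correlation matrix
#' (analyzed as a covariance matrix) and the model-implied matrix, under the
#' specification's lower bounds (variance parameters bounded at 0 by
#' default, the global Heywood guard). The optimizer is bound-constrained
#' quasi-Newton (L-BFGS-B) with the analytic gradient; no random numbers are
#' used, so the result is deterministic given `(spec, sample, start)`.
#'
#' Default starting values are 0.5 on free loadings (plus a small fixed
#' cell-dependent offset that breaks the column symmetry of full-loading
#' patterns), 0.2 on factor correlations, 0.5 / 0.3 on second-order loadings
#' and disturbances, and 0.5 on uniquenesses.
#'
#' @param spec an [fm_spec()]; must be counted-identified (df >= 0).
#' @param sample a [corr_sample()] with the spec's variable names.
#' @param start optional start vector (canonical parameter order).
#' @param grad_tol maximum absolute gradient over free non-active parameters
#'   accepted as converged.
#' @param maxit iteration cap for the optimizer.
#' @return An object of class `fm_fit`: list with `spec`, `theta_hat`
#'   (named), `Sigma_hat`, `F_min`, `chi2 = (N-1) F_min`, `df`, `n_obs`,
#'   `converged`, `grad_norm`, `active_bounds` (labels of parameters at
#'   their lower bound), `iterations`, `sample` and the parameter table
#'   `param_table`.
#' @export
fit_model <- function(spec, sample, start = NULL, grad_tol = 1e-4,
                      maxit = 2000L) {
  stopifnot(inherits(spec, "fm_spec"), inherits(sample, "corr_sample"))
  if (!identical(rownames(spec$pattern), sample$names))
    stop("alignment error: spec subtests and sample variable names differ")
  df <- model_df(spec)   # errors if over-parameterized
  info <- param_info(spec)
  q <- nrow(info)
  if (is.null(start)) start <- info$start
  if (length(start) != q)
    stop(sprintf("start has length %d, expected %d", length(start), q))
  S <- sample$R
  ldetS <- 2 * sum(log(diag(chol(S))))

  fn <- function(th) fml_grad(spec, th, S, info, ldetS)$F
  gr <- function(th) fml_grad(spec, th, S, info, ldetS)$grad
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = info$lower, upper = info$upper,
                      control = list(maxit = maxit, factr = 1e2, pgtol = 1e-7))

  theta_hat <- opt$par
  names(theta_hat) <- info$label
  g <- fml_grad(spec, theta_hat, S, info, ldetS)
  active <- is.finite(info$lower) & (theta_hat - info$lower < 1e-6)
  grad_norm <- if (all(active)) 0 else max(abs(g$grad[!active]))
  converged <- opt$convergence == 0L && grad_norm <= grad_tol
  if (opt$convergence == 1L)
    warning(sprintf("'%s': optimizer hit the iteration cap (%d); returning best point",
                    spec$name, maxit))
  neg_var <- info$type %in% c("theta", "psi") & theta_hat < 0
  if (any(neg_var))
    warning("Heywood case: negative variance estimate for ",
            paste(info$label[neg_var], collapse = ", "))

  structure(list(
    spec = spec,
    theta_hat = theta_hat,
    Sigma_hat = implied_matrix(spec, theta_hat),
    F_min = g$F,
    chi2 = (sample$n_obs - 1) * g$F,
    df = df,
    n_obs = sample$n_obs,
    converged = converged,
    grad_norm = grad_norm,
    active_bounds = info$label[active],
    iterations = opt$counts[["function"]],
    param_table = info,
    sample = sample
  ), class = "fm_fit")
}

#' @export
print.fm_fit <- function(x, ...) {
  cat(sprintf("ML fit of '%s' (N = %d)\n", x$spec$name, x$n_obs))
  cat(sprintf("  F_min = %.6g, chi2 = %.2f, df = %d, converged: %s\n",
              x$F_min, x$chi2, x$df, x$converged))
  if (length(x$active_bounds))
    cat("  active lower bounds:", paste(x$active_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' Estimated loadings of a fit, optionally sign-normalized
#'
#' @param fit an `fm_fit`.
#' @param normalize_sign flip columns so the largest-magnitude loading per
#'   factor is positive (see [sign_normalize()]).
#' @return p x m loading matrix (fixed cells included at their fixed value).
#' @export
loading_matrix <- function(fit, normalize_sign = FALSE) {
  u <- unpack_theta(fit$spec, fit$theta_hat, fit$param_table)
  if (normalize_sign && u$m > 0L) sign_normalize(u$Lambda)$Lambda else u$Lambda
}

#' Observed information matrix at the solution
#'
#' Numerical Hessian of `(N - 1)/2` times the discrepancy at `theta_hat`,
#' by central differences of the analytic gradient, symmetrized. This is
#' the curvature used by the Lagrange-multiplier and Wald projections. If
#' the numerical Hessian is indefinite its eigenvalues are floored at a
#' small positive multiple of the largest one, with a warning.
#'
#' @param fit a converged `fm_fit`.
#' @param S sample matrix (defaults to the fit's own).
#' @return symmetric q x q matrix with parameter-label dimnames.
#' @export
information_matrix <- function(fit, S = fit$sample$R) {
  stopifnot(inherits(fit, "fm_fit"))
  H <- discrepancy_hessian(fit$spec, fit$theta_hat, S)
  H <- (fit$n_obs - 1) / 2 * H
  ev <- eigen(H, symmetric = TRUE)
  floor_val <- max(ev$values) * 1e-10
  if (min(ev$values) < -abs(floor_val) * 10) {
    warning(sprintf(
      "information matrix indefinite (min eigenvalue %.3g); eigenvalue floor applied",
      min(ev$values)))
    vals <- pmax(ev$values, floor_val)
    H <- ev$vectors %*% (vals * t(ev$vectors))
    H <- (H + t(H)) / 2
  }
  dimnames(H) <- list(names(fit$theta_hat), names(fit$theta_hat))
  H
}

# Hessian of the discrepancy F (not yet scaled by (N-1)/2) by central
# differences of the analytic gradient.
discrepancy_hessian <- function(spec, theta, S, h = 1e-5) {
  info <- param_info(spec)
  ldetS <- 2 * sum(log(diag(chol(S))))
  q <- length(theta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    step <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + step
    tm <- theta; tm[j] <- tm[j] - step
    gp <- fml_grad(spec, tp, S, info, ldetS)$grad
    gm <- fml_grad(spec, tm, S, info, ldetS)$grad
    H[, j] <- (gp - gm) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Fit the uniqueness-only null model
#'
#' The baseline of the incremental fit indices: a diagonal implied matrix
#' with the p uniquenesses free, df = p(p+1)/2 - p. For unit-diagonal input
#' the solution is Sigma = I and chi2 = -(N-1) ln|R|.
#'
#' @param sample a [corr_sample()].
#' @return an `fm_fit`.
#' @export
null_model_fit <- function(sample) {
  fit_model(null_spec(sample$names), sample)
}
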