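# Stepwise model modification driven by score (Lagrange-multiplier) and
# Wald projections. Candidate parameters are fixed-zero loading cells only:
# no error covariances and no factor-correlation candidates. All projections
# exclude parameters sitting on an active lower bound.

# Free a fixed-zero pattern cell.
free_cell <- function(spec, row, col) {
  pat <- spec$pattern
  pat[row, col] <- NA_real_
  fm_spec(pat, spec$structure, spec$uniqueness_bounds, spec$name)
}

# Fix a free pattern cell back to zero.
fix_cell <- function(spec, row, col) {
  pat <- spec$pattern
  pat[row, col] <- 0
  fm_spec(pat, spec$structure, spec$uniqueness_bounds, spec$name)
}

#' Rank fixed loadings by Lagrange-multiplier (score) projections
#'
#' For every candidate fixed-zero loading cell, the score-test statistic
#' projects the chi-squared improvement from freeing that single cell
#' without refitting: the squared score over its information, partialed for
#' all currently free (non-active-bound) parameters. Candidates whose
#' partial information is numerically singular are skipped with a warning.
#'
#' @param fit a converged `fm_fit`.
#' @param candidates optional two-column matrix / data.frame of (row, col)
#'   pattern indices; default: every fixed-zero loading cell.
#' @return data.frame with columns `subtest`, `factor`, `row`, `col`,
#'   `projected_dchi2`, `p_value`, sorted by decreasing projected change
#'   (ties broken by subtest then factor order).
#' @export
lagrange_rank <- function(fit, candidates = NULL) {
  stopifnot(inherits(fit, "fm_fit"))
  spec <- fit$spec
  pat <- spec$pattern
  if (is.null(candidates)) {
    idx <- which(!is.na(pat) & pat == 0, arr.ind = TRUE)
  } else {
    idx <- as.matrix(candidates)[, 1:2, drop = FALSE]
  }
  if (nrow(idx) == 0L)
    return(data.frame(subtest = character(), factor = character(),
                      row = integer(), col = integer(),
                      projected_dchi2 = numeric(), p_value = numeric()))

  # Expanded spec with every candidate freed at value 0.
  pat_ext <- pat
  pat_ext[idx] <- NA_real_
  spec_ext <- fm_spec(pat_ext, spec$structure, spec$uniqueness_bounds, spec$name)
  info_ext <- param_info(spec_ext)
  info_old <- fit$param_table
  key <- function(ii) paste(ii$type, ii$row, ii$col)
  match_old <- match(key(info_ext), key(info_old))
  theta_ext <- ifelse(is.na(match_old), 0, fit$theta_hat[match_old])

  S <- fit$sample$R
  ldetS <- 2 * sum(log(diag(chol(S))))
  g <- fml_grad(spec_ext, theta_ext, S, info_ext, ldetS)$grad
  H <- discrepancy_hessian(spec_ext, theta_ext, S)

  is_cand <- is.na(match_old)
  cand_cells <- paste(info_ext$row, info_ext$col)
  active_old <- names(fit$theta_hat) %in% fit$active_bounds
  is_free <- !is.na(match_old) & !active_old[match_old]

  Hff <- H[is_free, is_free, drop = FALSE]
  cf <- tryCatch(chol(Hff), error = function(e) NULL)
  n1 <- fit$n_obs - 1

  out <- lapply(which(is_cand), function(a) {
    hf <- H[a, is_free]
    part <- if (is.null(cf)) NA_real_ else
      H[a, a] - sum(hf * backsolve(cf, forwardsolve(t(cf), hf)))
    if (!is.finite(part) || part <= .Machine$double.eps * abs(H[a, a]) + 1e-12) {
      warning(sprintf("candidate %s skipped: singular partial information",
                      info_ext$label[a]))
      return(NULL)
    }
    lm_stat <- (n1 / 2) * g[a]^2 / part
    data.frame(subtest = rownames(pat)[info_ext$row[a]],
               factor = colnames(pat)[info_ext$col[a]],
               row = info_ext$row[a], col = info_ext$col[a],
               projected_dchi2 = lm_stat,
               p_value = stats::pchisq(lm_stat, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(subtest = character(), factor = character(),
                                      row = integer(), col = integer(),
                                      projected_dchi2 = numeric(),
                                      p_value = numeric()))
  out[order(-out$projected_dchi2, out$row, out$col), , drop = FALSE]
}

#' Rank free loadings by Wald projections
#'
#' For every free loading, the Wald statistic `(estimate / s.e.)^2` projects
#' the chi-squared deterioration from fixing that cell to zero. Standard
#' errors come from the inverse information over free non-active-bound
#' parameters; cells with a non-positive variance estimate are excluded with
#' a warning.
#'
#' @param fit a converged `fm_fit`.
#' @return data.frame like [lagrange_rank()]'s, sorted by increasing
#'   projected change.
#' @export
wald_rank <- function(fit) {
  stopifnot(inherits(fit, "fm_fit"))
  info <- fit$param_table
  S <- fit$sample$R
  H <- discrepancy_hessian(fit$spec, fit$theta_hat, S)
  active <- names(fit$theta_hat) %in% fit$active_bounds
  is_free <- !active
  I_ff <- (fit$n_obs - 1) / 2 * H[is_free, is_free, drop = FALSE]
  V <- tryCatch(solve(I_ff), error = function(e) NULL)
  if (is.null(V)) stop("information matrix is singular; Wald ranks unavailable")
  pos_free <- which(is_free)
  rows <- lapply(seq_along(pos_free), function(j) {
    a <- pos_free[j]
    if (info$type[a] != "lambda") return(NULL)
    se2 <- V[j, j]
    if (!is.finite(se2) || se2 <= 0) {
      warning(sprintf("loading %s excluded: zero or negative variance estimate",
                      info$label[a]))
      return(NULL)
    }
    w <- fit$theta_hat[a]^2 / se2
    data.frame(subtest = rownames(fit$spec$pattern)[info$row[a]],
               factor = colnames(fit$spec$pattern)[info$col[a]],
               row = info$row[a], col = info$col[a],
               projected_dchi2 = w,
               p_value = stats::pchisq(w, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(subtest = character(), factor = character(),
                                      row = integer(), col = integer(),
                                      projected_dchi2 = numeric(),
                                      p_value = numeric()))
  out[order(out$projected_dchi2, out$row, out$col), , drop = FALSE]
}

#' Stepwise model modification
#'
#' One parameter changes per step. (1) The largest Lagrange-multiplier
#' candidate is added if its projected chi-squared change is significant at
#' `alpha`; (2) otherwise the free loading with the smallest Wald projection
#' is dropped if that projection is *not* significant at `alpha`; (3) the
#' model is refitted after every accepted step and the ACTUAL chi-squared
#' change must meet the same criterion (significant for an addition,
#' non-significant for a drop) — a step failing it is rolled back and the
#' search stops. `alpha` is per step and uncorrected. An oscillation guard
#' terminates the search if the same cell is toggled twice.
#'
#' @param spec starting [fm_spec()].
#' @param sample a [corr_sample()].
#' @param alpha per-step significance level (default 0.05).
#' @param max_steps safety cap on accepted steps.
#' @return list with `spec` (final), `fit` (final `fm_fit`), and `log`, an
#'   object of class `mod_log`: data.frame of steps (action, subtest,
#'   factor, projected_dchi2, actual_dchi2, p_value, accepted) plus
#'   attributes `initial`, `final`, `alpha`, `oscillation`.
#' @export
stepwise_modify <- function(spec, sample, alpha = 0.05, max_steps = 50L) {
  fit <- fit_model(spec, sample)
  crit <- stats::qchisq(1 - alpha, 1)
  steps <- list()
  history <- character()
  oscillation <- FALSE

  repeat {
    if (length(steps) >= max_steps) break
    lm <- lagrange_rank(fit)
    did <- FALSE
    if (nrow(lm) > 0L && lm$p_value[1] < alpha) {
      cand <- lm[1, ]
      key <- paste("ADD", cand$row, cand$col)
      rev_key <- paste("DROP", cand$row, cand$col)
      if (sum(history == key) >= 1L && sum(history == rev_key) >= 1L) {
        oscillation <- TRUE
        break
      }
      new_spec <- free_cell(fit$spec, cand$row, cand$col)
      new_fit <- fit_model(new_spec, sample)
      actual <- fit$chi2 - new_fit$chi2
      ok <- actual >= crit
      steps[[length(steps) + 1L]] <- data.frame(
        action = "ADD", subtest = cand$subtest, factor = cand$factor,
        projected_dchi2 = cand$projected_dchi2, actual_dchi2 = actual,
        p_value = cand$p_value, accepted = ok, stringsAsFactors = FALSE)
      if (!ok) break               # rolled back: fit/spec unchanged
      history <- c(history, key)
      fit <- new_fit
      did <- TRUE
    } else {
      wd <- wald_rank(fit)
      if (nrow(wd) > 0L && wd$p_value[1] >= alpha) {
        cand <- wd[1, ]
        key <- paste("DROP", cand$row, cand$col)
        rev_key <- paste("ADD", cand$row, cand$col)
        if (sum(history == key) >= 1L && sum(history == rev_key) >= 1L) {
          oscillation <- TRUE
          break
        }
        new_spec <- fix_cell(fit$spec, cand$row, cand$col)
        new_fit <- fit_model(new_spec, sample)
        actual <- new_fit$chi2 - fit$chi2
        ok <- actual < crit
        steps[[length(steps) + 1L]] <- data.frame(
          action = "DROP", subtest = cand$subtest, factor = cand$factor,
          projected_dchi2 = cand$projected_dchi2, actual_dchi2 = actual,
          p_value = cand$p_value, accepted = ok, stringsAsFactors = FALSE)
        if (!ok) break
        history <- c(history, key)
        fit <- new_fit
        did <- TRUE
      }
    }
    if (!did) break
  }

  log <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(), subtest = character(),
               factor = character(), projected_dchi2 = numeric(),
               actual_dchi2 = numeric(), p_value = numeric(),
               accepted = logical(), stringsAsFactors = FALSE)
  attr(log, "initial") <- spec$name
  attr(log, "final") <- fit$spec$name
  attr(log, "alpha") <- alpha
  attr(log, "oscillation") <- oscillation
  class(log) <- c("mod_log", class(log))
  list(spec = fit$spec, fit = fit, log = log)
}

#' @export
print.mod_log <- function(x, ...) {
  cat(sprintf("Stepwise modification of '%s' (alpha = %g)\n",
              attr(x, "initial"), attr(x, "alpha")))
  if (nrow(x) == 0L) {
    cat("  no steps taken\n")
  } else {
    print.data.frame(cbind(step = seq_len(nrow(x)), as.data.frame(x)),
                     row.names = FALSE, digits = 4)
  }
  if (isTRUE(attr(x, "oscillation")))
    cat("  terminated by oscillation guard\n")
  invisible(x)
}
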