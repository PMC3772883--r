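#' Factor model specification
#'
#' A confirmatory factor model is specified by a loading pattern and a
#' factor-covariance structure. The pattern is a p x m numeric matrix in
#' which `NA` marks a FREE loading and any number a FIXED value (almost
#' always 0). The structure is one of:
#'
#' * `"orthonormal"` — factor covariance matrix Phi fixed to the identity;
#' * `"oblique"` — Phi has unit diagonal and freely estimated off-diagonals;
#' * `"second_order"` — a hierarchical model: Phi = Gamma Gamma' + diag(Psi)
#'   with the m second-order loadings Gamma free, the m first-order
#'   disturbance variances Psi free with lower bound 0, and the variance of
#'   the general factor fixed to 1;
#' * `"nested"` — estimated exactly like `"orthonormal"`; the tag records
#'   that one pattern column is a general factor orthogonal to the group
#'   factors (bifactor-style), which matters for catalog bookkeeping only.
#'
#' All first-order latent variances are fixed to 1 except under
#' `"second_order"`, where a group factor's variance is `gamma^2 + psi` and
#' its scale is carried implicitly by Gamma and Psi (no reference loadings).
#'
#' @param pattern numeric p x m matrix, `NA` = free cell, number = fixed
#'   value; dimnames give subtest and factor names. `m = 0` gives the
#'   uniqueness-only null model.
#' @param structure one of `"orthonormal"`, `"oblique"`, `"second_order"`,
#'   `"nested"`.
#' @param uniqueness_bounds lower bound(s) for the p uniquenesses (scalar or
#'   length-p vector, all `>= 0`). Default 0, which also implements the
#'   global Heywood guard.
#' @param name model name used in reports.
#' @return An object of class `fm_spec`.
#' @examples
#' pat <- matrix(NA_real_, 3, 1, dimnames = list(c("a", "b", "c"), "F1"))
#' spec <- fm_spec(pat, "orthonormal", name = "one factor")
#' count_free_parameters(spec)  # 3 loadings + 3 uniquenesses
#' @export
fm_spec <- function(pattern, structure = c("orthonormal", "oblique",
                                           "second_order", "nested"),
                    uniqueness_bounds = 0, name = "model") {
  structure <- match.arg(structure)
  pattern <- as.matrix(pattern)
  storage.mode(pattern) <- "double"
  p <- nrow(pattern)
  m <- ncol(pattern)
  if (p < 1L) stop("pattern needs at least one row")
  if (is.null(rownames(pattern))) rownames(pattern) <- paste0("V", seq_len(p))
  if (m > 0L && is.null(colnames(pattern))) colnames(pattern) <- paste0("F", seq_len(m))
  if (m > 0L) {
    live <- is.na(pattern) | pattern != 0
    if (any(colSums(live) == 0L))
      stop("every factor column needs at least one free or nonzero-fixed cell")
    if (any(rowSums(live) == 0L))
      stop("every subtest row needs at least one free or nonzero-fixed cell")
  }
  if (structure == "second_order" && m < 2L)
    stop("a second-order structure requires at least 2 group factors")
  ub <- rep_len(as.numeric(uniqueness_bounds), p)
  if (any(ub < 0)) stop("uniqueness bounds must be >= 0")
  structure(
    list(pattern = pattern, structure = structure,
         uniqueness_bounds = ub, name = as.character(name)[1]),
    class = "fm_spec"
  )
}

#' @export
print.fm_spec <- function(x, ...) {
  p <- nrow(x$pattern); m <- ncol(x$pattern)
  cat(sprintf("Factor model '%s': %d subtests, %d factors, %s structure\n",
              x$name, p, m, x$structure))
  cat(sprintf("  free parameters: %d, df (p=%d): %d\n",
              count_free_parameters(x), p, model_df(x)))
  if (m > 0L) {
    disp <- matrix("", p, m, dimnames = dimnames(x$pattern))
    disp[is.na(x$pattern)] <- "*"
    nz <- !is.na(x$pattern) & x$pattern != 0
    disp[nz] <- formatC(x$pattern[nz], format = "g", digits = 4)
    print(as.data.frame(disp), right = FALSE)
    cat("  ('*' = free loading, blank = fixed 0)\n")
  }
  invisible(x)
}

# Free-parameter bookkeeping table: one row per free parameter, in the
# canonical theta order (loadings column-major, then structure parameters,
# then uniquenesses). `start` holds the deterministic default starts: 0.5 on
# loadings plus a small fixed cell-dependent offset that breaks the exact
# column symmetry of full-loading patterns (a flat start leaves exchangeable
# columns on a saddle that gradient methods cannot leave).
param_info <- function(spec) {
  pat <- spec$pattern
  p <- nrow(pat); m <- ncol(pat)
  subtests <- rownames(pat); factors <- colnames(pat)
  rows <- list()
  if (m > 0L) {
    free <- which(is.na(pat), arr.ind = TRUE)
    if (nrow(free) > 0L) {
      free <- free[order(free[, 2L], free[, 1L]), , drop = FALSE]
      jit <- 0.02 * (((free[, 1L] * 7 + free[, 2L] * 13) %% 11) - 5) / 5
      rows[[length(rows) + 1L]] <- data.frame(
        type = "lambda", row = free[, 1L], col = free[, 2L],
        label = sprintf("lambda[%s,%s]", subtests[free[, 1L]], factors[free[, 2L]]),
        lower = -Inf, upper = Inf, start = 0.5 + jit,
        stringsAsFactors = FALSE)
    }
  }
  if (spec$structure == "oblique" && m >= 2L) {
    idx <- which(lower.tri(matrix(0, m, m)), arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      type = "phi", row = idx[, 1L], col = idx[, 2L],
      label = sprintf("phi[%s,%s]", factors[idx[, 1L]], factors[idx[, 2L]]),
      lower = -0.995, upper = 0.995, start = 0.2,
      stringsAsFactors = FALSE)
  }
  if (spec$structure == "second_order") {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "gamma", row = seq_len(m), col = 0L,
      label = sprintf("gamma[%s]", factors),
      lower = -Inf, upper = Inf, start = 0.5, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "psi", row = seq_len(m), col = 0L,
      label = sprintf("psi[%s]", factors),
      lower = 0, upper = Inf, start = 0.3, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    type = "theta", row = seq_len(p), col = 0L,
    label = sprintf("theta[%s]", subtests),
    lower = spec$uniqueness_bounds, upper = Inf, start = 0.5,
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Number of free parameters of a model specification
#'
#' Free loadings plus free factor-structure entries (oblique correlations,
#' or second-order loadings and disturbances) plus the p uniquenesses.
#'
#' @param spec an [fm_spec()].
#' @return integer count.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "fm_spec"))
  nrow(param_info(spec))
}

#' Model degrees of freedom
#'
#' `p(p+1)/2` data moments minus the free-parameter count. Rotational or
#' scale indeterminacies are not subtracted; this is the conventional SEM
#' df bookkeeping.
#'
#' @param spec an [fm_spec()].
#' @param p number of observed variables (defaults to the pattern's rows).
#' @return integer df; an error if negative.
#' @export
model_df <- function(spec, p = nrow(spec$pattern)) {
  q <- count_free_parameters(spec)
  moments <- (p * (p + 1L)) %/% 2L
  df <- moments - q
  if (df < 0L)
    stop(sprintf("over-parameterized model: %d free parameters exceed %d moments",
                 q, moments))
  as.integer(df)
}

#' Orthogonal partition count of an oblique model
#'
#' An oblique model with m correlated factors can be re-expressed with
#' orthogonal components: one shared component per factor pair plus one
#' unique component per factor, i.e. `m(m-1)/2 + m = choose(m, 2) + m`
#' orthogonal factors in total. A five-factor oblique model is thus
#' equivalent to a model with 15 orthogonal factors.
#'
#' @param m number of oblique factors, at least 2.
#' @return integer count of orthogonal components.
#' @export
oblique_partition_count <- function(m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 2L)
    stop("m must be a single integer >= 2")
  (m * (m - 1L)) %/% 2L + m
}

#' Serialize a model specification to a YAML config
#'
#' The config lists the subtests, the structure kind, per-factor free cells
#' and nonzero fixed cells (unlisted cells are fixed at 0), the uniqueness
#' lower bounds and the model name. [read_model_spec()] restores an
#' identical specification.
#'
#' @param spec an [fm_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fm_spec"))
  pat <- spec$pattern
  factors <- lapply(seq_len(ncol(pat)), function(k) {
    fr <- rownames(pat)[is.na(pat[, k])]
    nz <- which(!is.na(pat[, k]) & pat[, k] != 0)
    entry <- list(name = colnames(pat)[k])
    if (length(fr)) entry$free <- as.list(fr)
    if (length(nz)) entry$fixed <- as.list(stats::setNames(pat[nz, k], rownames(pat)[nz]))
    entry
  })
  cfg <- list(
    name = spec$name,
    structure = spec$structure,
    subtests = as.list(rownames(pat)),
    factors = factors,
    uniqueness_bounds = as.list(spec$uniqueness_bounds)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a model specification config
#'
#' @param path a YAML config written by [write_model_spec()] (or by hand in
#'   the same layout).
#' @return an [fm_spec()].
#' @export
read_model_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  subtests <- unlist(cfg$subtests)
  p <- length(subtests)
  m <- length(cfg$factors)
  pat <- matrix(0, p, m,
                dimnames = list(subtests,
                                vapply(cfg$factors, function(f) f$name, "")))
  for (k in seq_len(m)) {
    f <- cfg$factors[[k]]
    if (!is.null(f$free)) {
      fr <- unlist(f$free)
      bad <- setdiff(fr, subtests)
      if (length(bad)) stop("unknown subtest in config: ", paste(bad, collapse = ", "))
      pat[fr, k] <- NA_real_
    }
    if (!is.null(f$fixed)) {
      for (nm in names(f$fixed)) pat[nm, k] <- as.numeric(f$fixed[[nm]])
    }
  }
  ub <- if (is.null(cfg$uniqueness_bounds)) 0 else unlist(cfg$uniqueness_bounds)
  fm_spec(pat, structure = cfg$structure, uniqueness_bounds = ub,
          name = if (is.null(cfg$name)) "model" else cfg$name)
}

#' Resolve factor sign indeterminacy for reporting
#'
#' Flips each loading column whose largest-magnitude entry is negative, so
#' that printed tables have a positive anchor loading per factor. The flip is
#' exact and reversible: for oblique structures the corresponding rows and
#' columns of Phi are flipped too, and for second-order structures the
#' corresponding Gamma entries, so the implied matrix is unchanged. Raw
#' estimates stay unflipped inside fit objects; this is a report-time
#' transform.
#'
#' @param Lambda p x m loading matrix.
#' @param Phi optional m x m factor covariance matrix.
#' @param Gamma optional m-vector of second-order loadings.
#' @return list with `Lambda`, `Phi`, `Gamma` (transformed) and `flips`, the
#'   vector of per-column signs applied.
#' @export
sign_normalize <- function(Lambda, Phi = NULL, Gamma = NULL) {
  m <- ncol(Lambda)
  flips <- rep(1, m)
  for (k in seq_len(m)) {
    col <- Lambda[, k]
    if (all(col == 0)) next
    if (col[which.max(abs(col))] < 0) flips[k] <- -1
  }
  Lambda <- sweep(Lambda, 2L, flips, `*`)
  if (!is.null(Phi)) Phi <- diag(flips, m) %*% Phi %*% diag(flips, m)
  if (!is.null(Gamma)) Gamma <- Gamma * flips
  list(Lambda = Lambda, Phi = Phi, Gamma = Gamma, flips = flips)
}
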