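#' Correlation sample
#'
#' Container for a named p x p Pearson correlation matrix together with its
#' effective sample size and a free-text population label. This is the input
#' object of every fitting function in the package: the correlation matrix is
#' analyzed as if it were a covariance matrix (the CALIS/LISREL convention for
#' matrix input), so the chi-squared multiplier is `n_obs - 1`.
#'
#' Validation is strict and no repair is attempted: an indefinite matrix is an
#' error (naming the smallest eigenvalue), never smoothed or bent, because any
#' silent repair would change every downstream statistic.
#'
#' @param R numeric p x p matrix, symmetric, unit diagonal, positive definite.
#' @param n_obs positive integer sample size; must be at least `p + 1`.
#' @param names character vector of p variable labels; defaults to
#'   `rownames(R)`.
#' @param label free-text population tag (e.g. `"ages 20-54"`).
#' @return An object of class `corr_sample`: a list with elements `names`,
#'   `R` (with dimnames set), `n_obs` and `label`.
#' @examples
#' R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
#' s <- corr_sample(R, n_obs = 100, names = c("a", "b", "c"))
#' s$R["a", "b"]
#' @export
corr_sample <- function(R, n_obs, names = rownames(R), label = "") {
  R <- as.matrix(R)
  p <- nrow(R)
  if (p < 2L || ncol(R) != p)
    stop("R must be a square matrix with p >= 2")
  if (is.null(names)) names <- paste0("V", seq_len(p))
  names <- as.character(names)
  if (length(names) != p) stop("length(names) must equal nrow(R)")
  if (anyDuplicated(names)) stop("variable names must be unique")
  if (any(!is.finite(R))) stop("R contains non-finite entries")
  asym <- max(abs(R - t(R)))
  if (asym > 1e-12)
    stop(sprintf("R is asymmetric beyond tolerance (max |R - t(R)| = %.3g)", asym))
  R <- (R + t(R)) / 2
  if (max(abs(diag(R) - 1)) > 1e-12)
    stop("diagonal of a correlation matrix must be exactly 1")
  diag(R) <- 1
  if (max(abs(R)) > 1 + 1e-12)
    stop("correlations must satisfy |r| <= 1")
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop(sprintf("R is not positive definite (smallest eigenvalue %.6g)", ev_min))
  n_obs <- as.integer(n_obs)
  if (length(n_obs) != 1L || is.na(n_obs) || n_obs < p + 1L)
    stop("n_obs must be a single integer >= p + 1")
  dimnames(R) <- list(names, names)
  structure(
    list(names = names, R = R, n_obs = n_obs, label = as.character(label)[1]),
    class = "corr_sample"
  )
}

#' @export
print.corr_sample <- function(x, ...) {
  cat(sprintf("Correlation sample: %d variables, N = %d%s\n",
              length(x$names), x$n_obs,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  print(round(x$R, 4))
  invisible(x)
}

# Parse "# key=value" metadata lines from a matrix file.
parse_meta <- function(lines) {
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      out[[key]] <- val
    }
  }
  out
}

#' Read a correlation matrix file
#'
#' Reads the package's plain-text correlation matrix format: optional
#' `# key=value` metadata lines (a `# N=<int>` line is mandatory; `# label=`
#' is optional), a header row of variable names, and a numeric body that is
#' either the full symmetric matrix (`dialect = "full"`, one row per
#' variable, row label first) or the lower triangle including the unit
#' diagonal (`dialect = "lower_triangle"`, row i holding i values after the
#' row label). Fields are separated by whitespace or commas.
#'
#' @param path file path.
#' @param dialect `"full"` or `"lower_triangle"`.
#' @return A validated [corr_sample()].
#' @seealso [write_correlation_matrix()]
#' @export
read_correlation_matrix <- function(path, dialect = c("full", "lower_triangle")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- parse_meta(lines)
  if (is.null(meta$N))
    stop("metadata error: mandatory '# N=<int>' line is missing in ", path)
  n_obs <- suppressWarnings(as.integer(meta$N))
  if (is.na(n_obs)) stop("metadata error: '# N=", meta$N, "' is not an integer")
  label <- if (is.null(meta$label)) "" else meta$label

  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("format error: no matrix body in ", path)
  # Comma-separated lines keep multi-word variable names intact; lines
  # without commas fall back to whitespace splitting.
  toks <- lapply(body, function(ln) {
    tk <- if (grepl(",", ln, fixed = TRUE))
      trimws(strsplit(trimws(ln), ",")[[1]])
    else strsplit(trimws(ln), "[[:space:]]+")[[1]]
    tk[nzchar(tk)]
  })
  vars <- toks[[1]]
  p <- length(vars)
  rows <- toks[-1]
  if (length(rows) != p)
    stop(sprintf("format error: expected %d data rows, found %d", p, length(rows)))

  R <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    tk <- rows[[i]]
    expect <- if (dialect == "full") p else i
    if (length(tk) == expect + 1L) {
      if (tk[1] != vars[i])
        stop(sprintf("format error: row label '%s' does not match header '%s'",
                     tk[1], vars[i]))
      tk <- tk[-1]
    }
    if (length(tk) != expect)
      stop(sprintf("format error: row %d has %d values, expected %d",
                   i, length(tk), expect))
    vals <- suppressWarnings(as.numeric(tk))
    if (any(is.na(vals)))
      stop(sprintf("format error: non-numeric value in row %d", i))
    if (dialect == "full") {
      R[i, ] <- vals
    } else {
      R[i, seq_len(i)] <- vals
      R[seq_len(i), i] <- vals
    }
  }
  if (dialect == "full") {
    asym <- max(abs(R - t(R)))
    if (asym > 1e-8)
      stop(sprintf("format error: full matrix asymmetric (max deviation %.3g)", asym))
    R <- (R + t(R)) / 2
  }
  corr_sample(R, n_obs = n_obs, names = vars, label = label)
}

#' Write a correlation matrix file
#'
#' Writes a [corr_sample()] in either dialect accepted by
#' [read_correlation_matrix()]. Values are printed at `digits` significant
#' digits (default 6); a file written by this function reads back and
#' re-writes byte-identically.
#'
#' @param sample a [corr_sample()].
#' @param path output file path.
#' @param dialect `"full"` or `"lower_triangle"`.
#' @param digits significant digits for correlation values.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(sample, path,
                                     dialect = c("full", "lower_triangle"),
                                     digits = 6) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(sample, "corr_sample"))
  p <- length(sample$names)
  fmt <- function(x) formatC(signif(x, digits), format = "g", digits = digits)
  sep <- if (any(grepl("[[:space:]]", sample$names))) ", " else " "
  lines <- c(
    sprintf("# N=%d", sample$n_obs),
    if (nzchar(sample$label)) sprintf("# label=%s", sample$label),
    paste(sample$names, collapse = sep)
  )
  for (i in seq_len(p)) {
    idx <- if (dialect == "full") seq_len(p) else seq_len(i)
    lines <- c(lines, paste(c(sample$names[i], fmt(sample$R[i, idx])),
                            collapse = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Pool correlation samples by Fisher's z transform
#'
#' Averages several correlation tables entry-wise on the Fisher z scale:
#' each off-diagonal entry of the result is `tanh(mean(atanh(r_k)))`. The
#' mean is unweighted, which presumes every input table rests on the same
#' number of observations (as the per-age-band manual tables do); the
#' function checks this. The pooled sample size is not inferred — the caller
#' supplies it explicitly (e.g. 1000 for five tables of 200).
#'
#' @param samples list of [corr_sample()] objects sharing variable names and
#'   per-table `n_obs`.
#' @param pooled_n sample size recorded on the pooled result.
#' @param label label for the pooled result (default: first input's label).
#' @return A [corr_sample()] with the pooled matrix and `n_obs = pooled_n`.
#' @export
pool_correlations <- function(samples, pooled_n, label = NULL) {
  if (inherits(samples, "corr_sample")) samples <- list(samples)
  if (length(samples) < 1L) stop("need at least one sample to pool")
  stopifnot(all(vapply(samples, inherits, logical(1), "corr_sample")))
  nm <- samples[[1]]$names
  for (s in samples[-1]) {
    if (!identical(s$names, nm))
      stop("alignment error: samples do not share variable names")
  }
  ns <- vapply(samples, `[[`, integer(1), "n_obs")
  if (length(unique(ns)) != 1L)
    stop("pooling assumes equal per-table n_obs; got ", paste(ns, collapse = ", "))
  zs <- lapply(samples, function(s) {
    off <- s$R[lower.tri(s$R)]
    if (any(abs(off) >= 1))
      stop("transform-domain error: |r| = 1 has infinite Fisher z")
    atanh(s$R)
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  R <- tanh(zbar)
  diag(R) <- 1
  if (is.null(label)) label <- samples[[1]]$label
  corr_sample(R, n_obs = pooled_n, names = nm, label = label)
}
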