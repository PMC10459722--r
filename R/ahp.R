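# Direct-eliciting benchmark: AHP reciprocal comparison matrices, principal
# eigenvector weights and Saaty consistency diagnostics.

# Saaty random consistency indices by matrix order
.saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Construct a pairwise comparison matrix
#'
#' @param m Square numeric matrix of positive comparison ratios (a_ij = how
#'   much category i is preferred over category j on Saaty's 1-9 scale).
#' @param labels Optional category labels (defaults to dimnames of `m`).
#' @param tol Reciprocity tolerance: every a_ij * a_ji must equal 1.
#' @return A `comparison_matrix` object.
#' @export
comparison_matrix <- function(m, labels = NULL, tol = 1e-6) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("comparison matrix must be square")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("comparison matrix entries must be positive numbers")
  labels <- labels %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  if (any(abs(diag(m) - 1) > tol)) stop("diagonal entries must equal 1")
  rec <- abs(m * t(m) - 1)
  if (any(rec > tol)) {
    bad <- which(rec == max(rec), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "reciprocity violated for (%s, %s): a_ij = %g but a_ji = %g",
      labels[bad[1L]], labels[bad[2L]], m[bad[1L], bad[2L]], m[bad[2L], bad[1L]]))
  }
  off <- m[row(m) != col(m)]
  if (any(off < 1 / 9 - tol | off > 9 + tol))
    warning("entries outside the Saaty 1/9..9 scale")
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("comparison_matrix", "matrix", "array"))
}

#' Read a comparison matrix from CSV
#'
#' The CSV carries a header row and a first label column; entries may be
#' fractions written as "p/q" (e.g. "1/3").
#'
#' @param path CSV file path.
#' @param labels Optional replacement category labels.
#' @return A validated [comparison_matrix()].
#' @export
parse_comparison_matrix <- function(path, labels = NULL) {
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  row_labels <- d[[1L]]
  m <- vapply(d[-1L], parse_fraction, numeric(nrow(d)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("unparseable entry at row %d, column %d of %s",
                 bad[1L], bad[2L] + 1L, path))
  }
  m <- matrix(m, nrow(d), dimnames = list(row_labels, names(d)[-1L]))
  comparison_matrix(m, labels = labels %||% row_labels)
}

#' AHP priority weights and consistency diagnostics
#'
#' Extracts category weights as the principal right eigenvector of the
#' comparison matrix (power iteration to tolerance 1e-12), normalised to sum
#' one, together with the principal eigenvalue, consistency index
#' CI = (lambda_max - n)/(n - 1) and consistency ratio CR = CI/RI(n). A
#' CR above 0.1 raises a warning but never invalidates the matrix. Geometric
#' mean weights are available as a sensitivity alternative.
#'
#' @param matrix A [comparison_matrix()].
#' @param method `"eigen"` (classical AHP, default) or `"geomean"`.
#' @param tol Power-iteration convergence tolerance.
#' @return An `ahp_result` list: `weights`, `lambda_max`, `ci`, `cr`.
#' @examples
#' v <- c(4, 2, 1, 1)
#' m <- outer(v, v, "/")            # fully consistent
#' ahp_weights(comparison_matrix(m))  # weights 0.5 0.25 0.125 0.125, CR 0
#' @export
ahp_weights <- function(matrix, method = c("eigen", "geomean"), tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "comparison_matrix"))
  A <- unclass(matrix)
  n <- nrow(A)
  if (method == "geomean") {
    g <- apply(A, 1L, function(r) exp(mean(log(r))))
    w <- g / sum(g)
  } else {
    w <- rep(1 / n, n)
    for (it in seq_len(10000L)) {
      v <- as.numeric(A %*% w)
      v <- v / sum(v)
      if (max(abs(v - w)) < tol) { w <- v; break }
      w <- v
    }
  }
  lambda <- mean(as.numeric(A %*% w) / w)
  ci <- if (n > 1) (lambda - n) / (n - 1) else 0
  ri <- if (n <= length(.saaty_ri)) .saaty_ri[n] else 1.49
  cr <- if (ri > 0) ci / ri else 0
  if (cr > 0.1)
    warning(sprintf("consistency ratio %.3f exceeds 0.1", cr))
  structure(list(weights = stats::setNames(w, rownames(A)),
                 lambda_max = lambda, ci = ci, cr = cr, method = method),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("ahp_result (%s): lambda_max %.4f, CI %.4f, CR %.4f\n",
              x$method, x$lambda_max, x$ci, x$cr))
  print(round(x$weights, 4))
  invisible(x)
}

#' Bundled operator comparison matrices
#'
#' Loads the four per-operator AHP matrices shipped with the package
#' (transcribed fixture files; sub-unity entries restored as fractions via
#' the reciprocity constraint). Categories are ordered pm25, pmv,
#' illuminance, sound.
#'
#' @param operator Operator number 1-4, or `NULL` for all four as a list.
#' @return A [comparison_matrix()] or a named list of them.
#' @export
ieq_ahp_fixtures <- function(operator = NULL) {
  load1 <- function(i) {
    parse_comparison_matrix(
      system.file("extdata", sprintf("ahp_operator%d.csv", i),
                  package = "ieqelicit", mustWork = TRUE))
  }
  if (!is.null(operator)) return(load1(operator))
  stats::setNames(lapply(1:4, load1), paste0("operator", 1:4))
}
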