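# Global time-step scoring: TOPSIS closeness and PROMETHEE net flows.
# Both operate on cost-oriented panels (lower raw values = better).

#' Weight vector on the simplex
#'
#' Validates a vector of nonnegative category weights summing to one.
#'
#' @param w Numeric vector, optionally named by criterion.
#' @param tol Tolerance on the sum-to-one constraint.
#' @return The validated weight vector.
#' @export
weight_vector <- function(w, tol = 1e-9) {
  w <- as.numeric(w0 <- w)
  names(w) <- names(w0)
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > tol) stop("weights must sum to one")
  w
}

new_scores <- function(values, hours, method, internals = NULL) {
  s <- as.numeric(values)
  names(s) <- as.character(hours)
  structure(s, method = method, internals = internals,
            class = c("ieq_scores", "numeric"))
}

#' @export
print.ieq_scores <- function(x, ...) {
  cat(sprintf("ieq_scores (%s):\n", attr(x, "method")))
  v <- as.numeric(x); names(v) <- names(x)
  print(v, ...)
  invisible(x)
}

check_panel_weights <- function(panel, weights) {
  if (!is_cost_panel(panel))
    stop("scoring requires a cost-oriented ieq_panel")
  if (length(weights) != ncol(panel))
    stop(sprintf("%d weights for %d criteria", length(weights), ncol(panel)))
  if (!is.null(names(weights)) && !is.null(colnames(panel)) &&
      !identical(names(weights), colnames(panel)))
    weights <- weights[colnames(panel)]
  weight_vector(weights)
}

#' TOPSIS closeness scores
#'
#' Scores each time step by its relative closeness to the ideal solution.
#' Each cost criterion is vector-normalised (divided by its Euclidean
#' column norm); the ideal is the per-criterion minimum of the normalised
#' values and the anti-ideal the maximum; weighted Euclidean distances to
#' both give the closeness r_t = d-/(d+ + d-). Higher r_t means better
#' global comfort; r_t is always in \[0, 1\].
#'
#' A constant-zero criterion has no column norm and is normalised to zero
#' with a warning; a time step at zero distance from both poles (all
#' criteria constant) gets the neutral score 0.5 with a warning.
#'
#' @param panel Cost-oriented [ieq_panel()].
#' @param weights [weight_vector()] of length K (criteria).
#' @param details If `TRUE`, attach the normalised matrix, ideal/anti-ideal
#'   points, weighted matrix and distances as the `internals` attribute.
#' @return An `ieq_scores` vector named by hour, method `"topsis_r"`.
#' @examples
#' m <- cbind(x = c(1, 2)); rownames(m) <- c("9", "10")
#' topsis_scores(ieq_panel(m, "cost"), 1)  # best hour scores 1, worst 0
#' @export
topsis_scores <- function(panel, weights, details = FALSE) {
  w <- check_panel_weights(panel, weights)
  S <- unclass_panel(panel)
  norms <- sqrt(colSums(S^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("criterion with all-zero values normalised to 0: %s",
                    paste(colnames(S)[zero], collapse = ", ")))
    norms[zero] <- 1
  }
  n <- sweep(S, 2L, norms, "/")
  a_plus <- apply(n, 2L, min)   # cost orientation: ideal is the minimum
  a_minus <- apply(n, 2L, max)
  cmat <- sweep(n, 2L, w, "*")
  d_plus <- sqrt(rowSums(sweep(cmat, 2L, w * a_plus)^2))
  d_minus <- sqrt(rowSums(sweep(cmat, 2L, w * a_minus)^2))
  denom <- d_plus + d_minus
  r <- ifelse(denom == 0, 0.5, d_minus / denom)
  if (any(denom == 0))
    warning("time step equidistant (0) from ideal and anti-ideal; scored 0.5")
  internals <- NULL
  if (details)
    internals <- list(normalized = n, ideal = a_plus, anti_ideal = a_minus,
                      weighted = cmat, d_plus = d_plus, d_minus = d_minus)
  new_scores(r, rownames(S), "topsis_r", internals)
}

#' Linear preference function
#'
#' Maps a pairwise criterion difference d (positive when the first time step
#' is better) to a preference degree: 0 for d <= 0, d/D for 0 < d < D, and 1
#' for d >= D, where D is the largest positive difference observed for that
#' criterion. D = 0 (constant criterion) yields preference 0 everywhere.
#'
#' @param d Numeric difference(s).
#' @param D Preference saturation threshold, >= 0.
#' @return Preference degree(s) in \[0, 1\].
#' @export
linear_preference <- function(d, D) {
  if (length(D) != 1L || is.na(D) || D < 0) stop("D must be a single value >= 0")
  if (D == 0) return(rep(0, length(d)))
  pmin(pmax(d / D, 0), 1)
}

# Per-criterion net flows with unit weight: K x T matrix such that
# phi(w) = t(Phi) %*% w. Exploits the linearity of net flows in the weights.
.promethee_phi_by_criterion <- function(S) {
  T_ <- nrow(S); K <- ncol(S)
  Phi <- matrix(0, K, T_)
  const <- logical(K)
  for (k in seq_len(K)) {
    # cost criterion: t is preferred to t' when S[t', k] > S[t, k]
    d <- outer(S[, k], S[, k], function(a, b) b - a)
    D <- max(d, 0)
    const[k] <- D == 0
    p <- linear_preference(as.numeric(d), D)
    p <- matrix(p, T_, T_)
    diag(p) <- 0
    Phi[k, ] <- rowSums(p) - colSums(p)
  }
  list(Phi = Phi, const = const)
}

#' PROMETHEE net outranking flows
#'
#' Scores each time step by its net flow. For every ordered pair of time
#' steps and every cost criterion, the difference "t better than t'"
#' (raw value at t' minus raw value at t) is mapped through the
#' [linear_preference()] function with per-criterion saturation at the
#' largest positive difference in the panel; the weighted preference
#' s_tt' = sum_k w_k p_ktt' is aggregated into leaving (row-sum) and
#' entering (column-sum) flows, and the net flow is their difference.
#' Flows are plain sums over the other time steps (no 1/(T-1) scaling).
#' Net flows always sum to zero; higher is better.
#'
#' @inheritParams topsis_scores
#' @return An `ieq_scores` vector named by hour, method `"promethee_phi"`.
#' @examples
#' m <- cbind(x = c(1, 2)); rownames(m) <- c("9", "10")
#' promethee_scores(ieq_panel(m, "cost"), 1)  # phi = (1, -1)
#' @export
promethee_scores <- function(panel, weights, details = FALSE) {
  w <- check_panel_weights(panel, weights)
  S <- unclass_panel(panel)
  pc <- .promethee_phi_by_criterion(S)
  if (any(pc$const))
    warning(sprintf("constant criterion contributes no preference: %s",
                    paste(colnames(S)[pc$const], collapse = ", ")))
  phi <- as.numeric(crossprod(pc$Phi, w))
  internals <- NULL
  if (details) internals <- list(phi_by_criterion = pc$Phi)
  new_scores(phi, rownames(S), "promethee_phi", internals)
}

#' Export scores as a tidy data.frame
#' @param x An `ieq_scores` vector.
#' @param ... Unused.
#' @return data.frame with columns `hour`, `score`, `method`.
#' @export
as.data.frame.ieq_scores <- function(x, ...) {
  data.frame(hour = names(x), score = as.numeric(x),
             method = attr(x, "method"), row.names = NULL)
}
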