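# Indirect eliciting: ordinal comfort ratings -> strict preference relations
# -> category weights maximising a log-sigmoid pairwise likelihood over the
# scoring engine's global comfort values.

new_relations <- function(preferred, other, provenance) {
  d <- data.frame(preferred = as.character(preferred),
                  other = as.character(other),
                  stringsAsFactors = FALSE)
  structure(d, provenance = provenance,
            class = c("ieq_relations", "data.frame"))
}

#' Strict preference relations from ordinal ratings
#'
#' Each operator rates every time step on a 1-5 scale (5 = ideal). For every
#' ordered pair of time steps where one rating is strictly higher, a strict
#' preference "t over t'" is recorded; ties contribute nothing.
#'
#' @param ratings Named numeric vector (names = hour labels, values in 1..5)
#'   or a data.frame with columns `hour` and `rating`.
#' @return An `ieq_relations` data.frame with columns `preferred`, `other`
#'   and provenance `"all"`.
#' @examples
#' relations_from_ratings(c(`9` = 3, `10` = 2, `11` = 4))
#' @export
relations_from_ratings <- function(ratings) {
  if (is.data.frame(ratings)) {
    r <- ratings$rating
    names(r) <- as.character(ratings$hour)
    ratings <- r
  }
  if (is.null(names(ratings))) stop("ratings must be named by hour")
  if (anyNA(ratings)) stop("ratings contain missing values")
  if (!all(ratings %in% 1:5))
    stop("ratings must be integers in 1..5")
  hours <- names(ratings)
  idx <- which(outer(ratings, ratings, ">"), arr.ind = TRUE)
  new_relations(hours[idx[, 1L]], hours[idx[, 2L]], "all")
}

# reachability closure of a boolean adjacency matrix (Floyd-Warshall)
.closure <- function(A) {
  n <- nrow(A)
  R <- A
  for (k in seq_len(n)) R <- R | outer(R[, k], R[k, ], "&")
  R
}

#' Transitive reduction of a preference relation
#'
#' Removes every pair implied by transitivity of the remaining pairs; for
#' rating-derived relations (a weak order) the result is exactly the pairs
#' between adjacent distinct rating levels, and the reduction is unique.
#' A cyclic relation (impossible from ratings) is an error.
#'
#' @param relations An `ieq_relations` set as returned by
#'   [relations_from_ratings()].
#' @return The nonredundant `ieq_relations` subset (provenance
#'   `"nonredundant"`).
#' @examples
#' r <- relations_from_ratings(c(`9` = 3, `10` = 2, `11` = 4))
#' transitive_reduction(r)   # drops the implied pair 11 > 10
#' @export
transitive_reduction <- function(relations) {
  stopifnot(inherits(relations, "ieq_relations"))
  if (nrow(relations) == 0L) return(new_relations(character(), character(), "nonredundant"))
  nodes <- sort(unique(c(relations$preferred, relations$other)))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(relations$preferred, nodes), match(relations$other, nodes))] <- TRUE
  R <- .closure(A)
  if (any(diag(R))) stop("preference relation is cyclic")
  # in a DAG an edge u->v is redundant iff some successor of u reaches v
  keep <- logical(nrow(relations))
  for (i in seq_len(nrow(relations))) {
    u <- match(relations$preferred[i], nodes)
    v <- match(relations$other[i], nodes)
    via <- A[u, ] & R[, v]
    via[v] <- FALSE
    keep[i] <- !any(via)
  }
  new_relations(relations$preferred[keep], relations$other[keep], "nonredundant")
}

#' Log-sigmoid pairwise preference likelihood
#'
#' The elicitation objective: for every strict preference "t over t'", the
#' log of the logistic probability of the score margin,
#' sum over pairs of ln(1 / (1 + exp(-(score_t - score_t')))). Always
#' <= 0; an empty relation set scores 0.
#'
#' @param scores An `ieq_scores` vector (or any numeric vector named by hour).
#' @param relations An `ieq_relations` set whose hours all appear in `scores`.
#' @return The scalar objective value.
#' @export
pairwise_log_likelihood <- function(scores, relations) {
  if (nrow(relations) == 0L) return(0)
  miss <- setdiff(unique(c(relations$preferred, relations$other)), names(scores))
  if (length(miss))
    stop(sprintf("scores missing for hour(s): %s", paste(miss, collapse = ", ")))
  margins <- as.numeric(scores[relations$preferred]) -
    as.numeric(scores[relations$other])
  sum(stats::plogis(margins, log.p = TRUE))
}

.score_engine <- function(method) {
  switch(method, topsis = topsis_scores, promethee = promethee_scores,
         stop("method must be 'topsis' or 'promethee'"))
}

# log-parametrization of the nonnegative cone; capped to avoid overflow
# (beyond the cap the likelihood is flat anyway)
.z_to_w <- function(z) exp(pmin(z, 40))

# Fast likelihood evaluator for one (panel, relations, method) problem:
# panel-level quantities are precomputed so the optimizer pays only a few
# small matrix-vector products per evaluation. Must agree exactly with
# pairwise_log_likelihood() of the public scoring engines.
.elicit_objective <- function(panel, relations, method) {
  S <- unclass_panel(panel)
  hours <- rownames(S)
  ip <- match(relations$preferred, hours)
  io <- match(relations$other, hours)
  if (anyNA(ip) || anyNA(io))
    stop("relations refer to hours missing from the panel")
  if (method == "promethee") {
    Phi <- .promethee_phi_by_criterion(S)$Phi          # K x T, phi = Phi' w
    M <- Phi[, ip, drop = FALSE] - Phi[, io, drop = FALSE]
    fn <- function(w) sum(stats::plogis(as.numeric(crossprod(M, w)), log.p = TRUE))
    attr(fn, "margin_matrix") <- M
    fn
  } else {
    norms <- sqrt(colSums(S^2))
    norms[norms == 0] <- 1
    n <- sweep(S, 2L, norms, "/")
    Dp <- sweep(n, 2L, apply(n, 2L, min))^2            # (n - a+)^2, T x K
    Dm <- sweep(n, 2L, apply(n, 2L, max))^2
    function(w) {
      w2 <- w * w
      dp <- sqrt(as.numeric(Dp %*% w2))
      dm <- sqrt(as.numeric(Dm %*% w2))
      den <- dp + dm
      r <- ifelse(den == 0, 0.5, dm / den)
      sum(stats::plogis(r[ip] - r[io], log.p = TRUE))
    }
  }
}

#' Elicit category weights from preference relations
#'
#' Maximises [pairwise_log_likelihood()] of the chosen engine's scores over
#' the nonnegatively weighted cone `w >= 0` (weights are parameterised as
#' `w = exp(z)` and optimised by BFGS), after which the maximiser is
#' rescaled onto the simplex. The programme deliberately leaves the overall
#' scale of `w` free: TOPSIS closeness is scale-invariant in the weights, so
#' nothing changes there, while PROMETHEE net flows grow linearly with the
#' scale, so whenever some weight direction satisfies every relation the
#' optimiser can drive all margins up and the returned weights reproduce the
#' preferences exactly. The reported `objective` is the best likelihood
#' found over the cone (at the optimising scale); the reported `weights` are
#' its direction, normalised to sum one.
#'
#' The TOPSIS objective is not concave, so the search restarts from the
#' equal-weight point plus `restarts - 1` random flat-Dirichlet points drawn
#' from `seed`; PROMETHEE margins are linear in `w`, making the likelihood
#' concave in `w`, and a single start suffices (the same restart scheme is
#' applied for uniformity). Simplex corners, the equal-weight point and a
#' geometric scale sweep along the best direction are also evaluated as
#' candidates, so the returned objective is never below the equal-weight
#' objective and exact corner optima are representable.
#'
#' @param panel Cost-oriented [ieq_panel()].
#' @param relations Nonredundant `ieq_relations` (an "all" set works too and
#'   yields the same optimum, just a different objective value).
#' @param method `"topsis"` or `"promethee"`.
#' @param restarts Number of optimisation starts (>= 1), default 20.
#' @param seed Integer seed controlling the random restarts (recorded in the
#'   result).
#' @param tolerance Relative convergence tolerance on the objective.
#' @return An `ieq_elicitation` list: `method`, `weights` (named, summing to
#'   one), `objective`, `restarts`, `best_start`, `converged`, `seed`,
#'   `empty_relations`.
#' @export
elicit_weights <- function(panel, relations, method = c("topsis", "promethee"),
                           restarts = 20L, seed = 1L, tolerance = 1e-8) {
  method <- match.arg(method)
  if (!is_cost_panel(panel)) stop("elicitation requires a cost-oriented panel")
  K <- ncol(panel)
  crit <- colnames(panel)
  equal <- rep(1 / K, K)

  if (nrow(relations) == 0L) {
    warning("empty relation set: returning equal weights")
    return(structure(list(method = method,
                          weights = stats::setNames(equal, crit),
                          objective = 0, restarts = 0L, best_start = NA_integer_,
                          converged = TRUE, seed = seed,
                          empty_relations = TRUE),
                     class = "ieq_elicitation"))
  }

  obj_w <- .elicit_objective(panel, relations, method)
  neg_obj_z <- function(z) -obj_w(.z_to_w(z))

  starts <- vector("list", max(1L, restarts))
  starts[[1L]] <- rep(0, K)
  if (restarts > 1L) {
    rand <- with_local_seed(seed, {
      lapply(seq_len(restarts - 1L), function(i)
        log(pmax(rdirichlet1(K), 1e-6)))
    })
    starts[seq_len(restarts - 1L) + 1L] <- rand
  }

  best <- list(value = -Inf, w = equal, start = NA_integer_, converged = FALSE)
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[i]], neg_obj_z, method = "BFGS",
                   control = list(maxit = 500L, reltol = tolerance)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    val <- -fit$value
    if (val > best$value) {
      best <- list(value = val, w = .z_to_w(fit$par), start = i,
                   converged = fit$convergence == 0L)
    }
  }
  # candidate polish: corners, the equal-weight point, and a scale sweep
  # along the best direction (the cone's scale coordinate)
  corners <- diag(K)
  cand <- c(list(equal), lapply(seq_len(K), function(k) corners[k, ]),
            lapply(2^(1:16), function(s) s * best$w))
  for (j in seq_along(cand)) {
    val <- obj_w(cand[[j]])
    if (val > best$value)
      best <- list(value = val, w = cand[[j]], start = best$start,
                   converged = TRUE)
  }

  # When every relation is verified the PROMETHEE likelihood saturates along
  # any separating direction (free scale), leaving the direction
  # underdetermined; ties are broken by the largest worst-case margin
  # (hard-margin rule) over the candidate directions.
  if (method == "promethee") {
    M <- attr(obj_w, "margin_matrix")
    margins_of <- function(w) as.numeric(crossprod(M, w / sum(w)))
    if (all(margins_of(best$w) > 0)) {
      dirs <- c(list(best$w, equal), lapply(seq_len(K), function(k) corners[k, ]))
      minm <- vapply(dirs, function(w) min(margins_of(w)), numeric(1))
      best$w <- dirs[[which.max(minm)]]
    }
  }

  structure(list(method = method,
                 weights = stats::setNames(best$w / sum(best$w), crit),
                 objective = best$value,
                 restarts = as.integer(max(1L, restarts)),
                 best_start = best$start,
                 converged = best$converged,
                 seed = seed,
                 empty_relations = FALSE),
            class = "ieq_elicitation")
}

#' @export
print.ieq_elicitation <- function(x, ...) {
  cat(sprintf("ieq_elicitation (%s): objective %.6f (seed %s, %d starts)\n",
              x$method, x$objective, x$seed, x$restarts))
  print(round(x$weights, 4))
  invisible(x)
}

#' Export a relation set as a tidy data.frame
#'
#' @param relations An `ieq_relations` set with provenance `"all"`; redundant
#'   pairs are flagged against its transitive reduction.
#' @return data.frame `preferred_hour`, `other_hour`, `redundant_flag`.
#' @export
relations_table <- function(relations) {
  red <- transitive_reduction(relations)
  key <- paste(relations$preferred, relations$other)
  keep <- paste(red$preferred, red$other)
  data.frame(preferred_hour = relations$preferred,
             other_hour = relations$other,
             redundant_flag = !(key %in% keep),
             row.names = NULL)
}
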