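# Independent straight-line oracles used to cross-check the package
# implementations. Deliberately written as plain loops over the published
# equation sets, sharing no code with the R/ implementations.

# TOPSIS closeness for cost criteria: vector normalisation, min as ideal,
# weighted Euclidean distances, closeness ratio.
oracle_topsis <- function(S, w) {
  K <- ncol(S); T_ <- nrow(S)
  n <- matrix(0, T_, K)
  for (k in 1:K) {
    nk <- sqrt(sum(S[, k]^2))
    for (t in 1:T_) n[t, k] <- if (nk > 0) S[t, k] / nk else 0
  }
  r <- numeric(T_)
  for (t in 1:T_) {
    dp <- 0; dm <- 0
    for (k in 1:K) {
      ap <- min(n[, k]); am <- max(n[, k])
      dp <- dp + (w[k] * n[t, k] - w[k] * ap)^2
      dm <- dm + (w[k] * n[t, k] - w[k] * am)^2
    }
    dp <- sqrt(dp); dm <- sqrt(dm)
    r[t] <- if (dp + dm > 0) dm / (dp + dm) else 0.5
  }
  r
}

# PROMETHEE net flows for cost criteria: pairwise differences, linear
# preference saturating at the largest positive difference per criterion,
# weighted aggregation, leaving minus entering flows (unnormalised sums).
oracle_promethee <- function(S, w) {
  K <- ncol(S); T_ <- nrow(S)
  s <- matrix(0, T_, T_)
  for (k in 1:K) {
    d <- matrix(0, T_, T_)
    for (t in 1:T_) for (tp in 1:T_) d[t, tp] <- S[tp, k] - S[t, k]
    D <- max(c(d[d > 0], 0))
    for (t in 1:T_) for (tp in 1:T_) {
      p <- if (d[t, tp] <= 0 || D == 0) 0 else min(d[t, tp] / D, 1)
      if (t != tp) s[t, tp] <- s[t, tp] + w[k] * p
    }
  }
  phi <- numeric(T_)
  for (t in 1:T_) phi[t] <- sum(s[t, ]) - sum(s[, t])
  phi
}

oracle_loglik <- function(scores, pref_idx, other_idx) {
  total <- 0
  for (i in seq_along(pref_idx)) {
    m <- scores[pref_idx[i]] - scores[other_idx[i]]
    total <- total + log(1 / (1 + exp(-m)))
  }
  total
}

# all weight vectors on the K-simplex with entries that are multiples of step
grid_simplex <- function(K, step = 0.02) {
  n <- round(1 / step)
  if (K == 2) {
    a <- 0:n
    return(cbind(a, n - a) / n)
  }
  if (K == 3) {
    out <- list()
    for (a in 0:n) for (b in 0:(n - a)) {
      out[[length(out) + 1L]] <- c(a, b, n - a - b)
    }
    return(do.call(rbind, out) / n)
  }
  stop("grid_simplex oracle supports K <= 3")
}

# best simplex-grid objective for a (panel matrix, relations) problem
grid_best_objective <- function(S, pref_idx, other_idx, method, step = 0.02) {
  W <- grid_simplex(ncol(S), step)
  best <- -Inf
  for (i in seq_len(nrow(W))) {
    sc <- if (method == "topsis") oracle_topsis(S, W[i, ])
          else oracle_promethee(S, W[i, ])
    val <- oracle_loglik(sc, pref_idx, other_idx)
    if (val > best) best <- val
  }
  best
}

# Independent PMV: solves the clothing-surface heat balance with uniroot
# instead of the fixed-point iteration, then evaluates the thermal load.
oracle_pmv <- function(ta, tr, vel, rh, met, clo, wme = 0) {
  pa <- rh * 10 * exp(16.6536 - 4030.183 / (ta + 235))
  icl <- 0.155 * clo
  m <- met * 58.15; w <- wme * 58.15; mw <- m - w
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hc_of <- function(tcl) max(12.1 * sqrt(vel), 2.38 * abs(tcl - ta)^0.25)
  balance <- function(tcl) {
    hc <- hc_of(tcl)
    35.7 - 0.028 * mw -
      icl * (3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4) +
               fcl * hc * (tcl - ta)) - tcl
  }
  tcl <- stats::uniroot(balance, c(ta - 20, 60), tol = 1e-10)$root
  hc <- hc_of(tcl)
  hl1 <- 3.05e-3 * (5733 - 6.99 * mw - pa)
  hl2 <- if (mw > 58.15) 0.42 * (mw - 58.15) else 0
  hl3 <- 1.7e-5 * m * (5867 - pa)
  hl4 <- 0.0014 * m * (34 - ta)
  hl5 <- 3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4)
  hl6 <- fcl * hc * (tcl - ta)
  (0.303 * exp(-0.036 * m) + 0.028) * (mw - hl1 - hl2 - hl3 - hl4 - hl5 - hl6)
}

# exact minimum SSE of a k-segment piecewise-linear fit (segments of >= 2
# points) by dynamic programming over all breakpoint placements
oracle_best_sse <- function(x, y, k) {
  n <- length(x)
  seg_sse <- function(i, j) {
    xs <- x[i:j]; ys <- y[i:j]
    f <- stats::lm.fit(cbind(1, xs), ys)
    sum(f$residuals^2)
  }
  cost <- matrix(Inf, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) cost[i, j] <- seg_sse(i, j)
  dp <- matrix(Inf, k, n)
  for (j in 2:n) dp[1, j] <- cost[1, j]
  if (k > 1) for (s in 2:k) for (j in (2 * s):n) {
    for (b in (2 * s - 2):(j - 2)) {
      v <- dp[s - 1, b] + cost[b + 1, j]
      if (v < dp[s, j]) dp[s, j] <- v
    }
  }
  dp[k, n]
}

# boolean transitive closure of an edge list over given nodes
rel_closure <- function(pref, other, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(pref, nodes), match(other, nodes))] <- TRUE
  for (k in 1:n) A <- A | outer(A[, k], A[k, ], "&")
  A
}

# small helper: a labelled cost panel from a plain matrix
make_cost_panel <- function(m, hours = NULL) {
  if (is.null(hours)) hours <- as.character(seq_len(nrow(m)) + 8L)
  rownames(m) <- hours
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  ieq_panel(m, "cost")
}

random_cost_panel <- function(T_, K, seed) {
  set.seed(seed)
  make_cost_panel(matrix(stats::runif(T_ * K, 0.1, 10), T_, K))
}
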