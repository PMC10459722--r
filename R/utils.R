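# internal helpers shared across modules

# Run code with a temporary RNG state so callers' .Random.seed is untouched.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Parse "p/q" fraction strings (also plain numbers) to numeric.
parse_fraction <- function(x) {
  x <- trimws(as.character(x))
  out <- vapply(x, function(s) {
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) return(NA_real_)
      num <- suppressWarnings(as.numeric(parts))
      if (anyNA(num) || num[2L] == 0) return(NA_real_)
      num[1L] / num[2L]
    } else {
      suppressWarnings(as.numeric(s))
    }
  }, numeric(1))
  unname(out)
}

# Draw one flat-Dirichlet vector of length k.
rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
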