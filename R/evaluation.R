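# Preference-reconstruction error rates and cross-method weight analysis.

#' Error rate of a score vector against preference relations
#'
#' The fraction of strict preference relations not verified by the scores:
#' a relation "t over t'" counts as violated when score_t <= score_t'
#' (a tie fails to verify a strict preference). An empty relation set gives
#' 0 with a warning.
#'
#' @param scores An `ieq_scores` vector (or numeric vector named by hour).
#' @param relations An `ieq_relations` set (typically nonredundant).
#' @return A fraction in \[0, 1\].
#' @export
error_rate <- function(scores, relations) {
  if (nrow(relations) == 0L) {
    warning("empty relation set: error rate 0 by convention")
    return(0)
  }
  miss <- setdiff(unique(c(relations$preferred, relations$other)), names(scores))
  if (length(miss))
    stop(sprintf("scores missing for hour(s): %s", paste(miss, collapse = ", ")))
  mean(as.numeric(scores[relations$preferred]) <=
         as.numeric(scores[relations$other]))
}

#' Benchmark direct vs indirect eliciting across operators
#'
#' Runs the four-method design on a cohort: AHP weights scored through
#' TOPSIS, AHP weights scored through PROMETHEE, indirectly elicited
#' (optimised) TOPSIS, and indirectly elicited PROMETHEE; each method's
#' scores are checked against the operator's nonredundant preference
#' relations via [error_rate()].
#'
#' @param panels Named list of cost-oriented [ieq_panel()], one per operator.
#' @param ratings Named list (same names) of rating vectors (see
#'   [relations_from_ratings()]).
#' @param matrices Named list (same names) of [comparison_matrix()] objects.
#' @param restarts,seed,tolerance Passed to [elicit_weights()].
#' @return An `ieq_evaluation` list: `report` (tidy data.frame
#'   `operator,method,error_rate,n_relations,n_relations_all`), `weights`
#'   (long data.frame `operator,method,category,weight`) and `elicitations`.
#' @export
compare_methods <- function(panels, ratings, matrices,
                            restarts = 20L, seed = 1L, tolerance = 1e-8) {
  ops <- names(panels)
  if (is.null(ops)) stop("panels must be a named list keyed by operator")
  for (nm in c("ratings", "matrices")) {
    x <- get(nm)
    miss <- setdiff(ops, names(x))
    if (length(miss))
      stop(sprintf("operator(s) missing from %s: %s", nm,
                   paste(miss, collapse = ", ")))
  }
  methods <- c("ahp_topsis", "ahp_promethee", "topsis", "promethee")
  report <- list(); wtab <- list(); elics <- list()
  for (op in ops) {
    panel <- panels[[op]]
    rel_all <- relations_from_ratings(ratings[[op]])
    rel <- transitive_reduction(rel_all)
    ahp <- ahp_weights(matrices[[op]])
    w_ahp <- ahp$weights[colnames(panel)]
    el_t <- elicit_weights(panel, rel, "topsis", restarts, seed, tolerance)
    el_p <- elicit_weights(panel, rel, "promethee", restarts, seed, tolerance)
    elics[[op]] <- list(topsis = el_t, promethee = el_p)
    score_sets <- list(
      ahp_topsis = topsis_scores(panel, w_ahp),
      ahp_promethee = promethee_scores(panel, w_ahp),
      topsis = topsis_scores(panel, el_t$weights),
      promethee = promethee_scores(panel, el_p$weights))
    weight_sets <- list(ahp_topsis = w_ahp, ahp_promethee = w_ahp,
                        topsis = el_t$weights, promethee = el_p$weights)
    ers <- vapply(score_sets, function(s)
      suppressWarnings(error_rate(s, rel)), numeric(1))
    report[[op]] <- data.frame(
      operator = op, method = methods, error_rate = unname(ers[methods]),
      n_relations = nrow(rel), n_relations_all = nrow(rel_all),
      row.names = NULL)
    wtab[[op]] <- do.call(rbind, lapply(methods, function(m)
      data.frame(operator = op, method = m, category = colnames(panel),
                 weight = unname(weight_sets[[m]][colnames(panel)]),
                 row.names = NULL)))
  }
  structure(list(report = do.call(rbind, c(report, make.row.names = FALSE)),
                 weights = do.call(rbind, c(wtab, make.row.names = FALSE)),
                 elicitations = elics),
            class = "ieq_evaluation")
}

#' @export
print.ieq_evaluation <- function(x, ...) {
  cat("ieq_evaluation: error rates by operator and method\n")
  wide <- stats::reshape(
    x$report[c("operator", "method", "error_rate")],
    idvar = "operator", timevar = "method", direction = "wide")
  names(wide) <- sub("^error_rate\\.", "", names(wide))
  wide[-1L] <- lapply(wide[-1L], function(v) sprintf("%.2f", v))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Correlations between method weight columns
#'
#' Compares weight sets across methods: each method's weights over all
#' operators and retained categories form one column, and the columns are
#' correlated pairwise. One category is dropped first because simplex
#' weights sum to one, which induces a spurious negative correlation
#' (the noise-level weight is the conventional choice to discard).
#'
#' @param weight_table Long data.frame with columns `operator`, `method`,
#'   `category`, `weight` (as produced by [compare_methods()]).
#' @param drop_category Category label to discard (default `"sound"`).
#' @param method Correlation coefficient, `"pearson"` (default) or
#'   `"spearman"`.
#' @return Correlation matrix across methods; entries involving a
#'   zero-variance column are `NA`.
#' @export
weight_correlations <- function(weight_table, drop_category = "sound",
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d <- weight_table[!(weight_table$category %in% drop_category), ]
  if (length(unique(d$operator)) < 3L)
    stop("weight correlations need at least 3 operators")
  wide <- stats::reshape(d, idvar = c("operator", "category"),
                         timevar = "method", direction = "wide")
  cols <- grep("^weight\\.", names(wide), value = TRUE)
  m <- as.matrix(wide[cols])
  colnames(m) <- sub("^weight\\.", "", cols)
  const <- apply(m, 2L, function(v) stats::sd(v) == 0)
  cm <- suppressWarnings(stats::cor(m, method = method))
  cm[const, ] <- NA; cm[, const] <- NA; diag(cm) <- 1
  cm
}
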