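test_that("ratings induce exactly the strict pairwise preferences", {
  rel <- relations_from_ratings(c(`9` = 3, `10` = 2, `11` = 4))
  got <- paste(rel$preferred, rel$other)
  expect_setequal(got, c("9 10", "11 10", "11 9"))
  expect_identical(attr(rel, "provenance"), "all")

  expect_identical(nrow(relations_from_ratings(c(a = 3, b = 3, c = 3))), 0L)
  one <- relations_from_ratings(c(a = 5, b = 1))
  expect_identical(paste(one$preferred, one$other), "a b")
})

test_that("transitive reduction drops exactly the implied pairs", {
  rel <- relations_from_ratings(c(`9` = 3, `10` = 2, `11` = 4))
  red <- transitive_reduction(rel)
  expect_setequal(paste(red$preferred, red$other), c("11 9", "9 10"))

  chain <- relations_from_ratings(setNames(1:5, letters[1:5]))
  expect_identical(nrow(transitive_reduction(chain)), 4L)

  cyc <- ieqelicit:::new_relations(c("a", "b"), c("b", "a"), "all")
  expect_error(transitive_reduction(cyc), "cyclic")
})

test_that("reduction preserves the closure and is minimal (brute force)", {
  for (seed in 1:15) {
    set.seed(seed)
    T_ <- sample(3:7, 1)
    ratings <- setNames(sample(1:5, T_, replace = TRUE), paste0("h", 1:T_))
    rel <- relations_from_ratings(ratings)
    if (nrow(rel) == 0L) next
    red <- transitive_reduction(rel)
    nodes <- sort(unique(c(rel$preferred, rel$other)))
    expect_identical(rel_closure(red$preferred, red$other, nodes),
                     rel_closure(rel$preferred, rel$other, nodes))
    # minimality: removing any single retained pair changes the closure
    for (i in seq_len(nrow(red))) {
      sub <- red[-i, ]
      expect_false(identical(
        rel_closure(sub$preferred, sub$other, nodes),
        rel_closure(red$preferred, red$other, nodes)))
    }
  }
})

test_that("reduction never changes which score vectors have zero error", {
  for (seed in 1:10) {
    set.seed(seed)
    T_ <- 6
    ratings <- setNames(sample(1:5, T_, replace = TRUE), paste0("h", 1:T_))
    rel <- relations_from_ratings(ratings)
    if (nrow(rel) == 0L) next
    red <- transitive_reduction(rel)
    for (j in 1:10) {
      sc <- setNames(rnorm(T_), paste0("h", 1:T_))
      expect_identical(
        suppressWarnings(error_rate(sc, rel)) == 0,
        suppressWarnings(error_rate(sc, red)) == 0)
    }
  }
})

test_that("pairwise log likelihood matches the scalar formula", {
  rel <- ieqelicit:::new_relations("a", "b", "nonredundant")
  expect_equal(pairwise_log_likelihood(c(a = 1, b = 1), rel), log(0.5))
  expect_gt(pairwise_log_likelihood(c(a = 100, b = 0), rel), -1e-10)

  rel3 <- ieqelicit:::new_relations(c("a", "b", "c"), c("x", "y", "z"), "all")
  sc <- c(a = 0.5, x = 0, b = 0, y = 0.2, c = 0.1, z = 0)
  expect_equal(pairwise_log_likelihood(sc, rel3),
               sum(log(1 / (1 + exp(-c(0.5, -0.2, 0.1))))))
  empty <- ieqelicit:::new_relations(character(), character(), "all")
  expect_identical(pairwise_log_likelihood(sc, empty), 0)
})

test_that("a single decisive criterion gets all the weight", {
  p <- make_cost_panel(cbind(a = c(1, 2), b = c(2, 1)), c("9", "10"))
  rel <- transitive_reduction(relations_from_ratings(c(`9` = 5, `10` = 1)))
  for (m in c("topsis", "promethee")) {
    fit <- elicit_weights(p, rel, m, restarts = 5, seed = 1)
    expect_equal(unname(fit$weights), c(1, 0), tolerance = 1e-3)
    expect_lte(fit$objective, 0)
  }
})

test_that("elicited objective matches the simplex grid-search oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    p <- random_cost_panel(6, 3, seed + 300)
    ratings <- setNames(sample(1:5, 6, replace = TRUE), rownames(p))
    rel <- transitive_reduction(relations_from_ratings(ratings))
    if (nrow(rel) == 0L) next
    S <- unclass(p); attr(S, "orientation") <- NULL
    ip <- match(rel$preferred, rownames(p)); io <- match(rel$other, rownames(p))
    for (m in c("topsis", "promethee")) {
      fit <- elicit_weights(p, rel, m, restarts = 12, seed = seed)
      oracle <- grid_best_objective(S, ip, io, m, step = 0.02)
      expect_gte(fit$objective, oracle - 1e-3)
    }
  }
})

test_that("elicitation beats equal weights and is deterministic in the seed", {
  p <- to_cost_panel(ieq_example_panel(2))
  rel <- transitive_reduction(
    relations_from_ratings(setNames(c(2, 1, 3, 3, 4, 4, 5, 5), rownames(p))))
  for (m in c("topsis", "promethee")) {
    fit <- elicit_weights(p, rel, m, restarts = 8, seed = 42)
    eq_scores <- ieqelicit:::.score_engine(m)(p, rep(0.25, 4))
    expect_gte(fit$objective, pairwise_log_likelihood(eq_scores, rel))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(fit$weights >= 0))
    fit2 <- elicit_weights(p, rel, m, restarts = 8, seed = 42)
    expect_identical(fit$weights, fit2$weights)
    expect_identical(fit$objective, fit2$objective)
  }
})

test_that("the TOPSIS likelihood is constant along weight rays", {
  p <- random_cost_panel(6, 4, 9)
  ratings <- setNames(c(1, 2, 3, 4, 5, 5), rownames(p))
  rel <- transitive_reduction(relations_from_ratings(ratings))
  obj <- ieqelicit:::.elicit_objective(p, rel, "topsis")
  for (seed in 1:8) {
    w <- ieqelicit:::with_local_seed(seed, ieqelicit:::rdirichlet1(4))
    expect_equal(obj(3 * w), obj(w), tolerance = 1e-12)
  }
})

test_that("empty relation sets produce equal weights with a warning", {
  p <- random_cost_panel(5, 3, 1)
  empty <- transitive_reduction(
    relations_from_ratings(setNames(rep(3, 5), rownames(p))))
  expect_warning(fit <- elicit_weights(p, empty, "promethee"), "empty")
  expect_equal(unname(fit$weights), rep(1 / 3, 3))
  expect_true(fit$empty_relations)
})

test_that("relations export flags redundant pairs", {
  rel <- relations_from_ratings(c(`9` = 3, `10` = 2, `11` = 4))
  tab <- relations_table(rel)
  expect_identical(sum(tab$redundant_flag), 1L)
  expect_identical(
    tab[tab$redundant_flag, c("preferred_hour", "other_hour")],
    data.frame(preferred_hour = "11", other_hour = "10",
               row.names = which(tab$redundant_flag)))
})
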