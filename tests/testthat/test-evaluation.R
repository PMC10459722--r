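test_that("error rate counts unverified strict preferences", {
  rel <- ieqelicit:::new_relations(paste0("h", 1:9), paste0("g", 1:9), "all")
  sc <- c(setNames(rep(1, 9), paste0("h", 1:9)),
          setNames(rep(0, 9), paste0("g", 1:9)))
  expect_equal(error_rate(sc, rel), 0)
  sc2 <- c(setNames(rep(0, 9), paste0("h", 1:9)),
           setNames(rep(1, 9), paste0("g", 1:9)))
  expect_equal(error_rate(sc2, rel), 1)

  sc3 <- sc
  sc3[c("h1", "h2")] <- -1           # two violated out of nine
  expect_equal(error_rate(sc3, rel), 2 / 9)

  sc4 <- sc; sc4["h1"] <- 0          # a tie is not verified
  expect_equal(error_rate(sc4, rel), 1 / 9)

  empty <- ieqelicit:::new_relations(character(), character(), "all")
  expect_warning(er <- error_rate(sc, empty), "empty")
  expect_equal(er, 0)
})

test_that("error rate is invariant under increasing score transforms", {
  set.seed(5)
  for (i in 1:10) {
    sc <- setNames(rnorm(8), paste0("h", 1:8))
    ratings <- setNames(sample(1:5, 8, replace = TRUE), names(sc))
    rel <- transitive_reduction(relations_from_ratings(ratings))
    if (nrow(rel) == 0L) next
    expect_identical(error_rate(sc, rel), error_rate(exp(3 * sc) + 2, rel))
  }
})

test_that("removing a satisfied relation never increases violations", {
  set.seed(8)
  sc <- setNames(rnorm(7), paste0("h", 1:7))
  rel <- transitive_reduction(relations_from_ratings(
    setNames(sample(1:5, 7, replace = TRUE), names(sc))))
  viol <- function(r) round(error_rate(sc, r) * nrow(r))
  satisfied <- which(as.numeric(sc[rel$preferred]) > as.numeric(sc[rel$other]))
  for (i in satisfied) expect_lte(viol(rel[-i, ]), viol(rel))
})

test_that("the four-method benchmark favours indirect eliciting by design", {
  # cohort whose ratings derive from latent weights while the AHP matrices
  # encode different (consistent) judgments
  ops <- paste0("op", 1:4)
  panels <- setNames(lapply(1:4, function(i)
    ieqelicit:::gen_cost_panel(8, 4, seed = 400 + i)), ops)
  set.seed(99)
  ratings <- list(); matrices <- list()
  for (i in 1:4) {
    w <- ieqelicit:::rdirichlet1(4)
    occ <- synthetic_occupant(ops[i], w, engine = "promethee")
    ratings[[ops[i]]] <- gen_ratings(panels[[i]], occ, seed = 500 + i)
    v <- ieqelicit:::rdirichlet1(4); v <- pmax(v, max(v) / 9)
    matrices[[ops[i]]] <- comparison_matrix(
      outer(v, v, "/"), labels = colnames(panels[[i]]))
  }
  ev <- suppressWarnings(
    compare_methods(panels, ratings, matrices, restarts = 8, seed = 3))
  rep <- ev$report
  expect_identical(nrow(rep), 16L)   # 4 operators x 4 methods
  mean_by <- tapply(rep$error_rate, rep$method, mean)
  expect_lte(mean_by[["topsis"]], mean_by[["ahp_topsis"]])
  expect_lte(mean_by[["promethee"]], mean_by[["ahp_promethee"]])
  expect_true(all(rep$error_rate >= 0 & rep$error_rate <= 1))
  expect_identical(unique(rep$n_relations_all >= rep$n_relations), TRUE)

  # identical inputs give identical report rows
  ev2 <- suppressWarnings(compare_methods(
    list(a = panels[[1]], b = panels[[1]]),
    list(a = ratings[[1]], b = ratings[[1]]),
    list(a = matrices[[1]], b = matrices[[1]]),
    restarts = 8, seed = 3))
  r2 <- ev2$report
  expect_equal(r2$error_rate[r2$operator == "a"],
               r2$error_rate[r2$operator == "b"])

  expect_error(compare_methods(panels, ratings[1:3], matrices),
               "missing from ratings")
})

test_that("all-equal ratings give zero error with empty-relation warnings", {
  ops <- "solo"
  panel <- ieqelicit:::gen_cost_panel(8, 4, seed = 7)
  ratings <- list(solo = setNames(rep(3, 8), rownames(panel)))
  v <- c(4, 2, 1, 1)
  mats <- list(solo = comparison_matrix(outer(v, v, "/"),
                                        labels = colnames(panel)))
  ws <- capture_warnings(
    ev <- compare_methods(setNames(list(panel), ops), ratings, mats,
                          restarts = 3, seed = 1))
  expect_true(any(grepl("empty", ws)))
  expect_equal(ev$report$error_rate, rep(0, 4))
})

test_that("weight correlations behave on constructed columns", {
  tab <- expand.grid(operator = paste0("op", 1:4),
                     category = c("pm25", "pmv", "illuminance", "sound"),
                     stringsAsFactors = FALSE)
  set.seed(11)
  base <- runif(nrow(tab))
  t1 <- rbind(cbind(tab, method = "m1", weight = base),
              cbind(tab, method = "m2", weight = base))
  expect_equal(weight_correlations(t1)["m1", "m2"], 1)

  # a column and its complement are strongly negatively correlated
  two_cat <- expand.grid(operator = paste0("op", 1:4),
                         category = c("a", "b"), stringsAsFactors = FALSE)
  w <- ifelse(two_cat$category == "a", base[1:8], 1 - base[1:8])
  t2 <- rbind(cbind(two_cat, method = "m1", weight = w),
              cbind(two_cat, method = "m2", weight = 1 - w))
  expect_lt(weight_correlations(t2, drop_category = character(0))["m1", "m2"],
            -0.99)

  # zero-variance column reported as missing
  t3 <- rbind(cbind(tab, method = "m1", weight = base),
              cbind(tab, method = "m2", weight = 0.25))
  expect_true(is.na(weight_correlations(t3)["m1", "m2"]))

  expect_error(weight_correlations(t1[t1$operator %in% c("op1", "op2"), ]),
               "at least 3 operators")
})

test_that("shared latent weights align the two optimised engines", {
  # six simulated occupants share the latent-weight mechanism; AHP matrices
  # are unrelated, so optimised TOPSIS and PROMETHEE weights should agree
  # with each other more than either agrees with AHP
  ops <- paste0("op", 1:6)
  panels <- list(); ratings <- list(); matrices <- list()
  set.seed(21)
  for (i in seq_along(ops)) {
    panels[[ops[i]]] <- ieqelicit:::gen_cost_panel(8, 4, seed = 600 + i)
    w <- ieqelicit:::rdirichlet1(4)
    occ <- synthetic_occupant(ops[i], w, engine = "promethee")
    ratings[[ops[i]]] <- gen_ratings(panels[[i]], occ, seed = 700 + i)
    v <- ieqelicit:::rdirichlet1(4); v <- pmax(v, max(v) / 9)
    matrices[[ops[i]]] <- comparison_matrix(outer(v, v, "/"),
                                            labels = colnames(panels[[i]]))
  }
  ev <- suppressWarnings(
    compare_methods(panels, ratings, matrices, restarts = 8, seed = 5))
  cm <- weight_correlations(ev$weights, drop_category = "c4")
  expect_gt(cm["topsis", "promethee"], cm["ahp_topsis", "topsis"])
  expect_gt(cm["topsis", "promethee"], cm["ahp_promethee", "promethee"])
})
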