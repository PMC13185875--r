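test_that("weighted Euclidean distance behaves as a metric", {
  a <- encode(parse_name("1-NO2"))
  expect_equal(weighted_distance(a, a), 0)
  expect_equal(weighted_distance(a, encode(helicene())), 0.78)
  withr::with_seed(51, {
    for (i in 1:50) {
      u <- rnorm(16); v <- rnorm(16); w <- runif(16, 0.1, 2)
      expect_equal(weighted_distance(u, v, w), weighted_distance(v, u, w))
      z <- rnorm(16)
      expect_lte(weighted_distance(u, z, w),
                 weighted_distance(u, v, w) + weighted_distance(v, z, w) + 1e-12)
    }
  })
  expect_error(weighted_distance(1:3, 1:4), class = "dimension_error")
  expect_error(weighted_distance(1:3, 4:6, rep(0, 3)), class = "value_error")
})

test_that("neighbour retrieval matches a brute-force all-pairs sort", {
  ds <- fixture_dataset(150, seed = 5)
  feats <- dataset_features(ds)
  withr::with_seed(52, {
    for (i in 1:10) {
      q <- random_molecule()
      keep <- ds$name != format_name(q)
      d <- sqrt(colSums((t(feats[keep, ]) - encode(q))^2))
      expected <- ds$name[keep][order(d, ds$name[keep])][1:30]
      nb <- nearest_neighbours(q, ds, k = 30)
      expect_identical(nb$name, expected)
      expect_false(is.unsorted(attr(nb, "distances")))
    }
  })
})

test_that("a query never appears in its own neighbourhood", {
  ds <- fixture_dataset(150, seed = 5)
  q <- dataset_molecule(ds, 10)
  nb <- nearest_neighbours(q, ds, k = nrow(ds) - 1L)
  expect_false(format_name(q) %in% nb$name)
  expect_equal(nrow(nb), nrow(ds) - 1L)
  expect_error(nearest_neighbours(q, ds, k = nrow(ds)),
               class = "insufficient_pool_error")
})

test_that("local fits are seeded-deterministic and handle degeneracy", {
  ds <- fixture_dataset(300, seed = 7)
  q <- parse_name("2-CN_15-CN")
  p1 <- fit_predict_local(q, ds, k = 60, seed = 3)
  p2 <- fit_predict_local(q, ds, k = 60, seed = 3)
  expect_identical(p1, p2)
  expect_named(p1, c("R_plus", "R_minus", "R_1", "lambda_plus",
                     "lambda_minus", "lambda_1", "m_abs", "mu_abs", "g_abs"))
  expect_lte(abs(p1[["g_abs"]]), 2)

  # constant-property neighbourhood predicts that constant
  const <- ds
  const$R_plus <- rep(500, nrow(const))
  pc <- fit_predict_local(q, const, k = 60, seed = 3,
                          properties = "R_plus")
  expect_equal(unname(pc), 500)
})

test_that("local predictions track a smooth noiseless landscape", {
  ds <- fixture_dataset(400, seed = 8, noiseless = TRUE)
  params <- noiseless_params()
  withr::with_seed(53, {
    queries <- replicate(30, random_molecule(), simplify = FALSE)
  })
  queries <- Filter(function(q) !format_name(q) %in% ds$name, queries)
  truth <- vapply(queries, function(q) {
    oracle_properties(q, params, 1)[["R_plus"]]
  }, numeric(1))
  pred <- vapply(queries, function(q) {
    fit_predict_local(q, ds, k = 100, seed = 4,
                      properties = "R_plus")[["R_plus"]]
  }, numeric(1))
  mae <- mean(abs(pred - truth))
  # the local model must clearly beat the trivial spread of the landscape
  expect_lt(mae, 0.6 * sd(truth))
})

test_that("the batch protocol agrees with per-query local fits", {
  ds <- fixture_dataset(300, seed = 7)
  rep_ <- evaluate_local_protocol(ds, k = 50, test_fraction = 0.1,
                                  seed = 19, fp = forest_params(100))
  parts <- split_dataset(ds, 0.1, seed = 19)
  i <- 3L
  q <- dataset_molecule(parts$test, i)
  direct <- fit_predict_local(q, parts$train, k = 50,
                              fp = forest_params(100),
                              seed = derive_seed(19, paste0("q", i)))
  row <- rep_$residuals[rep_$residuals$name == parts$test$name[i], ]
  for (p in row$property) {
    expect_equal(row$predicted[row$property == p], direct[[p]],
                 label = paste("protocol vs direct for", p))
  }
})

test_that("the evaluation report applies the scaled-MAD outlier rule", {
  perfect <- evaluate_predictions(cbind(p = 1:10), cbind(p = 1:10))
  expect_equal(perfect$metrics$mae, 0)
  expect_equal(perfect$metrics$rmse, 0)
  expect_equal(perfect$metrics$outlier_fraction, 0)

  # residuals (0,...,0,100): the single deviant is the only outlier
  truths <- rep(0, 10)
  preds <- c(rep(0, 9), 100)
  rep_ <- evaluate_predictions(cbind(p = preds), cbind(p = truths))
  expect_equal(rep_$metrics$outlier_fraction, 0.1)
  expect_true(rep_$residuals$outlier[10])
  expect_false(any(rep_$residuals$outlier[1:9]))

  withr::with_seed(54, {
    for (i in 1:20) {
      pr <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
      tr <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
      ev <- evaluate_predictions(pr, tr)
      expect_true(all(ev$metrics$mae <= ev$metrics$rmse + 1e-12))
      # shift invariance
      ev2 <- evaluate_predictions(pr + 5, tr + 5)
      expect_equal(ev2$metrics, ev$metrics)
    }
  })
  expect_error(evaluate_predictions(cbind(1:3), cbind(1:4)),
               class = "dimension_error")
})

test_that("global fits are deterministic and comparable on containment", {
  ds <- fixture_dataset(300, seed = 7)
  withr::with_seed(55, {
    queries <- replicate(5, random_molecule(), simplify = FALSE)
  })
  g1 <- fit_predict_global(ds, queries, seed = 6, properties = "g_abs")
  g2 <- fit_predict_global(ds, queries, seed = 6, properties = "g_abs")
  expect_identical(g1, g2)
  expect_true(all(abs(g1[, "g_abs"]) <= 2))
})
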