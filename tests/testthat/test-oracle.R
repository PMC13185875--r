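test_that("the noiseless parent reproduces the anchor property values", {
  rec <- oracle_properties(helicene(), noiseless_params(), seed = 1)
  expect_equal(rec[["R_plus"]], 694)
  expect_equal(rec[["R_minus"]], -514)
  expect_equal(rec[["lambda_plus"]], 342.6)
  expect_equal(rec[["lambda_minus"]], 254)
  expect_equal(rec[["m_abs"]], 0.36)
})

test_that("the oracle is deterministic and g is derived from its moments", {
  params <- default_oracle_params()
  withr::with_seed(31, {
    for (i in 1:50) {
      m <- random_molecule()
      r1 <- oracle_properties(m, params, seed = 5)
      r2 <- oracle_properties(m, params, seed = 5)
      expect_identical(unclass(r1), unclass(r2))
      g_check <- g_from_moments(transition_moments(
        r1[["mu_abs"]], r1[["m_abs"]], attr(r1, "theta")))
      expect_equal(r1[["g_abs"]], g_check, tolerance = 1e-14)
      expect_lte(abs(r1[["g_abs"]]), 2)
      expect_true(all(r1[c("lambda_plus", "lambda_minus", "lambda_1")] > 0))
      expect_gte(r1[["R_plus"]], 0)
      expect_lte(r1[["R_minus"]], 0)
    }
  })
})

test_that("generated datasets respect family and stratification structure", {
  params <- default_oracle_params()
  ds <- generate_dataset(100, "halogen", max_subs = 2, params = params,
                         seed = 3)
  expect_equal(nrow(ds), 100)
  expect_equal(anyDuplicated(ds$name), 0L)
  occ <- as.matrix(as.data.frame(ds)[, paste0("pos", 1:16)])
  expect_true(all(occ %in% c("H", "F", "Cl", "Br", "I")))

  ds6 <- generate_dataset(600, "all16", max_subs = 6, params = params,
                          seed = 4)
  counts <- table(vapply(seq_len(600), function(i) {
    n_substituents(dataset_molecule(ds6, i))
  }, integer(1)))
  expect_equal(as.integer(counts), rep(100L, 6))

  expect_error(generate_dataset(300, "halogen", max_subs = 1,
                                params = params, seed = 1),
               class = "space_exhausted_error")
})

test_that("identical seeds give byte-identical dataset CSVs", {
  params <- default_oracle_params()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(generate_dataset(80, "mixed4", 4, params, seed = 9), f1)
  write_dataset(generate_dataset(80, "mixed4", 4, params, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("the noiseless landscape is Lipschitz-smooth in descriptor space", {
  params <- noiseless_params()
  # re-derive per-property Lipschitz bounds from the parameters:
  # |d shift| <= (max position coefficient + total pair coupling at the
  # largest sigma) per unit descriptor change; tanh saturation is
  # 1-Lipschitz; log-scale channels multiply by base * exp(sat bound).
  sig_max <- max(abs(sigma_table()))
  lip_raw <- apply(abs(params$position_effects), 2, max) +
    2 * sig_max * apply(abs(params$pair_coefs), 2, sum)
  base <- params$base
  scale_out <- c(R_plus = base[["R_plus"]] *
                   exp(params$saturation_scale[["R_plus"]]),
                 R_1 = 1, lambda_1 = 1)
  L <- c(R_plus = lip_raw[["R_plus"]] * scale_out[["R_plus"]],
         R_1 = lip_raw[["R_1"]], lambda_1 = lip_raw[["lambda_1"]])
  # pairs differing by one low-|sigma| substitution sit close in
  # descriptor space; their property gap must be bounded by L * distance
  low_codes <- c("F", "SH", "SMe")
  withr::with_seed(33, {
    for (i in 1:300) {
      m1 <- random_molecule(max_subs = 5)
      free <- which(m1$occupancy == "H")
      pos <- sample(free, 1)
      occ2 <- m1$occupancy
      occ2[pos] <- sample(low_codes, 1)
      m2 <- helicene(occ2)
      d <- weighted_distance(encode(m1), encode(m2))
      if (d == 0 || d > 0.2) next
      r1 <- oracle_properties(m1, params, 1)
      r2 <- oracle_properties(m2, params, 1)
      for (p in names(L)) {
        expect_lte(abs(r1[[p]] - r2[[p]]), L[[p]] * d + 1e-9)
      }
    }
  })
})

test_that("a planted optimum dominates exhaustive scans by its margin", {
  params <- noiseless_params()
  target <- parse_name("3-I")
  planted <- plant_optimum(params, target, "R_plus", margin = 50)

  mono <- enumerate_helicenes(substituent_codes(), max_subs = 1)
  vals <- vapply(mono, function(m) {
    oracle_properties(m, planted, 1)[["R_plus"]]
  }, numeric(1))
  names(vals) <- vapply(mono, format_name, character(1))
  expect_equal(names(which.max(vals)), "3-I")

  # margin holds against the whole <= 2-substituent halogen+NO2 space
  duo <- enumerate_helicenes(c("F", "Cl", "Br", "I", "NO2"), max_subs = 2)
  vals2 <- vapply(duo, function(m) {
    oracle_properties(m, planted, 1)[["R_plus"]]
  }, numeric(1))
  names(vals2) <- vapply(duo, format_name, character(1))
  best <- sort(vals2, decreasing = TRUE)
  expect_equal(names(best)[1], "3-I")
  runner_up <- max(vals2[names(vals2) != "3-I"])
  expect_gte(best[[1]] - runner_up, 50)

  # margin 0 leaves the landscape unchanged away from the bump
  planted0 <- plant_optimum(params, target, "R_plus", margin = 0)
  far <- parse_name("1-NO2_8-CN")
  expect_identical(oracle_properties(far, planted0, 1)[["R_plus"]],
                   oracle_properties(far, params, 1)[["R_plus"]])
  expect_error(plant_optimum(params, target, "g_abs"), class = "value_error")
})

test_that("the regime-switch landscape defeats a single global linear fit", {
  params <- default_oracle_params(regime_switch = TRUE)
  ds <- generate_dataset(2000, "all16", 6, params, seed = 13)
  x <- dataset_features(ds)
  y <- ds$g_abs
  cell <- apply(x, 1, helidesign:::regime_cell)
  d <- data.frame(y = y, x)
  mae_global <- mean(abs(residuals(lm(y ~ ., data = d))))
  resid_piece <- unlist(lapply(split(seq_along(y), cell), function(idx) {
    if (length(idx) > 40) residuals(lm(y ~ ., data = d[idx, ]))
    else y[idx] - mean(y[idx])
  }))
  expect_gt(mae_global, mean(abs(resid_piece)))
})
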