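oracle_predictor <- function(params = noiseless_params(), seed = 1) {
  function(mol) oracle_properties(mol, params, seed)
}

test_that("population initialization respects constraints and seeds", {
  cfg <- ga_config(population = 200, generations = 1)
  expect_error(
    init_population(cfg, constraint_set(forbidden_codes = substituent_codes()),
                    seed = 1),
    class = "infeasible_constraint_error")

  sym <- init_population(cfg, constraint_set(require_symmetry = TRUE),
                         seed = 2)
  for (occ in sym) {
    expect_true(is_symmetric(helicene(occ, max_substituents = 16)))
  }

  pop <- init_population(cfg, constraint_set(), seed = 3)
  counts <- vapply(pop, function(occ) sum(occ != "H"), integer(1))
  expect_setequal(sort(unique(counts)), 1:6)
  expect_identical(init_population(cfg, constraint_set(), seed = 3), pop)
})

test_that("repair enforces the substituent cap, dropping uniformly", {
  cs <- constraint_set(max_substituents = 1L)
  occ <- rep("H", 16)
  occ[c(1, 3)] <- c("SH", "F")
  dropped <- withr::with_seed(61, {
    vapply(1:4000, function(i) {
      kept <- helidesign:::repair_occ(occ, cs)
      which(kept != "H")
    }, integer(1))
  })
  tab <- table(dropped)
  expect_setequal(as.integer(names(tab)), c(1L, 3L))
  expect_gt(chisq.test(tab)$p.value, 0.01)

  # forbidden codes are re-rolled, forbidden positions cleared
  cs2 <- constraint_set(forbidden_codes = c("CCH", "CCPh"),
                        forbidden_positions = 1L)
  occ2 <- rep("H", 16)
  occ2[c(1, 2, 5)] <- c("F", "CCH", "CCPh")
  withr::with_seed(62, {
    for (i in 1:50) {
      rep_ <- helidesign:::repair_occ(occ2, cs2)
      expect_false(any(rep_ %in% c("CCH", "CCPh")))
      expect_equal(rep_[1], "H")
    }
  })
})

test_that("fitness scalarization ranks candidates as specified", {
  # maximize: the R+ = 1486 candidate outranks the 942 one
  lo <- c(R_plus = 942); hi <- c(R_plus = 1486)
  obj <- list(objective("maximize", "R_plus"))
  expect_gt(ga_fitness(hi, obj), ga_fitness(lo, obj))

  tv <- list(objective("target_value", "lambda_1", target = 400,
                       tolerance = 5))
  expect_equal(ga_fitness(c(lambda_1 = 400), tv), 0)
  expect_lt(ga_fitness(c(lambda_1 = 380), tv), 0)

  # joint thresholds: beat the parent on both bands
  thr <- list(objective("threshold", "R_plus", bound = 694, direction = ">"),
              objective("threshold", "R_minus", bound = -514,
                        direction = "<"))
  expect_equal(ga_fitness(c(R_plus = 818, R_minus = -764), thr), 0)
  expect_lt(ga_fitness(c(R_plus = 650, R_minus = -764), thr), 0)
})

test_that("the GA recovers a planted optimum on an enumerable space", {
  codes5 <- c("F", "Cl", "Br", "I", "NO2")
  banned <- setdiff(substituent_codes(), codes5)
  params <- plant_optimum(noiseless_params(), parse_name("2-Br_14-NO2"),
                          "R_plus", margin = 50)
  cs <- constraint_set(forbidden_codes = banned, max_substituents = 2L)
  all_mols <- enumerate_helicenes(codes5, max_subs = 2)
  all_vals <- vapply(all_mols, function(m) {
    oracle_properties(m, params, 1)[["R_plus"]]
  }, numeric(1))
  top1pc <- sort(all_vals, decreasing = TRUE)[ceiling(0.01 * length(all_vals))]

  cfg <- ga_config(population = 200, generations = 30, top_n = 5)
  res <- run_ga(cfg, list(objective("maximize", "R_plus")), cs,
                oracle_predictor(params), seed = 101)
  best_val <- oracle_properties(parse_name(res$candidates$name[1]),
                                params, 1)[["R_plus"]]
  expect_gte(best_val, top1pc)
  # elitism makes the best-fitness trace monotone non-decreasing
  expect_false(is.unsorted(res$trace))
})

test_that("GA runs are deterministic and candidates pass re-audit", {
  cs <- constraint_set(forbidden_codes = c("CCH", "CCPh"))
  cfg <- ga_config(population = 80, generations = 10, top_n = 10)
  obj <- list(objective("maximize", "m_abs"))
  res1 <- run_ga(cfg, obj, cs, oracle_predictor(), seed = 7)
  res2 <- run_ga(cfg, obj, cs, oracle_predictor(), seed = 7)
  expect_identical(res1$candidates, res2$candidates)
  expect_identical(res1$trace, res2$trace)

  expect_gt(nrow(res1$candidates), 0)
  for (nm in res1$candidates$name) {
    mol <- parse_name(nm)
    expect_true(satisfies_constraints(mol, cs))
    expect_false(any(mol$occupancy %in% c("CCH", "CCPh")))
  }
})

test_that("symmetric crossover offspring stay symmetric and windows audit", {
  cs <- constraint_set(require_symmetry = TRUE,
                       property_windows = data.frame(
                         property = "mu_abs", low = 0.5, high = 2))
  cfg <- ga_config(population = 60, generations = 8, top_n = 10)
  obj <- list(objective("maximize", "g_abs"))
  res <- run_ga(cfg, obj, cs, oracle_predictor(), seed = 21)
  params <- noiseless_params()
  for (nm in res$candidates$name) {
    mol <- parse_name(nm)
    expect_true(is_symmetric(mol))
    mu <- oracle_properties(mol, params, 1)[["mu_abs"]]
    expect_true(mu >= 0.5 && mu <= 2)
  }
})
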