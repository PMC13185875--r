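test_that("Position-Substituent names parse to the stated occupancy", {
  m <- parse_name("1-SH_3-F_8-OH")
  expect_equal(m$occupancy[c(1, 3, 8)], c("SH", "F", "OH"))
  expect_equal(sum(m$occupancy != "H"), 3L)

  expect_equal(parse_name("")$occupancy, rep("H", 16))
  expect_equal(parse_name("parent")$occupancy, rep("H", 16))

  # unicode hyphen variants from PDF extraction are normalized
  expect_equal(format_name(parse_name("1‐SH_3‑F")), "1-SH_3-F")
})

test_that("malformed names raise classed errors", {
  expect_error(parse_name("3-F_3-Cl"), class = "duplicate_position_error")
  expect_error(parse_name("2-XYZ"), class = "unknown_substituent_error")
  expect_error(parse_name("17-F"), class = "position_range_error")
  expect_error(parse_name("0-F"), class = "position_range_error")
  expect_error(parse_name("garbage"), class = "name_parse_error")
  expect_error(parse_name(paste(sprintf("%d-F", 1:7), collapse = "_")),
               class = "substituent_count_error")
})

test_that("format emits ascending positions and inverts parse", {
  expect_equal(format_name(helicene()), "parent")
  occ <- rep("H", 16); occ[1] <- "NO2"; occ[16] <- "CN"
  expect_equal(format_name(helicene(occ)), "1-NO2_16-CN")
  expect_equal(format_name(parse_name("2-Br_3-Br_14-Br_15-Br")),
               "2-Br_3-Br_14-Br_15-Br")
  # token order never matters after canonicalization
  expect_equal(format_name(parse_name("3-F_1-SH")), "1-SH_3-F")
})

test_that("parse/format round trip holds for many random molecules", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      m <- random_molecule()
      expect_true(parse_name(format_name(m)) == m)
    }
  })
})

test_that("encoding maps occupancies to sigma_p values", {
  expect_equal(encode(helicene()), rep(0, 16))
  v <- encode(parse_name("1-NO2"))
  expect_equal(v[1], 0.78)
  expect_equal(v[-1], rep(0, 15))
  # the degeneracy audit flags the SMe/H collision of the default table
  degen <- sigma_degeneracies()
  expect_true(any(vapply(degen, function(g) all(c("SMe", "H") %in% g),
                         logical(1))))
  expect_equal(encode(parse_name("4-SMe")), encode(helicene()))
  # identity is still distinct even when encodings collide
  expect_false(format_name(parse_name("4-SMe")) == format_name(helicene()))
  # optional code channel separates them
  expect_false(identical(encode(parse_name("4-SMe"), code_channel = TRUE),
                         encode(helicene(), code_channel = TRUE)))
})

test_that("mirror swaps i with 17-i, is an involution, commutes with encode", {
  expect_equal(format_name(mirror(parse_name("1-SH"))), "16-SH")
  sym <- parse_name("1-NO2_2-Br_15-Br_16-NO2")
  expect_true(mirror(sym) == sym)
  expect_true(is_symmetric(sym))
  expect_true(mirror(parse_name("2-Br_3-Br_14-Br_15-Br")) ==
                parse_name("2-Br_3-Br_14-Br_15-Br"))
  withr::with_seed(12, {
    for (i in 1:200) {
      m <- random_molecule()
      expect_true(mirror(mirror(m)) == m)
      expect_equal(n_substituents(mirror(m)), n_substituents(m))
      expect_equal(encode(mirror(m)), rev(encode(m)))
    }
  })
})

test_that("count_space closed form matches brute-force orbit enumeration", {
  expect_equal(count_space(2, 1, 2, FALSE), 4) # {}, {1}, {2}, {1,2}
  expect_equal(count_space(2, 1, 2, TRUE), 3) # {1} ~ {2}
  for (np in c(2, 4, 6)) {
    for (nt in 1:3) {
      for (ms in 1:3) {
        expect_equal(count_space(np, nt, ms, FALSE),
                     nrow(enumerate_patterns(np, nt, ms, FALSE)),
                     info = sprintf("plain np=%d nt=%d ms=%d", np, nt, ms))
        expect_equal(count_space(np, nt, ms, TRUE),
                     nrow(enumerate_patterns(np, nt, ms, TRUE)),
                     info = sprintf("folded np=%d nt=%d ms=%d", np, nt, ms))
      }
    }
  }
  # odd position counts are fine without folding
  expect_equal(count_space(5, 3, 2, FALSE),
               nrow(enumerate_patterns(5, 3, 2, FALSE)))
  expect_error(count_space(5, 3, 2, TRUE), class = "value_error")
  expect_error(count_space(-1, 3, 2), class = "value_error")
})

test_that("the full helicene space counts exactly and folds to ~7e10", {
  expect_identical(count_space(16, 16, 6, FALSE), 139053725953)
  expect_identical(count_space(16, 16, 6, TRUE), 69526981313)
  expect_equal(signif(count_space(16, 16, 6, TRUE), 1), 7e10)
})

test_that("enumerate_helicenes covers the small sub-space exactly", {
  mols <- enumerate_helicenes(c("F", "Cl", "Br", "I", "NO2"), max_subs = 2)
  expect_length(mols, 3081) # 1 + 16*5 + C(16,2)*25
  expect_equal(anyDuplicated(vapply(mols, format_name, character(1))), 0L)
})
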