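# Shared fixtures, built in code.

# noiseless oracle landscape (exact parent anchors, smooth response)
noiseless_params <- function(...) default_oracle_params(noise_sd = 0, ...)

# a random valid molecule under the default inventory
random_molecule <- function(max_subs = 6L) {
  k <- sample.int(max_subs, 1L)
  occ <- rep("H", 16)
  occ[sample.int(16, k)] <- sample(substituent_codes(), k, replace = TRUE)
  helicene(occ)
}

# random property record with consistent sign structure
random_record <- function() {
  property_record(
    R_plus = runif(1, 0, 1500), R_minus = -runif(1, 0, 1500),
    R_1 = runif(1, -300, 300),
    lambda_plus = runif(1, 200, 500), lambda_minus = runif(1, 200, 500),
    lambda_1 = runif(1, 250, 650),
    m_abs = runif(1, 0, 4), mu_abs = runif(1, 0, 5),
    g_abs = runif(1, -2, 2)
  )
}

# small cached datasets so multiple test files reuse one generation pass
.fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function(n = 300, seed = 7, noiseless = FALSE) {
  key <- sprintf("ds_%d_%d_%d", n, seed, noiseless)
  got <- get0(key, envir = .fixture_cache)
  if (is.null(got)) {
    params <- if (noiseless) noiseless_params() else default_oracle_params()
    got <- generate_dataset(n, "all16", 6, params, seed = seed)
    assign(key, got, envir = .fixture_cache)
  }
  got
}
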