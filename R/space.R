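#' Count the substituted-scaffold chemical space
#'
#' Closed-form size of the space of patterns over `n_positions` sites, each
#' either unsubstituted or carrying one of `n_types` substituent types, with
#' at most `max_subs` substituted sites. Without symmetry folding this is
#' \deqn{\sum_{k=0}^{max\_subs} \binom{n_{pos}}{k}\, n_{types}^k.}
#' With `fold_symmetry = TRUE` patterns related by the end-to-end mirror
#' (position i paired with n+1-i) are counted once, via Burnside's lemma:
#' the orbit count is the average of the total count and the number of
#' mirror-fixed patterns (patterns determined by their n/2 position pairs,
#' each non-H pair contributing two substituents).
#'
#' All quantities are integer-valued and below 2^53, so double arithmetic is
#' exact here; results are returned as doubles to hold values beyond the
#' 32-bit integer range. The default 16-position, 16-type, 6-substituent
#' space folds to about 7e10 distinct molecules.
#'
#' @param n_positions Number of substitutable sites (even when folding).
#' @param n_types Number of substituent types (excluding H).
#' @param max_subs Maximum substituted sites per molecule.
#' @param fold_symmetry Count mirror-related patterns once.
#' @return The count, as a double holding an exact integer.
#' @export
#' @examples
#' count_space(16, 16, 6, fold_symmetry = TRUE)
count_space <- function(n_positions = 16L, n_types = 16L, max_subs = 6L,
                        fold_symmetry = FALSE) {
  if (any(c(n_positions, n_types, max_subs) < 0) ||
      any(c(n_positions, n_types, max_subs) != floor(c(n_positions, n_types, max_subs)))) {
    hel_error("arguments must be non-negative integers", "value_error")
  }
  if (fold_symmetry && n_positions %% 2 != 0) {
    hel_error("symmetry folding requires an even number of positions",
              "value_error")
  }
  kmax <- min(max_subs, n_positions)
  total <- sum(choose(n_positions, 0:kmax) * n_types^(0:kmax))
  if (!fold_symmetry) return(total)
  # mirror-fixed patterns: choose k of the n/2 pairs (each pair = 2 subs)
  pmax <- min(max_subs %/% 2L, n_positions %/% 2L)
  fixed <- sum(choose(n_positions %/% 2L, 0:pmax) * n_types^(0:pmax))
  (total + fixed) / 2
}

#' Exhaustively enumerate a small substitution space
#'
#' Brute-force enumeration of all patterns (as integer type matrices, 0 = H)
#' with at most `max_subs` substituted positions, optionally reduced to one
#' canonical representative per mirror orbit. Intended as the independent
#' cross-check of [count_space()] and as the ground-truth landscape for
#' small-space searches; infeasible beyond a few positions/types.
#'
#' @inheritParams count_space
#' @return Integer matrix, one row per pattern, entries in `0:n_types`.
#' @export
enumerate_patterns <- function(n_positions, n_types, max_subs,
                               fold_symmetry = FALSE) {
  stopifnot(n_positions >= 1, n_types >= 0, max_subs >= 0)
  grid <- as.matrix(expand.grid(rep(list(0:n_types), n_positions),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  grid <- grid[rowSums(grid != 0) <= max_subs, , drop = FALSE]
  if (fold_symmetry) {
    fwd <- apply(grid, 1L, paste, collapse = ",")
    rev_ <- apply(grid[, rev(seq_len(n_positions)), drop = FALSE], 1L,
                  paste, collapse = ",")
    grid <- grid[!duplicated(pmin(fwd, rev_)), , drop = FALSE]
  }
  grid
}

#' Enumerate all helicenes over a code set up to a substituent limit
#'
#' Generates every molecule with at most `max_subs` substituents drawn from
#' `codes` on the 16-position scaffold, as `helicene` objects. Used for
#' exhaustive ground-truth scans on small sub-spaces (e.g. all 3081
#' molecules with up to two substituents from five codes).
#'
#' @param codes Allowed substituent codes.
#' @param max_subs Maximum substituents.
#' @return List of `helicene` objects (parent included).
#' @export
enumerate_helicenes <- function(codes, max_subs = 2L) {
  stopifnot(max_subs <= 3L) # combinatorial guard: this is for small scans
  out <- list(helicene())
  pos_sets <- unlist(lapply(seq_len(max_subs), function(k) {
    utils::combn(N_POSITIONS, k, simplify = FALSE)
  }), recursive = FALSE)
  for (ps in pos_sets) {
    assign_grid <- expand.grid(rep(list(codes), length(ps)),
                               stringsAsFactors = FALSE)
    for (r in seq_len(nrow(assign_grid))) {
      occ <- rep("H", N_POSITIONS)
      occ[ps] <- as.character(assign_grid[r, ])
      out[[length(out) + 1L]] <- helicene(occ, max_substituents = max_subs)
    }
  }
  out
}
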