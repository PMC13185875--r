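# Constrained genetic algorithm over substitution patterns. Individuals are
# occupancy vectors; fitness is supplied by any molecule -> properties
# predictor (local model in production, oracle in benchmarks). Constraint
# handling is repair-based so the population size never collapses under
# tight constraint ladders.

#' Design objective
#'
#' One term of a design specification: maximize or minimize a property, hit
#' a target value, or require a threshold. Multiple objectives are combined
#' by [ga_fitness()] as a weighted sum of their scalarized scores.
#'
#' @param kind `"maximize"`, `"minimize"`, `"target_value"` or `"threshold"`.
#' @param property One of the nine property names.
#' @param target Target value (for `target_value`).
#' @param tolerance Positive tolerance used only to report target attainment.
#' @param bound,direction Threshold bound and `">"` or `"<"` (for
#'   `threshold`).
#' @param weight Positive weight in the scalarization.
#' @return An `objective` object.
#' @export
#' @examples
#' objective("maximize", "R_plus")
#' objective("target_value", "lambda_1", target = 400, tolerance = 5)
objective <- function(kind = c("maximize", "minimize", "target_value",
                               "threshold"),
                      property, target = NULL, tolerance = NULL,
                      bound = NULL, direction = c(">", "<"), weight = 1) {
  kind <- match.arg(kind)
  stopifnot(property %in% PROPERTY_NAMES, weight > 0)
  if (kind == "target_value") {
    stopifnot(!is.null(target), is.null(tolerance) || tolerance > 0)
  }
  if (kind == "threshold") {
    stopifnot(!is.null(bound))
    direction <- match.arg(direction)
  }
  structure(list(kind = kind, property = property, target = target,
                 tolerance = tolerance %||% 1, bound = bound,
                 direction = if (kind == "threshold") direction else NULL,
                 weight = weight), class = "objective")
}

#' Hard constraints on candidate molecules
#'
#' The constraint vocabulary of the synthesis-aware design scenarios:
#' banned substituent codes, banned positions, required mirror symmetry,
#' a substituent-count cap, and hard property windows (candidates whose
#' predicted property falls outside a window are rejected in the audit, not
#' penalized in fitness).
#'
#' @param forbidden_codes Character vector of banned codes.
#' @param forbidden_positions Integer vector of banned positions (1..16).
#' @param require_symmetry Require `mol == mirror(mol)`.
#' @param max_substituents Cap on non-H positions (default 6).
#' @param property_windows Data frame with columns `property, low, high`,
#'   or NULL.
#' @return A `constraint_set`.
#' @export
constraint_set <- function(forbidden_codes = character(0),
                           forbidden_positions = integer(0),
                           require_symmetry = FALSE,
                           max_substituents = 6L,
                           property_windows = NULL) {
  stopifnot(all(forbidden_codes %in% substituent_codes()),
            all(forbidden_positions %in% 1:16))
  if (require_symmetry) {
    partners <- 17L - forbidden_positions
    # a symmetric molecule occupies both members of a pair or neither, so a
    # ban on one side implies the pair is unusable; record both for clarity
    forbidden_positions <- sort(unique(c(forbidden_positions, partners)))
  }
  if (!is.null(property_windows)) {
    stopifnot(all(c("property", "low", "high") %in% names(property_windows)),
              all(property_windows$property %in% PROPERTY_NAMES))
  }
  structure(list(forbidden_codes = forbidden_codes,
                 forbidden_positions = as.integer(forbidden_positions),
                 require_symmetry = require_symmetry,
                 max_substituents = as.integer(max_substituents),
                 property_windows = property_windows),
            class = "constraint_set")
}

allowed_codes <- function(cs) setdiff(substituent_codes(), cs$forbidden_codes)

allowed_positions <- function(cs) setdiff(1:16, cs$forbidden_positions)

#' Audit a molecule against structural constraints
#'
#' Independent re-check used on every reported candidate: codes, positions,
#' symmetry (via [mirror()]) and substituent count.
#'
#' @param mol A [helicene()].
#' @param cs A [constraint_set()].
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_constraints <- function(mol, cs) {
  occ <- mol$occupancy
  subs <- which(occ != "H")
  if (length(subs) > cs$max_substituents) return(FALSE)
  if (any(occ[subs] %in% cs$forbidden_codes)) return(FALSE)
  if (any(subs %in% cs$forbidden_positions)) return(FALSE)
  if (cs$require_symmetry && !(mol == mirror(mol))) return(FALSE)
  TRUE
}

#' Audit predicted properties against hard windows
#' @param pred Named numeric prediction vector.
#' @param cs A [constraint_set()].
#' @return `TRUE` if every window is met (or no windows are set).
#' @export
satisfies_windows <- function(pred, cs) {
  window_deficit(pred, cs) == 0
}

# summed relative violation of the property windows (0 when all met);
# used to steer selection toward the feasible region -- the hard audit on
# reported candidates is separate
window_deficit <- function(pred, cs) {
  pw <- cs$property_windows
  if (is.null(pw) || !nrow(pw)) return(0)
  sum(vapply(seq_len(nrow(pw)), function(i) {
    v <- pred[[pw$property[i]]]
    scale <- max(abs(pw$low[i]), abs(pw$high[i]), 1e-12)
    (max(0, pw$low[i] - v) + max(0, v - pw$high[i])) / scale
  }, numeric(1)))
}

#' Genetic-algorithm configuration
#'
#' Defaults: an initial population of 1000 individuals for adequate
#' exploration of the space, 100 generations, tournament selection (size 3),
#' uniform crossover at rate 0.8, per-position code mutation 0.05 plus
#' add/drop/move substituent moves, elitism 5.
#'
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a child is produced by crossover.
#' @param mutation_rate Per-position code-mutation probability.
#' @param add_rate,drop_rate,move_rate Probabilities of the add-, drop- and
#'   relocate-substituent moves per offspring.
#' @param tournament_size Selection tournament size.
#' @param elitism Number of elites copied unchanged each generation.
#' @param top_n Number of ranked candidates reported.
#' @return A `ga_config`.
#' @export
ga_config <- function(population = 1000L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      add_rate = 0.2, drop_rate = 0.2, move_rate = 0.2,
                      tournament_size = 3L, elitism = 5L, top_n = 20L) {
  stopifnot(population >= 2,
            all(c(crossover_rate, mutation_rate, add_rate, drop_rate,
                  move_rate) >= 0),
            all(c(crossover_rate, mutation_rate, add_rate, drop_rate,
                  move_rate) <= 1))
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 add_rate = add_rate, drop_rate = drop_rate,
                 move_rate = move_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 top_n = as.integer(top_n)), class = "ga_config")
}

# repair an occupancy vector in place to satisfy structural constraints
repair_occ <- function(occ, cs) {
  # forbidden codes: re-roll to an allowed code
  ok_codes <- allowed_codes(cs)
  if (!length(ok_codes)) {
    hel_error("all substituent codes are forbidden", "infeasible_constraint_error")
  }
  bad <- which(occ != "H" & occ %in% cs$forbidden_codes)
  if (length(bad)) occ[bad] <- sample(ok_codes, length(bad), replace = TRUE)
  # forbidden positions: clear
  occ[cs$forbidden_positions] <- "H"
  # symmetry: copy the lower position of each pair onto its partner
  if (cs$require_symmetry) {
    for (i in 1:8) occ[17L - i] <- occ[i]
  }
  # substituent cap: drop random substituents (pairs under symmetry)
  excess <- function(o) sum(o != "H") - cs$max_substituents
  while (excess(occ) > 0) {
    subs <- which(occ != "H")
    if (cs$require_symmetry) {
      low <- unique(pmin(subs, 17L - subs))
      drop <- low[sample.int(length(low), 1L)]
      occ[c(drop, 17L - drop)] <- "H"
    } else {
      occ[subs[sample.int(length(subs), 1L)]] <- "H"
    }
  }
  occ
}

random_individual <- function(cs, target_subs = NULL) {
  pos_ok <- allowed_positions(cs)
  codes <- allowed_codes(cs)
  if (!length(codes)) {
    hel_error("all substituent codes are forbidden",
              "infeasible_constraint_error")
  }
  occ <- rep("H", N_POSITIONS)
  if (cs$require_symmetry) {
    pairs_ok <- intersect(1:8, pmin(pos_ok, 17L - pos_ok))
    kmax <- min(cs$max_substituents %/% 2L, length(pairs_ok))
    if (kmax < 1L) {
      hel_error("symmetry plus the position bans leave no usable pair",
                "infeasible_constraint_error")
    }
    k <- target_subs %||% sample.int(kmax, 1L)
    k <- min(k, kmax)
    sel <- pairs_ok[sample.int(length(pairs_ok), k)]
    occ[sel] <- sample(codes, k, replace = TRUE)
    occ[17L - sel] <- occ[sel]
  } else {
    kmax <- min(cs$max_substituents, length(pos_ok))
    if (kmax < 1L || !length(codes)) {
      hel_error("constraints leave no feasible molecule",
                "infeasible_constraint_error")
    }
    k <- min(target_subs %||% sample.int(kmax, 1L), kmax)
    sel <- pos_ok[sample.int(length(pos_ok), k)]
    occ[sel] <- sample(codes, k, replace = TRUE)
  }
  occ
}

#' Initialize a GA population
#'
#' Generates `cfg$population` constraint-valid occupancy vectors with
#' substituent counts spread over `1..max_substituents`, distinct by
#' canonical name where the space allows.
#'
#' @param cfg A [ga_config()].
#' @param cs A [constraint_set()].
#' @param seed Integer seed.
#' @return List of occupancy vectors.
#' @export
init_population <- function(cfg, cs, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    pop <- list()
    seen <- character(0)
    kmax <- if (cs$require_symmetry) {
      max(1L, cs$max_substituents %/% 2L)
    } else {
      cs$max_substituents
    }
    tries <- 0L
    while (length(pop) < cfg$population) {
      occ <- random_individual(cs, target_subs = (length(pop) %% kmax) + 1L)
      nm <- paste(occ, collapse = "|")
      tries <- tries + 1L
      if (!nm %in% seen || tries > 20L * cfg$population) {
        seen <- c(seen, nm)
        pop[[length(pop) + 1L]] <- occ
      }
    }
    pop
  })
}

# uniform crossover + mutation moves, followed by repair
vary_pair <- function(p1, p2, cfg, cs) {
  child <- p1
  if (stats::runif(1) < cfg$crossover_rate) {
    take2 <- stats::runif(N_POSITIONS) < 0.5
    child[take2] <- p2[take2]
  }
  # per-position code mutation
  mut <- which(stats::runif(N_POSITIONS) < cfg$mutation_rate &
                 child != "H")
  if (length(mut)) {
    child[mut] <- sample(allowed_codes(cs), length(mut), replace = TRUE)
  }
  # add a substituent
  if (stats::runif(1) < cfg$add_rate) {
    free <- intersect(which(child == "H"), allowed_positions(cs))
    if (length(free)) {
      child[free[sample.int(length(free), 1L)]] <-
        sample(allowed_codes(cs), 1L)
    }
  }
  # drop a substituent
  if (stats::runif(1) < cfg$drop_rate) {
    subs <- which(child != "H")
    if (length(subs)) child[subs[sample.int(length(subs), 1L)]] <- "H"
  }
  # relocate a substituent
  if (stats::runif(1) < cfg$move_rate) {
    subs <- which(child != "H")
    free <- intersect(which(child == "H"), allowed_positions(cs))
    if (length(subs) && length(free)) {
      from <- subs[sample.int(length(subs), 1L)]
      to <- free[sample.int(length(free), 1L)]
      child[to] <- child[from]
      child[from] <- "H"
    }
  }
  repair_occ(child, cs)
}

#' Scalarized fitness of a prediction under a set of objectives
#'
#' maximize -> +value; minimize -> -value; target_value -> -|value - target|;
#' threshold -> 0 when met, else minus the weighted deficit. Terms are
#' combined as a weighted sum. Hard property windows are not part of the
#' fitness; they are audited separately.
#'
#' @param pred Named numeric prediction vector.
#' @param objectives List of [objective()]s.
#' @return Scalar fitness (larger is better).
#' @export
ga_fitness <- function(pred, objectives) {
  sum(vapply(objectives, function(ob) {
    v <- pred[[ob$property]]
    s <- switch(ob$kind,
      maximize = v,
      minimize = -v,
      target_value = -abs(v - ob$target),
      threshold = {
        deficit <- if (ob$direction == ">") max(0, ob$bound - v)
                   else max(0, v - ob$bound)
        -deficit
      })
    ob$weight * s
  }, numeric(1)))
}

#' Run the constrained genetic algorithm
#'
#' Tournament selection with elitism over repaired variation
#' (uniform crossover; code, add, drop and move mutations). Every candidate
#' is evaluated through `predictor`; a predictor failure scores the
#' candidate `-Inf`. Reported candidates are re-audited independently
#' against the structural constraints and any property windows. Fully
#' deterministic given `seed`.
#'
#' @param cfg A [ga_config()].
#' @param objectives List of [objective()]s.
#' @param cs A [constraint_set()].
#' @param predictor Function `helicene -> named numeric properties`.
#' @param seed Integer seed.
#' @return A `design_result`: data frame `candidates` (name, fitness,
#'   predicted properties, audit flags, ranked by fitness), numeric
#'   `trace` of the best fitness per generation, and the `ga_config` used.
#' @export
run_ga <- function(cfg, objectives, cs = constraint_set(), predictor,
                   seed = 1L) {
  pop <- init_population(cfg, cs, seed)
  evaluate <- function(occ) {
    mol <- helicene(occ, max_substituents = N_POSITIONS)
    pred <- tryCatch(predictor(mol), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(unlist(pred)))) {
      return(list(fit = -Inf, pred = NULL))
    }
    # hard windows enter selection as a dominant feasibility penalty so the
    # search concentrates inside the feasible region; ranking among
    # feasible candidates is unaffected
    penalty <- 1e4 * window_deficit(pred, cs)
    list(fit = ga_fitness(pred, objectives) - penalty, pred = pred)
  }
  evals <- lapply(pop, evaluate)
  fits <- vapply(evals, `[[`, numeric(1), "fit")
  trace <- numeric(cfg$generations + 1L)
  trace[1] <- max(fits)
  # archive of the best distinct candidates seen anywhere in the run
  archive <- new.env(parent = emptyenv())
  stash <- function(occ, ev) {
    if (is.null(ev$pred)) return(invisible())
    nm <- format_name(helicene(occ, max_substituents = N_POSITIONS))
    old <- get0(nm, envir = archive)
    if (is.null(old) || ev$fit > old$fit) {
      assign(nm, list(occ = occ, fit = ev$fit, pred = ev$pred),
             envir = archive)
    }
  }
  mapply(stash, pop, evals, SIMPLIFY = FALSE)
  with_seed(derive_seed(seed, "evolve"), {
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fits, decreasing = TRUE)
      elites <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
      elite_evals <- evals[ord[seq_len(length(elites))]]
      tournament <- function() {
        idx <- sample.int(length(pop), cfg$tournament_size, replace = TRUE)
        pop[[idx[which.max(fits[idx])]]]
      }
      offspring <- lapply(seq_len(cfg$population - length(elites)),
                          function(i) vary_pair(tournament(), tournament(),
                                                cfg, cs))
      off_evals <- lapply(offspring, evaluate)
      mapply(stash, offspring, off_evals, SIMPLIFY = FALSE)
      pop <- c(elites, offspring)
      evals <- c(elite_evals, off_evals)
      fits <- vapply(evals, `[[`, numeric(1), "fit")
      trace[gen + 1L] <- max(fits)
    }
  })
  cands <- mget(sort(ls(archive)), envir = archive)
  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "fit"),
                       names(cands))]
  ok <- vapply(cands, function(cd) {
    satisfies_constraints(helicene(cd$occ, max_substituents = N_POSITIONS),
                          cs) && satisfies_windows(cd$pred, cs)
  }, logical(1))
  cands <- utils::head(cands[ok], cfg$top_n)
  rows <- lapply(names(cands), function(nm) {
    cd <- cands[[nm]]
    data.frame(name = nm, fitness = cd$fit,
               as.data.frame(as.list(cd$pred), check.names = FALSE),
               passes_constraints = TRUE, passes_windows = TRUE,
               stringsAsFactors = FALSE)
  })
  candidates <- do.call(rbind, rows)
  if (is.null(candidates)) {
    candidates <- data.frame(name = character(0), fitness = numeric(0),
                             passes_constraints = logical(0),
                             passes_windows = logical(0))
  }
  rownames(candidates) <- NULL
  structure(list(candidates = candidates, trace = trace, config = cfg,
                 constraints = cs, seed = seed),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %d audited candidate(s); best fitness %.4g\n",
              nrow(x$candidates), max(x$trace)))
  print(utils::head(x$candidates[, c("name", "fitness")], 5), row.names = FALSE)
  invisible(x)
}
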