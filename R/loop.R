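#' Iterative design loop (design / evaluate / retrain)
#'
#' The protocol for reaching sparsely sampled property regions: each round
#' runs the GA with a local-model predictor trained on the current dataset,
#' evaluates the top `batch` novel candidates with the ground-truth
#' evaluator (the oracle in tests; an electronic-structure code in real
#' use), appends the evaluated rows to the dataset, and retrains. Appended
#' rows always come from the evaluator, never from the predictor, so the
#' loop cannot self-confirm its own predictions.
#'
#' @param target An [objective()] (typically `target_value`); the per-round
#'   gap is `|best true value - target|` for target objectives, otherwise
#'   the negated best true value (so smaller is always better).
#' @param rounds Number of design rounds (>= 1).
#' @param batch Ground-truth evaluations per round (default 20).
#' @param ga_cfg A [ga_config()].
#' @param cs A [constraint_set()].
#' @param dataset Seed `helicene_dataset`.
#' @param evaluator Function `helicene -> property_record` (ground truth).
#' @param seed Integer seed.
#' @param k,w,fp,predictor_properties Local-model settings for the per-round
#'   predictor.
#' @param tolerance Early stop when the gap drops to this value or below.
#' @return A `loop_history`: data frame `history` (round, dataset size, best
#'   candidate name, best true value, gap), the final dataset, and the
#'   per-round candidate tables.
#' @export
iterate_design <- function(target, rounds = 3L, batch = 20L, ga_cfg,
                           cs = constraint_set(), dataset, evaluator,
                           seed = 1L, k = 100L, w = rep(1, N_POSITIONS),
                           fp = forest_params(),
                           predictor_properties = target$property,
                           tolerance = 0) {
  stopifnot(rounds >= 1, batch >= 1, inherits(target, "objective"))
  score_gap <- function(value) {
    if (target$kind == "target_value") abs(value - target$target)
    else if (target$kind == "minimize") value
    else -value
  }
  history <- list()
  round_candidates <- list()
  ds <- dataset
  for (r in seq_len(rounds)) {
    predictor <- make_local_predictor(ds, k = k, w = w, fp = fp,
                                      seed = derive_seed(seed, paste0("fit", r)),
                                      properties = predictor_properties)
    res <- run_ga(ga_cfg, list(target), cs, predictor,
                  seed = derive_seed(seed, paste0("ga", r)))
    novel <- res$candidates[!res$candidates$name %in% ds$name, , drop = FALSE]
    novel <- utils::head(novel, batch)
    if (!nrow(novel)) {
      history[[r]] <- data.frame(round = r, dataset_size = nrow(ds),
                                 best_name = NA_character_,
                                 best_value = NA_real_, gap = NA_real_,
                                 status = "no novel candidates")
      break
    }
    mols <- lapply(novel$name, parse_name)
    recs <- lapply(mols, evaluator)
    ds <- append_rows(ds, helicene_dataset(mols, recs, "oracle"),
                      quiet = TRUE)
    truths <- vapply(recs, function(rec) rec[[target$property]], numeric(1))
    best <- which.min(vapply(truths, score_gap, numeric(1)))
    history[[r]] <- data.frame(round = r, dataset_size = nrow(ds),
                               best_name = novel$name[best],
                               best_value = truths[best],
                               gap = score_gap(truths[best]),
                               status = "ok")
    round_candidates[[r]] <- cbind(novel, true_value = truths)
    if (target$kind == "target_value" &&
        score_gap(truths[best]) <= tolerance) break
  }
  structure(list(history = do.call(rbind, history), dataset = ds,
                 round_candidates = round_candidates, seed = seed),
            class = "loop_history")
}

#' @export
print.loop_history <- function(x, ...) {
  cat("<loop_history>\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}
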