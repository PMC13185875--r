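#' Read a design specification from JSON or YAML
#'
#' A design spec bundles the objectives, hard constraints, GA configuration
#' and seed of one inverse-design run:
#' ```
#' {
#'   "objectives": [{"kind": "maximize", "property": "R_plus"}],
#'   "constraints": {"forbidden_codes": ["CCH", "CCPh"]},
#'   "ga": {"population": 1000, "generations": 100},
#'   "seed": 1
#' }
#' ```
#' YAML files (`.yml`/`.yaml`) require the `yaml` package.
#'
#' @param path Path to the spec file.
#' @return List with elements `objectives` (list of [objective()]s),
#'   `constraints` ([constraint_set()]), `ga` ([ga_config()]), `seed`.
#' @export
read_design_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      hel_error("the yaml package is required for YAML design specs",
                "value_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  objs <- lapply(raw$objectives, function(o) {
    do.call(objective, o[!vapply(o, is.null, logical(1))])
  })
  cr <- raw$constraints %||% list()
  pw <- cr$property_windows
  if (!is.null(pw)) pw <- do.call(rbind, lapply(pw, as.data.frame))
  cs <- constraint_set(
    forbidden_codes = unlist(cr$forbidden_codes) %||% character(0),
    forbidden_positions = unlist(cr$forbidden_positions) %||% integer(0),
    require_symmetry = isTRUE(cr$require_symmetry),
    max_substituents = cr$max_substituents %||% 6L,
    property_windows = pw
  )
  ga <- do.call(ga_config, raw$ga %||% list())
  list(objectives = objs, constraints = cs, ga = ga,
       seed = raw$seed %||% 1L)
}

#' Write a design result to CSV plus a JSON audit
#'
#' @param res A `design_result` from [run_ga()].
#' @param csv_path Candidate table CSV (name, fitness, predicted properties).
#' @param json_path Optional JSON audit (config, trace, constraint flags).
#' @return `csv_path`, invisibly.
#' @export
write_design_result <- function(res, csv_path, json_path = NULL) {
  utils::write.csv(res$candidates, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      seed = res$seed,
      config = unclass(res$config),
      best_fitness = max(res$trace),
      trace = res$trace,
      n_candidates = nrow(res$candidates),
      all_pass_audit = all(res$candidates$passes_constraints &
                             res$candidates$passes_windows)
    ), json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv_path)
}
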