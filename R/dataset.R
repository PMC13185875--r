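DATASET_SCHEMA <- c("name", paste0("pos", 1:16), PROPERTY_NAMES)

#' Construct a molecule-property dataset
#'
#' A validated data frame with one row per molecule: the canonical
#' Position-Substituent name, the 16 occupancy columns `pos1..pos16`
#' (substituent codes, `H` for unsubstituted) and the nine property columns.
#' Names are canonical, so a molecule appears at most once regardless of the
#' token order it was supplied in.
#'
#' @param molecules List of [helicene()] objects.
#' @param records List of [property_record()]s, same length.
#' @param provenance `"oracle"` or `"external"`.
#' @return Object of class `helicene_dataset` (a data frame).
#' @export
helicene_dataset <- function(molecules, records, provenance = "oracle") {
  stopifnot(length(molecules) == length(records))
  occ <- do.call(rbind, lapply(molecules, function(m) m$occupancy))
  props <- do.call(rbind, lapply(records, function(r) as.numeric(r)))
  colnames(props) <- PROPERTY_NAMES
  df <- data.frame(name = vapply(molecules, format_name, character(1)),
                   occ, props, stringsAsFactors = FALSE)
  names(df)[2:17] <- paste0("pos", 1:16)
  new_dataset(df, provenance)
}

new_dataset <- function(df, provenance = "oracle") {
  if (!identical(names(df), DATASET_SCHEMA)) {
    missing <- setdiff(DATASET_SCHEMA, names(df))
    hel_error(paste0("dataset schema mismatch; missing/misordered columns: ",
                     paste(c(missing, setdiff(names(df), DATASET_SCHEMA)),
                           collapse = ", ")), "schema_error")
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) {
    hel_error(paste0("duplicate molecule name(s): ",
                     paste(unique(dup), collapse = ", ")),
              "duplicate_molecule_error")
  }
  if (nrow(df)) {
    pm <- as.matrix(df[, PROPERTY_NAMES])
    bad <- !is.finite(pm) |
      cbind(pm[, "R_plus"] < 0, pm[, "R_minus"] > 0, FALSE,
            pm[, "lambda_plus"] <= 0, pm[, "lambda_minus"] <= 0,
            pm[, "lambda_1"] <= 0, pm[, "m_abs"] < 0, pm[, "mu_abs"] < 0,
            abs(pm[, "g_abs"]) > 2)
    if (any(bad)) {
      at <- which(bad, arr.ind = TRUE)[1, ]
      hel_error(sprintf("property invariant violated at row %d, column %s",
                        at[1], PROPERTY_NAMES[at[2]]), "validation_error")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("helicene_dataset", "data.frame"),
            provenance = provenance, schema_version = 1L)
}

#' Rebuild the i-th molecule of a dataset
#' @param ds A `helicene_dataset`.
#' @param i Row index.
#' @return A [helicene()].
#' @export
dataset_molecule <- function(ds, i) {
  helicene(as.character(ds[i, paste0("pos", 1:16)]),
           max_substituents = N_POSITIONS)
}

#' Descriptor matrix of a dataset
#' @param ds A `helicene_dataset`.
#' @param sigma Descriptor table.
#' @return Numeric matrix, one row per molecule, 16 sigma_p columns.
#' @export
dataset_features <- function(ds, sigma = sigma_table()) {
  occ <- as.matrix(ds[, paste0("pos", 1:16)])
  missing <- setdiff(unique(as.vector(occ)), names(sigma))
  if (length(missing)) {
    hel_error(paste0("no sigma_p entry for: ", paste(missing, collapse = ", ")),
              "descriptor_table_error")
  }
  m <- matrix(sigma[occ], nrow = nrow(ds))
  colnames(m) <- paste0("s", 1:16)
  m
}

#' Write a dataset to CSV
#'
#' Floats are serialized at full (repr-level) precision so seeded pipelines
#' round-trip losslessly.
#'
#' @param ds A `helicene_dataset`.
#' @param path Output file; a `.gz` suffix writes through a gzip connection.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds)
  for (p in PROPERTY_NAMES) df[[p]] <- sprintf("%.17g", df[[p]])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a dataset CSV
#'
#' @param path CSV path (optionally gzip-compressed).
#' @param provenance Provenance tag to attach.
#' @return A `helicene_dataset`; row order preserved.
#' @export
read_dataset <- function(path, provenance = "external") {
  open_con <- function() if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  hdr <- names(utils::read.csv(open_con(), nrows = 1,
                               check.names = FALSE))
  if (!identical(hdr, DATASET_SCHEMA)) {
    missing <- setdiff(DATASET_SCHEMA, hdr)
    hel_error(paste0("dataset schema mismatch; missing/misordered columns: ",
                     paste(c(missing, setdiff(hdr, DATASET_SCHEMA)),
                           collapse = ", ")), "schema_error")
  }
  df <- utils::read.csv(open_con(), stringsAsFactors = FALSE,
                        colClasses = c(rep("character", 17),
                                       rep("numeric", 9)))
  new_dataset(df, provenance)
}

#' Split a dataset into train and test parts
#'
#' Seeded random partition; the default 20% test fraction is the standard
#' held-out evaluation protocol.
#'
#' @param ds A `helicene_dataset`.
#' @param test_fraction Proportion in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(ds, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    hel_error("test_fraction must lie strictly between 0 and 1", "value_error")
  }
  n <- nrow(ds)
  n_test <- max(1L, round(n * test_fraction))
  idx <- with_seed(derive_seed(seed, "split"), sample.int(n, n_test))
  prov <- attr(ds, "provenance")
  list(train = new_dataset(as.data.frame(ds)[-idx, , drop = FALSE], prov),
       test = new_dataset(as.data.frame(ds)[idx, , drop = FALSE], prov))
}

#' Append rows to a dataset, de-duplicating by canonical name
#'
#' Rows whose canonical name is already present are dropped (one molecule,
#' one row); a warning reports how many, unless `quiet`.
#'
#' @param ds A `helicene_dataset`.
#' @param new_rows A `helicene_dataset` (or conforming data frame) to append.
#' @param quiet Suppress the de-duplication warning.
#' @return The grown `helicene_dataset`.
#' @export
append_rows <- function(ds, new_rows, quiet = FALSE) {
  nd <- as.data.frame(new_rows)
  if (!identical(names(nd), DATASET_SCHEMA)) {
    hel_error("appended rows do not match the dataset schema", "schema_error")
  }
  dup <- nd$name %in% ds$name | duplicated(nd$name)
  if (any(dup) && !quiet) {
    hel_warning(sprintf("dropping %d duplicate molecule(s) on append",
                        sum(dup)), "duplicate_append_warning")
  }
  new_dataset(rbind(as.data.frame(ds), nd[!dup, , drop = FALSE]),
              attr(ds, "provenance"))
}
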