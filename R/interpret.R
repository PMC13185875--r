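#' Position/substituent pattern summary of a candidate set
#'
#' The interpretability layer: for each of the 16 scaffold positions,
#' the fraction of candidates substituted there, the mean Hammett sigma_p of
#' the occupying groups, and the three most frequent codes. This is the
#' tabular form of the bubble plot reading (circle size = substitution
#' frequency, colour = average Hammett constant), from which design rules
#' such as "strong acceptors at position 1" are extracted.
#'
#' @param candidates Non-empty list of [helicene()]s (or a
#'   `helicene_dataset`, whose molecules are used).
#' @param sigma Descriptor table.
#' @param count_H_as_zero With the default `FALSE`, the mean sigma_p at a
#'   position averages over its substituted instances only (and is `NA`
#'   where the position is never substituted); with `TRUE`, unsubstituted
#'   instances enter the average as sigma_p(H) = 0.
#' @return A `pattern_summary` data frame with columns `position`,
#'   `frequency`, `mean_sigma_p`, `top_codes` ("code:count" tokens).
#' @export
#' @examples
#' pattern_summary(list(parse_name("1-NO2"), parse_name("1-CN_2-Br")))
pattern_summary <- function(candidates, sigma = sigma_table(),
                            count_H_as_zero = FALSE) {
  if (inherits(candidates, "helicene_dataset")) {
    candidates <- lapply(seq_len(nrow(candidates)), dataset_molecule,
                         ds = candidates)
  }
  if (!length(candidates)) {
    hel_error("candidate list is empty", "empty_input_error")
  }
  occ <- do.call(rbind, lapply(candidates, function(m) m$occupancy))
  rows <- lapply(1:16, function(i) {
    col <- occ[, i]
    sub <- col[col != "H"]
    freq <- length(sub) / length(col)
    mean_sig <- if (count_H_as_zero) {
      mean(sigma[col])
    } else if (length(sub)) {
      mean(sigma[sub])
    } else {
      NA_real_
    }
    top <- if (length(sub)) {
      tb <- sort(table(sub), decreasing = TRUE)
      paste(sprintf("%s:%d", names(tb), as.integer(tb))[seq_len(min(3, length(tb)))],
            collapse = " ")
    } else {
      ""
    }
    data.frame(position = i, frequency = freq, mean_sigma_p = mean_sig,
               top_codes = top, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("pattern_summary", "data.frame"))
}

#' Write a pattern summary to CSV
#' @param ps A [pattern_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pattern_summary <- function(ps, path) {
  df <- as.data.frame(ps)
  df$frequency <- sprintf("%.17g", df$frequency)
  df$mean_sigma_p <- ifelse(is.na(df$mean_sigma_p), "",
                            sprintf("%.17g", df$mean_sigma_p))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a pattern summary back from CSV
#' @param path CSV path written by [write_pattern_summary()].
#' @return A `pattern_summary` data frame.
#' @export
read_pattern_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$position <- as.integer(df$position)
  df$frequency <- as.numeric(df$frequency)
  df$mean_sigma_p <- suppressWarnings(as.numeric(df$mean_sigma_p))
  df$top_codes[is.na(df$top_codes)] <- ""
  structure(df, class = c("pattern_summary", "data.frame"))
}
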