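N_POSITIONS <- 16L

#' Construct a substituted [6]helicene
#'
#' The scaffold is implicit: a molecule is the occupancy of its 16
#' substitutable positions (1-based, the standard scaffold numbering) by
#' substituent codes, `"H"` meaning unsubstituted, plus the helical sense.
#'
#' @param occupancy Character vector of length 16 of substituent codes.
#' @param helicity `"P"` (default; all training data refer to the P
#'   enantiomer) or `"M"`.
#' @param max_substituents Maximum allowed number of non-H positions
#'   (default 6, the training-set limit).
#' @return An object of class `helicene`.
#' @export
#' @examples
#' helicene(c("NO2", rep("H", 15)))
helicene <- function(occupancy = rep("H", N_POSITIONS), helicity = "P",
                     max_substituents = 6L) {
  if (length(occupancy) != N_POSITIONS) {
    hel_error("occupancy must have exactly 16 positions", "position_range_error")
  }
  valid <- names(sigma_table())
  bad <- setdiff(unique(occupancy), valid)
  if (length(bad)) {
    hel_error(paste0("unknown substituent code(s): ", paste(bad, collapse = ", ")),
              "unknown_substituent_error")
  }
  n_sub <- sum(occupancy != "H")
  if (n_sub > max_substituents) {
    hel_error(sprintf("%d substituents exceeds the limit of %d",
                      n_sub, max_substituents), "substituent_count_error")
  }
  if (!helicity %in% c("P", "M")) {
    hel_error("helicity must be 'P' or 'M'", "helicity_error")
  }
  structure(list(occupancy = as.character(occupancy), helicity = helicity),
            class = "helicene")
}

#' @export
print.helicene <- function(x, ...) {
  cat(sprintf("<helicene (%s)> %s\n", x$helicity, format_name(x)))
  invisible(x)
}

#' @export
`==.helicene` <- function(e1, e2) {
  identical(e1$occupancy, e2$occupancy) && identical(e1$helicity, e2$helicity)
}

#' Number of substituted (non-H) positions
#' @param mol A `helicene`.
#' @return Integer count.
#' @export
n_substituents <- function(mol) sum(mol$occupancy != "H")

#' Parse a Position-Substituent name
#'
#' Names are underscore-joined `<position>-<code>` tokens, e.g.
#' `"1-SH_3-F_8-OH"`. The empty string or `"parent"` denote the unsubstituted
#' scaffold. Unicode hyphen variants (as produced by PDF extraction) are
#' accepted and normalized to ASCII.
#'
#' @param name Position-Substituent string.
#' @inheritParams helicene
#' @return A `helicene`.
#' @export
#' @examples
#' parse_name("1-SH_3-F_8-OH")
#' parse_name("parent")
parse_name <- function(name, helicity = "P", max_substituents = 6L) {
  stopifnot(is.character(name), length(name) == 1L)
  # non-breaking / unicode hyphens seen in PDF-extracted names
  name <- gsub("[‐‑‒–—−]", "-", name)
  name <- trimws(name)
  occ <- rep("H", N_POSITIONS)
  if (!nzchar(name) || identical(name, "parent")) {
    return(helicene(occ, helicity, max_substituents))
  }
  tokens <- strsplit(name, "_", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([0-9]+)-(.+)$", tokens))
  seen <- integer(0)
  for (i in seq_along(tokens)) {
    if (length(m[[i]]) != 3L) {
      hel_error(paste0("malformed token: ", tokens[i]), "name_parse_error")
    }
    pos <- as.integer(m[[i]][2])
    code <- m[[i]][3]
    if (is.na(pos) || pos < 1L || pos > N_POSITIONS) {
      hel_error(paste0("position out of range 1..16: ", m[[i]][2]),
                "position_range_error")
    }
    if (pos %in% seen) {
      hel_error(paste0("duplicate position: ", pos), "duplicate_position_error")
    }
    if (!code %in% names(sigma_table())) {
      hel_error(paste0("unknown substituent code: ", code),
                "unknown_substituent_error")
    }
    seen <- c(seen, pos)
    occ[pos] <- code
  }
  helicene(occ, helicity, max_substituents)
}

#' Format a helicene as its canonical Position-Substituent name
#'
#' Tokens are emitted in ascending position order, so the name is a canonical
#' identifier: two occupancies are equal iff their names are equal. The parent
#' scaffold formats as `"parent"`.
#'
#' @param mol A `helicene`.
#' @return A single string; `parse_name(format_name(mol))` recovers `mol`.
#' @export
#' @examples
#' format_name(parse_name("3-F_1-SH")) # "1-SH_3-F"
format_name <- function(mol) {
  idx <- which(mol$occupancy != "H")
  if (!length(idx)) return("parent")
  paste(sprintf("%d-%s", idx, mol$occupancy[idx]), collapse = "_")
}

#' Encode a helicene as its Hammett descriptor vector
#'
#' The model representation: a length-16 numeric vector whose i-th entry is
#' the sigma_p of the substituent at position i (0 for H). Optionally an
#' integer code channel can be appended (positions 17..32) to break ties
#' between codes that share a sigma_p value; all defaults leave it off so the
#' representation is the pure electronic descriptor.
#'
#' @param mol A `helicene`.
#' @param sigma Descriptor table ([sigma_table()] by default).
#' @param code_channel If `TRUE`, append the per-position integer code index.
#' @return Numeric vector of length 16 (or 32 with the code channel).
#' @export
#' @examples
#' encode(parse_name("1-NO2"))[1] # 0.78
encode <- function(mol, sigma = sigma_table(), code_channel = FALSE) {
  missing <- setdiff(unique(mol$occupancy), names(sigma))
  if (length(missing)) {
    hel_error(paste0("no sigma_p entry for: ", paste(missing, collapse = ", ")),
              "descriptor_table_error")
  }
  v <- unname(sigma[mol$occupancy])
  if (code_channel) {
    v <- c(v, match(mol$occupancy, names(sigma)) - 1L)
  }
  v
}

#' Mirror a substitution pattern across the helicene's C2-like position pairing
#'
#' Swaps occupancy between paired positions i and 17 - i (1/16, 2/15, ...,
#' 8/9). A molecule equal to its mirror has the symmetric substitution
#' pattern that the symmetry-constrained design scenarios require. `mirror`
#' is an involution and preserves the substituent count.
#'
#' @param mol A `helicene`.
#' @return The mirrored `helicene` (helicity unchanged: this is a pattern
#'   symmetry operation, not an enantiomer flip).
#' @export
#' @examples
#' format_name(mirror(parse_name("1-SH"))) # "16-SH"
mirror <- function(mol) {
  helicene(rev(mol$occupancy), mol$helicity,
           max_substituents = N_POSITIONS)
}

#' Test whether a substitution pattern is mirror-symmetric
#' @param mol A `helicene`.
#' @return Logical.
#' @export
is_symmetric <- function(mol) identical(mol$occupancy, rev(mol$occupancy))
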