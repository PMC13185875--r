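#' Hammett sigma-para descriptor table
#'
#' The sole descriptor channel of the molecular representation: each
#' substituent is reduced to its para Hammett constant (electron donors
#' negative, acceptors positive, H exactly zero). The default table ships the
#' Hansch--Leo--Taft compilation values for the 16-group inventory (halogens;
#' electron donors NH2, OH, OMe, SH, SMe; acceptors NO2, CN, CHO, COOH;
#' carbon-based CH3, C#CH written `CCH`, C#C-Ph written `CCPh`) plus H.
#'
#' @param path Optional path to a CSV with columns `code,sigma_p` replacing
#'   the shipped table. The table must contain an `H` row with `sigma_p = 0`.
#' @return Named numeric vector mapping code to sigma_p.
#' @export
#' @examples
#' sigma_table()[["NO2"]] # 0.78
sigma_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("default_sigma", envir = .hel_cache)
    if (!is.null(cached)) return(cached)
  }
  default <- is.null(path)
  path <- path %||% system.file("extdata", "sigma_p.csv", package = "helidesign")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "sigma_p") %in% names(tab))) {
    hel_error("descriptor table must have columns code,sigma_p",
              "descriptor_table_error")
  }
  if (anyDuplicated(tab$code)) {
    hel_error("descriptor table has duplicate codes", "descriptor_table_error")
  }
  sig <- stats::setNames(as.numeric(tab$sigma_p), tab$code)
  if (!"H" %in% names(sig) || sig[["H"]] != 0) {
    hel_error("descriptor table must map H to 0", "descriptor_table_error")
  }
  if (default) assign("default_sigma", sig, envir = .hel_cache)
  sig
}

#' The 16 non-hydrogen substituent codes of the default inventory
#' @return Character vector of length 16.
#' @export
substituent_codes <- function() {
  setdiff(names(sigma_table()), "H")
}

#' Substituent family inventories
#'
#' The dataset is organized into six families: the four chemical groups
#' (halogens, electron donors, electron acceptors, carbon-based), a mixed
#' family taking one representative of each group (F, CN, OMe, C#CH), and the
#' full 16-substituent inventory.
#'
#' @param family One of `"halogen"`, `"EDG"`, `"EWG"`, `"carbon"`,
#'   `"mixed4"`, `"all16"`.
#' @return Character vector of allowed substituent codes.
#' @export
#' @examples
#' family_codes("mixed4")
family_codes <- function(family = c("halogen", "EDG", "EWG", "carbon",
                                    "mixed4", "all16")) {
  family <- match.arg(family)
  switch(family,
    halogen = c("F", "Cl", "Br", "I"),
    EDG     = c("NH2", "OH", "OMe", "SH", "SMe"),
    EWG     = c("NO2", "CN", "CHO", "COOH"),
    carbon  = c("CH3", "CCH", "CCPh"),
    mixed4  = c("F", "CN", "OMe", "CCH"),
    all16   = substituent_codes()
  )
}

#' Audit the descriptor table for sigma_p collisions
#'
#' Encoding by sigma_p alone is degenerate wherever two codes share a value
#' (e.g. SMe and H are both 0.00 in the default table): such molecules have
#' identical feature vectors although they are distinct chemical species.
#' Molecule identity is therefore always kept as the code sequence; this
#' audit reports which codes collide under a given table.
#'
#' @param sigma Descriptor table as returned by [sigma_table()].
#' @return A list of character vectors, one per colliding sigma_p value.
#' @export
sigma_degeneracies <- function(sigma = sigma_table()) {
  groups <- split(names(sigma), sigma)
  Filter(function(g) length(g) > 1, unname(groups))
}
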