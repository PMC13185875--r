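#' Transition dipole moments of an electronic transition
#'
#' Magnitudes of the electric and magnetic transition dipole moments and the
#' angle between the two vectors, in the conventional scaled cgs units used
#' throughout: `mu_abs` in 1e-18 esu cm (Debye-scale), `m_abs` in
#' 1e-20 erg G^-1 (Bohr-magneton scale).
#'
#' @param mu_abs Electric transition dipole magnitude (units of 1e-18 esu cm).
#' @param m_abs Magnetic transition dipole magnitude (units of 1e-20 erg G^-1).
#' @param theta Angle between the two vectors, radians, in `[0, pi]`.
#' @return An object of class `transition_moments`.
#' @export
transition_moments <- function(mu_abs, m_abs, theta) {
  if (mu_abs < 0 || m_abs < 0) {
    hel_error("moment magnitudes must be non-negative", "value_error")
  }
  if (theta < 0 || theta > pi) {
    hel_error("theta must lie in [0, pi]", "value_error")
  }
  structure(list(mu_abs = mu_abs, m_abs = m_abs, theta = theta),
            class = "transition_moments")
}

# scale factors from the stored units to absolute cgs
MU_UNIT <- 1e-18
M_UNIT <- 1e-20

#' Absorption dissymmetry factor from transition moments
#'
#' Evaluates the two-vector expression for the dissymmetry factor of an
#' absorbing transition in an isotropic sample,
#' \deqn{g_{abs} = \frac{4 |m| |\mu| \cos\theta}{|\mu|^2 + |m|^2},}
#' with both magnitudes first converted from their scaled storage units to
#' absolute cgs. The result is bounded by +/-2, the pure left/right
#' circularly polarized limit, attained exactly when the absolute magnitudes
#' are equal and the vectors are (anti)parallel. Typical organic
#' chromophores sit three orders of magnitude apart in |m| and |mu|, hence
#' the usual g ~ 1e-3..1e-4 regime.
#'
#' @param t A [transition_moments()] object.
#' @return Dimensionless g, in `[-2, 2]`.
#' @export
#' @examples
#' g_from_moments(transition_moments(mu_abs = 0.01, m_abs = 1, theta = 0)) # 2
g_from_moments <- function(t) {
  stopifnot(inherits(t, "transition_moments"))
  if (t$mu_abs == 0 && t$m_abs == 0) {
    hel_error("both transition moments are zero: g undefined",
              "degenerate_transition_error")
  }
  # work in units of MU_UNIT (factor out 1e-18 from numerator and
  # denominator): numerically stable and exact in the matched-moment case
  m_scaled <- t$m_abs * (M_UNIT / MU_UNIT)
  4 * m_scaled * t$mu_abs * cos(t$theta) / (t$mu_abs^2 + m_scaled^2)
}

PROPERTY_NAMES <- c("R_plus", "R_minus", "R_1", "lambda_plus", "lambda_minus",
                    "lambda_1", "m_abs", "mu_abs", "g_abs")

#' Bundle the nine target properties of a helicene
#'
#' Rotatory strengths (1e-40 esu cm erg G^-1) and wavelengths (nm) of the
#' maximum positive band, the maximum negative band and the lowest-energy
#' transition, the S0->S1 transition moment magnitudes (scaled cgs units as
#' in [transition_moments()]) and the S0->S1 absorption dissymmetry factor.
#'
#' @param R_plus,R_minus,R_1 Rotatory strengths; `R_plus >= 0`,
#'   `R_minus <= 0` by definition of maximum positive/negative band.
#' @param lambda_plus,lambda_minus,lambda_1 Wavelengths (nm), positive.
#' @param m_abs,mu_abs S0->S1 moment magnitudes, non-negative.
#' @param g_abs Dissymmetry factor, `|g_abs| <= 2`.
#' @return An object of class `property_record` (a named numeric vector).
#' @export
property_record <- function(R_plus, R_minus, R_1, lambda_plus, lambda_minus,
                            lambda_1, m_abs, mu_abs, g_abs) {
  rec <- c(R_plus = R_plus, R_minus = R_minus, R_1 = R_1,
           lambda_plus = lambda_plus, lambda_minus = lambda_minus,
           lambda_1 = lambda_1, m_abs = m_abs, mu_abs = mu_abs, g_abs = g_abs)
  validate_record(rec)
  structure(rec, class = "property_record")
}

validate_record <- function(rec, where = "") {
  msg <- function(s) hel_error(paste0(s, where), "validation_error")
  if (any(!is.finite(rec))) msg("non-finite property value")
  if (rec[["R_plus"]] < 0) msg("R_plus must be >= 0")
  if (rec[["R_minus"]] > 0) msg("R_minus must be <= 0")
  lam <- rec[c("lambda_plus", "lambda_minus", "lambda_1")]
  if (any(lam <= 0)) msg("wavelengths must be positive")
  if (rec[["m_abs"]] < 0 || rec[["mu_abs"]] < 0) msg("moment magnitudes must be >= 0")
  if (abs(rec[["g_abs"]]) > 2) msg("|g_abs| must not exceed 2")
  invisible(rec)
}

#' Property record of the opposite enantiomer
#'
#' All chiroptical signs invert between the P and M enantiomers while
#' magnitudes and wavelengths are unchanged. The negated maximum-positive
#' band of one enantiomer is the maximum-negative band of the other, so the
#' R_plus/R_minus roles (and their wavelengths) swap, preserving the sign
#' invariants; R_1 and g_abs simply change sign. Applying the flip twice is
#' the identity.
#'
#' @param rec A [property_record()].
#' @return The flipped `property_record`.
#' @export
enantiomer_flip <- function(rec) {
  stopifnot(inherits(rec, "property_record"))
  property_record(
    R_plus = -rec[["R_minus"]],
    R_minus = -rec[["R_plus"]],
    R_1 = -rec[["R_1"]],
    lambda_plus = rec[["lambda_minus"]],
    lambda_minus = rec[["lambda_plus"]],
    lambda_1 = rec[["lambda_1"]],
    m_abs = rec[["m_abs"]],
    mu_abs = rec[["mu_abs"]],
    g_abs = -rec[["g_abs"]]
  )
}

#' Synthesize an ECD curve from discrete transitions
#'
#' Renders a stick spectrum (wavelength, rotatory strength pairs) as a
#' continuous curve by summing Gaussian line shapes centred at each
#' transition, amplitude proportional to its rotatory strength. Purely a
#' rendering aid (the model predicts band descriptors, not full spectra);
#' Gaussian broadening in wavelength space with a 15 nm default width.
#'
#' @param transitions Data frame with columns `wavelength_nm`, `R`.
#' @param width_nm Gaussian standard deviation in nm (> 0).
#' @param grid Wavelength grid (nm) to sample on.
#' @return Data frame with columns `wavelength_nm`, `delta_epsilon` (arbitrary
#'   units); the zero curve for an empty transition list.
#' @export
ecd_curve <- function(transitions, width_nm = 15,
                      grid = seq(200, 700, by = 1)) {
  stopifnot(width_nm > 0, length(grid) >= 1)
  y <- numeric(length(grid))
  if (nrow(transitions)) {
    if (any(transitions$wavelength_nm <= 0)) {
      hel_error("transition wavelengths must be positive", "validation_error")
    }
    for (i in seq_len(nrow(transitions))) {
      y <- y + transitions$R[i] *
        exp(-0.5 * ((grid - transitions$wavelength_nm[i]) / width_nm)^2)
    }
  }
  data.frame(wavelength_nm = grid, delta_epsilon = y)
}
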