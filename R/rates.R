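# Rate laws of the six-state model. y1 biomass (g dry cells/100 g), y2
# total protein and y3 nonprotein nitrogen (both g N/100 g), y4 lactic
# acid, y5 formic acid, y6 glucose (g/100 g); time in hours.

#' State vector of the fermentation model
#'
#' @param y1,y2,y3,y4,y5,y6 state values (see package docs for units);
#'   all must be nonnegative.
#' @param t time (hr), nonnegative.
#' @return Named numeric vector `c(y1..y6, t)` of class `state_vector`.
#' @examples
#' state_vector(y1 = 0.004, y2 = 0.563, y3 = 0.109, t = 0)
#' @export
state_vector <- function(y1 = 0, y2 = 0, y3 = 0, y4 = 0, y5 = 0, y6 = 0, t = 0) {
  x <- c(y1 = y1, y2 = y2, y3 = y3, y4 = y4, y5 = y5, y6 = y6, t = t)
  if (any(x < 0)) stop("state values and time must be nonnegative")
  structure(x, class = "state_vector")
}

#' Lag-phase factor
#'
#' The initial adjustment period is modelled as the multiplicative factor
#' `1 - exp(-k3*t)`, which rises monotonically from 0 at inoculation
#' towards 1 as the culture leaves the lag phase.
#'
#' @param t time (hr), nonnegative.
#' @param k3 lag-decay rate (1/hr), strictly positive.
#' @return Dimensionless factor in `[0, 1)`.
#' @examples
#' lag_factor(24, 0.141)
#' @export
lag_factor <- function(t, k3) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (length(k3) != 1 || k3 <= 0) stop("k3 must be a single positive rate")
  1 - exp(-k3 * t)
}

#' Biomass growth rate dy1/dt
#'
#' Monod growth on total protein, damped by the lag factor and by a
#' logistic bracket `(1 - y1/y1_max)`, minus first-order cell lysis:
#' `dy1 = (1 - exp(-k3 t)) * k1 y2/(k2 + y2) * y1 (1 - y1/y1_max) - k12 y1`.
#' When `y1` exceeds `y1_max` (solver overshoot or noisy data) the bracket
#' goes negative and self-corrects; a warning is emitted beyond tolerance.
#'
#' @param state a [state_vector()] (its `t` element supplies the time).
#' @param params a [ferm_params()] set.
#' @return dy1/dt (g/100 g/hr).
#' @export
biomass_rate <- function(state, params) {
  p <- as_ferm_params(params)
  y1 <- state[["y1"]]; y2 <- state[["y2"]]; t <- state[["t"]]
  if (y1 > p[["y1_max"]] * (1 + 1e-9))
    warning("y1 exceeds y1_max; logistic bracket is negative")
  # k3 = 0 denotes a never-ending lag (no growth), so bypass the
  # positivity check of the user-facing lag_factor()
  lag <- if (p[["k3"]] > 0) lag_factor(t, p[["k3"]]) else 0
  lag * p[["k1"]] * y2 / (p[["k2"]] + y2) *
    y1 * (1 - y1 / p[["y1_max"]]) - p[["k12"]] * y1
}

#' Coupled protein and nonprotein-nitrogen rates (dy2/dt, dy3/dt)
#'
#' Total protein nitrogen is consumed by biomass formation, by NPN
#' release, and by a first-order loss term:
#' `dy2 = -[cor_bio*frac_bio*dy1 + cor_NPN*frac_npn*dy3] - cor_X*y2`,
#' while NPN follows the Luedeking-Piret law `dy3 = -k4*dy2 + k5*y2`.
#' The two equations are linear in `(dy2, dy3)` and are solved in closed
#' form by substitution; the denominator `1 - cor_NPN*frac_npn*k4` must be
#' nonzero.
#'
#' @inheritParams biomass_rate
#' @param dy1 the biomass rate, already evaluated.
#' @param stoich a [stoichiometry()] object.
#' @return Named numeric `c(dy2, dy3)` (g N/100 g/hr).
#' @export
protein_npn_rates <- function(state, dy1, params, stoich = stoichiometry()) {
  p <- as_ferm_params(params)
  a <- p[["cor_bio"]] * stoich$frac_bio
  b <- p[["cor_NPN"]] * stoich$frac_npn
  den <- 1 - b * p[["k4"]]
  if (abs(den) < 1e-12)
    stop("singular protein/NPN coupling: cor_NPN*frac_npn*k4 equals 1 ",
         "(cor_NPN = ", p[["cor_NPN"]], ", k4 = ", p[["k4"]], ")")
  y2 <- state[["y2"]]
  dy2 <- -(a * dy1 + b * p[["k5"]] * y2 + p[["cor_X"]] * y2) / den
  dy3 <- -p[["k4"]] * dy2 + p[["k5"]] * y2
  c(dy2 = dy2, dy3 = dy3)
}

#' Lactic acid rate dy4/dt
#'
#' Luedeking-Piret form with product saturation:
#' `dy4 = k6*dy1 + k7*(1 - y4/y4_max)`.
#'
#' @inheritParams protein_npn_rates
#' @return dy4/dt (g/100 g/hr).
#' @export
lactate_rate <- function(state, dy1, params) {
  p <- as_ferm_params(params)
  p[["k6"]] * dy1 + p[["k7"]] * (1 - state[["y4"]] / p[["y4_max"]])
}

#' Formic acid rate dy5/dt
#'
#' Hetero-fermentative by-product formation:
#' `dy5 = k8*dy1 + k9*(1 - y5/y5_max)`.
#'
#' @inheritParams protein_npn_rates
#' @return dy5/dt (g/100 g/hr).
#' @export
formate_rate <- function(state, dy1, params) {
  p <- as_ferm_params(params)
  p[["k8"]] * dy1 + p[["k9"]] * (1 - state[["y5"]] / p[["y5_max"]])
}

#' Glucose uptake rate dy6/dt
#'
#' Glucose is consumed for biomass formation and for lactic acid
#' synthesis, the latter damped as lactate approaches its saturation
#' level: `dy6 = -k10*dy1 - k11*(1 - y4/y4_max)`.
#'
#' @inheritParams protein_npn_rates
#' @return dy6/dt (g/100 g/hr).
#' @export
glucose_rate <- function(state, dy1, params) {
  p <- as_ferm_params(params)
  -p[["k10"]] * dy1 - p[["k11"]] * (1 - state[["y4"]] / p[["y4_max"]])
}

#' Full right-hand side of the six-state model
#'
#' Assembles the component rate laws into the derivative vector
#' `(dy1..dy6)`, evaluating the biomass rate once and reusing it in the
#' coupled equations. Pure function of its arguments.
#'
#' @param t time (hr).
#' @param y numeric length-6 state `(y1..y6)`.
#' @param params a [ferm_params()] set.
#' @param stoich a [stoichiometry()] object.
#' @return Named numeric length-6 derivative vector.
#' @examples
#' ferm_rhs(12, c(0.004, 0.563, 0.109, 0, 0, 2.5), batch_params("control"))
#' @export
ferm_rhs <- function(t, y, params, stoich = stoichiometry()) {
  st <- c(y1 = y[[1]], y2 = y[[2]], y3 = y[[3]],
          y4 = y[[4]], y5 = y[[5]], y6 = y[[6]], t = t)
  dy1 <- biomass_rate(st, params)
  d23 <- protein_npn_rates(st, dy1, params, stoich)
  c(dy1 = dy1, dy2 = d23[["dy2"]], dy3 = d23[["dy3"]],
    dy4 = lactate_rate(st, dy1, params),
    dy5 = formate_rate(st, dy1, params),
    dy6 = glucose_rate(st, dy1, params))
}
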