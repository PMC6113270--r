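#' Sulfide toxicity response
#'
#' Piecewise-linear approximation of the sulfide toxicity curve: no effect
#' below `S_min`, a linear ramp between `S_min` and `S_max`, full effect
#' above `S_max`. Continuous and non-decreasing in `S`.
#'
#' @param S Pore-water sulfide concentration, umol L^-1 (vectorised).
#' @param p A [seagrass_params()] object.
#' @return The toxic fraction in `[0, 1]`, same length as `S`.
#' @examples
#' toxicity_fraction(c(100, 600, 1000, 5000), seagrass_params())
#' @export
toxicity_fraction <- function(S, p = seagrass_params()) {
  p <- as_seagrass_params(p)
  if (any(!is.finite(S))) stop("S must be finite")
  if (any(S < 0)) stop("S must be non-negative")
  pmin(1, pmax(0, (S - p$S_min) / (p$S_max - p$S_min)))
}

#' Seagrass mortality flux
#'
#' Total per-area loss of shoots: sulfide-driven mortality `m_s * fS(S) * Z`
#' plus natural background mortality `m_n * Z`. Linear in `Z` at fixed `S`.
#'
#' @param Z Shoot density, shoots m^-2 (vectorised with `S`).
#' @param S Pore-water sulfide concentration, umol L^-1.
#' @param p A [seagrass_params()] object.
#' @return Mortality flux, shoots m^-2 day^-1.
#' @examples
#' mortality_flux(8000, 0, seagrass_params())   # background loss only
#' @export
mortality_flux <- function(Z, S, p = seagrass_params()) {
  p <- as_seagrass_params(p)
  if (any(!is.finite(Z)) || any(!is.finite(S))) stop("Z and S must be finite")
  if (any(Z < 0)) stop("Z must be non-negative")
  (p$m_s * toxicity_fraction(S, p) + p$m_n) * Z
}

#' Model state vector
#'
#' Builds a named, validated state vector `(Z, S, OM, L)`.
#'
#' @param Z Shoot density, shoots m^-2.
#' @param S Pore-water sulfide, umol L^-1.
#' @param OM Sediment organic matter, percent.
#' @param L *Loripes* density, ind m^-2.
#' @return Named numeric vector of length 4.
#' @export
model_state <- function(Z = 0, S = 0, OM = 0, L = 0) {
  s <- c(Z = unname(Z), S = unname(S), OM = unname(OM), L = unname(L))
  if (any(!is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be non-negative")
  s
}

#' Right-hand side of the model
#'
#' The time derivatives of the four state variables:
#' \deqn{dZ/dt = r (1 - Z/Z_{max}) Z - (m_s fS(S) + m_n) Z}
#' \deqn{dS/dt = C_{om} OM - C_s L S - e_s S}
#' \deqn{dOM/dt = C_z (m_s fS(S) + m_n) Z - e_m OM}
#' \deqn{dL/dt = r_L (Z/Z_{max}) (1 - L/L_{max}) - m_L L}
#' With `mutualism = FALSE` the bivalve equation is frozen (`dL/dt = 0`);
#' runs without the mutualism start from `L = 0`, so the sulfide-uptake sink
#' `C_s L S` vanishes entirely.
#'
#' This is the pure-R reference implementation of the vector field; the
#' integrator uses a compiled copy of the same equations for speed, and the
#' two are required (and tested) to agree.
#'
#' @param state Named non-negative state vector, see [model_state()].
#' @param p A [seagrass_params()] object.
#' @param mutualism Logical: is the bivalve equation active?
#' @return Named numeric vector `(Z, S, OM, L)` of derivatives, units per day.
#' @examples
#' model_rhs(model_state(Z = 80), seagrass_params())
#' @export
model_rhs <- function(state, p = seagrass_params(), mutualism = TRUE) {
  p <- as_seagrass_params(p)
  if (any(!is.finite(state))) stop("state must be finite")
  if (any(state < 0)) stop("state must be non-negative")
  Z <- state[["Z"]]; S <- state[["S"]]; OM <- state[["OM"]]; L <- state[["L"]]
  mort <- (p$m_s * toxicity_fraction(S, p) + p$m_n) * Z
  dZ <- p$r * (1 - Z / p$Z_max) * Z - mort
  dS <- p$C_om * OM - p$C_s * L * S - p$e_s * S
  dOM <- p$C_z * mort - p$e_m * OM
  dL <- if (isTRUE(mutualism)) {
    p$r_L * (Z / p$Z_max) * (1 - L / p$L_max) - p$m_L * L
  } else 0
  c(Z = dZ, S = dS, OM = dOM, L = dL)
}

#' Algebraic high-seagrass fixed point
#'
#' The non-toxic equilibrium of the mutualism model, solved in closed form
#' under the assumption `fS = 0` (sulfide below the toxicity onset):
#' `Z* = Z_max (1 - m_n / r)`, `OM* = C_z m_n Z* / e_m`, `L*` from the
#' bivalve equation, `S* = C_om OM* / (C_s L* + e_s)`. The assumption is
#' checked and the function fails if the implied `S*` is not below `S_min`
#' (in which case no non-toxic equilibrium exists at these parameters).
#'
#' @param p A [seagrass_params()] object.
#' @return Named state vector at equilibrium.
#' @examples
#' high_fixed_point(seagrass_params())  # c(Z = 7840, S = 61.9, ...)
#' @export
high_fixed_point <- function(p = seagrass_params()) {
  p <- as_seagrass_params(p)
  if (p$m_n >= p$r) stop("no vegetated equilibrium: m_n >= r")
  Zs <- p$Z_max * (1 - p$m_n / p$r)
  OMs <- p$C_z * p$m_n * Zs / p$e_m
  # r_L (Z*/Z_max)(1 - L/L_max) = m_L L
  g <- p$r_L * Zs / p$Z_max
  Ls <- g / (g / p$L_max + p$m_L)
  Ss <- p$C_om * OMs / (p$C_s * Ls + p$e_s)
  if (Ss >= p$S_min)
    stop("fixed point with fS = 0 does not close: S* = ", signif(Ss, 4),
         " >= S_min; the non-toxic equilibrium does not exist here")
  c(Z = Zs, S = Ss, OM = OMs, L = Ls)
}
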