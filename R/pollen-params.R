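#' Physical parameters of the pollen / sub-pollen particle system
#'
#' All physical constants of the ryegrass pollen and SPP system. Defaults:
#' whole grains are 35 um spheres of density 1000 kg m^-3 with per-grain mass
#' `m_pol = 22.4e-9` g; SPPs are 600 nm spheres of the same density with mass
#' `m_spp = 1.13e-13` g; each ruptured grain releases `n_spg = 700` SPPs and
#' leaves one empty shell; the rupturing fraction is `f_rupt = 0.7`. Rupture
#' triggers: relative humidity at or above 80 % (osmotic), at or below 30 %
#' (static electricity), wind-speed threshold 5 m s^-1, and a minimum airborne
#' concentration of 1 grain m^-3 for in-atmosphere rupture.
#'
#' At construction, `m_pol` and `m_spp` are checked against the sphere-volume
#' mass `pi/6 * d^3 * rho` of their respective diameters: each must agree to
#' within 1 %.
#'
#' @param d_pol Whole-grain diameter, m.
#' @param d_spp SPP diameter, m.
#' @param density Particle density, kg m^-3 (shared by grain and SPP).
#' @param m_pol Mass of one whole grain, g.
#' @param m_spp Mass of one SPP, g.
#' @param n_spg SPPs released per ruptured grain, >= 1.
#' @param f_rupt Fraction of available grains that rupture per event, (0, 1].
#' @param rh_high_threshold Humidity-rupture threshold, %RH (rupture at RH >=).
#' @param rh_low_threshold Static-electricity threshold, %RH (rupture at RH <=).
#' @param ws_threshold Wind-speed rupture threshold, m s^-1.
#' @param min_grains Minimum whole-pollen concentration for in-atmosphere
#'   rupture, grains m^-3.
#' @return A `pollen_params` object.
#' @export
#' @examples
#' p <- pollen_params()
#' mass_to_grains(0.0224, p)  # 1 grain m^-3
pollen_params <- function(d_pol = 35e-6,
                          d_spp = 600e-9,
                          density = 1000,
                          m_pol = 22.4e-9,
                          m_spp = 1.13e-13,
                          n_spg = 700,
                          f_rupt = 0.7,
                          rh_high_threshold = 80,
                          rh_low_threshold = 30,
                          ws_threshold = 5,
                          min_grains = 1) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a finite scalar", nm), call. = FALSE)
    }
    x
  }
  for (nm in c("d_pol", "d_spp", "density", "m_pol", "m_spp")) {
    if (num1(get(nm), nm) <= 0) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  num1(n_spg, "n_spg"); num1(f_rupt, "f_rupt")
  num1(rh_high_threshold, "rh_high_threshold")
  num1(rh_low_threshold, "rh_low_threshold")
  num1(ws_threshold, "ws_threshold"); num1(min_grains, "min_grains")
  if (n_spg < 1) stop("`n_spg` must be >= 1", call. = FALSE)
  if (f_rupt <= 0 || f_rupt > 1) stop("`f_rupt` must be in (0, 1]", call. = FALSE)
  if (min_grains < 0) stop("`min_grains` must be >= 0", call. = FALSE)
  # consistency: stated masses vs sphere-volume masses, 1% tolerance
  for (pair in list(c(m_pol, d_pol, "m_pol"), c(m_spp, d_spp, "m_spp"))) {
    m_stated <- as.numeric(pair[[1]]); d <- as.numeric(pair[[2]])
    m_sphere <- sphere_mass(d, density)
    if (abs(m_stated - m_sphere) / m_sphere > 0.01) {
      stop(sprintf(
        "`%s` (%.4g g) disagrees with sphere mass of its diameter (%.4g g) by more than 1%%",
        pair[[3]], m_stated, m_sphere), call. = FALSE)
    }
  }
  structure(
    list(d_pol = d_pol, d_spp = d_spp, density = density,
         m_pol = m_pol, m_spp = m_spp, n_spg = n_spg, f_rupt = f_rupt,
         rh_high_threshold = rh_high_threshold,
         rh_low_threshold = rh_low_threshold,
         ws_threshold = ws_threshold, min_grains = min_grains),
    class = "pollen_params"
  )
}

#' @export
print.pollen_params <- function(x, ...) {
  cat("<pollen_params>\n")
  cat(sprintf("  grain: d = %.3g um, m = %.3g g;  SPP: d = %.3g nm, m = %.3g g\n",
              x$d_pol * 1e6, x$m_pol, x$d_spp * 1e9, x$m_spp))
  cat(sprintf("  density %.4g kg/m^3, n_spg %g, f_rupt %g\n",
              x$density, x$n_spg, x$f_rupt))
  cat(sprintf("  thresholds: RH >= %g%%, RH <= %g%%, WS >= %g m/s, chi >= %g grains/m^3\n",
              x$rh_high_threshold, x$rh_low_threshold, x$ws_threshold,
              x$min_grains))
  invisible(x)
}

#' Mass of a sphere
#'
#' `pi/6 * d^3 * rho`, returned in grams. Used for the consistency check
#' between stated per-particle masses and the diameter/density they derive
#' from.
#'
#' @param diameter Diameter, m.
#' @param density Density, kg m^-3.
#' @return Mass in g.
#' @export
sphere_mass <- function(diameter, density) {
  stopifnot(is.numeric(diameter), is.numeric(density))
  if (any(diameter <= 0) || any(density <= 0)) {
    stop("diameter and density must be positive", call. = FALSE)
  }
  pi / 6 * diameter^3 * density * 1000  # kg -> g
}

#' Convert pollen mass concentration to grain number concentration
#'
#' Tracers carry pollen as a mass concentration (ug m^-3); rupture laws act on
#' grain counts. 1 grain m^-3 corresponds to 0.0224 ug m^-3 at the default
#' grain mass.
#'
#' @param mass_conc Mass concentration, ug m^-3, non-negative. Vectorised.
#' @param params A [pollen_params()] object.
#' @return Grain number concentration, grains m^-3.
#' @export
mass_to_grains <- function(mass_conc, params = pollen_params()) {
  stopifnot(inherits(params, "pollen_params"), is.numeric(mass_conc))
  if (any(mass_conc < 0, na.rm = TRUE)) {
    stop("`mass_conc` must be non-negative", call. = FALSE)
  }
  mass_conc / (params$m_pol * 1e6)  # m_pol g -> ug
}

#' Convert grain number concentration to mass concentration
#'
#' Exact inverse of [mass_to_grains()].
#'
#' @param grains Grain number concentration, grains m^-3, non-negative.
#' @inheritParams mass_to_grains
#' @return Mass concentration, ug m^-3.
#' @export
grains_to_mass <- function(grains, params = pollen_params()) {
  stopifnot(inherits(params, "pollen_params"), is.numeric(grains))
  if (any(grains < 0, na.rm = TRUE)) {
    stop("`grains` must be non-negative", call. = FALSE)
  }
  grains * (params$m_pol * 1e6)
}
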