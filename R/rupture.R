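#' Rupture tendency record
#'
#' Internal constructor shared by the in-atmosphere rupture laws. Applies the
#' cap policy (`n_rupt <= chi`, so the grain inventory can never go negative)
#' and the per-grain bookkeeping: one empty shell per ruptured grain, `n_spg`
#' SPPs per grain, SPP mass `spp_number * m_spp`.
#'
#' All fields are vectorised over the input shape (scalars, vectors or
#' arrays): `n_rupt` (grains m^-3), `n_rupt_uncapped` (diagnostic),
#' `spp_number` (m^-3), `spp_mass` (ug m^-3), `pollen_mass_loss` (ug m^-3,
#' the mass that leaves the whole-pollen tracer in `"spp_mass"` mode).
#'
#' @param n_rupt_uncapped Raw mechanism output, grains m^-3.
#' @param chi Available whole-pollen concentration, grains m^-3.
#' @param params A [pollen_params()] object.
#' @return A `rupture_tendency` object.
#' @keywords internal
new_rupture_tendency <- function(n_rupt_uncapped, chi, params) {
  n_rupt <- pmin(n_rupt_uncapped, chi)
  spp_number <- n_rupt * params$n_spg
  spp_mass <- spp_number * params$m_spp * 1e6  # g -> ug
  structure(
    list(n_rupt = n_rupt,
         n_rupt_uncapped = n_rupt_uncapped,
         spp_number = spp_number,
         spp_mass = spp_mass,
         pollen_mass_loss = spp_mass),
    class = "rupture_tendency"
  )
}

#' @export
print.rupture_tendency <- function(x, ...) {
  cat(sprintf("<rupture_tendency> total n_rupt = %.4g grains/m^3, SPP mass = %.4g ug/m^3\n",
              sum(x$n_rupt), sum(x$spp_mass)))
  invisible(x)
}

#' Summarise a rupture tendency as a tibble
#'
#' @param x A `rupture_tendency`.
#' @param ... Unused.
#' @return One row per element with `n_rupt`, `n_rupt_uncapped`,
#'   `spp_number`, `spp_mass`.
#' @method tidy rupture_tendency
#' @export
tidy.rupture_tendency <- function(x, ...) {
  tibble::tibble(
    n_rupt = as.vector(x$n_rupt),
    n_rupt_uncapped = as.vector(x$n_rupt_uncapped),
    spp_number = as.vector(x$spp_number),
    spp_mass = as.vector(x$spp_mass)
  )
}

check_chi <- function(chi) {
  if (!is.numeric(chi) || any(chi < 0, na.rm = TRUE)) {
    stop("`chi` must be a non-negative numeric", call. = FALSE)
  }
}

#' Humidity / static-electricity threshold rupture
#'
#' The threshold in-atmosphere rupture law `N_rupt = F_rupt * chi`, triggered
#' where the threshold condition holds and at least `min_grains` grains m^-3
#' are present. `mode = "high"` is osmotic rupture at RH at or above the high
#' threshold (80 % default); `mode = "low"` is the static-electricity
#' hypothesis, rupturing at RH at or below the low threshold (30 % default).
#'
#' @param chi Whole-pollen concentration, grains m^-3 (vectorised).
#' @param rh Relative humidity, %RH, same shape as `chi` (or scalar).
#' @param mode `"high"` or `"low"`.
#' @param params A [pollen_params()] object.
#' @return A `rupture_tendency`.
#' @export
#' @examples
#' rupture_rh_threshold(100, rh = 85, mode = "high")$n_rupt  # 70
rupture_rh_threshold <- function(chi, rh, mode = c("high", "low"),
                                 params = pollen_params()) {
  mode <- match.arg(mode)
  check_chi(chi)
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    stop("`rh` must lie in [0, 100]", call. = FALSE)
  }
  triggered <- if (mode == "high") rh >= params$rh_high_threshold
               else rh <= params$rh_low_threshold
  active <- triggered & (chi >= params$min_grains)
  new_rupture_tendency(params$f_rupt * chi * as.numeric(active), chi, params)
}

#' Wind-function in-atmosphere rupture
#'
#' `N_rupt = F_rupt * chi * f_WS(WS)`: the wind-speed activity function
#' modulates the rupture fraction with no wind threshold, so some rupture
#' occurs even at calm (f_WS floor 0.33). The minimum-concentration gate
#' still applies (see `gate`).
#'
#' @inheritParams rupture_rh_threshold
#' @param ws Wind speed, m s^-1 (vectorised).
#' @param act An [activity_params()] object.
#' @param gate Apply the `min_grains` gate (`TRUE`, default, consistent with
#'   the other in-atmosphere laws) or not (`FALSE`, threshold-law-only gate).
#' @return A `rupture_tendency`.
#' @export
rupture_fws <- function(chi, ws, act = activity_params(),
                        params = pollen_params(), gate = TRUE) {
  check_chi(chi)
  active <- if (gate) chi >= params$min_grains else rep(TRUE, length(chi))
  new_rupture_tendency(
    params$f_rupt * chi * f_ws(ws, act) * as.numeric(active), chi, params)
}

#' Wind-threshold in-atmosphere rupture
#'
#' `N_rupt = F_rupt * chi * WS` applied only at wind speeds at or above the
#' threshold (`ws_threshold`, 5 m s^-1 default), so rupture is restricted to
#' genuinely windy conditions. Because the wind-speed multiplier is unbounded
#' the raw product can exceed the available grains; the cap policy limits
#' `n_rupt` to `chi` (the uncapped value is kept as a diagnostic).
#'
#' @inheritParams rupture_fws
#' @return A `rupture_tendency`.
#' @export
rupture_ws <- function(chi, ws, params = pollen_params(), gate = TRUE) {
  check_chi(chi)
  if (any(!is.finite(ws)) || any(ws < 0)) {
    stop("`ws` must be non-negative", call. = FALSE)
  }
  active <- (ws >= params$ws_threshold) &
    (if (gate) chi >= params$min_grains else TRUE)
  new_rupture_tendency(params$f_rupt * chi * ws * as.numeric(active),
                       chi, params)
}

#' Lightning-count in-atmosphere rupture
#'
#' `N_rupt = F_rupt * chi * n_lightning`: rupture is triggered only in cells
#' where lightning occurred and whole pollen is present, and is stronger the
#' more strikes the cell-hour received. Capped at `chi`.
#'
#' @inheritParams rupture_fws
#' @param n_lightning Integer count of lightning occurrences per cell-hour
#'   (vectorised, >= 0).
#' @return A `rupture_tendency`.
#' @export
rupture_lightning <- function(chi, n_lightning, params = pollen_params(),
                              gate = TRUE) {
  check_chi(chi)
  if (any(!is.finite(n_lightning)) || any(n_lightning < 0) ||
      any(abs(n_lightning - round(n_lightning)) > 1e-8)) {
    stop("`n_lightning` must be a non-negative integer count", call. = FALSE)
  }
  active <- if (gate) chi >= params$min_grains else rep(TRUE, length(chi))
  new_rupture_tendency(
    params$f_rupt * chi * n_lightning * as.numeric(active), chi, params)
}

#' Apply a rupture tendency to tracer values
#'
#' Bookkeeping of an in-atmosphere rupture event: one empty shell is produced
#' per ruptured grain, `n_spg` SPPs per grain are added to the SPP mass
#' tracer, and mass is removed from the whole-pollen tracer. In the default
#' `"spp_mass"` mode only the SPP mass produced leaves the whole-pollen
#' tracer (the shell's mass implicitly remains there, ~99.65 % of the grain);
#' in `"full_grain"` mode the entire grain mass of the ruptured grains is
#' removed.
#'
#' Updates are clipped at zero (a warning is emitted rather than an error, so
#' a long run never aborts mid-step).
#'
#' @param state_cell List (or list of arrays) with elements `pollen_mass`
#'   (ug m^-3), `spp_mass` (ug m^-3), `shell_number` (m^-3).
#' @param tend A `rupture_tendency` of matching shape.
#' @param params A [pollen_params()] object.
#' @param mass_loss_mode `"spp_mass"` (default) or `"full_grain"`.
#' @return The updated state list.
#' @export
#' @examples
#' st <- list(pollen_mass = 0.0224, spp_mass = 0, shell_number = 0)
#' tend <- rupture_rh_threshold(1, rh = 90, mode = "high")
#' apply_rupture(st, tend)
apply_rupture <- function(state_cell, tend, params = pollen_params(),
                          mass_loss_mode = c("spp_mass", "full_grain")) {
  mass_loss_mode <- match.arg(mass_loss_mode)
  stopifnot(inherits(tend, "rupture_tendency"))
  loss <- switch(mass_loss_mode,
                 spp_mass = tend$pollen_mass_loss,
                 full_grain = tend$n_rupt * params$m_pol * 1e6)
  new_pollen <- state_cell$pollen_mass - loss
  if (any(new_pollen < -1e-12 * max(state_cell$pollen_mass, 1))) {
    warning("rupture would drive whole-pollen mass negative; clipped to zero",
            call. = FALSE)
  }
  state_cell$pollen_mass <- pmax(new_pollen, 0)
  state_cell$spp_mass <- state_cell$spp_mass + tend$spp_mass
  state_cell$shell_number <- state_cell$shell_number + tend$n_rupt
  state_cell
}

#' On-plant mechanical rupture emission flux
#'
#' Surface emission of SPP mass from pollen retained on the plant:
#' `M_rupt = F_rupt * n_spg * P_fx * G * (m_spp / m_pol)`, g m^-2 s^-1,
#' where `P_fx` is the whole-pollen emission rate and the retained-fraction
#' term `G` depends on the variant: `(1 - f_PR * f_RH)` for moisture-driven
#' rupture (`"rh"`), `f_WS` for the wind-function variant (`"fws"`), or the
#' raw wind speed for the wind variant (`"ws"`, applied at or above the wind
#' threshold only).
#'
#' @param p_fx Whole-pollen emission rate, g m^-2 s^-1 (vectorised).
#' @param rh,pr,ws Surface relative humidity (%), precipitation (mm h^-1) and
#'   wind speed (m s^-1); whichever the variant needs.
#' @param act An [activity_params()] object.
#' @param params A [pollen_params()] object.
#' @param variant `"rh"`, `"fws"` or `"ws"`.
#' @return SPP mass emission flux, g m^-2 s^-1, same shape as `p_fx`.
#' @export
mech_rupture <- function(p_fx, rh = NULL, pr = NULL, ws = NULL,
                         act = activity_params(), params = pollen_params(),
                         variant = c("rh", "fws", "ws")) {
  variant <- match.arg(variant)
  if (!is.numeric(p_fx) || any(p_fx < 0, na.rm = TRUE)) {
    stop("`p_fx` must be non-negative", call. = FALSE)
  }
  g <- switch(variant,
    rh = {
      if (is.null(rh) || is.null(pr)) {
        stop("variant \"rh\" needs `rh` and `pr`", call. = FALSE)
      }
      1 - f_pr(pr, act) * f_rh(rh, act)
    },
    fws = {
      if (is.null(ws)) stop("variant \"fws\" needs `ws`", call. = FALSE)
      f_ws(ws, act)
    },
    ws = {
      if (is.null(ws)) stop("variant \"ws\" needs `ws`", call. = FALSE)
      ws * as.numeric(ws >= params$ws_threshold)
    })
  params$f_rupt * params$n_spg * p_fx * g * (params$m_spp / params$m_pol)
}

#' Grains ruptured on the plant per unit area and time
#'
#' Companion to [mech_rupture()]: the number of grains whose rupture the SPP
#' flux represents, `M_rupt / (n_spg * m_spp)` = `F_rupt * P_fx * G / m_pol`
#' (grains m^-2 s^-1). One airborne empty shell per grain accompanies the SPP
#' emission.
#'
#' @param m_rupt SPP mass flux from [mech_rupture()], g m^-2 s^-1.
#' @param params A [pollen_params()] object.
#' @return Grains m^-2 s^-1.
#' @export
mech_rupture_grains <- function(m_rupt, params = pollen_params()) {
  m_rupt / (params$n_spg * params$m_spp)
}
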