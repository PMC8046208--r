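#' Named experiment configurations
#'
#' The eight runnable rupture experiments, mapping names to their
#' in-atmosphere rupture rule and (for the `mrupt_*` rows) the on-plant
#' mechanical-rupture variant:
#'
#' | name        | in-atmosphere rule          | mechanical rule |
#' |-------------|-----------------------------|-----------------|
#' | `rh80`      | threshold RH >= 80 %        | none            |
#' | `mrupt_rh80`| threshold RH >= 80 %        | moisture (rh)   |
#' | `fws`       | wind function `f_WS`        | none            |
#' | `mrupt_fws` | wind function `f_WS`        | wind function   |
#' | `ws5`       | wind speed >= 5 m s^-1      | none            |
#' | `mrupt_ws`  | wind speed >= 5 m s^-1      | wind speed      |
#' | `rh30`      | threshold RH <= 30 %        | none            |
#' | `lightning` | lightning count             | none            |
#'
#' The `mrupt_*` experiments run both their mechanical rule and the paired
#' in-atmosphere rule simultaneously (switchable with
#' `mech_includes_in_atmosphere = FALSE` to run the surface emission alone).
#'
#' @param name One of the eight experiment names above.
#' @param pollen_params A [pollen_params()] object.
#' @param activity_params An [activity_params()] object.
#' @param mass_loss_mode `"spp_mass"` (default: only the SPP mass produced
#'   leaves the whole-pollen tracer) or `"full_grain"`.
#' @param gate_all_mechanisms Apply the 1 grain m^-3 minimum-concentration
#'   gate to every in-atmosphere mechanism (default `TRUE`) or to the
#'   humidity threshold mechanisms only (`FALSE`).
#' @param mech_includes_in_atmosphere Run the paired in-atmosphere rule in
#'   `mrupt_*` experiments (default `TRUE`).
#' @param settling Named settling velocities (m s^-1) per tracer. Defaults:
#'   Stokes velocity of the whole grain for pollen mass and shells, and
#'   1e-4 m s^-1 for SPPs (the adopted SPP fall speed of 0.01 cm s^-1, which
#'   exceeds the plain Stokes value for a 600 nm sphere; see the methods
#'   vignette).
#' @return An `experiment_config` object.
#' @export
#' @examples
#' experiment_config("rh80")
experiment_config <- function(name,
                              pollen_params = sppsim::pollen_params(),
                              activity_params = sppsim::activity_params(),
                              mass_loss_mode = c("spp_mass", "full_grain"),
                              gate_all_mechanisms = TRUE,
                              mech_includes_in_atmosphere = TRUE,
                              settling = NULL) {
  table1 <- experiment_names()
  if (!is.character(name) || length(name) != 1L || !name %in% table1) {
    stop(sprintf("unknown experiment %s; valid names: %s",
                 deparse(substitute(name)), paste(table1, collapse = ", ")),
         call. = FALSE)
  }
  mass_loss_mode <- match.arg(mass_loss_mode)
  rules <- list(
    rh80       = c(in_atm = "rh_high",  mech = "none"),
    mrupt_rh80 = c(in_atm = "rh_high",  mech = "rh"),
    fws        = c(in_atm = "fws",      mech = "none"),
    mrupt_fws  = c(in_atm = "fws",      mech = "fws"),
    ws5        = c(in_atm = "ws",       mech = "none"),
    mrupt_ws   = c(in_atm = "ws",       mech = "ws"),
    rh30       = c(in_atm = "rh_low",   mech = "none"),
    lightning  = c(in_atm = "lightning", mech = "none")
  )[[name]]
  in_atm <- unname(rules[["in_atm"]])
  mech <- unname(rules[["mech"]])
  if (mech != "none" && !mech_includes_in_atmosphere) in_atm_run <- "none"
  else in_atm_run <- in_atm
  if (is.null(settling)) {
    v_pol <- settling_velocity(pollen_params$d_pol, pollen_params$density)
    settling <- c(pollen_mass = v_pol, spp_mass = 1e-4, shell_number = v_pol)
  }
  stopifnot(all(c("pollen_mass", "spp_mass", "shell_number") %in%
                  names(settling)))
  structure(
    list(name = name,
         in_atmosphere_rule = in_atm_run,
         mechanical_rule = mech,
         pollen_params = pollen_params,
         activity_params = activity_params,
         mass_loss_mode = mass_loss_mode,
         gate_all_mechanisms = gate_all_mechanisms,
         settling = settling),
    class = "experiment_config"
  )
}

#' Valid experiment names
#'
#' @return Character vector of the eight experiment names.
#' @export
experiment_names <- function() {
  c("rh80", "mrupt_rh80", "fws", "mrupt_fws", "ws5", "mrupt_ws",
    "rh30", "lightning")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s: in-atmosphere rule '%s', mechanical rule '%s'\n",
              x$name, x$in_atmosphere_rule, x$mechanical_rule))
  invisible(x)
}

#' Whole-pollen surface emission flux
#'
#' Composition of a potential-emission field with the three activity
#' factors: `P_fx = potential * f_RH(rh) * f_PR(pr) * f_WS(ws)`. High
#' temperatures and low humidity promote emission; rain and humidity
#' suppress it towards the baseline floors; wind enhances it up to the
#' saturation speed. The result is bounded by `0 <= P_fx <= potential`.
#'
#' @param potential Potential emission field, g m^-2 s^-1 (scalar or matrix).
#' @param rh,pr,ws Surface relative humidity (%), precipitation (mm h^-1)
#'   and wind speed (m s^-1), same shape as `potential` (or scalars).
#' @param act An [activity_params()] object.
#' @return Emission flux, g m^-2 s^-1.
#' @export
pollen_emission_flux <- function(potential, rh, pr, ws,
                                 act = activity_params()) {
  if (!is.numeric(potential) || any(potential < 0, na.rm = TRUE)) {
    stop("`potential` must be non-negative", call. = FALSE)
  }
  potential * f_rh(rh, act) * f_pr(pr, act) * f_ws(ws, act)
}

#' Run one rupture experiment end-to-end
#'
#' Executes [step_simulation()] over the full met record, accumulating
#' hourly outputs: the site time series (surface whole pollen, shells and
#' SPPs plus the driving surface met), hourly surface fields of all three
#' tracers, the site vertical column, and a mass/number budget per tracer.
#'
#' @param config An [experiment_config()].
#' @param met A [met_fields()] record covering the run.
#' @param potential Pollen emission potential, g m^-2 s^-1 (scalar or
#'   `(nx, ny)` matrix). Default 1e-7 gives realistic surface
#'   concentrations of order 100 grains m^-3 under active emission.
#' @param site Named numeric `c(lon, lat)` of the evaluation site; default
#'   is the Melbourne University pollen trap.
#' @param init Optional initial [tracer_state()].
#' @return An `spp_run` object: `site` (tibble of hourly site values),
#'   `surface` (list of `(nx, ny, n_hours)` arrays per tracer),
#'   `site_column` (list of `(nz, n_hours)` matrices), `budget`
#'   (tibble, see [budget_report()]), `state` (final `tracer_state`),
#'   plus `config`, `grid`, `site_index`.
#' @export
run_experiment <- function(config, met,
                           potential = 1e-7,
                           site = c(lon = 144.965, lat = -37.797),
                           init = NULL) {
  stopifnot(inherits(config, "experiment_config"), inherits(met, "met_fields"))
  grid <- met$grid
  n_hours <- length(met$hours)
  steps_per_hour <- 3600 / grid$dt
  if (abs(steps_per_hour - round(steps_per_hour)) > 1e-9) {
    stop("grid$dt must divide 3600 s evenly", call. = FALSE)
  }
  steps_per_hour <- as.integer(round(steps_per_hour))
  state <- if (is.null(init)) tracer_state(grid) else init
  if (!identical(state$grid[c("nx", "ny", "nz")], grid[c("nx", "ny", "nz")])) {
    stop("initial state grid does not match the met grid", call. = FALSE)
  }
  si <- lonlat_to_index(grid, site[["lon"]], site[["lat"]])
  if (is.matrix(potential)) {
    stopifnot(identical(dim(potential), c(grid$nx, grid$ny)))
  }
  tracers <- c("pollen_mass", "spp_mass", "shell_number")
  surface <- lapply(tracers, function(t) array(0, c(grid$nx, grid$ny, n_hours)))
  names(surface) <- tracers
  site_column <- lapply(tracers, function(t) matrix(0, grid$nz, n_hours))
  names(site_column) <- tracers
  pp <- config$pollen_params
  site_rows <- vector("list", n_hours)
  budget_rows <- vector("list", n_hours)
  for (h in seq_len(n_hours)) {
    met_t <- list(
      u = met$u[, , , h], v = met$v[, , , h], w = met$w[, , , h],
      rh = met$rh[, , , h], precip = met$precip[, , h],
      lightning = met$lightning[, , h], kz = met$kz[, h]
    )
    site_rupt_h <- 0
    for (s in seq_len(steps_per_hour)) {
      res <- step_simulation(state, met_t, grid, config, potential)
      state <- res$state
      if (!is.null(res$tendency)) {
        site_rupt_h <- site_rupt_h + res$tendency$n_rupt[si[["ix"]], si[["iy"]], 1]
      }
    }
    for (t in tracers) {
      surface[[t]][, , h] <- state[[t]][, , 1]
      site_column[[t]][, h] <- state[[t]][si[["ix"]], si[["iy"]], ]
    }
    site_rows[[h]] <- tibble::tibble(
      hour = met$hours[h],
      whole_pollen = mass_to_grains(state$pollen_mass[si[["ix"]], si[["iy"]], 1], pp),
      shell_number = state$shell_number[si[["ix"]], si[["iy"]], 1],
      spp_number = state$spp_mass[si[["ix"]], si[["iy"]], 1] / (pp$m_spp * 1e6),
      spp_mass = state$spp_mass[si[["ix"]], si[["iy"]], 1],
      rh = met$rh[si[["ix"]], si[["iy"]], 1, h],
      ws = sqrt(met$u[si[["ix"]], si[["iy"]], 1, h]^2 +
                  met$v[si[["ix"]], si[["iy"]], 1, h]^2),
      precip = met$precip[si[["ix"]], si[["iy"]], h],
      lightning = met$lightning[si[["ix"]], si[["iy"]], h],
      site_rupture = site_rupt_h
    )
    budget_rows[[h]] <- dplyr::mutate(budget_report(state), hour = met$hours[h],
                                      .before = 1)
  }
  structure(
    list(config = config, grid = grid, site_index = si, site_lonlat = site,
         potential = potential,
         site = dplyr::bind_rows(site_rows),
         surface = surface, site_column = site_column,
         budget = dplyr::bind_rows(budget_rows),
         hours = met$hours,
         state = state),
    class = "spp_run"
  )
}

#' @export
print.spp_run <- function(x, ...) {
  cat(sprintf("<spp_run> experiment '%s', %d hours on %d x %d x %d grid\n",
              x$config$name, length(x$hours), x$grid$nx, x$grid$ny, x$grid$nz))
  cat(sprintf("  site peak whole pollen %.3g grains/m^3, peak shells %.3g /m^3\n",
              max(x$site$whole_pollen), max(x$site$shell_number)))
  invisible(x)
}

#' Mass/number budget of a tracer state
#'
#' For each tracer: cumulative sources (surface emission plus in-atmosphere
#' rupture production), sinks (deposition, boundary outflow, rupture removal
#' from the pollen tracer) and the airborne burden, with the closure
#' residual. The residual relative to total source is the budget-closure
#' diagnostic (should be at roundoff, well under 1e-8).
#'
#' @param state A [tracer_state()].
#' @return Tibble with one row per tracer: `tracer`, `emitted`, `ruptured_in`
#'   (production by in-atmosphere rupture), `airborne`, `deposited`,
#'   `outflow`, `ruptured_out` (removal by rupture), `residual`,
#'   `rel_residual`.
#' @export
budget_report <- function(state) {
  rows <- lapply(c("pollen_mass", "spp_mass", "shell_number"), function(tr) {
    emitted <- state$emitted[[tr]]
    rupt_in <- switch(tr, pollen_mass = 0, spp_mass = state$rupture_spp_mass,
                      shell_number = state$rupture_shells)
    rupt_out <- switch(tr, pollen_mass = state$rupture_loss_pollen, 0)
    airborne <- domain_total(state, tr)
    deposited <- deposited_total(state, tr)
    outflow <- state$outflow[[tr]]
    residual <- emitted + rupt_in - rupt_out - airborne - deposited - outflow
    source <- emitted + rupt_in
    tibble::tibble(tracer = tr, emitted = emitted, ruptured_in = rupt_in,
                   airborne = airborne, deposited = deposited,
                   outflow = outflow, ruptured_out = rupt_out,
                   residual = residual,
                   rel_residual = ifelse(source > 0, abs(residual) / source, 0))
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a run
#'
#' @param x An `spp_run`.
#' @param ... Unused.
#' @return Tibble with the experiment name, run length, site peaks, total
#'   grains ruptured and the worst budget-closure residual.
#' @method glance spp_run
#' @export
glance.spp_run <- function(x, ...) {
  final <- budget_report(x$state)
  tibble::tibble(
    experiment = x$config$name,
    n_hours = length(x$hours),
    peak_whole_pollen = max(x$site$whole_pollen),
    peak_shells = max(x$site$shell_number),
    peak_spp_number = max(x$site$spp_number),
    total_ruptured_grains = x$state$rupture_grains,
    max_rel_residual = max(final$rel_residual)
  )
}

#' Hourly site series of a run as a tibble
#'
#' @param x An `spp_run`.
#' @param ... Unused.
#' @return The run's hourly site tibble in long form (`hour`, `tracer`,
#'   `value`), for plotting and joins.
#' @method tidy spp_run
#' @export
tidy.spp_run <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$site, "hour", "whole_pollen", "shell_number", "spp_number"),
    cols = -"hour", names_to = "tracer", values_to = "value")
}
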