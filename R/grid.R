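#' Model grid definition
#'
#' Regular lat/lon-referenced Cartesian grid with fixed height levels.
#' Defaults emulate the study scale: 3 km horizontal spacing over a 40 x 40
#' cell domain and 15 vertical levels to 5 km with a ~40 m lowest layer, so
#' the near-surface diagnostic layer maps onto the lowest model level.
#'
#' @param nx,ny Cell counts in the west-east / south-north directions.
#' @param dx,dy Cell sizes, m.
#' @param z_levels Strictly increasing layer-interface heights, m, starting
#'   at 0 (surface). `length(z_levels) - 1` layers; top at most ~5 km.
#' @param dt Model time step, s (met is hourly; steps sub-divide the hour).
#' @param origin Named numeric `c(lon, lat)` of the centre of cell (1, 1)
#'   (south-west corner cell).
#' @return A `sim_grid` object with derived fields `nz`, `dz` (layer
#'   thicknesses), `z_mid` (layer mid-heights).
#' @export
#' @examples
#' g <- sim_grid()
#' g$nz
sim_grid <- function(nx = 40, ny = 40, dx = 3000, dy = 3000,
                     z_levels = c(0, 40, 100, 180, 300, 460, 680, 960, 1300,
                                  1700, 2200, 2800, 3450, 4150, 4550, 5000),
                     dt = 300,
                     origin = c(lon = 144.044, lat = -38.313)) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, dy > 0, dt > 0)
  if (is.unsorted(z_levels, strictly = TRUE) || z_levels[1] != 0) {
    stop("`z_levels` must be strictly increasing and start at 0", call. = FALSE)
  }
  if (max(z_levels) > 6000) {
    stop("`z_levels` top must be at most ~5 km (<= 6000 m)", call. = FALSE)
  }
  nz <- length(z_levels) - 1L
  if (nz < 1L) stop("need at least one layer", call. = FALSE)
  origin <- unlist(origin)
  if (length(origin) != 2L) stop("`origin` must be c(lon, lat)", call. = FALSE)
  if (!all(c("lon", "lat") %in% names(origin))) {
    names(origin) <- c("lon", "lat")
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
         z_levels = z_levels, nz = nz,
         dz = diff(z_levels),
         z_mid = (z_levels[-1] + z_levels[-(nz + 1)]) / 2,
         dt = dt,
         origin = c(lon = unname(origin[["lon"]]), lat = unname(origin[["lat"]]))),
    class = "sim_grid"
  )
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d x %d cells, dx = %g m, top %g m, dt = %g s\n",
              x$nx, x$ny, x$nz, x$dx, max(x$z_levels), x$dt))
  cat(sprintf("  origin (cell 1,1 centre): %.4f E, %.4f N\n",
              x$origin[["lon"]], x$origin[["lat"]]))
  invisible(x)
}

# metres per degree at the grid's latitude (local equirectangular mapping)
grid_metres_per_degree <- function(grid) {
  lat <- grid$origin[["lat"]]
  c(lon = 111320 * cos(lat * pi / 180), lat = 110540)
}

#' Convert lon/lat to grid cell indices
#'
#' Nearest-cell lookup on the grid's local equirectangular projection.
#'
#' @param grid A [sim_grid()].
#' @param lon,lat Coordinates, degrees.
#' @return Integer vector `c(ix, iy)`.
#' @export
lonlat_to_index <- function(grid, lon, lat) {
  mpd <- grid_metres_per_degree(grid)
  ix <- round((lon - grid$origin[["lon"]]) * mpd[["lon"]] / grid$dx) + 1
  iy <- round((lat - grid$origin[["lat"]]) * mpd[["lat"]] / grid$dy) + 1
  if (ix < 1 || ix > grid$nx || iy < 1 || iy > grid$ny) {
    stop("location outside the model domain", call. = FALSE)
  }
  c(ix = as.integer(ix), iy = as.integer(iy))
}

#' Convert grid cell indices to lon/lat
#'
#' @param grid A [sim_grid()].
#' @param ix,iy Cell indices (vectorised).
#' @return Tibble with `ix`, `iy`, `lon`, `lat`.
#' @export
index_to_lonlat <- function(grid, ix, iy) {
  mpd <- grid_metres_per_degree(grid)
  tibble::tibble(
    ix = ix, iy = iy,
    lon = grid$origin[["lon"]] + (ix - 1) * grid$dx / mpd[["lon"]],
    lat = grid$origin[["lat"]] + (iy - 1) * grid$dy / mpd[["lat"]]
  )
}

#' Hourly gridded meteorology container
#'
#' Bundles the hourly 3-D meteorological fields driving the simulator.
#' 3-D fields (`temp` degC, `rh` %, `u`, `v`, `w` m s^-1) have dimensions
#' `(nx, ny, nz, n_hours)`; surface fields (`precip` mm h^-1, `lightning`
#' strikes per cell-hour) are `(nx, ny, n_hours)`; vertical eddy diffusivity
#' `kz` (m^2 s^-1) is horizontally uniform, `(nz, n_hours)`. Met is
#' time-stamped at the beginning of the hour and held constant within it.
#'
#' @param grid A [sim_grid()].
#' @param temp,rh,u,v,w 4-D arrays `(nx, ny, nz, n_hours)`.
#' @param precip,lightning 3-D arrays `(nx, ny, n_hours)`.
#' @param kz Matrix `(nz, n_hours)`.
#' @param hours Numeric vector of hour offsets from run start (0, 1, ...).
#' @return A `met_fields` object.
#' @export
met_fields <- function(grid, temp, rh, u, v, w, precip, lightning, kz,
                       hours = seq_len(dim(rh)[4]) - 1) {
  d3 <- c(grid$nx, grid$ny, grid$nz)
  nt <- length(hours)
  for (nm in c("temp", "rh", "u", "v", "w")) {
    x <- get(nm)
    if (!identical(dim(x), as.integer(c(d3, nt)))) {
      stop(sprintf("`%s` must have dim (nx, ny, nz, n_hours)", nm),
           call. = FALSE)
    }
  }
  for (nm in c("precip", "lightning")) {
    x <- get(nm)
    if (!identical(dim(x), as.integer(c(grid$nx, grid$ny, nt)))) {
      stop(sprintf("`%s` must have dim (nx, ny, n_hours)", nm), call. = FALSE)
    }
  }
  if (!identical(dim(kz), as.integer(c(grid$nz, nt)))) {
    stop("`kz` must have dim (nz, n_hours)", call. = FALSE)
  }
  if (any(rh < 0) || any(rh > 100)) stop("`rh` must lie in [0, 100]", call. = FALSE)
  if (any(precip < 0)) stop("`precip` must be non-negative", call. = FALSE)
  if (any(lightning < 0) || any(abs(lightning - round(lightning)) > 1e-8)) {
    stop("`lightning` must be non-negative integer counts", call. = FALSE)
  }
  if (any(kz < 0)) stop("`kz` must be non-negative", call. = FALSE)
  structure(
    list(grid = grid, hours = hours, temp = temp, rh = rh, u = u, v = v,
         w = w, precip = precip, lightning = lightning, kz = kz),
    class = "met_fields"
  )
}

#' @export
print.met_fields <- function(x, ...) {
  cat(sprintf("<met_fields> %d hours on %d x %d x %d grid\n",
              length(x$hours), x$grid$nx, x$grid$ny, x$grid$nz))
  cat(sprintf("  surface RH range %.0f-%.0f%%, total lightning strikes %d\n",
              min(x$rh[, , 1, ]), max(x$rh[, , 1, ]), sum(x$lightning)))
  invisible(x)
}

#' Gridded tracer state
#'
#' Holds the three tracers carried by every run — whole-pollen mass and SPP
#' mass (ug m^-3) and shell number (m^-3) — as `(nx, ny, nz)` arrays, plus
#' surface deposition accumulators (ug m^-2 or shells m^-2), cumulative
#' boundary-outflow and source/sink budgets used for mass-closure checks.
#'
#' @param grid A [sim_grid()].
#' @param pollen_mass,spp_mass,shell_number Optional initial `(nx, ny, nz)`
#'   arrays; default zero.
#' @return A `tracer_state` object.
#' @export
tracer_state <- function(grid, pollen_mass = NULL, spp_mass = NULL,
                         shell_number = NULL) {
  zero <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  as_field <- function(x, nm) {
    if (is.null(x)) return(zero)
    if (!identical(dim(x), dim(zero))) {
      stop(sprintf("`%s` must have dim (nx, ny, nz)", nm), call. = FALSE)
    }
    if (any(x < 0)) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    x
  }
  zero2 <- matrix(0, grid$nx, grid$ny)
  structure(
    list(grid = grid,
         pollen_mass = as_field(pollen_mass, "pollen_mass"),
         spp_mass = as_field(spp_mass, "spp_mass"),
         shell_number = as_field(shell_number, "shell_number"),
         deposited_pollen = zero2, deposited_spp = zero2,
         deposited_shell = zero2,
         outflow = c(pollen_mass = 0, spp_mass = 0, shell_number = 0),
         emitted = c(pollen_mass = 0, spp_mass = 0, shell_number = 0),
         rupture_loss_pollen = 0,   # mass removed from pollen tracer (ug, domain)
         rupture_spp_mass = 0,      # SPP mass produced in-atmosphere (ug, domain)
         rupture_shells = 0,        # shells produced in-atmosphere (number, domain)
         rupture_grains = 0),       # grains ruptured in-atmosphere (number, domain)
    class = "tracer_state"
  )
}

#' @export
print.tracer_state <- function(x, ...) {
  cat("<tracer_state>\n")
  cat(sprintf("  airborne: pollen %.4g ug, SPP %.4g ug, shells %.4g\n",
              domain_total(x, "pollen_mass"), domain_total(x, "spp_mass"),
              domain_total(x, "shell_number")))
  invisible(x)
}

# volume-integrated tracer amount over the domain (ug, or number for shells)
domain_total <- function(state, tracer) {
  g <- state$grid
  cell_area <- g$dx * g$dy
  field <- state[[tracer]]
  tot <- 0
  for (k in seq_len(g$nz)) {
    tot <- tot + sum(field[, , k]) * cell_area * g$dz[k]
  }
  tot
}

# surface-integrated deposition (ug or number)
deposited_total <- function(state, tracer) {
  g <- state$grid
  dep <- switch(tracer,
                pollen_mass = state$deposited_pollen,
                spp_mass = state$deposited_spp,
                shell_number = state$deposited_shell)
  sum(dep) * g$dx * g$dy
}
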