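#' Gust-front storm scenario parameters
#'
#' Defaults encode the observed anchors of the 2016 Melbourne event: a hot
#' (34 degC), very dry (18 %RH) pre-frontal airmass under north-westerly
#' flow; a dry gust front sweeping eastward through the site 26 h into the
#' 34-h run (17:30 local time); surface humidity recovering to 80 % five
#' hours after frontal passage; a sharp temperature drop; scant rainfall
#' (up to 4 mm west of the site, 2 mm east); and a track of lightning
#' strikes accompanying the front from the north-west, passing west and
#' south of the site, never exceeding 6 strikes per cell-hour.
#'
#' @param run_hours Run length, h.
#' @param pre_front_rh Pre-frontal surface relative humidity, %.
#' @param pre_front_temp Pre-frontal surface temperature, degC.
#' @param front_passage_time Hour of frontal passage at the site.
#' @param front_speed Eastward frontal propagation speed, m s^-1 (free
#'   parameter; the event's speed was not measured).
#' @param gust_peak Peak gust-front wind speed, m s^-1.
#' @param rh_recovery_lag Hours after local frontal passage at which surface
#'   RH reaches 80 %.
#' @param post_front_temp_drop Surface cooling across the front, degC.
#' @param post_front_wind Post-frontal steady westerly wind, m s^-1.
#' @param pre_front_wind Named `c(u, v)` pre-frontal wind components
#'   (north-westerly), m s^-1.
#' @param rain_total_west,rain_total_east Post-frontal rain totals, mm,
#'   west/east of the site.
#' @param n_lightning_strikes Number of strikes along the generated track.
#' @param seed Integer seed for the reproducible noise and strike jitter.
#' @return A `gust_front_params` list.
#' @export
gust_front_params <- function(run_hours = 34,
                              pre_front_rh = 18,
                              pre_front_temp = 34,
                              front_passage_time = 26,
                              front_speed = 15,
                              gust_peak = 20,
                              rh_recovery_lag = 5,
                              post_front_temp_drop = 10,
                              post_front_wind = 3,
                              pre_front_wind = c(u = 6, v = -3),
                              rain_total_west = 4,
                              rain_total_east = 2,
                              n_lightning_strikes = 120,
                              seed = 1L) {
  stopifnot(run_hours > front_passage_time, front_speed > 0, gust_peak > 0,
            rh_recovery_lag > 0, pre_front_rh > 0, pre_front_rh < 100)
  structure(as.list(environment()), class = "gust_front_params")
}

# west-east cell-centre x coordinates, m
grid_x <- function(grid) (seq_len(grid$nx) - 1) * grid$dx
grid_y <- function(grid) (seq_len(grid$ny) - 1) * grid$dy

#' Frontal position at a given hour
#'
#' x-coordinate (m, grid-relative) of the gust front under a scenario: the
#' front moves eastward at `front_speed` and crosses the site column at
#' `front_passage_time`.
#'
#' @param params A [gust_front_params()].
#' @param grid A [sim_grid()].
#' @param hour Hours since run start (vectorised).
#' @param site Site lon/lat used to anchor the passage time.
#' @return x position(s), m (may lie outside `[0, nx*dx]` before/after
#'   traversal).
#' @export
front_position <- function(params, grid, hour,
                           site = c(lon = 144.965, lat = -37.797)) {
  si <- lonlat_to_index(grid, site[["lon"]], site[["lat"]])
  x_site <- (si[["ix"]] - 1) * grid$dx
  x_site + (hour - params$front_passage_time) * 3600 * params$front_speed
}

#' Generate the gust-front storm scenario
#'
#' Deterministic (seeded) hourly gridded meteorology emulating a dry
#' gust-front thunderstorm. Per column, conditions switch at local frontal
#' passage: hot, very dry north-westerly flow before; a one-hour wind spike
#' to `gust_peak` at passage, then steady westerlies; surface RH ramping
#' linearly from `pre_front_rh` to 80 % over `rh_recovery_lag` hours (then
#' on to a humid plateau); a temperature drop; scant rain in the two hours
#' after passage. A moist band around ~4 km (the storm mid-level) tracks
#' the front without reaching the 80 % rupture threshold, and lightning
#' strikes are laid along a north-west-to-south track just behind the
#' front, re-gridded to per-cell hourly counts.
#'
#' @param params A [gust_front_params()].
#' @param grid A [sim_grid()].
#' @param site Site lon/lat anchoring the frontal passage time.
#' @return A [met_fields()] record; the strike list used is attached as
#'   attribute `"strikes"` and the scenario parameters as `"scenario"`.
#' @export
gust_front_scenario <- function(params = gust_front_params(),
                                grid = sim_grid(),
                                site = c(lon = 144.965, lat = -37.797)) {
  stopifnot(inherits(params, "gust_front_params"), inherits(grid, "sim_grid"))
  nt <- as.integer(params$run_hours)
  hours <- seq_len(nt) - 1
  # front must traverse the domain during the run
  fp <- front_position(params, grid, c(0, max(hours)), site)
  if (fp[1] > grid$nx * grid$dx || fp[2] < 0) {
    stop("the front never crosses the model domain during the run",
         call. = FALSE)
  }
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  xs <- grid_x(grid)
  d4 <- c(nx, ny, nz, nt)
  temp <- array(0, d4); rh <- array(0, d4)
  u <- array(0, d4); v <- array(0, d4); w <- array(0, d4)
  precip <- array(0, c(nx, ny, nt)); lightning <- array(0L, c(nx, ny, nt))
  kz <- matrix(0, nz, nt)
  si <- lonlat_to_index(grid, site[["lon"]], site[["lat"]])
  x_site <- (si[["ix"]] - 1) * grid$dx
  lapse <- 6.5 / 1000                                  # K per m
  set.seed(params$seed)
  wind_noise <- array(stats::rnorm(nx * ny * nt, sd = 0.2), c(nx, ny, nt))
  for (h in seq_len(nt)) {
    t_h <- hours[h]
    x_front <- front_position(params, grid, t_h, site)
    # hours since local frontal passage per column (negative = pre-frontal)
    since <- (x_front - xs) / (params$front_speed * 3600)
    # surface RH: pre-frontal dry; linear ramp hitting 80 at the lag, then
    # on to a humid plateau at 88
    rh_sfc <- ifelse(
      since < 0, params$pre_front_rh,
      pmin(params$pre_front_rh +
             (80 - params$pre_front_rh) * since / params$rh_recovery_lag, 88))
    t_sfc <- params$pre_front_temp -
      params$post_front_temp_drop * pmin(pmax(since, 0), 1)
    # winds: NW flow ahead; gust spike for the first post-frontal hour
    gust <- pmax(params$gust_peak * (1 - pmin(pmax(since, 0), 1)), 0) *
      (since >= 0)
    u_col <- ifelse(since < 0, params$pre_front_wind[["u"]],
                    params$post_front_wind + gust)
    v_col <- ifelse(since < 0, params$pre_front_wind[["v"]], 0)
    for (k in seq_len(nz)) {
      zmid <- grid$z_mid[k]
      # mid-level moist band (~3.5-4.5 km) tracking the front
      moist_band <- (zmid > 3200 & zmid < 4800)
      prox <- exp(-((xs - x_front) / 5e4)^2)
      zrel <- max(zmid - grid$z_mid[1], 0)     # lowest level = surface value
      rh_k <- if (moist_band) pmax(rh_sfc * 0.6, 70 * prox) else
        rh_sfc * (1 - 0.4 * zrel / max(grid$z_mid))
      temp_k <- t_sfc - lapse * zmid
      for (j in seq_len(ny)) {
        rh[, j, k, h] <- pmin(pmax(rh_k, 1), 100)
        temp[, j, k, h] <- temp_k
        u[, j, k, h] <- u_col
        v[, j, k, h] <- v_col
      }
    }
    # small seeded wind perturbation in the lowest levels (realism; does not
    # alter the deterministic RH anchors)
    u[, , 1, h] <- u[, , 1, h] + wind_noise[, , h]
    # scant rain during the two hours after local passage, heavier west
    rain_rate <- ifelse(since >= 0.5 & since < 2.5,
                        ifelse(xs < x_site, params$rain_total_west / 2,
                               params$rain_total_east / 2), 0)
    precip[, , h] <- matrix(rain_rate, nx, ny)
    # boundary-layer mixing: stronger in the turbulent post-frontal air
    frac_post <- mean(since > 0)
    kz[, h] <- ifelse(grid$z_mid < 1500, 5 + 25 * frac_post, 0.5)
  }
  strikes <- gust_front_strikes(params, grid, site)
  lightning <- regrid_lightning(strikes, grid, hours = hours)
  met <- met_fields(grid, temp = temp, rh = rh, u = u, v = v, w = w,
                    precip = precip, lightning = lightning, kz = kz,
                    hours = hours)
  attr(met, "strikes") <- strikes
  attr(met, "scenario") <- params
  attr(met, "site") <- site
  met
}

# Synthetic WWLLN-like strike list: strikes accompany the front from the
# north-west of the domain to south of the site, placed just behind the
# front line at their time, deterministically jittered; thinned so no
# cell-hour exceeds 6 strikes.
gust_front_strikes <- function(params, grid, site) {
  set.seed(params$seed + 1L)
  n <- params$n_lightning_strikes
  t0 <- params$front_passage_time - 5
  times <- sort(stats::runif(n, t0, params$front_passage_time + 1.5))
  x_front <- front_position(params, grid, times, site)
  # the convective cores (and their strikes) trail the gust front's leading
  # edge: 5-20 km behind, so no strikes reach the front line itself
  x <- x_front - stats::runif(n, 5e3, 2e4)
  # sweep from the domain's north towards south of the site as time advances
  si <- lonlat_to_index(grid, site[["lon"]], site[["lat"]])
  y_hi <- (grid$ny - 2) * grid$dy
  y_lo <- max((si[["iy"]] - 8) * grid$dy, 0)
  frac <- (times - t0) / (params$front_passage_time + 1.5 - t0)
  y <- y_hi - (y_hi - y_lo) * frac + stats::rnorm(n, sd = 2 * grid$dy)
  keep <- x >= 0 & x <= (grid$nx - 1) * grid$dx &
    y >= 0 & y <= (grid$ny - 1) * grid$dy
  mpd <- grid_metres_per_degree(grid)
  strikes <- tibble::tibble(
    time = times[keep],
    lon = grid$origin[["lon"]] + x[keep] / mpd[["lon"]],
    lat = grid$origin[["lat"]] + y[keep] / mpd[["lat"]]
  )
  # enforce the observed per-cell-hour ceiling of 6 strikes
  strikes <- dplyr::mutate(
    strikes,
    ix = round((.data$lon - grid$origin[["lon"]]) * mpd[["lon"]] / grid$dx),
    iy = round((.data$lat - grid$origin[["lat"]]) * mpd[["lat"]] / grid$dy),
    cell_hour = paste(floor(.data$time), .data$ix, .data$iy)
  )
  strikes <- dplyr::slice_head(
    dplyr::group_by(strikes, .data$cell_hour), n = 6L)
  dplyr::select(dplyr::ungroup(strikes), "time", "lon", "lat")
}

#' Humid-night counterfactual scenario
#'
#' Multi-day meteorology with a diurnal humidity cycle — dry afternoons
#' (RH < 50 %) and humid nights (RH > 80 % around 03:00 local) — light
#' winds, no rain and no lightning. Under the humidity-threshold rupture
#' rule this scenario produces the nocturnal false-positive behaviour:
#' rupture occurs every night even though no storm is present.
#'
#' @param days Number of simulated days (run starts at local midnight).
#' @param rh_mean,rh_amp Mean and amplitude of the surface diurnal RH
#'   cycle, %; RH(t) = mean + amp * cos(2 pi (t - peak_hour)/24).
#' @param rh_peak_hour Local hour of maximum humidity.
#' @param temp_mean,temp_amp Surface temperature cycle, degC (phase opposite
#'   to humidity).
#' @param wind Light steady westerly wind, m s^-1.
#' @param grid A [sim_grid()].
#' @return A [met_fields()] record.
#' @export
humid_night_scenario <- function(days = 3, rh_mean = 65, rh_amp = 25,
                                 rh_peak_hour = 3, temp_mean = 22,
                                 temp_amp = 8, wind = 1,
                                 grid = sim_grid()) {
  stopifnot(days >= 1, rh_amp >= 0, rh_mean + rh_amp <= 100,
            rh_mean - rh_amp >= 0)
  nt <- as.integer(days * 24)
  hours <- seq_len(nt) - 1
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  d4 <- c(nx, ny, nz, nt)
  rh <- array(0, d4); temp <- array(0, d4)
  u <- array(wind, d4); v <- array(0, d4); w <- array(0, d4)
  rh_sfc <- rh_mean + rh_amp * cos(2 * pi * (hours - rh_peak_hour) / 24)
  t_sfc <- temp_mean - temp_amp * cos(2 * pi * (hours - rh_peak_hour) / 24)
  for (h in seq_len(nt)) {
    for (k in seq_len(nz)) {
      zfac <- 1 - 0.4 * max(grid$z_mid[k] - grid$z_mid[1], 0) / max(grid$z_mid)
      rh[, , k, h] <- rh_sfc[h] * zfac
      temp[, , k, h] <- t_sfc[h] - 6.5e-3 * grid$z_mid[k]
    }
  }
  kz <- matrix(0.5, nz, nt)
  kz[grid$z_mid < 1500, ] <- rep(ifelse(
    cos(2 * pi * (hours - rh_peak_hour) / 24) < 0, 10, 1),
    each = sum(grid$z_mid < 1500))
  met_fields(grid, temp = temp, rh = pmin(pmax(rh, 0), 100),
             u = u, v = v, w = w,
             precip = array(0, c(nx, ny, nt)),
             lightning = array(0L, c(nx, ny, nt)),
             kz = kz, hours = hours)
}

#' Re-grid a lightning strike list to per-cell hourly counts
#'
#' Bins point strikes (decimal hour, lon, lat) onto the model grid,
#' conserving the total count of in-domain strikes; strikes outside the
#' domain or run window are dropped (their number reported via message).
#'
#' @param strikes Data frame with columns `time` (decimal hours since run
#'   start), `lon`, `lat`.
#' @param grid A [sim_grid()].
#' @param hours Hour stamps of the target record (default from the strike
#'   times).
#' @param quiet Suppress the dropped-strike message.
#' @return Integer array `(nx, ny, n_hours)` of counts.
#' @export
regrid_lightning <- function(strikes, grid,
                             hours = seq_len(max(1, ceiling(max(strikes$time, 0) + 1e-9))) - 1,
                             quiet = FALSE) {
  stopifnot(is.data.frame(strikes))
  need <- c("time", "lon", "lat")
  if (!all(need %in% names(strikes))) {
    stop("`strikes` must have columns time, lon, lat", call. = FALSE)
  }
  nt <- length(hours)
  counts <- array(0L, c(grid$nx, grid$ny, nt))
  if (nrow(strikes) == 0) return(counts)
  bad <- !is.finite(strikes$time) | !is.finite(strikes$lon) |
    !is.finite(strikes$lat)
  if (any(bad)) {
    stop(sprintf("malformed strike record at line %d", which(bad)[1]),
         call. = FALSE)
  }
  mpd <- grid_metres_per_degree(grid)
  ix <- round((strikes$lon - grid$origin[["lon"]]) * mpd[["lon"]] / grid$dx) + 1
  iy <- round((strikes$lat - grid$origin[["lat"]]) * mpd[["lat"]] / grid$dy) + 1
  ih <- findInterval(strikes$time, c(hours, max(hours) + 1))
  inside <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny &
    ih >= 1 & ih <= nt & strikes$time >= hours[1]
  n_drop <- sum(!inside)
  if (n_drop > 0 && !quiet) {
    message(sprintf("regrid_lightning: dropped %d strikes outside the domain/window",
                    n_drop))
  }
  for (s in which(inside)) {
    counts[ix[s], iy[s], ih[s]] <- counts[ix[s], iy[s], ih[s]] + 1L
  }
  counts
}

#' Synthetic pollen-trap observations
#'
#' Emulates hourly volumetric-trap counting: the true concentration is
#' sampled at the trap's volumetric rate (10 L min^-1, i.e. 0.6 m^3 per
#' hourly transect), grains counted with Poisson noise, and converted back
#' to grains m^-3. With `noise = "none"` the truth is returned unchanged.
#'
#' @param truth Data frame with columns `hour` and one or more tracer
#'   columns (grains m^-3), or a numeric vector.
#' @param noise `"poisson"` (default) or `"none"`.
#' @param seed Integer seed.
#' @param sample_volume Air volume per hourly transect, m^3.
#' @return Tibble with the same columns, noised.
#' @export
synthetic_observations <- function(truth, noise = c("poisson", "none"),
                                   seed = 1L, sample_volume = 0.6) {
  noise <- match.arg(noise)
  if (is.numeric(truth)) truth <- tibble::tibble(hour = seq_along(truth) - 1,
                                                 whole_pollen = truth)
  stopifnot(is.data.frame(truth), sample_volume > 0)
  vals <- dplyr::select(truth, -dplyr::any_of("hour"))
  if (any(as.matrix(vals) < 0, na.rm = TRUE)) {
    stop("truth concentrations must be non-negative", call. = FALSE)
  }
  if (noise == "none") return(tibble::as_tibble(truth))
  set.seed(seed)
  noised <- lapply(vals, function(x) {
    stats::rpois(length(x), lambda = x * sample_volume) / sample_volume
  })
  out <- tibble::as_tibble(c(truth[intersect("hour", names(truth))], noised))
  out
}
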