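#' Extract the hourly site series from a run
#'
#' Nearest-cell lookup. Surface (level 1) series are available for any
#' location in the domain from the stored surface history; higher levels
#' are stored for the run's evaluation site column only.
#'
#' @param run An `spp_run`.
#' @param lon,lat Location, degrees; defaults to the run's site.
#' @param level Model level (1 = surface layer).
#' @return Tibble `hour`, `whole_pollen` (grains m^-3), `shell_number`
#'   (m^-3), `spp_number` (m^-3), `spp_mass` (ug m^-3).
#' @export
extract_site_series <- function(run, lon = NULL, lat = NULL, level = 1L) {
  stopifnot(inherits(run, "spp_run"))
  pp <- run$config$pollen_params
  if (is.null(lon) || is.null(lat)) {
    idx <- run$site_index
  } else {
    idx <- lonlat_to_index(run$grid, lon, lat)
  }
  if (level < 1 || level > run$grid$nz) {
    stop("`level` outside the model column", call. = FALSE)
  }
  if (level == 1L) {
    pol <- run$surface$pollen_mass[idx[["ix"]], idx[["iy"]], ]
    spp <- run$surface$spp_mass[idx[["ix"]], idx[["iy"]], ]
    shl <- run$surface$shell_number[idx[["ix"]], idx[["iy"]], ]
  } else {
    if (!identical(idx, run$site_index)) {
      stop("levels above the surface are stored for the run's site only",
           call. = FALSE)
    }
    pol <- run$site_column$pollen_mass[level, ]
    spp <- run$site_column$spp_mass[level, ]
    shl <- run$site_column$shell_number[level, ]
  }
  tibble::tibble(
    hour = run$hours,
    whole_pollen = mass_to_grains(pol, pp),
    shell_number = shl,
    spp_number = spp / (pp$m_spp * 1e6),
    spp_mass = spp
  )
}

#' Regression slope and Pearson correlation of model vs observations
#'
#' The evaluation statistic pair: ordinary least-squares slope `s` of the
#' modelled series regressed on the observed series, and the Pearson
#' correlation `r`. Hours with a missing value in either series are dropped
#' pairwise.
#'
#' @param model,obs Numeric vectors of paired hourly values, or a data
#'   frame in `model` with columns named by `model_col`/`obs_col`.
#' @param model_col,obs_col Column names when `model` is a data frame.
#' @return An `eval_result` with `slope`, `slope_se`, `intercept`,
#'   `pearson_r`, `n_hours` and the paired series; see [tidy.eval_result()]
#'   and [glance.eval_result()].
#' @export
#' @examples
#' regression_stats(model = c(2, 1, 4, 3), obs = 1:4)
regression_stats <- function(model, obs = NULL,
                             model_col = "model", obs_col = "obs") {
  if (is.data.frame(model)) {
    obs <- model[[obs_col]]
    model <- model[[model_col]]
  }
  stopifnot(is.numeric(model), is.numeric(obs))
  if (length(model) != length(obs)) {
    stop("`model` and `obs` must have equal length", call. = FALSE)
  }
  ok <- is.finite(model) & is.finite(obs)
  m <- model[ok]; o <- obs[ok]
  if (length(m) < 3) {
    stop("need at least 3 paired finite values", call. = FALSE)
  }
  if (stats::var(o) == 0 || stats::var(m) == 0) {
    stop("zero variance in one of the series", call. = FALSE)
  }
  fit <- stats::lm(m ~ o)
  # slope standard error computed directly (summary.lm warns on an exact
  # fit, which is a legitimate input here: identical series give s = 1)
  n <- length(m)
  rss <- sum(stats::residuals(fit)^2)
  slope_se <- sqrt(rss / (n - 2)) / sqrt(sum((o - mean(o))^2))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         slope_se = slope_se,
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = stats::cor(m, o),
         n_hours = length(m),
         model = m, obs = o),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n = %d hours: s = %.3f (se %.3f), r = %.3f\n",
              x$n_hours, x$slope, x$slope_se, x$pearson_r))
  invisible(x)
}

#' Evaluation regression terms
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with one row per regression term (`intercept`, `slope`)
#'   and columns `term`, `estimate`, `std.error`.
#' @method tidy eval_result
#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se)
  )
}

#' One-row evaluation summary
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with `slope`, `slope_se`, `pearson_r`, `n_hours`.
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 pearson_r = x$pearson_r, n_hours = x$n_hours)
}

#' Vertical tracer profile at the site
#'
#' Column concentrations at a given hour, with the height at which the
#' whole-pollen concentration falls below a threshold (1 grain m^-3 by
#' default), found by log-linear interpolation between layer mid-heights
#' (exact for an exponentially decaying column).
#'
#' @param run An `spp_run`.
#' @param hour Hour stamp (must be one of the run's hours).
#' @param threshold Whole-pollen threshold, grains m^-3.
#' @return Tibble `level`, `z_mid`, `whole_pollen`, `shell_number`,
#'   `spp_number`, with the crossing height as attribute
#'   `"threshold_height"` (NA if the column never crosses).
#' @export
vertical_profile <- function(run, hour, threshold = 1) {
  stopifnot(inherits(run, "spp_run"))
  h <- match(hour, run$hours)
  if (is.na(h)) stop("`hour` not in the run", call. = FALSE)
  pp <- run$config$pollen_params
  grains <- mass_to_grains(run$site_column$pollen_mass[, h], pp)
  prof <- tibble::tibble(
    level = seq_len(run$grid$nz),
    z_mid = run$grid$z_mid,
    whole_pollen = grains,
    shell_number = run$site_column$shell_number[, h],
    spp_number = run$site_column$spp_mass[, h] / (pp$m_spp * 1e6)
  )
  attr(prof, "threshold_height") <-
    threshold_crossing_height(grains, run$grid$z_mid, threshold)
  prof
}

# log-linear interpolation of the first downward crossing of `threshold`
threshold_crossing_height <- function(conc, z_mid, threshold) {
  if (all(conc >= threshold)) return(NA_real_)
  if (conc[1] < threshold) return(0)
  k <- which(conc < threshold)[1]
  c_hi <- conc[k - 1]; c_lo <- max(conc[k], .Machine$double.xmin)
  z_mid[k - 1] + (z_mid[k] - z_mid[k - 1]) *
    (log(c_hi) - log(threshold)) / (log(c_hi) - log(c_lo))
}

#' Fraction of a column burden below a height
#'
#' Layer-thickness-weighted fraction of the site column burden located
#' below `height` (partial layers counted pro rata, i.e. assuming uniform
#' concentration within a layer). Monotone non-decreasing in `height`,
#' reaching 1 at the column top.
#'
#' @param run An `spp_run`.
#' @param height Height above ground, m.
#' @param tracer `"pollen_mass"`, `"spp_mass"` or `"shell_number"`.
#' @param hour Hour stamp; default the run's last hour.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below <- function(run, height, tracer = "pollen_mass",
                           hour = NULL) {
  stopifnot(inherits(run, "spp_run"),
            tracer %in% c("pollen_mass", "spp_mass", "shell_number"))
  if (height < 0 || height > max(run$grid$z_levels)) {
    stop("`height` outside the model column", call. = FALSE)
  }
  h <- if (is.null(hour)) length(run$hours) else match(hour, run$hours)
  if (is.na(h)) stop("`hour` not in the run", call. = FALSE)
  conc <- run$site_column[[tracer]][, h]
  zl <- run$grid$z_levels
  dz <- run$grid$dz
  total <- sum(conc * dz)
  if (total <= 0) stop("empty column: fraction undefined", call. = FALSE)
  # thickness of each layer lying below `height`
  below <- pmin(pmax(height - zl[-length(zl)], 0), dz)
  sum(conc * below) / total
}

#' Surface tracer field with a behind-front split
#'
#' Georeferenced surface concentrations at an hour, plus the fraction of
#' the domain-total tracer burden located behind (west of) the storm front
#' line at that time.
#'
#' @param run An `spp_run`.
#' @param hour Hour stamp.
#' @param tracer Tracer name.
#' @param front_x Front x-position, m (grid-relative), e.g. from
#'   [front_position()]; `NULL` for no split.
#' @return Tibble `ix`, `iy`, `lon`, `lat`, `value` with attribute
#'   `"behind_fraction"` (NA when `front_x` is NULL or the field is empty).
#' @export
surface_map <- function(run, hour, tracer = "spp_mass", front_x = NULL) {
  stopifnot(inherits(run, "spp_run"),
            tracer %in% c("pollen_mass", "spp_mass", "shell_number"))
  h <- match(hour, run$hours)
  if (is.na(h)) stop("`hour` not in the run", call. = FALSE)
  field <- run$surface[[tracer]][, , h]
  grid <- run$grid
  cells <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
  out <- index_to_lonlat(grid, cells$ix, cells$iy)
  out$value <- as.vector(field)
  behind <- NA_real_
  if (!is.null(front_x)) {
    x <- (cells$ix - 1) * grid$dx
    total <- sum(out$value)
    behind <- if (total > 0) sum(out$value[x < front_x]) / total else NA_real_
  }
  attr(out, "behind_fraction") <- behind
  out
}
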