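#' Read a lightning strike list from CSV
#'
#' Expected columns: `time` (decimal hours since run start, or an ISO-8601
#' timestamp when `start` is given), `lon`, `lat`. Each record is
#' validated; a malformed row raises an error naming its line.
#'
#' @param path CSV file path.
#' @param start Optional ISO-8601 run start; when given, `time` may be a
#'   timestamp and is converted to decimal hours since `start`.
#' @return Tibble `time` (hours), `lon`, `lat`.
#' @export
read_lightning_csv <- function(path, start = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time", "lon", "lat")
  if (!all(need %in% names(raw))) {
    stop("lightning CSV must have columns time, lon, lat", call. = FALSE)
  }
  time <- raw$time
  if (!is.numeric(time)) {
    if (is.null(start)) {
      stop("timestamped lightning CSV needs `start`", call. = FALSE)
    }
    t0 <- as.POSIXct(start, tz = "UTC")
    time <- as.numeric(difftime(as.POSIXct(time, tz = "UTC"), t0,
                                units = "hours"))
  }
  bad <- !is.finite(time) | !is.finite(raw$lon) | !is.finite(raw$lat) |
    abs(raw$lat) > 90
  if (any(bad)) {
    stop(sprintf("malformed lightning record at line %d of %s",
                 which(bad)[1] + 1L, path), call. = FALSE)
  }
  tibble::tibble(time = time, lon = raw$lon, lat = raw$lat)
}

#' Read hourly pollen observations from CSV
#'
#' Expected columns: `hour` (or `time`), `whole_pollen` and optionally
#' `shells` / `shell_number`, grains m^-3.
#'
#' @param path CSV file path.
#' @return Tibble with `hour`, `whole_pollen` and (if present)
#'   `shell_number`.
#' @export
read_observations_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!"hour" %in% names(raw) && "time" %in% names(raw)) {
    raw$hour <- raw$time
  }
  if (!all(c("hour", "whole_pollen") %in% names(raw))) {
    stop("observations CSV must have columns hour (or time) and whole_pollen",
         call. = FALSE)
  }
  if ("shells" %in% names(raw) && !"shell_number" %in% names(raw)) {
    raw$shell_number <- raw$shells
  }
  keep <- intersect(c("hour", "whole_pollen", "shell_number"), names(raw))
  if (any(raw$whole_pollen < 0, na.rm = TRUE)) {
    stop("negative pollen counts in observations", call. = FALSE)
  }
  tibble::as_tibble(raw[keep])
}

#' Write a gridded field history as self-describing long-format CSV
#'
#' Named-dimension long format: columns `time` (hour stamp), `level`, `y`,
#' `x`, one value column per field, with a leading comment line recording
#' the units. [read_gridded_csv()] round-trips it.
#'
#' @param fields Named list of arrays, either `(nx, ny, n_hours)` surface
#'   fields or `(nx, ny, nz, n_hours)` 3-D fields (mixes allowed; surface
#'   fields are written at level 1).
#' @param grid A [sim_grid()].
#' @param path Output path.
#' @param hours Hour stamps.
#' @param units Named character vector of units per field (stored in the
#'   header comment).
#' @return `path`, invisibly.
#' @export
write_gridded_csv <- function(fields, grid, path, hours, units = NULL) {
  stopifnot(is.list(fields), length(names(fields)) == length(fields))
  long <- NULL
  for (nm in names(fields)) {
    arr <- fields[[nm]]
    if (length(dim(arr)) == 3L) {
      dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3])
    }
    d <- dim(arr)
    df <- tibble::tibble(
      time = rep(hours, each = prod(d[1:3])),
      level = rep(rep(seq_len(d[3]), each = d[1] * d[2]), times = d[4]),
      y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3] * d[4]),
      x = rep(seq_len(d[1]), times = prod(d[2:4])),
      value = as.vector(arr),
      field = nm
    )
    long <- dplyr::bind_rows(long, df)
  }
  long <- tidyr::pivot_wider(long, names_from = "field",
                             values_from = "value")
  hdr <- sprintf("# dims: time,level,y,x; dx=%g m dy=%g m; origin=%.5f,%.5f; units: %s",
                 grid$dx, grid$dy, grid$origin[["lon"]], grid$origin[["lat"]],
                 if (is.null(units)) "unspecified"
                 else paste(names(units), units, sep = "=", collapse = "; "))
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(long, path, append = TRUE, sep = ",",
                       row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Read a long-format gridded CSV back into arrays
#'
#' @param path File written by [write_gridded_csv()].
#' @return Named list of `(nx, ny, nz, n_hours)` arrays, with the header
#'   comment attached as attribute `"header"`.
#' @export
read_gridded_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  dims <- c(max(df$x), max(df$y), max(df$level), length(unique(df$time)))
  df <- df[order(df$time, df$level, df$y, df$x), ]
  value_cols <- setdiff(names(df), c("time", "level", "y", "x"))
  out <- lapply(value_cols, function(nm) array(df[[nm]], dim = dims))
  names(out) <- value_cols
  attr(out, "header") <- hdr
  attr(out, "hours") <- sort(unique(df$time))
  out
}

#' Write the hourly site series of a run to CSV
#'
#' @param run An `spp_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_series <- function(run, path) {
  stopifnot(inherits(run, "spp_run"))
  readr::write_csv(run$site, path)
  invisible(path)
}

#' Write an evaluation result as a small JSON summary
#'
#' @param eval An `eval_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(eval, path) {
  stopifnot(inherits(eval, "eval_result"))
  jsonlite::write_json(
    list(slope = eval$slope, slope_se = eval$slope_se,
         pearson_r = eval$pearson_r, n_hours = eval$n_hours),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
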