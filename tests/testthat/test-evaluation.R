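# minimal run object for the column/series helpers
fake_run <- function(grid = sim_grid(), column = NULL, surface = NULL,
                     n_hours = 3) {
  nz <- grid$nz
  col0 <- matrix(1, nz, n_hours)
  sur0 <- array(1, c(grid$nx, grid$ny, n_hours))
  structure(
    list(grid = grid,
         config = list(pollen_params = pollen_params()),
         hours = seq_len(n_hours) - 1,
         site_index = c(ix = 1L, iy = 1L),
         site_column = list(pollen_mass = column %||% col0,
                            spp_mass = column %||% col0,
                            shell_number = column %||% col0),
         surface = list(pollen_mass = surface %||% sur0,
                        spp_mass = surface %||% sur0,
                        shell_number = surface %||% sur0)),
    class = "spp_run")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("regression statistics match hand-computed values", {
  r1 <- regression_stats(model = 1:10, obs = 1:10)
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_equal(r1$pearson_r, 1, tolerance = 1e-12)
  r2 <- regression_stats(model = 2 * (1:10), obs = 1:10)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$pearson_r, 1, tolerance = 1e-12)
  # four-point example: r = 0.6 by hand
  r3 <- regression_stats(model = c(2, 1, 4, 3), obs = 1:4)
  expect_equal(r3$pearson_r, 0.6, tolerance = 1e-12)
  expect_error(regression_stats(1:2, 1:2), "at least 3")
  expect_error(regression_stats(c(1, 1, 1), 1:3), "zero variance")
  # NA hours dropped pairwise
  r4 <- regression_stats(model = c(1, NA, 3, 4, 5), obs = c(1, 2, 3, NA, 5))
  expect_equal(r4$n_hours, 3)
})

test_that("regression agrees with the covariance formula on random series", {
  set.seed(21)
  for (i in 1:20) {
    o <- rnorm(30); m <- 0.5 * o + rnorm(30, sd = 0.3)
    r <- regression_stats(m, o)
    expect_equal(r$slope, stats::cov(m, o) / stats::var(o),
                 tolerance = 1e-12)
    expect_equal(r$pearson_r,
                 stats::cov(m, o) / sqrt(stats::var(m) * stats::var(o)),
                 tolerance = 1e-12)
    expect_gte(r$pearson_r, -1); expect_lte(r$pearson_r, 1)
  }
})

test_that("tidy and glance methods summarise an evaluation", {
  r <- regression_stats(model = c(2, 1, 4, 3), obs = 1:4)
  td <- tidy(r)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], r$slope)
  g <- glance(r)
  expect_named(g, c("slope", "slope_se", "pearson_r", "n_hours"))
})

test_that("site series extraction picks the nearest cell", {
  grid <- small_grid()
  sur <- array(0, c(grid$nx, grid$ny, 3))
  for (h in 1:3) sur[, , h] <- outer(seq_len(grid$nx), seq_len(grid$ny), `+`) + h
  run <- fake_run(grid, surface = sur)
  at <- index_to_lonlat(grid, 3, 5)
  got <- extract_site_series(run, at$lon, at$lat)
  expect_equal(got$shell_number, sur[3, 5, ])
  # two adjacent cells differ; the nearer one is picked
  near <- index_to_lonlat(grid, 4, 5)
  got2 <- extract_site_series(run, near$lon + 1e-4, near$lat)
  expect_equal(got2$shell_number, sur[4, 5, ])
  # constant field gives a constant series
  runc <- fake_run(grid)
  expect_equal(unique(extract_site_series(runc, at$lon, at$lat)$shell_number),
               1)
  expect_error(extract_site_series(run, 100, 0), "outside")
})

test_that("vertical profile reports the threshold-crossing height", {
  grid <- sim_grid()
  pp <- pollen_params()
  # exponential column: chi(z) = 100 exp(-z/500), crossing 1 grain at
  # z = 500 log(100) = 2302.6 m (log-linear interpolation is exact here)
  chi <- 100 * exp(-grid$z_mid / 500)
  col <- matrix(grains_to_mass(chi, pp), grid$nz, 3)
  run <- fake_run(grid, column = col)
  prof <- vertical_profile(run, 1)
  expect_equal(nrow(prof), grid$nz)
  expect_equal(prof$whole_pollen, chi, tolerance = 1e-6)
  expect_equal(attr(prof, "threshold_height"), 500 * log(100),
               tolerance = 1e-2)
  # uniform column: flat profile, never crosses
  runf <- fake_run(grid, column = matrix(grains_to_mass(5, pp), grid$nz, 3))
  expect_true(is.na(attr(vertical_profile(runf, 0), "threshold_height")))
})

test_that("fraction below a height is thickness-weighted and monotone", {
  grid <- sim_grid()
  run <- fake_run(grid)   # uniform column to 5 km
  expect_equal(fraction_below(run, 40), 40 / 5000, tolerance = 1e-12)
  expect_equal(fraction_below(run, 5000), 1, tolerance = 1e-12)
  # partial layers pro rata
  expect_equal(fraction_below(run, 20), 20 / 5000, tolerance = 1e-12)
  hs <- seq(0, 5000, 100)
  fb <- vapply(hs, function(h) fraction_below(run, h), numeric(1))
  expect_true(all(diff(fb) >= 0))
  # all mass in the lowest 40 m layer
  col <- matrix(0, grid$nz, 3); col[1, ] <- 10
  run1 <- fake_run(grid, column = col)
  expect_equal(fraction_below(run1, 40), 1, tolerance = 1e-12)
  # empty column is undefined
  run0 <- fake_run(grid, column = matrix(0, grid$nz, 3))
  expect_error(fraction_below(run0, 40), "empty column")
})

test_that("surface maps split the burden about the front line", {
  grid <- small_grid()
  west <- array(0, c(grid$nx, grid$ny, 3)); west[1:3, , ] <- 1
  runw <- fake_run(grid, surface = west)
  mw <- surface_map(runw, 1, "spp_mass", front_x = 4 * grid$dx)
  expect_equal(attr(mw, "behind_fraction"), 1)
  sym <- array(1, c(grid$nx, grid$ny, 3))
  runs <- fake_run(grid, surface = sym)
  ms <- surface_map(runs, 1, "spp_mass", front_x = grid$nx / 2 * grid$dx)
  expect_equal(attr(ms, "behind_fraction"), 0.5)
  expect_true(all(c("lon", "lat", "value") %in% names(ms)))
  expect_true(is.na(attr(surface_map(runs, 1, "spp_mass"),
                         "behind_fraction")))
})
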