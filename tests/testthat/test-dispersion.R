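test_that("Stokes settling velocity matches hand calculation", {
  # rho g d^2 / (18 mu): 35 um grain ~0.0369 m/s, 600 nm SPP ~1.08e-5 m/s
  expect_equal(settling_velocity(35e-6, 1000), 0.0369, tolerance = 1e-2)
  expect_equal(settling_velocity(600e-9, 1000), 1.08e-5, tolerance = 1e-2)
  expect_identical(settling_velocity(0, 1000), 0)
  expect_error(settling_velocity(1e-6, -1), "density")
})

test_that("advection preserves constants, moves centroids and conserves mass", {
  grid <- small_grid()
  st <- tracer_state(grid)
  # zero wind: unchanged
  st$pollen_mass[3, 4, 2] <- 5
  met0 <- uniform_met_slice(grid, u = 0)
  expect_identical(advect(st, met0, grid)$pollen_mass, st$pollen_mass)
  # uniform field + uniform wind: interior cells unchanged (boundaries
  # exchange with tracer-free ambient air)
  stu <- tracer_state(grid)
  stu$pollen_mass[] <- 2
  metu <- uniform_met_slice(grid, u = 3, v = -2)
  outu <- advect(stu, metu, grid)
  expect_equal(outu$pollen_mass[3:6, 3:6, ], stu$pollen_mass[3:6, 3:6, ],
               tolerance = 1e-12)
  # monotone: no new extrema
  expect_lte(max(outu$pollen_mass), 2 + 1e-12)
  expect_gte(min(outu$pollen_mass), 0)
  # point release at u = 10 m/s, dt = 600 s, dx = 3000 m: centroid moves
  # exactly 2 cells east (first moment is exact for flux-form upwind)
  stp <- tracer_state(grid)
  stp$pollen_mass[3, 4, 1] <- 10
  outp <- advect(stp, uniform_met_slice(grid, u = 10), grid)
  f <- outp$pollen_mass[, 4, 1]
  expect_equal(sum(f * seq_len(grid$nx)) / sum(f), 5, tolerance = 1e-10)
  # random field and winds: airborne + recorded outflow is conserved
  set.seed(5)
  str <- tracer_state(grid)
  str$pollen_mass[] <- runif(length(str$pollen_mass))
  metr <- uniform_met_slice(grid)
  metr$u[] <- runif(length(metr$u), -6, 6)
  metr$v[] <- runif(length(metr$v), -6, 6)
  metr$w[] <- runif(length(metr$w), -0.02, 0.02)
  before <- total_amount(str, "pollen_mass")
  outr <- advect(str, metr, grid)
  after <- total_amount(outr, "pollen_mass") + outr$outflow[["pollen_mass"]]
  expect_equal(after, before, tolerance = 1e-10)
  expect_gte(min(outr$pollen_mass), 0)
})

test_that("implicit vertical diffusion conserves columns and mixes them", {
  grid <- small_grid()
  st <- tracer_state(grid)
  st$spp_mass[2, 2, 1] <- 100
  # K = 0: unchanged
  expect_identical(diffuse_vertical(st, rep(0, grid$nz), grid)$spp_mass,
                   st$spp_mass)
  # uniform column: unchanged under any K
  stu <- tracer_state(grid)
  stu$spp_mass[] <- 3
  outu <- diffuse_vertical(stu, rep(25, grid$nz), grid)
  expect_equal(outu$spp_mass, stu$spp_mass, tolerance = 1e-12)
  # surface-confined tracer approaches the well-mixed column; burden kept
  stc <- tracer_state(grid)
  stc$spp_mass[2, 2, 1] <- 100
  burden0 <- sum(stc$spp_mass[2, 2, ] * grid$dz)
  out <- stc
  for (i in 1:400) out <- diffuse_vertical(out, rep(60, grid$nz), grid)
  col <- out$spp_mass[2, 2, ]
  expect_equal(sum(col * grid$dz), burden0, tolerance = 1e-10)
  expect_lt(diff(range(col)) / mean(col), 0.02)       # well mixed
  expect_gte(min(out$spp_mass), 0)
})

test_that("settling moves mass downward into the deposition accumulator", {
  grid <- small_grid()
  v0 <- c(pollen_mass = 0, spp_mass = 0, shell_number = 0)
  st <- tracer_state(grid)
  st$pollen_mass[4, 4, 2] <- 7
  # zero velocity: unchanged
  expect_identical(settle_and_deposit(st, grid, v0)$pollen_mass,
                   st$pollen_mass)
  # v dt = lowest-layer thickness: the surface layer empties in one step
  st1 <- tracer_state(grid)
  st1$pollen_mass[4, 4, 1] <- 10
  v <- c(pollen_mass = grid$dz[1] / grid$dt, spp_mass = 0, shell_number = 0)
  out1 <- settle_and_deposit(st1, grid, v)
  expect_equal(out1$pollen_mass[4, 4, 1], 0, tolerance = 1e-12)
  expect_equal(out1$deposited_pollen[4, 4], 10 * grid$dz[1],
               tolerance = 1e-12)
  # airborne + deposited conserved
  set.seed(9)
  str <- tracer_state(grid)
  str$pollen_mass[] <- runif(length(str$pollen_mass))
  vs <- c(pollen_mass = 0.037, spp_mass = 0, shell_number = 0)
  before <- total_amount(str, "pollen_mass")
  outr <- settle_and_deposit(str, grid, vs)
  expect_equal(total_amount(outr, "pollen_mass") +
                 sppsim:::deposited_total(outr, "pollen_mass"),
               before, tolerance = 1e-10)
})

test_that("whole pollen settles out of 100 m within the hour; SPPs stay aloft", {
  # grain fall ~133 m/h vs SPP fall 0.36 m/h at the adopted velocities
  grid <- small_grid()
  st <- tracer_state(grid)
  st$pollen_mass[4, 4, 2] <- 50   # layer 2: 40-150 m
  st$spp_mass[4, 4, 2] <- 50
  v <- c(pollen_mass = settling_velocity(35e-6, 1000), spp_mass = 1e-4,
         shell_number = 0)
  out <- st
  for (i in seq_len(3600 / grid$dt)) out <- settle_and_deposit(out, grid, v)
  pol_airborne <- total_amount(out, "pollen_mass") /
    total_amount(st, "pollen_mass")
  spp_airborne <- total_amount(out, "spp_mass") / total_amount(st, "spp_mass")
  # donor-cell settling smears the falling front, so "fully settles" means
  # most of the burden here; the SPP burden is untouched
  expect_lt(pol_airborne, 0.5)
  expect_gt(spp_airborne, 0.99)
  expect_gt(spp_airborne - pol_airborne, 0.5)
})

test_that("a quiescent step leaves the state invariant", {
  grid <- small_grid()
  config <- experiment_config(
    "rh80", settling = c(pollen_mass = 0, spp_mass = 0, shell_number = 0))
  st <- tracer_state(grid)
  st$pollen_mass[] <- 1
  met <- uniform_met_slice(grid, rh = 50)   # below every trigger
  out <- step_simulation(st, met, grid, config, potential = 0)
  expect_equal(out$state$pollen_mass, st$pollen_mass, tolerance = 1e-12)
  expect_identical(sum(out$state$spp_mass), 0)
  expect_identical(sum(out$state$shell_number), 0)
})

test_that("one humid step converts the rupturing fraction to shells", {
  grid <- small_grid()
  config <- experiment_config(
    "rh80", settling = c(pollen_mass = 0, spp_mass = 0, shell_number = 0))
  st <- tracer_state(grid)
  pp <- config$pollen_params
  st$pollen_mass[2, 3, 1] <- grains_to_mass(10, pp)
  met <- uniform_met_slice(grid, rh = 100)
  out <- step_simulation(st, met, grid, config, potential = 0)
  expect_equal(out$state$shell_number[2, 3, 1], 7, tolerance = 1e-12)
  expect_equal(out$state$spp_mass[2, 3, 1] / (pp$m_spp * 1e6), 7 * 700,
               tolerance = 1e-12)
  # full-grain accounting removes the ruptured grains from the inventory
  config_fg <- experiment_config(
    "rh80", mass_loss_mode = "full_grain",
    settling = c(pollen_mass = 0, spp_mass = 0, shell_number = 0))
  out_fg <- step_simulation(st, met, grid, config_fg, potential = 0)
  expect_equal(mass_to_grains(out_fg$state$pollen_mass[2, 3, 1], pp), 3,
               tolerance = 1e-12)
})

test_that("surface emission increments the lowest layer by F dt / h", {
  grid <- small_grid()
  config <- experiment_config(
    "rh80", settling = c(pollen_mass = 0, spp_mass = 0, shell_number = 0))
  st <- tracer_state(grid)
  met <- uniform_met_slice(grid, rh = 50)
  pot <- 1e-7
  out <- step_simulation(st, met, grid, config, potential = pot)
  act <- config$activity_params
  p_fx <- pot * f_rh(50, act) * f_pr(0, act) * f_ws(0, act)
  expect_equal(out$state$pollen_mass[1, 1, 1],
               p_fx * 1e6 * grid$dt / grid$dz[1], tolerance = 1e-12)
})

test_that("with rupture disabled the SPP and shell tracers stay at zero", {
  grid <- small_grid()
  met <- uniform_met(grid, hours = 4, rh = 50, u = 2, kz = 5)
  run <- run_experiment(experiment_config("rh80"), met, potential = 1e-7,
                        site = c(lon = 144.965, lat = -37.797))
  expect_identical(sum(run$state$spp_mass), 0)
  expect_identical(sum(run$state$shell_number), 0)
  expect_gt(max(run$site$whole_pollen), 0)
  expect_lt(max(run$budget$rel_residual), 1e-8)
})

test_that("budget closes through emission, transport and rupture", {
  grid <- small_grid()
  met <- uniform_met(grid, hours = 6, rh = c(50, 60, 85, 90, 70, 85),
                     u = 3, kz = 5)
  run <- run_experiment(experiment_config("rh80"), met, potential = 1e-7)
  expect_lt(max(run$budget$rel_residual), 1e-8)
  expect_gt(run$state$rupture_grains, 0)
  expect_gte(min(run$state$pollen_mass), 0)
  expect_gte(min(run$state$spp_mass), 0)
  expect_gte(min(run$state$shell_number), 0)
})

test_that("halving the time step changes the site series by < 5%", {
  # first-order scheme: run where the settling Courant number v dt / dz is
  # small so the leading truncation term is resolved
  rh_seq <- c(40, 55, 70, 85, 90, 75, 60, 45, 85, 90, 55, 40)
  series <- function(dt) {
    grid <- small_grid(dt = dt)
    met <- uniform_met(grid, hours = 12, rh = rh_seq, u = 2, kz = 5)
    run_experiment(experiment_config("rh80"), met,
                   potential = 1e-7)$site$whole_pollen
  }
  a <- series(100)
  b <- series(50)
  expect_lt(max(abs(a - b)) / max(b), 0.05)
})
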