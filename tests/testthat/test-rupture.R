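test_that("humidity-threshold rupture follows the threshold and gate", {
  pp <- pollen_params()
  expect_equal(rupture_rh_threshold(100, 85, "high", pp)$n_rupt, 70)
  expect_equal(rupture_rh_threshold(100, 79, "high", pp)$n_rupt, 0)
  expect_equal(rupture_rh_threshold(100, 80, "high", pp)$n_rupt, 70) # at threshold
  # below the 1 grain m^-3 gate nothing ruptures however humid
  expect_equal(rupture_rh_threshold(0.5, 90, "high", pp)$n_rupt, 0)
  # static-electricity mode triggers at low humidity
  expect_equal(rupture_rh_threshold(100, 18, "low", pp)$n_rupt, 70)
  expect_equal(rupture_rh_threshold(100, 31, "low", pp)$n_rupt, 0)
  expect_error(rupture_rh_threshold(100, 85, "sideways"), "arg")
  expect_error(rupture_rh_threshold(-1, 85, "high"), "non-negative")
})

test_that("wind-function rupture has no wind threshold", {
  pp <- pollen_params(); act <- activity_params()
  expect_equal(rupture_fws(100, 5, act, pp)$n_rupt, 70 * f_ws(5, act),
               tolerance = 1e-12)
  # calm air still ruptures at the f_WS floor
  expect_equal(rupture_fws(100, 0, act, pp)$n_rupt, 23.1, tolerance = 1e-12)
  expect_equal(rupture_fws(0, 10, act, pp)$n_rupt, 0)
})

test_that("wind-threshold rupture gates on U_sat and caps at chi", {
  pp <- pollen_params()
  expect_equal(rupture_ws(100, 4.9, pp)$n_rupt, 0)
  expect_equal(rupture_ws(100, 1, pp)$n_rupt, 0)          # below threshold
  expect_equal(rupture_ws(100, 1, pollen_params(ws_threshold = 0))$n_rupt, 70)
  t10 <- rupture_ws(100, 10, pp)
  expect_equal(t10$n_rupt_uncapped, 700)
  expect_equal(t10$n_rupt, 100)                           # cap policy
})

test_that("lightning rupture scales with strike count and caps at chi", {
  pp <- pollen_params()
  expect_equal(rupture_lightning(100, 1, pp)$n_rupt, 70)
  expect_equal(rupture_lightning(100, 0, pp)$n_rupt, 0)
  t6 <- rupture_lightning(100, 6, pp)                     # domain hourly max
  expect_equal(t6$n_rupt_uncapped, 420)
  expect_equal(t6$n_rupt, 100)
  expect_error(rupture_lightning(100, 1.5, pp), "integer")
  expect_error(rupture_lightning(100, -1, pp), "integer")
})

test_that("rupture bookkeeping produces shells, SPP number and mass", {
  pp <- pollen_params()
  st <- list(pollen_mass = grains_to_mass(1, pp), spp_mass = 0,
             shell_number = 0)
  tend <- rupture_rh_threshold(1, 90, "high", pp)
  expect_equal(tend$n_rupt, 0.7)
  one <- rupture_rh_threshold(1, 90, "high",
                              pollen_params(f_rupt = 1))
  new <- apply_rupture(st, one, pp)
  expect_equal(new$shell_number, 1)
  expect_equal(new$spp_mass / (pp$m_spp * 1e6), 700, tolerance = 1e-12)
  # SPP mass produced by one grain: 700 x 1.13e-13 g = 7.91e-11 g m^-3
  expect_equal(new$spp_mass * 1e-6, 7.91e-11, tolerance = 1e-3)
  # default mode removes only the SPP mass from the pollen tracer (~0.35%)
  expect_equal(st$pollen_mass - new$pollen_mass, new$spp_mass,
               tolerance = 1e-12)
  expect_equal((st$pollen_mass - new$pollen_mass) / st$pollen_mass,
               0.00353, tolerance = 1e-2)
  # full-grain mode removes the whole grain mass
  full <- apply_rupture(st, one, pp, mass_loss_mode = "full_grain")
  expect_equal(full$pollen_mass, 0, tolerance = 1e-12)
  # zero tendency leaves the state untouched
  zero <- rupture_rh_threshold(1, 10, "high", pp)
  expect_identical(apply_rupture(st, zero, pp), st)
})

test_that("mechanical rupture flux evaluates the emission formula", {
  pp <- pollen_params(); act <- activity_params()
  # G = 1 - f_PR * f_RH with saturated humidity and no rain: ~0.67
  m <- mech_rupture(1e-6, rh = 100, pr = 0, act = act, params = pp,
                    variant = "rh")
  expect_equal(m, 0.7 * 700 * 1e-6 * 0.67 * (1.13e-13 / 22.4e-9),
               tolerance = 1e-3)
  expect_equal(mech_rupture(0, rh = 50, pr = 0, variant = "rh"), 0)
  expect_equal(mech_rupture(0, ws = 10, variant = "fws"), 0)
  expect_equal(mech_rupture(0, ws = 10, variant = "ws"), 0)
  # wind variant applies the U_sat threshold
  expect_equal(mech_rupture(1e-6, ws = 4, act = act, params = pp,
                            variant = "ws"), 0)
  expect_gt(mech_rupture(1e-6, ws = 6, act = act, params = pp,
                         variant = "ws"), 0)
  # f_WS variant equals the formula
  expect_equal(mech_rupture(1e-6, ws = 5, act = act, params = pp,
                            variant = "fws"),
               0.7 * 700 * 1e-6 * f_ws(5, act) * pp$m_spp / pp$m_pol,
               tolerance = 1e-12)
  # grains companion: one shell per SPP packet of n_spg
  g <- mech_rupture_grains(mech_rupture(1e-6, ws = 5, act = act,
                                        params = pp, variant = "fws"), pp)
  expect_equal(g, 0.7 * 1e-6 * f_ws(5, act) / pp$m_pol, tolerance = 1e-12)
})

test_that("vectorised mechanisms agree with a per-cell scalar reference", {
  set.seed(7)
  pp <- pollen_params(); act <- activity_params()
  n <- 200
  chi <- runif(n, 0, 150); chi[sample(n, 40)] <- runif(40, 0, 0.9)
  rh <- runif(n, 0, 100)
  ws <- runif(n, 0, 12)
  nl <- rpois(n, 1)
  # independent scalar reference of each mechanism row
  ref <- function(chi, rh, ws, nl, law) {
    raw <- switch(law,
      rh_high = if (rh >= 80 && chi >= 1) 0.7 * chi else 0,
      rh_low = if (rh <= 30 && chi >= 1) 0.7 * chi else 0,
      fws = if (chi >= 1) 0.7 * chi * (0.33 + 0.67 * (1 - exp(-ws / 5))) else 0,
      ws = if (ws >= 5 && chi >= 1) 0.7 * chi * ws else 0,
      lightning = if (chi >= 1) 0.7 * chi * nl else 0)
    min(raw, chi)
  }
  got <- list(
    rh_high = rupture_rh_threshold(chi, rh, "high", pp)$n_rupt,
    rh_low = rupture_rh_threshold(chi, rh, "low", pp)$n_rupt,
    fws = rupture_fws(chi, ws, act, pp)$n_rupt,
    ws = rupture_ws(chi, ws, pp)$n_rupt,
    lightning = rupture_lightning(chi, nl, pp)$n_rupt
  )
  for (law in names(got)) {
    want <- mapply(ref, chi, rh, ws, nl, MoreArgs = list(law = law))
    expect_equal(got[[law]], want, tolerance = 1e-12, label = law)
    expect_true(all(got[[law]] <= chi + 1e-12), label = law)
    expect_true(all(got[[law]][chi == 0] == 0), label = law)
  }
  # mechanical rows against the same scalar logic
  pfx <- runif(n, 0, 1e-6); pr <- runif(n, 0, 1)
  ref_mech <- function(pfx, rh, pr, ws, variant) {
    g <- switch(variant,
      rh = 1 - (0.33 + 0.67 * logistic(pr, act$pr_logistic) /
                  logistic(0, act$pr_logistic)) *
        (0.33 + 0.67 * logistic(rh, act$rh_logistic)),
      fws = 0.33 + 0.67 * (1 - exp(-ws / 5)),
      ws = if (ws >= 5) ws else 0)
    0.7 * 700 * pfx * g * 1.13e-13 / 22.4e-9
  }
  for (variant in c("rh", "fws", "ws")) {
    want <- mapply(ref_mech, pfx, rh, pr, ws,
                   MoreArgs = list(variant = variant))
    got_m <- mech_rupture(pfx, rh = rh, pr = pr, ws = ws, act = act,
                          params = pp, variant = variant)
    expect_equal(got_m, want, tolerance = 1e-12, label = variant)
  }
})

test_that("number bookkeeping is exact across accumulated ruptures", {
  set.seed(3)
  pp <- pollen_params()
  shells <- 0; spp_n <- 0; nr_total <- 0
  for (i in 1:50) {
    chi <- runif(1, 0, 200)
    tend <- rupture_rh_threshold(chi, runif(1, 60, 100), "high", pp)
    nr_total <- nr_total + tend$n_rupt
    shells <- shells + tend$n_rupt
    spp_n <- spp_n + tend$spp_number
  }
  expect_equal(shells, nr_total, tolerance = 1e-10)
  expect_equal(spp_n, pp$n_spg * nr_total, tolerance = 1e-10)
})
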