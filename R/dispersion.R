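#' Stokes terminal settling velocity
#'
#' `v_s = rho * g * d^2 / (18 * mu_air)` with air dynamic viscosity
#' `mu_air = 1.81e-5` Pa s. Gives ~0.037 m s^-1 for a 35 um, 1000 kg m^-3
#' pollen grain and ~1.1e-5 m s^-1 for a 600 nm SPP. Per-tracer velocities
#' are overridable in the experiment configuration (the SPP default there is
#' 1e-4 m s^-1, the value adopted for sub-pollen particles in this
#' parameterisation family).
#'
#' @param diameter Particle diameter, m (> 0).
#' @param density Particle density, kg m^-3 (> 0).
#' @return Terminal velocity, m s^-1.
#' @export
#' @examples
#' settling_velocity(35e-6, 1000)
settling_velocity <- function(diameter, density) {
  if (!is.numeric(diameter) || !is.numeric(density) ||
      any(diameter < 0) || any(density <= 0)) {
    stop("diameter must be >= 0 and density > 0", call. = FALSE)
  }
  mu_air <- 1.81e-5
  density * 9.81 * diameter^2 / (18 * mu_air)
}

# --- first-order upwind advection (flux form, dimensionally split) --------

# One 1-D upwind sweep along dimension `along` of a (nx,ny,nz) array.
# Face velocities are averages of adjacent cell-centred values; domain
# boundaries use the edge cell's velocity, inflowing air is tracer-free and
# outflowing flux is returned (as concentration equivalents at each of the
# two boundary slabs) for budget accounting.
upwind_sweep <- function(C, vel, dtau, dspace, along) {
  dims <- dim(C)
  n <- dims[along]
  # move `along` to the first dimension
  perm <- c(along, setdiff(1:3, along))
  Cp <- aperm(C, perm)
  Vp <- aperm(vel, perm)
  dp <- dim(Cp)
  # interior face velocities (n-1 faces)
  vf <- 0.5 * (Vp[-n, , , drop = FALSE] + Vp[-1, , , drop = FALSE])
  crn <- dtau / dspace
  Fint <- (pmax(vf, 0) * Cp[-n, , , drop = FALSE] +
           pmin(vf, 0) * Cp[-1, , , drop = FALSE]) * crn
  Flow <- pmin(Vp[1, , , drop = FALSE], 0) * Cp[1, , , drop = FALSE] * crn
  Fhigh <- pmax(Vp[n, , , drop = FALSE], 0) * Cp[n, , , drop = FALSE] * crn
  Ffull <- array(0, dim = c(n + 1L, dp[2], dp[3]))
  Ffull[1, , ] <- Flow
  if (n > 1) Ffull[2:n, , ] <- Fint
  Ffull[n + 1L, , ] <- Fhigh
  Cp <- Cp - (Ffull[-1, , , drop = FALSE] - Ffull[-(n + 1L), , , drop = FALSE])
  list(
    C = aperm(Cp, order(perm)),
    # outflow as concentration leaving each boundary slab (>= 0)
    out_low = -array(Flow, dim = dp[2:3]),
    out_high = array(Fhigh, dim = dp[2:3])
  )
}

# Vertical upwind sweep on non-uniform layers: flux form on layer burdens
# (C * dz), zero flux through the ground (callers clip downward w in the
# lowest layer), outflow through the domain top returned per column as a
# burden (concentration * m).
upwind_sweep_z <- function(C, w, dtau, dz) {
  nz <- length(dz)
  dims <- dim(C)
  if (nz == 1L) {
    top <- pmax(w[, , 1], 0) * C[, , 1] * dtau
    C[, , 1] <- C[, , 1] - top / dz[1]
    return(list(C = C, out_top = top))
  }
  # interface velocities between k and k+1 (nz-1 interfaces)
  wf <- 0.5 * (w[, , -nz, drop = FALSE] + w[, , -1, drop = FALSE])
  # upward flux positive; donor cell. F has units conc * m per substep.
  Fint <- (pmax(wf, 0) * C[, , -nz, drop = FALSE] +
           pmin(wf, 0) * C[, , -1, drop = FALSE]) * dtau
  Ftop <- pmax(w[, , nz], 0) * C[, , nz] * dtau
  for (k in seq_len(nz)) {
    f_below <- if (k == 1) 0 else Fint[, , k - 1]
    f_above <- if (k == nz) Ftop else Fint[, , k]
    C[, , k] <- C[, , k] + (f_below - f_above) / dz[k]
  }
  list(C = C, out_top = Ftop)
}

#' Advect the tracer fields
#'
#' First-order upwind transport of all three tracers in flux form with
#' dimensional splitting (x, then y, then z). Mass is conserved to roundoff
#' (airborne + recorded boundary outflow); the scheme is
#' positivity-preserving and monotone. The time step is automatically
#' sub-divided so that the total outflow Courant number of every cell stays
#' at or below one; no vertical advective flux crosses the ground.
#'
#' @param state A [tracer_state()].
#' @param met_t List with `u`, `v`, `w` arrays `(nx, ny, nz)`, m s^-1.
#' @param grid A [sim_grid()].
#' @param max_substeps Abort if more sub-steps than this would be needed.
#' @return The updated `tracer_state` (boundary outflow accumulated into
#'   `state$outflow` per tracer).
#' @export
advect <- function(state, met_t, grid, max_substeps = 200L) {
  cfl <- max(2 * max(abs(met_t$u)) * grid$dt / grid$dx,
             2 * max(abs(met_t$v)) * grid$dt / grid$dy,
             2 * max(abs(met_t$w)) * grid$dt / min(grid$dz))
  nsub <- max(1L, ceiling(cfl))
  if (nsub > max_substeps) {
    stop(sprintf("advection would need %d sub-steps (> %d); reduce dt or winds",
                 nsub, max_substeps), call. = FALSE)
  }
  dtau <- grid$dt / nsub
  # vertical velocity with zero flux through the ground: handled by the
  # sweep's boundary convention only when w >= 0 at the lowest level, so
  # explicitly zero any downward velocity in the bottom layer (settling is
  # modelled separately).
  wz <- met_t$w
  wz[, , 1] <- pmax(wz[, , 1], 0)
  cell_area <- grid$dx * grid$dy
  for (tracer in c("pollen_mass", "spp_mass", "shell_number")) {
    C <- state[[tracer]]
    out_mass <- 0
    for (s in seq_len(nsub)) {
      sx <- upwind_sweep(C, met_t$u, dtau, grid$dx, along = 1L)
      # out_* dims (ny, nz): weight by dy*dz*dx? mass = conc * cell volume
      out_mass <- out_mass +
        sum((sx$out_low + sx$out_high) *
              rep(grid$dz, each = grid$ny)) * cell_area
      C <- sx$C
      sy <- upwind_sweep(C, met_t$v, dtau, grid$dy, along = 2L)
      out_mass <- out_mass +
        sum((sy$out_low + sy$out_high) *
              rep(grid$dz, each = grid$nx)) * cell_area
      C <- sy$C
      sz <- upwind_sweep_z(C, wz, dtau, grid$dz)
      C <- sz$C
      out_mass <- out_mass + sum(sz$out_top) * cell_area
      # ground-side flux is zero by construction (w clipped upward at k=1)
    }
    state[[tracer]] <- C
    state$outflow[[tracer]] <- state$outflow[[tracer]] + out_mass
  }
  state
}

#' Vertical diffusion (implicit)
#'
#' Unconditionally stable implicit (backward Euler) vertical mixing in flux
#' form with zero-flux top and bottom boundaries, solved column-by-column
#' with the Thomas algorithm (vectorised across columns). Column burden
#' `sum(dz_k * C_k)` is conserved to roundoff; concentrations stay
#' non-negative.
#'
#' @param state A [tracer_state()].
#' @param kz_t Numeric vector of eddy diffusivities at layer mid-heights,
#'   m^2 s^-1, length `nz`.
#' @param grid A [sim_grid()].
#' @return The updated `tracer_state`.
#' @export
diffuse_vertical <- function(state, kz_t, grid) {
  nz <- grid$nz
  if (length(kz_t) != nz || any(kz_t < 0)) {
    stop("`kz_t` must be a non-negative vector of length nz", call. = FALSE)
  }
  if (all(kz_t == 0) || nz == 1L) return(state)
  dz <- grid$dz
  h <- diff(grid$z_mid)                       # centre spacing, nz-1
  kf <- 0.5 * (kz_t[-nz] + kz_t[-1])          # interface K
  A <- kf / h                                 # conductance per interface
  dt <- grid$dt
  # tridiagonal coefficients (same for every column)
  Am <- c(0, A)        # lower interface conductance for level k
  Ap <- c(A, 0)        # upper interface conductance for level k
  diag_b <- dz / dt + Am + Ap
  for (tracer in c("pollen_mass", "spp_mass", "shell_number")) {
    C <- state[[tracer]]
    M <- matrix(C, nrow = grid$nx * grid$ny, ncol = nz)
    # Thomas forward sweep
    cp <- numeric(nz)
    Dp <- matrix(0, nrow(M), nz)
    cp[1] <- -Ap[1] / diag_b[1]
    Dp[, 1] <- (dz[1] / dt * M[, 1]) / diag_b[1]
    for (k in 2:nz) {
      denom <- diag_b[k] + Am[k] * cp[k - 1]
      cp[k] <- -Ap[k] / denom
      Dp[, k] <- (dz[k] / dt * M[, k] + Am[k] * Dp[, k - 1]) / denom
    }
    M[, nz] <- Dp[, nz]
    for (k in (nz - 1):1) {
      M[, k] <- Dp[, k] - cp[k] * M[, k + 1]
    }
    state[[tracer]] <- array(M, dim = dim(C))
  }
  state
}

#' Gravitational settling and surface dry deposition
#'
#' Explicit donor-cell downward flux `v_s * C` between layers; the flux
#' through the lowest layer's base is moved to the surface deposition
#' accumulator. The per-layer settled fraction is limited to 1 (a particle
#' cannot fall further than one layer per step at the velocities used here).
#' Airborne + deposited amount is conserved exactly.
#'
#' @param state A [tracer_state()].
#' @param grid A [sim_grid()].
#' @param velocities Named numeric: settling velocity (m s^-1) per tracer,
#'   names `pollen_mass`, `spp_mass`, `shell_number`.
#' @return The updated `tracer_state`.
#' @export
settle_and_deposit <- function(state, grid, velocities) {
  if (any(velocities < 0)) stop("settling velocities must be >= 0", call. = FALSE)
  nz <- grid$nz
  dz <- grid$dz
  dep_field <- c(pollen_mass = "deposited_pollen", spp_mass = "deposited_spp",
                 shell_number = "deposited_shell")
  for (tracer in names(dep_field)) {
    v <- velocities[[tracer]]
    if (v == 0) next
    C <- state[[tracer]]
    frac <- pmin(v * grid$dt / dz, 1)
    moved <- sweep(C, 3, frac, `*`)          # concentration leaving each layer
    C <- C - moved
    if (nz > 1) {
      for (k in 2:nz) {
        C[, , k - 1] <- C[, , k - 1] + moved[, , k] * dz[k] / dz[k - 1]
      }
    }
    state[[tracer]] <- C
    dep <- dep_field[[tracer]]
    state[[dep]] <- state[[dep]] + moved[, , 1] * dz[1]   # per m^2
  }
  state
}

#' Advance the simulation by one model time step
#'
#' Operator sequence: transport first (advection, vertical diffusion,
#' settling/deposition), then surface emissions (whole-pollen flux plus any
#' on-plant mechanical-rupture SPP and shell flux into the lowest layer),
#' and in-atmosphere rupture last, acting on the freshly updated airborne
#' whole-pollen concentration. Transport of the rupture products therefore
#' begins at the start of the next step.
#'
#' @param state A [tracer_state()].
#' @param met_t List of met slices at the current hour: `u`, `v`, `w`,
#'   `rh` (`(nx, ny, nz)`), `precip`, `lightning` (`(nx, ny)`), `kz` (length
#'   `nz`).
#' @param grid A [sim_grid()].
#' @param experiment An [experiment_config()].
#' @param potential Surface pollen emission potential, g m^-2 s^-1
#'   (`(nx, ny)` matrix or scalar).
#' @return List with the updated `state` and a `diagnostics` list
#'   (`ruptured_grains`, `emitted_pollen`, `emitted_spp`, `site tendencies`
#'   are accumulated on the state's budget fields).
#' @export
step_simulation <- function(state, met_t, grid, experiment, potential) {
  act <- experiment$activity_params
  pp <- experiment$pollen_params
  # -- transport ---------------------------------------------------------
  state <- advect(state, met_t, grid)
  state <- diffuse_vertical(state, met_t$kz, grid)
  state <- settle_and_deposit(state, grid, experiment$settling)
  # -- surface emission --------------------------------------------------
  sfc_rh <- met_t$rh[, , 1]
  sfc_ws <- sqrt(met_t$u[, , 1]^2 + met_t$v[, , 1]^2)
  p_fx <- pollen_emission_flux(potential, rh = sfc_rh, pr = met_t$precip,
                               ws = sfc_ws, act = act)
  dz1 <- grid$dz[1]
  cell_area <- grid$dx * grid$dy
  state$pollen_mass[, , 1] <- state$pollen_mass[, , 1] +
    p_fx * 1e6 * grid$dt / dz1
  state$emitted[["pollen_mass"]] <- state$emitted[["pollen_mass"]] +
    sum(p_fx) * 1e6 * grid$dt * cell_area
  mech_grains <- 0
  if (experiment$mechanical_rule != "none") {
    m_fx <- mech_rupture(p_fx, rh = sfc_rh, pr = met_t$precip, ws = sfc_ws,
                         act = act, params = pp,
                         variant = experiment$mechanical_rule)
    g_fx <- mech_rupture_grains(m_fx, pp)    # grains m^-2 s^-1 -> shells
    state$spp_mass[, , 1] <- state$spp_mass[, , 1] +
      m_fx * 1e6 * grid$dt / dz1
    state$shell_number[, , 1] <- state$shell_number[, , 1] +
      g_fx * grid$dt / dz1
    state$emitted[["spp_mass"]] <- state$emitted[["spp_mass"]] +
      sum(m_fx) * 1e6 * grid$dt * cell_area
    state$emitted[["shell_number"]] <- state$emitted[["shell_number"]] +
      sum(g_fx) * grid$dt * cell_area
    mech_grains <- sum(g_fx) * grid$dt * cell_area
  }
  # -- in-atmosphere rupture (end of step) -------------------------------
  tend <- NULL
  if (experiment$in_atmosphere_rule != "none") {
    chi <- mass_to_grains(state$pollen_mass, pp)
    gate <- experiment$gate_all_mechanisms
    ws3 <- NULL
    if (experiment$in_atmosphere_rule %in% c("fws", "ws")) {
      ws3 <- sqrt(met_t$u^2 + met_t$v^2)
    }
    tend <- switch(experiment$in_atmosphere_rule,
      rh_high = rupture_rh_threshold(chi, met_t$rh, "high", pp),
      rh_low = rupture_rh_threshold(chi, met_t$rh, "low", pp),
      fws = rupture_fws(chi, ws3, act, pp, gate = gate),
      ws = rupture_ws(chi, ws3, pp, gate = gate),
      lightning = {
        nl3 <- array(rep(met_t$lightning, times = grid$nz),
                     dim = c(grid$nx, grid$ny, grid$nz))
        rupture_lightning(chi, nl3, pp, gate = gate)
      })
    # per-step fractional rupture: tendency is per step by construction
    loss_mode <- experiment$mass_loss_mode
    before <- state$pollen_mass
    state[c("pollen_mass", "spp_mass", "shell_number")] <-
      apply_rupture(state[c("pollen_mass", "spp_mass", "shell_number")],
                    tend, pp, mass_loss_mode = loss_mode)
    # domain-integrated budgets
    vol_k <- grid$dz * cell_area
    sum_vol <- function(x) {
      s <- 0
      for (k in seq_len(grid$nz)) s <- s + sum(x[, , k]) * vol_k[k]
      s
    }
    state$rupture_grains <- state$rupture_grains + sum_vol(tend$n_rupt)
    state$rupture_shells <- state$rupture_shells + sum_vol(tend$n_rupt)
    state$rupture_spp_mass <- state$rupture_spp_mass + sum_vol(tend$spp_mass)
    state$rupture_loss_pollen <- state$rupture_loss_pollen +
      sum_vol(before - state$pollen_mass)
  }
  list(state = state, tendency = tend, mech_grains = mech_grains)
}
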