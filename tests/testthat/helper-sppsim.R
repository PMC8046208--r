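# Small grids and uniform met records used across the unit tests.

small_grid <- function(nx = 8, ny = 8, nz = 4, dt = 600) {
  # origin places the default evaluation site near cell (5, 5)
  sim_grid(nx = nx, ny = ny, dx = 3000, dy = 3000,
           z_levels = c(0, 40, 150, 500, 1500)[seq_len(nz + 1)],
           dt = dt, origin = c(lon = 144.8286, lat = -37.9056))
}

# spatially uniform hourly met; any argument may be a vector over hours
uniform_met <- function(grid, hours = 6, rh = 50, temp = 25, u = 0, v = 0,
                        w = 0, precip = 0, kz = 0, lightning = 0) {
  nt <- hours
  rep_h <- function(x) rep(x, length.out = nt)
  d4 <- c(grid$nx, grid$ny, grid$nz, nt)
  f4 <- function(x) array(rep(rep_h(x), each = prod(d4[1:3])), dim = d4)
  d3 <- c(grid$nx, grid$ny, nt)
  f3 <- function(x) array(rep(rep_h(x), each = prod(d3[1:2])), dim = d3)
  met_fields(grid,
             temp = f4(temp), rh = f4(rh), u = f4(u), v = f4(v), w = f4(w),
             precip = f3(precip), lightning = f3(lightning),
             kz = matrix(rep(rep_h(kz), each = grid$nz), grid$nz, nt),
             hours = seq_len(nt) - 1)
}

# met slice for direct step/advect calls
uniform_met_slice <- function(grid, rh = 50, u = 0, v = 0, w = 0,
                              precip = 0, kz = 0, lightning = 0) {
  d3 <- c(grid$nx, grid$ny, grid$nz)
  list(u = array(u, d3), v = array(v, d3), w = array(w, d3),
       rh = array(rh, d3),
       precip = matrix(precip, grid$nx, grid$ny),
       lightning = matrix(lightning, grid$nx, grid$ny),
       kz = rep(kz, grid$nz))
}

total_amount <- function(state, tracer) {
  sppsim:::domain_total(state, tracer)
}
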