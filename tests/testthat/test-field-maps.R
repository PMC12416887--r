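# Gaussian charge spreading, spectral Poisson solve vs erf closed form,
# external ramp, probing, averaging and DX round trips.

one_charge_system <- function(q = 1, pos = c(0, 0, 0), L = 48) {
  gs <- grid_spec(c(L, L, L), spacing = 1)
  rho <- spread_charges(matrix(pos, 1, 3), q, gs)
  list(gs = gs, rho = rho)
}

test_that("spread charge integrates to the total charge", {
  sys <- one_charge_system()
  h3 <- prod(sys$gs$spacing)
  expect_equal(sum(sys$rho) * h3, 1, tolerance = 1e-3)
  # two opposite charges integrate to zero
  gs <- grid_spec(c(40, 40, 40))
  rho2 <- spread_charges(rbind(c(-5, 0, 0), c(5, 0, 0)), c(1, -1), gs)
  expect_lt(abs(sum(rho2) * prod(gs$spacing)), 1e-6)
})

test_that("density at probe points matches the periodic Gaussian sum", {
  gs <- grid_spec(c(24, 24, 24))
  pos <- c(2.3, -4.1, 9.7)
  rho <- spread_charges(matrix(pos, 1, 3), 1.5, gs, beta = 0.25)
  beta <- 0.25
  pts <- rbind(c(0, 0, 0), c(3, -3, 10), c(-11, 11, -11))
  for (r in seq_len(nrow(pts))) {
    # direct sum over periodic images (+-2 boxes is ample at beta = 0.25)
    img <- expand.grid(i = -2:2, j = -2:2, k = -2:2)
    d2 <- (pts[r, 1] - pos[1] - 24 * img$i)^2 +
      (pts[r, 2] - pos[2] - 24 * img$j)^2 +
      (pts[r, 3] - pos[3] - 24 * img$k)^2
    oracle <- 1.5 * (beta / sqrt(pi))^3 * sum(exp(-beta^2 * d2))
    node <- (pts[r, ] - gs$origin) / gs$spacing + 1
    expect_equal(rho[node[1], node[2], node[3]], oracle,
                 tolerance = 1e-8)
  }
})

test_that("Poisson solution matches the erf closed form within 1%", {
  L <- 48
  sys <- one_charge_system(L = L)
  phi <- solve_poisson_periodic(sys$rho)
  beta <- 0.25
  rr <- 2:(L / 4)
  num <- probe_grid(phi, cbind(rr, 0, 0))$value
  erf <- 2 * stats::pnorm(sqrt(2) * beta * rr) - 1
  # closed form + uniform neutralizing-background term, constant gauge
  closed <- (erf / rr + 2 * pi * rr^2 / (3 * L^3)) * 14399.645
  off <- mean(num - closed)
  rel <- abs(num - closed - off) / abs(erf / rr * 14399.645)
  expect_lt(max(rel), 0.01)
})

test_that("dipole potential is antisymmetric and zero on the midplane", {
  gs <- grid_spec(c(32, 32, 32))
  rho <- spread_charges(rbind(c(0, 0, 6), c(0, 0, -6)), c(1, -1), gs)
  phi <- solve_poisson_periodic(rho)
  pts_up <- cbind(runif(20, -10, 10), runif(20, -10, 10), runif(20, 1, 12))
  up <- probe_grid(phi, pts_up)$value
  pts_dn <- pts_up
  pts_dn[, 3] <- -pts_dn[, 3]
  dn <- probe_grid(phi, pts_dn)$value
  expect_equal(up, -dn, tolerance = 1e-8)
  mid <- probe_grid(phi, cbind(runif(10, -10, 10), runif(10, -10, 10),
                               0))$value
  expect_lt(max(abs(mid)), 1e-8)
})

test_that("solver is linear and refines under grid halving", {
  gsA <- grid_spec(c(24, 24, 24), spacing = 1)
  r1 <- spread_charges(matrix(c(3, 0, 0), 1, 3), 1, gsA)
  r2 <- spread_charges(matrix(c(-3, 2, 0), 1, 3), -0.5, gsA)
  both <- spread_charges(rbind(c(3, 0, 0), c(-3, 2, 0)), c(1, -0.5), gsA)
  p_sum <- solve_poisson_periodic(r1) + solve_poisson_periodic(r2)
  p_both <- solve_poisson_periodic(both)
  expect_equal(unclass(p_both), unclass(p_sum), tolerance = 1e-10,
               ignore_attr = TRUE)
  # halving the spacing changes the probed potential by < 0.5%
  gsB <- grid_spec(c(24, 24, 24), spacing = 0.5)
  phiA <- solve_poisson_periodic(r1)
  phiB <- solve_poisson_periodic(
    spread_charges(matrix(c(3, 0, 0), 1, 3), 1, gsB))
  pts <- cbind(c(8, -6, 0), c(0, 3, 7), c(1, 2, -5))
  vA <- probe_grid(phiA, pts)$value
  vB <- probe_grid(phiB, pts)$value
  expect_lt(max(abs(vA - vB) / abs(vB)), 0.005)
})

test_that("external ramp applies V across the membrane span", {
  gs <- grid_spec(c(20, 20, 60))
  empty <- solve_poisson_periodic(
    spread_charges(matrix(0, 1, 3), 0, gs))
  withV <- add_external_potential(empty, 750, membrane_span = c(-20, 20))
  lo <- probe_grid(withV, c(0, 0, -25))$value
  hi <- probe_grid(withV, c(0, 0, 25))$value
  expect_equal(hi - lo, 750, tolerance = 1e-9)
  # slope equals V / span thickness at interior columns
  v1 <- probe_grid(withV, c(3, -4, -5))$value
  v2 <- probe_grid(withV, c(3, -4, 5))$value
  expect_equal((v2 - v1) / 10, 750 / 40, tolerance = 1e-9)
  # adding the negated ramp restores the original grid exactly
  back <- add_external_potential(withV, -750, membrane_span = c(-20, 20))
  expect_equal(unclass(back), unclass(empty), ignore_attr = TRUE)
  # sensed fraction reproduces the analytic electrical distance
  zs <- seq(-18, 18, by = 4)
  sensed <- (probe_grid(withV, cbind(0, 0, zs))$value - lo) / 750
  expect_equal(sensed, electrical_distance(zs, c(-20, 20)),
               tolerance = 1e-9)
})

test_that("time averaging is the arithmetic mean of per-frame maps", {
  gs <- grid_spec(c(20, 20, 20))
  top <- make_bead_topology(1, charge = 1)
  coords <- array(0, c(1, 3, 2))
  coords[1, , 1] <- c(0, 0, 4)
  coords[1, , 2] <- c(0, 0, -4)
  traj <- new_trajectory(coords, c(20, 20, 20))
  avg <- time_average_maps(traj, top, gs = gs)
  expect_equal(attr(avg, "frames_averaged"), 2L)
  f1 <- solve_poisson_periodic(
    spread_charges(matrix(coords[1, , 1], 1, 3), 1, gs))
  f2 <- solve_poisson_periodic(
    spread_charges(matrix(coords[1, , 2], 1, 3), 1, gs))
  expect_equal(unclass(avg), (unclass(f1) + unclass(f2)) / 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  # a single-frame window equals that frame's map
  one <- time_average_maps(traj, top, window = 1, gs = gs)
  expect_equal(unclass(one), unclass(f1), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(time_average_maps(traj, top, window = integer(0)), "empty")
})

test_that("probing interpolates trilinearly and respects nodes", {
  gs <- grid_spec(c(8, 8, 8))
  arr <- array(rnorm(prod(gs$dims)), gs$dims)
  grid <- structure(arr, class = "potential_grid", grid_spec = gs,
                    beta = 0.25, frames_averaged = 1L)
  # node value: exact
  node <- gs$origin + gs$spacing * c(2, 3, 4)
  expect_equal(probe_grid(grid, node)$value, arr[3, 4, 5])
  # midpoint of two nodes along x: arithmetic mean
  mid <- gs$origin + gs$spacing * c(2.5, 3, 4)
  expect_equal(probe_grid(grid, mid)$value,
               mean(c(arr[3, 4, 5], arr[4, 4, 5])))
  # random points vs an independent trilinear oracle
  set.seed(9)
  for (i in 1:10) {
    p <- runif(3, -4, 4)
    u <- (p - gs$origin) / gs$spacing
    i0 <- floor(u); fr <- u - i0
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      idx <- (i0 + c(dx, dy, dz)) %% gs$dims + 1
      val <- val + prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr)) *
        arr[idx[1], idx[2], idx[3]]
    }
    expect_equal(probe_grid(grid, p)$value, val, tolerance = 1e-10)
  }
  # plane extraction carries coordinates and errors on bad normals
  pl <- probe_plane(grid, c(0, 0, 0), c(0, 0, 1), extent = 2, spacing = 1)
  expect_equal(nrow(pl), 25)
  expect_true(all(abs(pl$z) < 1e-12))
  expect_error(probe_plane(grid, c(0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("DX grids round-trip", {
  gs <- grid_spec(c(10, 12, 14))
  arr <- array(rnorm(prod(gs$dims)), gs$dims)
  grid <- structure(arr, class = "potential_grid", grid_spec = gs,
                    beta = 0.25, frames_averaged = 3L)
  tmp <- withr::local_tempfile(fileext = ".dx")
  write_dx(grid, tmp)
  back <- read_dx(tmp)
  expect_equal(unclass(back), unclass(grid), tolerance = 1e-9,
               ignore_attr = TRUE)
  gsb <- attr(back, "grid_spec")
  expect_equal(gsb$dims, gs$dims)
  expect_equal(gsb$origin, gs$origin)
})
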