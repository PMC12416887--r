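# TI quadrature, coupling factors, gating-charge aggregation, slab
# capacitor recovery, block averaging.

test_that("trapezoidal TI is exact for constants and linear mean forces", {
  const <- ti_curve(mean_force = rep(3.2, 11), residue = "X", state = "c",
                    voltage = 0)
  expect_equal(integrate_ti(const)$delta_G, 3.2)
  lin <- ti_curve(mean_force = seq(0, 1, by = 0.1))
  expect_equal(integrate_ti(lin)$delta_G, 0.5)
  # lambda^2 on the 11-point grid: hand trapezoid sum = 0.335 (exact 1/3)
  quad <- ti_curve(mean_force = seq(0, 1, by = 0.1)^2)
  expect_equal(integrate_ti(quad)$delta_G, 0.335)
  expect_error(integrate_ti(ti_curve(lambda = seq(0, 0.9, by = 0.1),
                                     mean_force = rep(1, 10))),
               "span")
})

test_that("coupling factors recover slab electrical distances exactly", {
  charges <- data.frame(
    label = c("mid", "bulk", "r1", "r2", "r3"),
    q = c(1, 1, 1.4, -0.7, 2.1),
    x = 0, y = 0,
    z_resting = c(0, -35, -6, 13, 2),
    z_activated = c(0, -35, 8, 18, -11)
  )
  spec <- slab_system_spec(c(-20, 20), 750, charges, box = c(40, 40, 80))
  slab <- build_slab_system(spec)
  # charge at the membrane centre: f = 0.5 from TI at 0 and 750 mV
  cv750 <- slab_ti_curves(slab, spec, "resting", 750)
  cv0 <- slab_ti_curves(slab, spec, "resting", 0)
  g750 <- integrate_ti(cv750[cv750$residue == "mid", ])
  g0 <- integrate_ti(cv0[cv0$residue == "mid", ])
  f <- coupling_factor(g750, g0, q = 1)
  expect_equal(f$f, 0.5, tolerance = 1e-12)
  # charge in the intracellular bulk: f = 0
  gb750 <- integrate_ti(cv750[cv750$residue == "bulk", ])
  gb0 <- integrate_ti(cv0[cv0$residue == "bulk", ])
  expect_equal(coupling_factor(gb750, gb0, q = 1)$f, 0, tolerance = 1e-12)
  # randomized positions: TI-derived f equals the analytic fraction to 1e-10
  for (lb in c("r1", "r2", "r3")) {
    ga <- integrate_ti(cv750[cv750$residue == lb, ])
    gb <- integrate_ti(cv0[cv0$residue == lb, ])
    fan <- slab$couplings$f_resting[slab$couplings$label == lb]
    expect_equal(coupling_factor(ga, gb,
                                 charges$q[charges$label == lb])$f,
                 fan, tolerance = 1e-10)
  }
  expect_error(coupling_factor(g750, g750, q = 1), "different voltages")
  expect_error(coupling_factor(g750, g0, q = 0), "non-zero")
})

test_that("slab gating charge equals the displacement-charge oracle", {
  set.seed(8)
  charges <- data.frame(
    label = paste0("c", 1:3), q = c(1, -1, 0.5),
    x = runif(3, -10, 10), y = runif(3, -10, 10),
    z_resting = runif(3, -19, 19), z_activated = runif(3, -19, 19)
  )
  spec <- slab_system_spec(c(-20, 20), 750, charges, box = c(40, 40, 80))
  tab <- slab_gating_charge(spec)
  # capacitor oracle: sum q dz / L for in-membrane movements
  oracle <- sum(charges$q *
                  (charges$z_activated - charges$z_resting) / 40)
  expect_equal(attr(tab, "total"), oracle, tolerance = 1e-10)
  # per-charge contributions match q dz / L row by row
  expect_equal(tab$contribution,
               charges$q * (charges$z_activated - charges$z_resting) / 40,
               tolerance = 1e-10)
  # zero-movement null: identical states give exactly zero everywhere
  null_spec <- slab_system_spec(
    c(-20, 20), 750,
    transform(charges, z_activated = z_resting), box = c(40, 40, 80))
  null_tab <- slab_gating_charge(null_spec)
  expect_identical(unique(null_tab$contribution), 0)
})

test_that("gauge shift of all mean forces cancels in the coupling factor", {
  base <- seq(0, 1, by = 0.1) * 0.7
  g1 <- integrate_ti(ti_curve(mean_force = base, residue = "X",
                              state = "c", voltage = 0))
  g2 <- integrate_ti(ti_curve(mean_force = base + 5.5, residue = "X",
                              state = "c", voltage = 750))
  g2s <- integrate_ti(ti_curve(mean_force = base + 5.5 + 2.2,
                               residue = "X", state = "c", voltage = 750))
  g1s <- integrate_ti(ti_curve(mean_force = base + 2.2, residue = "X",
                               state = "c", voltage = 0))
  expect_equal(coupling_factor(g2, g1, 1)$f,
               coupling_factor(g2s, g1s, 1)$f, tolerance = 1e-12)
})

test_that("gating-charge table aggregates, signs and fractions correctly", {
  # +1 e charge moving delta f = 0.5 contributes +0.5 e
  tab <- total_gating_charge(
    f_closed = tibble::tibble(residue = "R", f = 0.2),
    f_open = tibble::tibble(residue = "R", f = 0.7),
    charges = tibble::tibble(residue = "R", q = 1))
  expect_equal(tab$contribution, 0.5)
  expect_equal(fraction_of_total(tab, "R"), 100)
  # additivity over disjoint residue sets
  mk <- function(res, fc, fo, q) {
    total_gating_charge(tibble::tibble(residue = res, f = fc),
                        tibble::tibble(residue = res, f = fo),
                        tibble::tibble(residue = res, q = q))
  }
  t1 <- mk(c("a", "b"), c(0.1, 0.3), c(0.4, 0.2), c(1, -1))
  t2 <- mk("c", 0.5, 0.9, 2)
  t12 <- mk(c("a", "b", "c"), c(0.1, 0.3, 0.5), c(0.4, 0.2, 0.9),
            c(1, -1, 2))
  expect_equal(attr(t12, "total"), attr(t1, "total") + attr(t2, "total"))
  expect_error(
    total_gating_charge(tibble::tibble(residue = "a", f = 1),
                        tibble::tibble(residue = "b", f = 1),
                        tibble::tibble(residue = "a", q = 1)),
    "match")
})

test_that("published per-residue table reproduces the stated percentages", {
  ref <- bk_gating_contributions()
  expect_equal(nrow(ref), 7)
  # the seven contributions sum to ~0.45 e as stated
  expect_equal(sum(ref$contribution_e), 0.462, tolerance = 1e-12)
  expect_equal(sum(ref$contribution_e), 0.45, tolerance = 0.05)
  # R210 + R213 over the stated per-VSD total of 0.45 e: ~97%
  pct <- 100 * sum(ref$contribution_e[ref$residue %in%
                                        c("R210", "R213")]) / 0.45
  expect_equal(pct, 97, tolerance = 0.02)
})

test_that("random tables match hand summation", {
  set.seed(77)
  res <- paste0("r", 1:6)
  fc <- runif(6); fo <- runif(6); q <- runif(6, -2, 2)
  tab <- total_gating_charge(tibble::tibble(residue = res, f = fc),
                             tibble::tibble(residue = res, f = fo),
                             tibble::tibble(residue = res, q = q))
  expect_equal(attr(tab, "total"), sum(q * (fo - fc)))
  pick <- c("r2", "r5")
  expect_equal(fraction_of_total(tab, pick),
               100 * sum((q * (fo - fc))[c(2, 5)]) / sum(q * (fo - fc)))
})

test_that("block averaging matches hand arithmetic and sampling theory", {
  # constant samples: zero error
  bm <- block_mean_force(rep(2.5, 100))
  expect_equal(bm$mean, 2.5)
  expect_equal(bm$stderr, 0)
  # two blocks with distinct means: SE = sd(block means)/sqrt(2)
  x <- c(rep(1, 50), rep(3, 50))
  bm2 <- block_mean_force(x, blocks = 2)
  expect_equal(bm2$mean, 2)
  expect_equal(bm2$stderr, stats::sd(c(1, 3)) / sqrt(2))
  # i.i.d. Gaussian: block SE ~ sigma/sqrt(n) within 30%
  set.seed(123)
  g <- rnorm(1e4, sd = 2)
  bm3 <- block_mean_force(g, blocks = 5)
  expect_equal(bm3$stderr, 2 / sqrt(1e4), tolerance = 0.3)
  expect_error(block_mean_force(numeric(1)), "2 samples")
})

test_that("TI sample tables flow through mean_force_from_samples", {
  set.seed(5)
  lam <- seq(0, 1, by = 0.1)
  samples <- do.call(rbind, lapply(lam, function(l) {
    data.frame(residue = "R210", state = "closed", voltage_mV = 750,
               lambda = l, sample = rnorm(200, mean = 2 * l, sd = 0.1))
  }))
  curves <- mean_force_from_samples(samples)
  expect_equal(nrow(curves), 11)
  expect_equal(curves$mean_force, 2 * lam, tolerance = 0.05)
  dg <- integrate_ti(curves)
  expect_equal(dg$delta_G, 1, tolerance = 0.02)
  expect_gt(dg$error, 0)
  # round trip through the CSV interchange format
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_ti_table(curves, tmp)
  back <- read_ti_table(tmp)
  expect_equal(back$mean_force_kcal_mol, curves$mean_force)
})
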