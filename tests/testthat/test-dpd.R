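# DPD engine tests: thermostat and equation-of-state oracles, momentum
# conservation, cross-linking statistics, solvent-quality response.

test_that("free streaming: with all forces off, positions advance by v dt n", {
  n <- 20
  set.seed(1)
  pos <- matrix(runif(3 * n, 2, 6), n, 3)
  vel <- matrix(rnorm(3 * n, sd = 0.01), n, 3)
  aij <- matrix(0, 5, 5)
  sys <- dpd_system(pos, vel, rep(3L, n), rep(TRUE, n), c(10, 10, 10),
                    periodic_z = TRUE, aij = aij, gamma = 0, kT = 0)
  r <- dpd_integrate(sys, 50, seed = 2)
  expect_equal(r$system$pos, pos + 50 * sys$dt * vel, tolerance = 1e-12)
  expect_equal(r$system$vel, vel)
})

test_that("thermostat holds the set point within 3% at rho_b = 3", {
  f <- dpd_fluid(L = c(6, 6, 6), seed = 3)
  r <- dpd_integrate(f, 600, seed = 4, sample_every = 10)
  n <- length(r$kT_trace)
  kT <- mean(r$kT_trace[(n %/% 2):n])
  expect_lt(abs(kT - 1), 0.03)
})

test_that("pure-fluid pressure matches the DPD equation of state within 5%", {
  # p ~ rho kT + 0.101 a rho^2; the 0.101 coefficient is the high-density
  # plateau, reached for rho >~ 4, so the check runs at rho_b = 5
  f <- dpd_fluid(L = c(6, 6, 6), rho_b = 5, seed = 5)
  r <- dpd_integrate(f, 800, seed = 6, sample_every = 20,
                     measure_pressure = TRUE)
  n <- length(r$p_trace)
  p <- mean(r$p_trace[(n %/% 2):n])
  kT <- mean(r$kT_trace[(n %/% 2):n])
  expect_lt(abs(p - (5 * kT + 0.101 * 25 * 25)) / (5 + 0.101 * 25 * 25), 0.05)
})

test_that("pair forces conserve total momentum to machine precision", {
  f <- dpd_fluid(L = c(6, 6, 6), seed = 7)
  r <- dpd_integrate(f, 200, seed = 8)
  expect_lt(max(abs(r$momentum)), 1e-9)
})

test_that("integration flags unstable timesteps", {
  f <- dpd_fluid(L = c(5, 5, 5), seed = 9)
  f$dt <- 1.5
  expect_error(dpd_integrate(f, 100, seed = 10), "unstable")
})

test_that("grafted-matrix builder lays out chains, bonds and anchors", {
  sys <- build_grafted_matrix(N_chain = 20, rho_g = 0.2,
                              box = c(20, 20, 20), seed = 11)
  n_chains <- round(0.2 * 20 * 20)   # 80 chains
  expect_equal(length(sys$anchor_idx), n_chains)
  expect_equal(nrow(sys$bonds), n_chains * 19)
  n_matrix <- sum(sys$type %in% c(1L, 2L))
  expect_equal(n_matrix, n_chains * 20)
  # about 30% cross-linkable
  expect_equal(sum(sys$active) / n_matrix, 0.3, tolerance = 0.1)
  # determinism
  sys2 <- build_grafted_matrix(N_chain = 20, rho_g = 0.2,
                               box = c(20, 20, 20), seed = 11)
  expect_identical(sys$pos, sys2$pos)
  expect_identical(sys$bonds, sys2$bonds)
  expect_error(build_grafted_matrix(N_chain = 100, rho_g = 4,
                                    box = c(10, 10, 10)), "capacity")
})

test_that("solvent-quality switch is a local involution", {
  sys <- build_grafted_matrix(N_chain = 10, rho_g = 0.2,
                              box = c(10, 10, 15), seed = 12)
  a0 <- sys$aij
  sysb <- set_solvent_quality(sys, "belowLCST")
  expect_equal(sysb$aij["PNIPAM", "WATER"], 25)
  expect_equal(sysb$aij["WATER", "WATER"], a0["WATER", "WATER"])
  expect_equal(sysb$aij["PGMA", "WATER"], a0["PGMA", "WATER"])
  sysa <- set_solvent_quality(sysb, "aboveLCST")
  expect_identical(sysa$aij, a0)
  expect_error(set_solvent_quality(sys, "lukewarm"), "unknown regime")
})

test_that("matrix height is the first-moment brush height", {
  f <- dpd_fluid(L = c(5, 5, 10), seed = 13)
  sys <- f
  sys$type <- rep(1L, nrow(sys$pos))
  # uniform slab of thickness t: h = 2 <z> = t
  t_slab <- 4
  sys$pos[, 3] <- seq(0, t_slab, length.out = nrow(sys$pos))
  expect_equal(matrix_height(sys), t_slab, tolerance = 1e-2)
  # delta profile at z = c: h = 2c
  sys$pos[, 3] <- 3.5
  expect_equal(matrix_height(sys), 7)
})

test_that("an isolated overlapping active pair bonds at the stated rate", {
  # two cross-linkable beads in contact, one reaction step at a time:
  # empirical bond frequency must match p_bond = 0.1
  n_rep <- 2000
  hits <- 0L
  pos <- matrix(c(2, 2, 2, 2.3, 2, 2), 2, 3, byrow = TRUE)
  aij <- matrix(0, 5, 5)
  base <- dpd_system(pos, matrix(0, 2, 3), c(2L, 2L), rep(TRUE, 2),
                     c(6, 6, 6), periodic_z = TRUE, aij = aij,
                     gamma = 0, kT = 0, active = c(TRUE, TRUE))
  for (k in seq_len(n_rep)) {
    r <- crosslink(base, nu_cr = 100, n_steps = 1, seed = k)
    hits <- hits + (r$n_bonds_formed > 0)
  }
  expect_equal(hits / n_rep, 0.1, tolerance = 0.15)
  # no active pairs in range: no bonds
  faro <- base
  faro$pos[2, ] <- c(5, 5, 5)
  r0 <- crosslink(faro, nu_cr = 100, n_steps = 1, seed = 1)
  expect_equal(r0$n_bonds_formed, 0)
})

test_that("cross-link accounting is exact and the trace saturates", {
  sys <- build_grafted_matrix(N_chain = 25, rho_g = 0.4,
                              box = c(8, 8, 16), seed = 15)
  n_matrix <- sum(sys$mobile & sys$type %in% c(1L, 2L))
  r <- dpd_integrate(sys, 300, seed = 16)
  cl <- crosslink(r$system, nu_cr = 8, n_steps = 800, seed = 17)
  # identity nu_cr = 2 N_b / N_matrix * 100, exactly
  expect_equal(cl$nu_cr_achieved, 200 * cl$n_bonds_formed / n_matrix)
  expect_lte(cl$nu_cr_achieved, 8 + 200 / n_matrix)
  # trace non-decreasing and saturating (final 10% adds < 1% of bonds)
  tr <- cl$nb_trace
  expect_true(all(diff(tr) >= 0))
  n <- length(tr)
  expect_lte(tr[n] - tr[round(0.9 * n)], max(0.01 * tr[n], 1))
  # each bead participates in at most one cross-link
  new_bonds <- cl$system$bonds[-seq_len(nrow(sys$bonds)), , drop = FALSE]
  expect_equal(anyDuplicated(as.vector(new_bonds)), 0)
  # leftover cross-linker converted once target reached
  expect_equal(sum(cl$system$type == 2L & cl$system$mobile),
               2 * nrow(new_bonds))
})

test_that("single-chain size responds to the solvent-quality switch", {
  # one tethered chain in solvent: radius of gyration larger below the
  # LCST (good solvent) than above (poor solvent)
  rg2 <- function(regime, seed) {
    sys <- build_grafted_matrix(N_chain = 30, rho_g = 1 / 64,
                                box = c(8, 8, 16), gma_frac = 0,
                                regime = regime, seed = seed)
    r <- dpd_integrate(sys, 2000, seed = seed + 1)
    sys <- r$system
    # time-averaged squared radius of gyration over late frames
    acc <- 0
    for (k in 1:5) {
      r <- dpd_integrate(sys, 300, seed = seed + 1 + k)
      sys <- r$system
      p <- sys$pos[sys$mobile & sys$type == 1L, ]
      acc <- acc + mean(scale(p, scale = FALSE)^2) * 3
    }
    acc / 5
  }
  expect_gt(mean(vapply(1:2, function(s) rg2("belowLCST", 100 + s), 1)),
            1.15 * mean(vapply(1:2, function(s) rg2("aboveLCST", 200 + s), 1)))
})

test_that("collapsed-state equilibrium stays near the melt-slab thickness", {
  sys <- build_grafted_matrix(N_chain = 30, rho_g = 0.3,
                              box = c(8, 8, 20), regime = "aboveLCST",
                              seed = 19)
  r <- dpd_integrate(sys, 1500, seed = 20)
  # dense collapsed layer: first-moment height close to the ideal melt
  # slab N_chain * rho_g / rho_b (diffuse interface allows some excess)
  n_matrix <- sum(sys$mobile & sys$type %in% c(1L, 2L))
  slab <- n_matrix / (3 * 8 * 8)
  h_eq <- matrix_height(r$system)
  expect_lt(h_eq, 2 * slab)
  # and far below the swollen height of the same network
  rb <- dpd_integrate(set_solvent_quality(r$system, "belowLCST"), 2500,
                      seed = 21)
  expect_lt(h_eq, matrix_height(rb$system))
})

test_that("cap-pinned builder respects the pinning ceiling", {
  sys <- build_cap_pinned_matrix(R = 30, s = 10, rho_pd = 0.4,
                                 N_chain = 20, Lz = 20, seed = 21)
  ps <- attr(sys, "pin_sites")
  expect_gt(nrow(ps), 0)
  expect_true(all(ps[, 3] <= 7 + 0.3))
  expect_true(all(ps[, 3] >= -0.3))
  # no pinning when rho_pd = 0
  sys0 <- build_cap_pinned_matrix(R = 30, s = 10, rho_pd = 0,
                                  N_chain = 20, Lz = 20, seed = 21)
  expect_equal(nrow(attr(sys0, "pin_sites")), 0)
  sys0 <- attach_pins(sys0)
  expect_equal(attr(sys0, "n_pinned"), 0L)
  expect_error(build_cap_pinned_matrix(R = 30, s = 0), "s > 0")
})

test_that("phase separation forms domains that grow with the PGMA fraction", {
  r_lo <- phase_separation_experiment(0.12, n_steps = 1500,
                                      box = c(12, 12, 10), N_chain = 10,
                                      seed = 23)
  r_hi <- phase_separation_experiment(0.35, n_steps = 1500,
                                      box = c(12, 12, 10), N_chain = 10,
                                      seed = 23)
  expect_gt(nrow(r_lo$domains), 0)
  expect_gt(nrow(r_hi$domains), 0)
  expect_gt(max(r_hi$domains$n_beads), max(r_lo$domains$n_beads))
  expect_gt(stats::weighted.mean(r_hi$domains$H, r_hi$domains$n_beads),
            stats::weighted.mean(r_lo$domains$H, r_lo$domains$n_beads))
})
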