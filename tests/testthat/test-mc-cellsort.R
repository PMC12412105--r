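# Tests of the Monte Carlo cell-sorting engine. Geometry operations are
# checked against uniform point-sampling oracles; sampling properties
# (Metropolis rule, barometric equilibrium) against closed forms.

surf_small <- function(Dd = 2, L = 60, sigma_d = 0.48, seed = 3) {
  place_domains_rsa(L, Dd, sigma_d, seed = seed)
}

test_that("RSA placement hits the target count with zero overlaps", {
  expect_equal(nrow(place_domains_rsa(60, 2, 0, seed = 1)$centers), 0)

  surf <- surf_small(seed = 5)
  n_expect <- round(0.48 * 60^2 / (pi * 1^2))
  expect_equal(nrow(surf$centers), n_expect)
  expect_lt(abs(surf$coverage - 0.48), 0.005)

  # brute-force pairwise scan with periodic wrap
  cen <- surf$centers; L <- surf$L; n <- nrow(cen)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    dx <- abs(cen[(i + 1):n, 1] - cen[i, 1]); dx <- pmin(dx, L - dx)
    dy <- abs(cen[(i + 1):n, 2] - cen[i, 2]); dy <- pmin(dy, L - dy)
    dmin <- min(dmin, sqrt(min(dx^2 + dy^2)))
  }
  expect_gte(dmin, surf$Dd)

  # determinism
  surf2 <- surf_small(seed = 5)
  expect_identical(surf$centers, surf2$centers)
  expect_error(place_domains_rsa(60, 2, 0.53, seed = 1), "jamming")
})

test_that("lens area reduces to the containment and tangency limits", {
  expect_equal(circle_lens_area(2, 1, 4), 0)            # disjoint
  expect_equal(circle_lens_area(2, 1, 3), 0)            # tangent
  expect_equal(circle_lens_area(3, 1, 0.5), pi * 1^2)   # contained
  # symmetric half-overlap checked against polar-integral oracle
  r <- 1; d <- 1
  oracle <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(circle_lens_area(r, r, d), oracle, tolerance = 1e-12)
})

test_that("contact area matches tangency, containment and coverage oracles", {
  p <- mc_params()
  surf <- surf_small(Dd = 0.5, L = 60, seed = 7)

  # tangency: cell just touching the domain-top plane
  z_touch <- surf$Hd + p$D / 2
  e <- cell_energy(c(10, 10, z_touch), 1, surf, p)
  expect_equal(e$contact_area, 0)

  # containment: giant domain swallows the whole facet
  giant <- structure(list(L = 100, Dd = 40, Hd = 40, sigma_d = NA,
                          coverage = NA, centers = matrix(c(50, 50), 1, 2),
                          seed = 0), class = "micro_surface")
  z <- giant$Hd + p$D / 2 - p$delta_max      # maximum deformation
  a2 <- (p$D / 2)^2 - (z - giant$Hd)^2
  e <- cell_energy(c(50, 50, z), 1, giant, p)
  expect_equal(e$contact_area, pi * a2, tolerance = 1e-12)

  # mean covered fraction over random placements approximates sigma_d
  set.seed(1)
  zs <- surf$Hd + p$D / 2 - p$delta_max
  a2 <- (p$D / 2)^2 - (zs - surf$Hd)^2
  areas <- vapply(1:100, function(i) {
    xy <- runif(2, 0, surf$L)
    cell_energy(c(xy, zs), 1, surf, p)$contact_area
  }, numeric(1))
  expect_equal(mean(areas), 0.48 * pi * a2, tolerance = 0.03)
})

test_that("contact and repulsion areas agree with point-sampling oracles", {
  p <- mc_params(swollen = TRUE, Bp = 0.3)
  surf <- surf_small(Dd = 2, L = 60, seed = 11)
  set.seed(2)
  n_pts <- 1e5
  for (rep in 1:5) {
    x <- runif(1, 0, 60); y <- runif(1, 0, 60)
    z <- surf$Hd + p$D / 2 - runif(1, 0, p$delta_max)
    e <- cell_energy(c(x, y, z), 1, surf, p)

    covered_frac <- function(radius) {
      # fraction of a disc at (x, y) covered by domain top discs
      th <- runif(n_pts, 0, 2 * pi); rr <- radius * sqrt(runif(n_pts))
      px <- (x + rr * cos(th)) %% 60; py <- (y + rr * sin(th)) %% 60
      hit <- logical(n_pts)
      cen <- surf$centers
      for (k in seq_len(nrow(cen))) {
        dx <- abs(px - cen[k, 1]); dx <- pmin(dx, 60 - dx)
        dy <- abs(py - cen[k, 2]); dy <- pmin(dy, 60 - dy)
        hit <- hit | (dx^2 + dy^2 <= 1)
        if (all(hit)) break
      }
      mean(hit)
    }
    a <- sqrt((p$D / 2)^2 - (z - surf$Hd)^2)
    expect_equal(e$contact_area, covered_frac(a) * pi * a^2,
                 tolerance = 0.012)
    dz <- z - (surf$Hd + p$hp)
    b <- if (dz <= 0) p$D / 2 else sqrt((p$D / 2)^2 - dz^2)
    expect_equal(e$repulsion_area, (1 - covered_frac(b)) * pi * b^2,
                 tolerance = 0.012)
  }
})

test_that("total energy assembles adhesion, repulsion and gravity terms", {
  surf <- surf_small(Dd = 2, L = 60, seed = 13)
  # suspended cell, collapsed polymer: gravity only
  p <- mc_params(gw = 0.1)
  e <- cell_energy(c(30, 30, 25), 1, surf, p)
  expect_equal(e$energy, 0.1 * 25)
  expect_equal(e$contact_area, 0)
  # swollen with Bp = 0, suspended: still gravity only
  p2 <- mc_params(gw = 0.1, swollen = TRUE, Bp = 0)
  e2 <- cell_energy(c(30, 30, 25), 1, surf, p2)
  expect_equal(e2$energy, 0.1 * 25)
  # term assembly at a contact configuration
  p3 <- mc_params(gw = 0.1, swollen = TRUE, Bp = 0.32)
  z <- surf$Hd + p3$D / 2 - 1
  e3 <- cell_energy(c(30, 30, z), 2, surf, p3)
  expect_equal(e3$energy,
               p3$A2 * e3$contact_area + 0.32 * e3$repulsion_area + 0.1 * z,
               tolerance = 1e-12)
  # hard-wall violation
  expect_error(cell_energy(c(30, 30, surf$Hd + p3$D / 2 - p3$delta_max - 1), 1,
                           surf, p3), "hard-wall")
})

test_that("Metropolis acceptance frequency matches exp(-dE/T)", {
  expect_equal(mc_acceptance_freq(-2, 1, 1e4, seed = 1), 1)
  f <- mc_acceptance_freq(1, 1, 1e4, seed = 2)
  expect_equal(f, exp(-1), tolerance = 0.01 / exp(-1))
  expect_lt(abs(f - 0.368), 0.01)
  f2 <- mc_acceptance_freq(2, 2, 1e4, seed = 3)
  expect_equal(f2, exp(-1), tolerance = 0.015 / exp(-1))
})

test_that("gravity-only system equilibrates to the barometric distribution", {
  # no adhesion, no repulsion: stationary height distribution above the
  # hard floor should be exponential with rate g_w / T_eff (truncated by
  # the reflecting top)
  # two cells in a tall box: dilute enough that hard-sphere exclusion is
  # negligible and the single-particle closed form applies
  p <- mc_params(A1 = 0, A2 = 0, gw = 0.1, delta = 4, Hbox = 80)
  surf <- place_domains_rsa(40, 2, 0.3, seed = 17)
  cells <- init_cells(surf, 1, 1, p, seed = 18)
  st <- mc_stage(surf, cells, p, 1.2e6, seed = 19, sample_every = 2000,
                 record_z = TRUE)
  zfloor <- surf$Hd + p$D / 2 - p$delta_max
  z <- st$z_samples - zfloor
  z <- z[seq(1, length(z), by = 4)]  # thin correlated samples
  lam <- p$gw / p$Teff
  span <- p$Hbox - zfloor
  ptrunc <- function(q) (1 - exp(-lam * q)) / (1 - exp(-lam * span))
  ks <- stats::ks.test(z, ptrunc)
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectories are reproducible and hard constraints never violated", {
  p <- mc_params(swollen = TRUE, Bp = 0.3)
  surf <- surf_small(Dd = 2, L = 60, seed = 23)
  cells <- init_cells(surf, 10, 10, p, seed = 24)
  a <- mc_stage(surf, cells, p, 5e4, seed = 25)
  b <- mc_stage(surf, cells, p, 5e4, seed = 25)
  expect_identical(a$cells$pos, b$cells$pos)
  expect_identical(a$energy_trace, b$energy_trace)

  pos <- a$cells$pos
  n <- nrow(pos)
  # exhaustive pairwise hard-sphere scan (periodic lateral)
  for (i in seq_len(n - 1)) {
    dx <- abs(pos[(i + 1):n, 1] - pos[i, 1]); dx <- pmin(dx, 60 - dx)
    dy <- abs(pos[(i + 1):n, 2] - pos[i, 2]); dy <- pmin(dy, 60 - dy)
    dz <- pos[(i + 1):n, 3] - pos[i, 3]
    expect_gte(min(dx^2 + dy^2 + dz^2), p$D^2 * (1 - 1e-12))
  }
  # hard wall
  expect_gte(min(pos[, 3]), surf$Hd + p$D / 2 - p$delta_max - 1e-12)
})

test_that("adsorption attaches all cells and reports energy saturation", {
  p <- mc_params()
  # cell counts chosen to match the study's monolayer packing fraction
  # (N pi (D/2)^2 / L^2 ~ 0.27), so the whole population can attach
  surf <- surf_small(Dd = 2, L = 60, seed = 29)
  cells <- init_cells(surf, 6, 6, p, seed = 30)
  ads <- run_adsorption(surf, cells, p, 1e6, seed = 31)
  expect_gte(ads$frac1, 95)
  expect_gte(ads$frac2, 95)
  expect_true(is.finite(ads$saturation_step))
  expect_lt(ads$saturation_step, 0.9 * 1e6)
  # energy decreases on average between settling and the stationary tail
  tr <- ads$energy_trace; n <- length(tr)
  expect_lt(mean(tr[(3 * n %/% 4):n]), mean(tr[1:(n %/% 4)]))
})

test_that("desorption limits: Bp = 0 keeps cells, huge Bp removes them", {
  p <- mc_params()
  surf <- surf_small(Dd = 2, L = 60, seed = 37)
  cells <- init_cells(surf, 6, 6, p, seed = 38)
  ads <- suppressWarnings(run_adsorption(surf, cells, p, 1e6, seed = 39))
  keep <- run_desorption(surf, ads$cells, p, 0, 2e5, seed = 40)
  expect_gte(keep$frac1, 95)
  expect_gte(keep$frac2, 95)
  gone <- run_desorption(surf, ads$cells, p, 4, 4e5, seed = 41)
  expect_lte(gone$frac1, 5)
  expect_lte(gone$frac2, 5)
})

test_that("separation factor handles enrichment and degenerate cases", {
  expect_equal(separation_factor_sim(35, 3)$sf, 35 / 3, tolerance = 1e-12)
  expect_equal(round(separation_factor_sim(35, 3)$sf, 1), 11.7)
  expect_equal(separation_factor_sim(20, 20)$sf, 1)
  r <- separation_factor_sim(35, 0)
  expect_false(r$defined)
  expect_true(is.na(r$sf))
  # 35 / 2.5 is 20% above 35 / 3
  expect_equal(separation_factor_sim(35, 2.5)$sf /
                 separation_factor_sim(35, 3)$sf, 1.2, tolerance = 1e-12)
})

test_that("sweep orders types correctly and responds to repulsion", {
  p <- mc_params()
  sw <- suppressWarnings(
    mc_sweep(c(1.0), c(0.25, 0.3, 0.35, 0.4), params = p, L = 80,
             sigma_d = 0.48, N1 = 25, N2 = 25, n_ads = 3e5, n_des = 3e5,
             n_seeds = 2, seed = 9))
  # type 1 binds stronger at every Bp
  expect_true(all(sw$frac1 >= sw$frac2))
  # remaining fractions non-increasing in Bp within 2 SE
  tol1 <- 2 * (sw$se1[-1] + sw$se1[-nrow(sw)]) + 3
  expect_true(all(diff(sw$frac1) <= tol1))
  tol2 <- 2 * (sw$se2[-1] + sw$se2[-nrow(sw)]) + 3
  expect_true(all(diff(sw$frac2) <= tol2))
  expect_s3_class(sw, "mc_sweep")
  expect_true(all(c("Dd", "Bp", "frac1", "frac2", "sf") %in% names(sw)))
  pk <- attr(sw, "peaks")
  expect_equal(nrow(pk), 1)
})
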