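#' Dissipative particle dynamics of grafted thermoresponsive films
#'
#' @description
#' Coarse-grained DPD model of the polymer film: repeating units of the
#' domain-forming polymer (PGMA), the thermoresponsive matrix (PNIPAM), its
#' cross-linkable comonomer (GMA) and explicit water are soft beads of ~10
#' atoms. Standard reduced units: cutoff `r_c = 1`, bead mass 1, `kT = 1`,
#' bead density `rho_b = 3`, like-like repulsion `a_ii = 25`, thermostat
#' `gamma = 4.5`, timestep `dt = 0.04`, integrator parameter
#' `lambda = 0.65`. The LCST switch is a solvent-quality change:
#' `a_PNIPAM-WATER = 25` below the LCST (good solvent) and `37` above (poor
#' solvent); `a_PGMA-PNIPAM = 40` (strong incompatibility) and
#' `a_PGMA-WATER = 27` (near-theta).
#'
#' @name dpd_film
NULL

# bead type codes
DPD_TYPES <- c(PGMA = 0L, PNIPAM = 1L, GMA = 2L, WATER = 3L, WALL = 4L)

#' Default DPD interaction matrix
#'
#' @param regime `"belowLCST"` (good solvent for the matrix) or
#'   `"aboveLCST"` (poor solvent).
#' @param a_ii Like-like repulsion.
#' @param a_incompat PGMA-matrix repulsion (phase separation driver).
#' @param a_theta PGMA-water repulsion (near-theta).
#' @param a_poor Matrix-water repulsion above the LCST.
#' @return A 5x5 symmetric matrix indexed PGMA, PNIPAM, GMA, WATER, WALL.
#' @export
dpd_aij <- function(regime = "aboveLCST", a_ii = 25, a_incompat = 40,
                    a_theta = 27, a_poor = 37) {
  a <- matrix(a_ii, 5, 5, dimnames = list(names(DPD_TYPES), names(DPD_TYPES)))
  a["PGMA", "PNIPAM"] <- a["PNIPAM", "PGMA"] <- a_incompat
  a["PGMA", "GMA"] <- a["GMA", "PGMA"] <- a_incompat
  a["PGMA", "WATER"] <- a["WATER", "PGMA"] <- a_theta
  aw <- switch(regime, belowLCST = a_ii, aboveLCST = a_poor,
               stop("unknown regime: ", regime))
  a["PNIPAM", "WATER"] <- a["WATER", "PNIPAM"] <- aw
  a["GMA", "WATER"] <- a["WATER", "GMA"] <- aw
  a
}

#' Construct a DPD system
#'
#' Low-level constructor assembling bead positions/velocities, types
#' (0 = PGMA, 1 = PNIPAM, 2 = GMA, 3 = WATER, 4 = WALL), mobility flags,
#' bond and anchor topology, box geometry and force-field table into a
#' `dpd_system`. The builders ([dpd_fluid()], [build_grafted_matrix()],
#' [build_cap_pinned_matrix()]) are the usual entry points; this
#' constructor serves custom geometries and tests.
#'
#' @param pos,vel n x 3 matrices.
#' @param type Integer bead types.
#' @param mobile Logical; frozen beads exert forces but do not move.
#' @param box `c(Lx, Ly, Lz)`.
#' @param periodic_z Periodic in z (TRUE) or bounce-back walls (FALSE).
#' @param aij 5x5 interaction matrix, see [dpd_aij()].
#' @param ... Topology and engine parameters: `bonds` (two-column integer
#'   matrix of harmonic bonds), `anchor_idx`/`anchor_xyz` (beads tethered
#'   to fixed points), `caps` (obstacle rows `c(cx, cz, R)`, y-invariant
#'   ridges), `active` (cross-linkable flags), `gamma`, `kT`, `dt`,
#'   `lambda`, `bond_k`, `a_cap`, `regime`.
#' @return A `dpd_system`.
#' @export
dpd_system <- function(pos, vel, type, mobile, box, periodic_z, aij, ...) {
  new_dpd_system(pos, vel, type, mobile, box, periodic_z, aij, ...)
}

new_dpd_system <- function(pos, vel, type, mobile, box, periodic_z, aij,
                           bonds = matrix(0L, 0, 2),
                           anchor_idx = integer(0),
                           anchor_xyz = matrix(0, 0, 3),
                           caps = matrix(0, 0, 3),
                           active = rep(FALSE, nrow(pos)),
                           gamma = 4.5, kT = 1, dt = 0.04, lambda = 0.65,
                           bond_k = 4, a_cap = 25, regime = "aboveLCST") {
  structure(list(pos = pos, vel = vel, type = type, mobile = mobile,
                 box = box, periodic_z = periodic_z, aij = aij,
                 bonds = bonds, anchor_idx = anchor_idx,
                 anchor_xyz = anchor_xyz, caps = caps, active = active,
                 gamma = gamma, kT = kT, dt = dt, lambda = lambda,
                 bond_k = bond_k, a_cap = a_cap, regime = regime),
            class = "dpd_system")
}

#' @export
print.dpd_system <- function(x, ...) {
  cat(sprintf("DPD system: %d beads (%d mobile) in %g x %g x %g box, %d bonds, %d anchors\n",
              nrow(x$pos), sum(x$mobile), x$box[1], x$box[2], x$box[3],
              nrow(x$bonds), length(x$anchor_idx)))
  cat(sprintf("  regime: %s; %d caps; %d active cross-linkable beads\n",
              x$regime, nrow(x$caps), sum(x$active)))
  invisible(x)
}

# random walk from z0 with given steps, reflected into [lo, hi]
reflect_walk <- function(z0, steps, lo, hi) {
  z <- z0 + cumsum(c(0, steps))
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  lo + ifelse(z > span, 2 * span - z, z)
}

rnorm_mom0 <- function(n, kT) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT)), n, 3)
  sweep(v, 2, colMeans(v))
}

#' Pure DPD fluid (periodic box)
#'
#' A single-component solvent at bead density `rho_b`, used for thermostat
#' and equation-of-state checks.
#'
#' @param L Box edge lengths, length 3.
#' @param rho_b Bead number density.
#' @param a_ii Repulsion parameter.
#' @param kT Set-point temperature.
#' @param seed Integer seed.
#' @return A `dpd_system`, fully periodic.
#' @export
dpd_fluid <- function(L = c(8, 8, 8), rho_b = 3, a_ii = 25, kT = 1, seed = 1) {
  set.seed(seed)
  n <- round(rho_b * prod(L))
  pos <- cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]),
               stats::runif(n, 0, L[3]))
  aij <- dpd_aij(a_ii = a_ii)
  aij[] <- a_ii
  new_dpd_system(pos, rnorm_mom0(n, kT), rep(DPD_TYPES[["WATER"]], n),
                 rep(TRUE, n), box = L, periodic_z = TRUE, aij = aij,
                 kT = kT)
}

run_engine <- function(sys, n_steps, seed, sample_every = 10,
                       crosslink = FALSE, p_bond = 0.1, target_nb = 0L,
                       measure_pressure = FALSE) {
  res <- .dpd_run(sys$pos, sys$vel, as.integer(sys$type),
                  sys$mobile, sys$bonds,
                  as.integer(sys$anchor_idx), sys$anchor_xyz,
                  as.numeric(sys$box), sys$periodic_z, sys$aij,
                  sys$gamma, sys$kT, sys$dt, sys$lambda, sys$bond_k,
                  sys$caps, sys$a_cap,
                  as.integer(n_steps), as.integer(sample_every),
                  as.integer(seed), crosslink, p_bond,
                  as.integer(target_nb), sys$active,
                  DPD_TYPES[c("PNIPAM", "GMA")], measure_pressure)
  sys$pos <- res$pos
  sys$vel <- res$vel
  sys$bonds <- res$bonds
  sys$active <- res$active
  list(system = sys, kT_trace = res$kT_trace, h_trace = res$h_trace,
       p_trace = res$p_trace, nb_trace = res$nb_trace,
       n_crosslinks = res$n_crosslinks, momentum = res$momentum)
}

#' Advance a DPD system
#'
#' Integrates `n_steps` timesteps of standard DPD dynamics with the
#' modified velocity-Verlet scheme, returning the updated system together
#' with sampled traces of the kinetic temperature, matrix first-moment
#' height, and (optionally) the virial pressure.
#'
#' @param sys A `dpd_system`.
#' @param n_steps Number of timesteps.
#' @param seed Integer seed for the pairwise random forces.
#' @param sample_every Sampling interval (steps).
#' @param measure_pressure Record the conservative-virial pressure trace.
#' @return A list: `system` (updated), `kT_trace`, `h_trace`, `p_trace`,
#'   `momentum` (total momentum of mobile beads after the run).
#' @export
dpd_integrate <- function(sys, n_steps, seed = 1, sample_every = 10,
                          measure_pressure = FALSE) {
  stopifnot(inherits(sys, "dpd_system"))
  run_engine(sys, n_steps, seed, sample_every,
             measure_pressure = measure_pressure)
}

#' Switch solvent quality across the LCST
#'
#' Updates the matrix-water repulsion between the good-solvent value (below
#' the LCST, swollen) and the poor-solvent value (above the LCST,
#' collapsed). Only the PNIPAM-water and GMA-water entries change.
#'
#' @param sys A `dpd_system`.
#' @param regime `"belowLCST"` or `"aboveLCST"`.
#' @return The system with updated force field.
#' @export
set_solvent_quality <- function(sys, regime) {
  stopifnot(inherits(sys, "dpd_system"))
  if (!regime %in% c("belowLCST", "aboveLCST")) {
    stop("unknown regime: ", regime)
  }
  aw <- if (regime == "belowLCST") 25 else 37
  for (t in c("PNIPAM", "GMA")) {
    sys$aij[t, "WATER"] <- sys$aij["WATER", t] <- aw
  }
  sys$regime <- regime
  sys
}

#' First-moment matrix height
#'
#' Brush height `h = 2 <z>` from the instantaneous mean height of the
#' (mobile) matrix beads; for a uniform slab of thickness `t` on the
#' substrate this equals `t`.
#'
#' @param sys A `dpd_system`.
#' @return Height in reduced units.
#' @export
matrix_height <- function(sys) {
  stopifnot(inherits(sys, "dpd_system"))
  sel <- sys$mobile & sys$type %in% DPD_TYPES[c("PNIPAM", "GMA")]
  if (!any(sel)) stop("no matrix beads in system")
  2 * mean(sys$pos[sel, 3])
}

#' Build a surface-grafted cross-linkable matrix
#'
#' Chains of `N_chain` beads are grafted at density `rho_g` (chains per unit
#' substrate area) with their first bead tethered to the substrate plane; a
#' fraction `gma_frac` of beads are cross-linkable GMA, the rest PNIPAM.
#' Solvent fills the box to total bead density `rho_b`. The substrate is a
#' frozen wall-bead layer plus bounce-back reflection in z.
#'
#' @param N_chain Beads per chain.
#' @param rho_g Grafting density (chains per unit area).
#' @param box Box dimensions `c(Lx, Ly, Lz)`.
#' @param gma_frac Fraction of matrix beads of GMA type before
#'   cross-linking (0.30 in the cross-linking stage).
#' @param rho_b Total bead density.
#' @param regime Initial solvent regime.
#' @param seed Integer seed.
#' @return A `dpd_system` with all GMA beads flagged active for
#'   cross-linking.
#' @export
build_grafted_matrix <- function(N_chain = 100, rho_g = 0.2,
                                 box = c(10, 10, 40), gma_frac = 0.30,
                                 rho_b = 3, regime = "aboveLCST", seed = 1) {
  set.seed(seed)
  Lx <- box[1]; Ly <- box[2]; Lz <- box[3]
  n_chains <- round(rho_g * Lx * Ly)
  if (n_chains < 1) stop("grafting density too low for this substrate")
  n_poly <- n_chains * N_chain
  if (n_poly > 0.9 * rho_b * prod(box)) {
    stop("grafting density exceeds geometric capacity of the box")
  }

  # frozen substrate layer, z in [-1, 0)
  n_wall <- round(rho_b * Lx * Ly)
  wall <- cbind(stats::runif(n_wall, 0, Lx), stats::runif(n_wall, 0, Ly),
                stats::runif(n_wall, -1, 0))

  gx <- stats::runif(n_chains, 0, Lx)
  gy <- stats::runif(n_chains, 0, Ly)
  pos <- vector("list", n_chains)
  bonds <- vector("list", n_chains)
  off <- n_wall
  # compact random-walk initialization near the substrate: starting close
  # to the collapsed-layer thickness avoids long relaxation from an
  # artificially stretched state
  h0 <- min(max(3, 1.5 * N_chain * rho_g / rho_b), Lz - 1)
  for (c in seq_len(n_chains)) {
    z <- reflect_walk(0.3, stats::rnorm(N_chain - 1, sd = 0.3), 0.2, h0)
    px <- (gx[c] + cumsum(stats::rnorm(N_chain, sd = 0.3))) %% Lx
    py <- (gy[c] + cumsum(stats::rnorm(N_chain, sd = 0.3))) %% Ly
    pos[[c]] <- cbind(px, py, z)
    idx <- off + seq_len(N_chain)
    bonds[[c]] <- cbind(idx[-N_chain], idx[-1])
    off <- off + N_chain
  }
  poly <- do.call(rbind, pos)
  ptype <- ifelse(stats::runif(n_poly) < gma_frac,
                  DPD_TYPES[["GMA"]], DPD_TYPES[["PNIPAM"]])

  n_solv <- round(rho_b * prod(box)) - n_poly
  solv <- cbind(stats::runif(n_solv, 0, Lx), stats::runif(n_solv, 0, Ly),
                stats::runif(n_solv, 0, Lz))

  pos_all <- rbind(wall, poly, solv)
  n <- nrow(pos_all)
  type <- c(rep(DPD_TYPES[["WALL"]], n_wall), ptype,
            rep(DPD_TYPES[["WATER"]], n_solv))
  mobile <- c(rep(FALSE, n_wall), rep(TRUE, n_poly + n_solv))
  vel <- matrix(0, n, 3)
  vel[mobile, ] <- rnorm_mom0(sum(mobile), 1)
  anchor_idx <- n_wall + (seq_len(n_chains) - 1) * N_chain + 1L
  anchor_xyz <- cbind(gx, gy, 0)
  active <- type == DPD_TYPES[["GMA"]]

  new_dpd_system(pos_all, vel, type, mobile, box, periodic_z = FALSE,
                 aij = dpd_aij(regime), bonds = do.call(rbind, bonds),
                 anchor_idx = anchor_idx, anchor_xyz = anchor_xyz,
                 active = active, regime = regime)
}

#' Stochastic cross-linking of the active beads
#'
#' Runs the dynamics with reaction sampling: at every step, each pair of
#' active (unreacted GMA) beads whose soft cores touch or interpenetrate
#' (`r < r_c`) forms a cross-link bond with probability `p_bond`; both
#' partners are then exempt from further attempts. Linking stops when the
#' target cross-link fraction `nu_cr = 2 N_b / N_matrix * 100` is reached;
#' leftover unreacted GMA beads are then converted to PNIPAM.
#'
#' @param sys A `dpd_system` with active beads flagged.
#' @param nu_cr Target cross-link fraction (percent of matrix beads).
#' @param n_steps Reaction-stage length (steps).
#' @param p_bond Bond formation probability per contact per step.
#' @param seed Integer seed.
#' @param sample_every Sampling interval for the bond-count trace.
#' @return A list: `system`, `nb_trace` (cross-link count vs time),
#'   `nu_cr_achieved`, `n_matrix`.
#' @export
crosslink <- function(sys, nu_cr, n_steps, p_bond = 0.1, seed = 1,
                      sample_every = 10) {
  stopifnot(inherits(sys, "dpd_system"), nu_cr >= 0)
  n_matrix <- sum(sys$mobile & sys$type %in% DPD_TYPES[c("PNIPAM", "GMA")])
  target_nb <- round(nu_cr / 100 * n_matrix / 2)
  res <- run_engine(sys, n_steps, seed, sample_every,
                    crosslink = TRUE, p_bond = p_bond, target_nb = target_nb)
  sys <- res$system
  # leftover cross-linker converts to plain matrix once the target is met
  leftover <- sys$active
  sys$type[leftover] <- DPD_TYPES[["PNIPAM"]]
  sys$active <- rep(FALSE, nrow(sys$pos))
  nb <- res$n_crosslinks
  list(system = sys, nb_trace = res$nb_trace,
       nu_cr_achieved = 200 * nb / n_matrix, n_matrix = n_matrix,
       n_bonds_formed = nb)
}

#' Cross-link-dependent swelling of a grafted matrix
#'
#' Full protocol: build the grafted matrix, pre-equilibrate in the collapsed
#' (above-LCST) state, cross-link to the target `nu_cr` in that state,
#' equilibrate and record the collapsed height `h2`, switch below the LCST,
#' re-equilibrate and record the swollen height `h1`. Heights are
#' first-moment brush heights averaged over the sampling window.
#'
#' @inheritParams build_grafted_matrix
#' @param nu_cr Target cross-link fraction (percent).
#' @param n_equil Equilibration steps in the collapsed state.
#' @param n_swell Equilibration steps after the switch below the LCST;
#'   swelling is the slow direction and needs the larger share.
#' @param n_sample Sampling steps per state.
#' @param n_cl Cross-linking stage length.
#' @param seed Integer seed.
#' @param drift_tol Relative drift between the two halves of a sampling
#'   window above which the `equilibrated` flag is set FALSE.
#' @return A list of class `swelling_result`: `h1`, `h2`, `ratio`,
#'   `nu_cr_achieved`, `se` (sampling error of the ratio), `equilibrated`.
#' @export
swelling_experiment <- function(N_chain = 100, rho_g = 0.2, nu_cr = 6,
                                box = c(8, 8, 32), gma_frac = 0.30,
                                n_equil = 3000, n_swell = 20000,
                                n_sample = 2000, n_cl = 1500, seed = 1,
                                drift_tol = 0.1) {
  sys <- build_grafted_matrix(N_chain, rho_g, box, gma_frac,
                              regime = "aboveLCST", seed = seed)
  r <- dpd_integrate(sys, n_equil, seed = seed + 1)
  cl <- crosslink(r$system, nu_cr, n_cl, seed = seed + 2)
  sys <- cl$system

  r2 <- dpd_integrate(sys, n_equil, seed = seed + 3)
  s2 <- dpd_integrate(r2$system, n_sample, seed = seed + 4)
  h2 <- mean(s2$h_trace)

  sys <- set_solvent_quality(s2$system, "belowLCST")
  r1 <- dpd_integrate(sys, n_swell, seed = seed + 5)
  s1 <- dpd_integrate(r1$system, n_sample, seed = seed + 6)
  h1 <- mean(s1$h_trace)

  drift <- function(tr) {
    n <- length(tr)
    a <- mean(tr[seq_len(n %/% 2)]); b <- mean(tr[(n %/% 2 + 1):n])
    abs(b - a) / max(abs(b), 1e-12)
  }
  eq <- drift(s1$h_trace) < drift_tol && drift(s2$h_trace) < drift_tol
  sd1 <- stats::sd(s1$h_trace); sd2 <- stats::sd(s2$h_trace)
  ratio <- h1 / h2
  se <- ratio * sqrt((sd1 / h1)^2 + (sd2 / h2)^2) /
    sqrt(length(s1$h_trace) / 10)
  structure(list(h1 = h1, h2 = h2, ratio = ratio, se = se,
                 nu_cr_achieved = cl$nu_cr_achieved,
                 equilibrated = eq, system = s1$system),
            class = "swelling_result")
}

#' @export
print.swelling_result <- function(x, ...) {
  cat(sprintf("swelling: h1 = %.2f (below LCST), h2 = %.2f (above), ratio %.2f +- %.2f (nu_cr %.1f%%)%s\n",
              x$h1, x$h2, x$ratio, x$se, x$nu_cr_achieved,
              if (x$equilibrated) "" else " [non-equilibrated]"))
  invisible(x)
}

#' Build a matrix pinned between spherical-cap domains
#'
#' Two rigid spherical caps (height 10, sphere radius `R`) sit at opposite
#' box sides, separated by `s` at substrate level; by lateral periodicity
#' they form a domain array. The box is narrow in y, so caps are modeled as
#' y-invariant circular ridges (their curvature across the width is
#' negligible). The matrix has two anchor populations: chains grafted to
#' the substrate strip between the cap feet at density `rho_g`, and chains
#' pinned to the cap surfaces below height `pin_zmax` at density `rho_pd`
#' (the copolymer is deposited over the whole structure and grafts to the
#' epoxy-bearing domain surface wherever it touches, so pinned chains are
#' anchored on the flanks directly).
#'
#' @param R Cap sphere radius (30, 50 or 100 at full scale).
#' @param s Separation between cap feet at substrate level.
#' @param rho_pd Pinning-site density on the cap surface (anchored chains
#'   per unit cap-surface area below the pinning ceiling).
#' @param rho_g Substrate grafting density (fixed at 0.2 in the study
#'   design).
#' @param N_chain Beads per matrix chain.
#' @param cap_H Cap height (fixed at 10).
#' @param pin_zmax Maximum pinning height on the cap (fixed at 7).
#' @param Ly,Lz Box width and height.
#' @param gma_frac GMA fraction for cross-linking.
#' @param seed Integer seed.
#' @return A `dpd_system` with attribute `"pin_sites"` (the anchor
#'   positions on the cap surfaces) and `"n_pinned"` (pinned chain count).
#' @export
build_cap_pinned_matrix <- function(R = 30, s = 10, rho_pd = 0.2,
                                    rho_g = 0.2, N_chain = 50, cap_H = 10,
                                    pin_zmax = 7, Ly = 4, Lz = 24,
                                    gma_frac = 0.30, seed = 1) {
  stopifnot(s > 0, cap_H < 2 * R, pin_zmax <= cap_H)
  set.seed(seed)
  rb <- sqrt(cap_H * (2 * R - cap_H))
  Lx <- 2 * rb + s
  cz <- cap_H - R
  box <- c(Lx, Ly, Lz)

  # substrate wall layer
  n_wall <- round(3 * Lx * Ly)
  wall <- cbind(stats::runif(n_wall, 0, Lx), stats::runif(n_wall, 0, Ly),
                stats::runif(n_wall, -1, 0))

  # substrate-grafted chains strictly between the cap feet (ridge at x = 0)
  n_sub <- max(1, round(rho_g * (Lx - 2 * rb - 1) * Ly))
  gx <- stats::runif(n_sub, rb + 0.5, Lx - rb - 0.5)
  gy <- stats::runif(n_sub, 0, Ly)
  gz <- rep(0, n_sub)

  # cap-pinned chains: anchors on the cap surface below pin_zmax
  th_max <- acos((0 - cz) / R)           # foot angle (substrate level)
  th_min <- acos((pin_zmax - cz) / R)    # angle at the pinning ceiling
  arc_len <- R * (th_max - th_min) * 2   # both flanks
  n_pin <- round(rho_pd * arc_len * Ly)
  if (n_pin > 0) {
    th <- stats::runif(n_pin, th_min, th_max)
    side <- sample(c(-1, 1), n_pin, replace = TRUE)
    px <- (side * (R + 0.3) * sin(th)) %% Lx
    pz <- cz + (R + 0.3) * cos(th)
    py <- stats::runif(n_pin, 0, Ly)
    gx <- c(gx, px); gy <- c(gy, py); gz <- c(gz, pz)
  }
  n_chains <- n_sub + n_pin
  pin_sites <- if (n_pin > 0) cbind(gx[(n_sub + 1):n_chains],
                                    gy[(n_sub + 1):n_chains],
                                    gz[(n_sub + 1):n_chains]) else matrix(0, 0, 3)

  pos <- vector("list", n_chains)
  bonds <- vector("list", n_chains)
  off <- n_wall
  h0 <- min(max(3, 1.5 * N_chain * rho_g / 3), Lz - 1)
  in_cap <- function(x, z) {
    dx <- x
    dx[dx > Lx / 2] <- dx[dx > Lx / 2] - Lx
    dx^2 + (z - cz)^2 < (R + 0.1)^2
  }
  for (c in seq_len(n_chains)) {
    z <- reflect_walk(max(gz[c], 0.3), stats::rnorm(N_chain - 1, sd = 0.3),
                      0.2, max(h0, gz[c] + 1))
    # lateral walk drifting off the cap toward the strip centre
    drift <- 0.15 * sign(((Lx / 2) - gx[c] + Lx) %% Lx - Lx / 2)
    px <- gx[c] + cumsum(c(0, stats::rnorm(N_chain - 1, mean = drift, sd = 0.3)))
    px <- px %% Lx
    # push beads that landed inside the cap ridge radially out
    bad <- in_cap(px, z)
    if (any(bad)) {
      dx <- px[bad]; dx[dx > Lx / 2] <- dx[dx > Lx / 2] - Lx
      d <- sqrt(dx^2 + (z[bad] - cz)^2)
      scale <- (R + 0.3) / pmax(d, 1e-6)
      px[bad] <- (dx * scale) %% Lx
      z[bad] <- pmin(pmax(cz + (z[bad] - cz) * scale, 0.2), Lz - 0.5)
    }
    py <- (gy[c] + cumsum(stats::rnorm(N_chain, sd = 0.3))) %% Ly
    pos[[c]] <- cbind(px, py, z)
    idx <- off + seq_len(N_chain)
    bonds[[c]] <- cbind(idx[-N_chain], idx[-1])
    off <- off + N_chain
  }
  poly <- do.call(rbind, pos)
  n_poly <- n_chains * N_chain
  ptype <- ifelse(stats::runif(n_poly) < gma_frac,
                  DPD_TYPES[["GMA"]], DPD_TYPES[["PNIPAM"]])

  # solvent outside the cap ridge
  n_try <- round(3 * Lx * Ly * Lz) - n_poly
  sx <- stats::runif(n_try, 0, Lx); sy <- stats::runif(n_try, 0, Ly)
  sz <- stats::runif(n_try, 0, Lz)
  keep <- !in_cap(sx, sz)
  solv <- cbind(sx[keep], sy[keep], sz[keep])
  n_solv <- nrow(solv)

  pos_all <- rbind(wall, poly, solv)
  n <- nrow(pos_all)
  type <- c(rep(DPD_TYPES[["WALL"]], n_wall), ptype,
            rep(DPD_TYPES[["WATER"]], n_solv))
  mobile <- c(rep(FALSE, n_wall), rep(TRUE, n_poly + n_solv))
  vel <- matrix(0, n, 3)
  vel[mobile, ] <- rnorm_mom0(sum(mobile), 1)
  anchor_idx <- n_wall + (seq_len(n_chains) - 1) * N_chain + 1L
  anchor_xyz <- cbind(gx, gy, gz)
  active <- type == DPD_TYPES[["GMA"]]

  sys <- new_dpd_system(pos_all, vel, type, mobile, box, periodic_z = FALSE,
                        aij = dpd_aij("aboveLCST"),
                        bonds = do.call(rbind, bonds),
                        anchor_idx = anchor_idx, anchor_xyz = anchor_xyz,
                        caps = matrix(c(0, cz, R), 1, 3), active = active,
                        regime = "aboveLCST")
  attr(sys, "pin_sites") <- pin_sites
  attr(sys, "n_pinned") <- n_pin
  sys
}

#' Attach matrix beads to cap pinning sites
#' Attach matrix beads to cap pinning sites
#'
#' For each candidate pin site (on the cap surface below the pinning
#' ceiling), the nearest mobile matrix bead within `cutoff` is anchored to
#' the site by a harmonic spring; sites with no bead in reach are skipped.
#' Call after pre-equilibration so the collapsed matrix is in contact with
#' the caps.
#'
#' @param sys A system built by [build_cap_pinned_matrix()].
#' @param pin_sites Candidate sites; default the ones stored on the system.
#' @param cutoff Maximum site-bead distance.
#' @return The system with pin anchors added; attribute `"n_pinned"` gives
#'   the number attached.
#' @export
attach_pins <- function(sys, pin_sites = NULL, cutoff = 1.5) {
  stopifnot(inherits(sys, "dpd_system"))
  if (is.null(pin_sites)) pin_sites <- attr(sys, "pin_sites")
  if (is.null(pin_sites) || nrow(pin_sites) == 0) {
    attr(sys, "n_pinned") <- 0L
    return(sys)
  }
  sel <- which(sys$mobile & sys$type %in% DPD_TYPES[c("PNIPAM", "GMA")])
  taken <- rep(FALSE, length(sel))
  Lx <- sys$box[1]; Ly <- sys$box[2]
  n_att <- 0L
  for (k in seq_len(nrow(pin_sites))) {
    dx <- abs(sys$pos[sel, 1] - pin_sites[k, 1]); dx <- pmin(dx, Lx - dx)
    dy <- abs(sys$pos[sel, 2] - pin_sites[k, 2]); dy <- pmin(dy, Ly - dy)
    dz <- sys$pos[sel, 3] - pin_sites[k, 3]
    d2 <- dx^2 + dy^2 + dz^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (d2[j] <= cutoff^2) {
      sys$anchor_idx <- c(sys$anchor_idx, sel[j])
      sys$anchor_xyz <- rbind(sys$anchor_xyz, pin_sites[k, ])
      taken[j] <- TRUE
      n_att <- n_att + 1L
    }
  }
  attr(sys, "n_pinned") <- n_att
  sys
}

#' Swelling of a cap-pinned matrix
#'
#' The cap-geometry analogue of [swelling_experiment()]: build the
#' cap-pinned system, pre-equilibrate collapsed, attach pins, cross-link,
#' record `h2`, switch below the LCST, record `h1`. As in the study design,
#' heights are recorded over a fixed late window and the result carries a
#' non-equilibration flag rather than extending the runs.
#'
#' @inheritParams build_cap_pinned_matrix
#' @param nu_cr Target cross-link fraction (percent).
#' @param n_equil,n_swell,n_sample,n_cl Stage lengths (steps).
#' @param seed Integer seed.
#' @return A `swelling_result` with an added `n_pinned` element.
#' @export
cap_swelling_experiment <- function(R = 30, s = 10, rho_pd = 0.2,
                                    nu_cr = 7, N_chain = 50,
                                    Ly = 4, Lz = 24,
                                    n_equil = 2000, n_swell = 4000,
                                    n_sample = 1200, n_cl = 1200, seed = 1) {
  sys <- build_cap_pinned_matrix(R = R, s = s, rho_pd = rho_pd,
                                 N_chain = N_chain, Ly = Ly, Lz = Lz,
                                 seed = seed)
  n_pinned <- attr(sys, "n_pinned")
  r <- dpd_integrate(sys, n_equil, seed = seed + 1)
  cl <- crosslink(r$system, nu_cr, n_cl, seed = seed + 2)

  r2 <- dpd_integrate(cl$system, n_equil, seed = seed + 3)
  s2 <- dpd_integrate(r2$system, n_sample, seed = seed + 4)
  h2 <- mean(s2$h_trace)

  sysb <- set_solvent_quality(s2$system, "belowLCST")
  r1 <- dpd_integrate(sysb, n_swell, seed = seed + 5)
  s1 <- dpd_integrate(r1$system, n_sample, seed = seed + 6)
  h1 <- mean(s1$h_trace)

  structure(list(h1 = h1, h2 = h2, ratio = h1 / h2,
                 se = NA_real_, nu_cr_achieved = cl$nu_cr_achieved,
                 equilibrated = NA, n_pinned = n_pinned,
                 system = s1$system),
            class = "swelling_result")
}

#' Phase separation of a tethered binary polymer film
#'
#' Surface-tethered PGMA and matrix chains at PGMA mass fraction `f` under
#' strong mutual repulsion in a near-theta solvent phase-separate into PGMA
#' domains. PGMA beads are then clustered (single linkage at the interaction
#' range) and each cluster is sliced horizontally and fitted with the
#' spherical-cap model.
#'
#' @param f PGMA mass fraction, in (0, 1).
#' @param n_steps Evolution steps.
#' @param box Box dimensions.
#' @param N_chain Beads per chain.
#' @param rho_graft Total grafting density of the tethered film.
#' @param seed Integer seed.
#' @return A list: `system`, `domains` (per-cluster size, height, base
#'   radius, fitted `R_sp`, slice-consistency spread), `f`.
#' @export
phase_separation_experiment <- function(f, n_steps = 4000,
                                        box = c(16, 16, 12), N_chain = 20,
                                        rho_graft = 0.6, seed = 1) {
  stopifnot(f > 0, f < 1)
  set.seed(seed)
  Lx <- box[1]; Ly <- box[2]; Lz <- box[3]
  n_chains <- round(rho_graft * Lx * Ly)
  n_pgma_chains <- max(1, round(f * n_chains))

  n_wall <- round(3 * Lx * Ly)
  wall <- cbind(stats::runif(n_wall, 0, Lx), stats::runif(n_wall, 0, Ly),
                stats::runif(n_wall, -1, 0))
  gx <- stats::runif(n_chains, 0, Lx); gy <- stats::runif(n_chains, 0, Ly)
  pos <- vector("list", n_chains); bonds <- vector("list", n_chains)
  off <- n_wall
  h0 <- min(max(3, 1.5 * N_chain * rho_graft / 3), Lz - 1)
  for (c in seq_len(n_chains)) {
    z <- reflect_walk(0.3, stats::rnorm(N_chain - 1, sd = 0.3), 0.2, h0)
    px <- (gx[c] + cumsum(stats::rnorm(N_chain, sd = 0.3))) %% Lx
    py <- (gy[c] + cumsum(stats::rnorm(N_chain, sd = 0.3))) %% Ly
    pos[[c]] <- cbind(px, py, z)
    idx <- off + seq_len(N_chain)
    bonds[[c]] <- cbind(idx[-N_chain], idx[-1])
    off <- off + N_chain
  }
  poly <- do.call(rbind, pos)
  n_poly <- n_chains * N_chain
  chain_is_pgma <- seq_len(n_chains) %in% sample(n_chains, n_pgma_chains)
  ptype <- rep(ifelse(chain_is_pgma, DPD_TYPES[["PGMA"]],
                      DPD_TYPES[["PNIPAM"]]), each = N_chain)
  n_solv <- round(3 * prod(box)) - n_poly
  solv <- cbind(stats::runif(n_solv, 0, Lx), stats::runif(n_solv, 0, Ly),
                stats::runif(n_solv, 0, Lz))
  pos_all <- rbind(wall, poly, solv)
  n <- nrow(pos_all)
  type <- c(rep(DPD_TYPES[["WALL"]], n_wall), ptype,
            rep(DPD_TYPES[["WATER"]], n_solv))
  mobile <- c(rep(FALSE, n_wall), rep(TRUE, n_poly + n_solv))
  vel <- matrix(0, n, 3)
  vel[mobile, ] <- rnorm_mom0(sum(mobile), 1)
  # theta-like solvent for both polymers during phase separation
  aij <- dpd_aij("aboveLCST")
  aij["PNIPAM", "WATER"] <- aij["WATER", "PNIPAM"] <- 27
  aij["GMA", "WATER"] <- aij["WATER", "GMA"] <- 27
  sys <- new_dpd_system(pos_all, vel, type, mobile, box, periodic_z = FALSE,
                        aij = aij, bonds = do.call(rbind, bonds),
                        anchor_idx = n_wall + (seq_len(n_chains) - 1) * N_chain + 1L,
                        anchor_xyz = cbind(gx, gy, 0), regime = "theta")
  r <- dpd_integrate(sys, n_steps, seed = seed + 1)
  sys <- r$system

  dom <- cluster_cap_fit(sys, box)
  list(system = sys, domains = dom, f = f)
}

# single-linkage clustering of PGMA beads at the interaction range, plus
# horizontal slicing and spherical-cap fits per cluster
cluster_cap_fit <- function(sys, box, cutoff = 1.0, min_size = 10) {
  sel <- which(sys$type == DPD_TYPES[["PGMA"]] & sys$mobile)
  if (length(sel) == 0) {
    warning("no domain-forming beads found")
    return(data.frame())
  }
  p <- sys$pos[sel, , drop = FALSE]
  # periodic-aware single linkage via union-find on neighbour pairs
  n <- nrow(p)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(p[, 1])
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      dx <- abs(p[i, 1] - p[j, 1]); dx <- min(dx, box[1] - dx)
      if (abs(p[i, 1] - p[j, 1]) > cutoff && dx > cutoff) break
      dy <- abs(p[i, 2] - p[j, 2]); dy <- min(dy, box[2] - dy)
      dz <- p[i, 3] - p[j, 3]
      if (dx^2 + dy^2 + dz^2 <= cutoff^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  lab <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), lab), function(ii) {
    if (length(ii) < min_size) return(NULL)
    q <- p[ii, , drop = FALSE]
    H <- max(q[, 3])
    # slice radii from bead counts (collapsed domains are near melt density)
    lv <- seq(0.15 * H, 0.85 * H, length.out = 4)
    dzs <- 0.15 * H
    r <- vapply(lv, function(h) {
      m <- sum(abs(q[, 3] - h) < dzs / 2)
      sqrt(m / (3 * dzs) / pi)
    }, numeric(1))
    d <- H - lv
    ok <- r > 0
    if (sum(ok) < 2) return(NULL)
    Rsp <- sum((r[ok]^2 + d[ok]^2) * d[ok]) / (2 * sum(d[ok]^2))
    Rsp_k <- (r[ok]^2 + d[ok]^2) / (2 * d[ok])
    data.frame(n_beads = length(ii), H = H,
               R_base = max(r), R_sp = Rsp,
               Rsp_spread = (max(Rsp_k) - min(Rsp_k)) / max(Rsp, 1e-9))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) data.frame() else out
}
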