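#' Monte Carlo model of cell sorting on a micropatterned surface
#'
#' @description
#' The simulator represents the microstructured surface as an array of
#' cylindrical adhesive domains of diameter `D_d` (height equal to diameter)
#' randomly placed without overlap at coverage `sigma_d`, with a
#' thermoresponsive polymer phase filling the gaps. In the collapsed state the
#' polymer is inert; in the swollen state its surface rises a height `h_p`
#' above the domain tops and repels cells with strength `B_p` per unit
#' overlap area. Cells are hard spheres of diameter `D` that deform locally
#' into a flat circular facet on contact (depth limited by `delta_max`), are
#' pulled toward the surface by a linear gravity field `g_w`, and move by
#' Metropolis dynamics at effective noise temperature `T_eff`.
#'
#' @name mc_cellsort
NULL

#' Default Monte Carlo parameters
#'
#' @description
#' Parameters of the cell-sorting Monte Carlo model in reduced units (cell
#' diameter `D = 10`, energies per unit area in units of `T_eff`). The
#' adhesion parameters `A1 = -0.4` and `A2 = -0.3` and the coverage
#' `sigma_d = 0.48` are the published model values; `h_p`, `delta_max`,
#' `g_w` and the move size `delta` are not published and carry a single
#' documented calibration (see the package vignette) chosen so that the
#' working points of the detachment sweeps are reproduced:
#' `delta_max = 3.25`, `h_p = 0.3`, `g_w = 0.1`, `delta = 1.5`.
#'
#' @param D Cell diameter (reduced units).
#' @param A1,A2 Adhesion energies per unit contact area for cell types 1 and
#'   2 (negative values attract).
#' @param Bp Polymer-cell repulsion per unit area (swollen state).
#' @param gw Gravity energy per unit height.
#' @param Teff Effective noise temperature (energy unit).
#' @param delta Maximum displacement per trial move (cube half-width).
#' @param delta_max Maximum deformation depth of the contact facet.
#' @param hp Swollen polymer surface height above the domain tops.
#' @param Hbox Box height (reflecting top boundary).
#' @param swollen Logical, polymer state.
#' @return A named list of parameters.
#' @export
mc_params <- function(D = 10, A1 = -0.4, A2 = -0.3, Bp = 0, gw = 0.1,
                      Teff = 1, delta = 1.5, delta_max = 3.25, hp = 0.3,
                      Hbox = 40, swollen = FALSE) {
  stopifnot(Teff > 0, delta_max > 0, delta_max < D / 2, delta > 0,
            Bp >= 0, hp >= 0)
  list(D = D, A1 = A1, A2 = A2, Bp = Bp, gw = gw, Teff = Teff,
       delta = delta, delta_max = delta_max, hp = hp, Hbox = Hbox,
       swollen = swollen)
}

#' Place adhesive domains by random sequential adsorption
#'
#' Non-overlapping discs of diameter `D_d` are placed uniformly at random
#' (with lateral periodic wrapping) until the target coverage `sigma_d` is
#' reached. The domain count is `round(sigma_d * L^2 / (pi * (D_d/2)^2))`.
#'
#' @param L Lateral box side (periodic).
#' @param Dd Domain diameter; the domain height equals `Dd`.
#' @param sigma_d Target coverage fraction; must stay below the disc RSA
#'   jamming bound (~0.547) so that placement terminates.
#' @param seed Integer seed.
#' @param attempts_per_disk Attempt budget per domain before failing.
#' @return An object of class `micro_surface` with the fixed domain centres.
#' @export
place_domains_rsa <- function(L, Dd, sigma_d, seed, attempts_per_disk = 5000) {
  stopifnot(L > 0, Dd > 0, sigma_d >= 0)
  if (sigma_d >= 0.52) stop("sigma_d too close to the RSA jamming coverage; placement would not terminate")
  n <- round(sigma_d * L^2 / (pi * (Dd / 2)^2))
  centers <- .rsa_disks(L, Dd, n, attempts_per_disk, as.integer(seed))
  achieved <- n * pi * (Dd / 2)^2 / L^2
  structure(list(L = L, Dd = Dd, Hd = Dd, sigma_d = sigma_d,
                 coverage = achieved, centers = centers, seed = seed),
            class = "micro_surface")
}

#' @export
print.micro_surface <- function(x, ...) {
  cat(sprintf("micro surface: L = %g, %d domains of diameter %g, coverage %.3f\n",
              x$L, nrow(x$centers), x$Dd, x$coverage))
  invisible(x)
}

#' Initial hard-sphere cell configuration
#'
#' Places `N1 + N2` cells of diameter `D` uniformly in the box without
#' hard-sphere overlap, above the surface.
#'
#' @param surface A [place_domains_rsa()] surface.
#' @param N1,N2 Cell counts of types 1 and 2.
#' @param params [mc_params()].
#' @param seed Integer seed.
#' @return A list with `pos` (N x 3) and `type`.
#' @export
init_cells <- function(surface, N1, N2, params, seed) {
  set.seed(seed)
  N <- N1 + N2
  D <- params$D
  zlo <- surface$Hd + D / 2
  zhi <- params$Hbox
  if (zhi - zlo < D) stop("box too short for cell placement")
  pos <- matrix(NA_real_, N, 3)
  L <- surface$L
  for (i in seq_len(N)) {
    for (attempt in 1:10000) {
      p <- c(stats::runif(1, 0, L), stats::runif(1, 0, L), stats::runif(1, zlo, zhi))
      if (i == 1) { pos[i, ] <- p; break }
      dx <- abs(pos[seq_len(i - 1), 1] - p[1]); dx <- pmin(dx, L - dx)
      dy <- abs(pos[seq_len(i - 1), 2] - p[2]); dy <- pmin(dy, L - dy)
      dz <- pos[seq_len(i - 1), 3] - p[3]
      if (all(dx^2 + dy^2 + dz^2 >= D^2)) { pos[i, ] <- p; break }
      if (attempt == 10000) stop("could not place cells without overlap")
    }
  }
  list(pos = pos, type = c(rep(1L, N1), rep(2L, N2)))
}

#' Contact and repulsion areas for a single cell
#'
#' Evaluates the energy model for one cell at a given position: the total
#' cell-domain contact area (sum of lens intersections between the flat
#' deformation facet and the domain top discs), the repulsion cross-section
#' area with the swollen polymer surface (domain areas excluded), and the
#' resulting potential energy.
#'
#' @param xyz Cell centre position, length 3.
#' @param type Cell type, 1 or 2.
#' @param surface A [place_domains_rsa()] surface.
#' @param params [mc_params()].
#' @return List with `energy`, `contact_area`, `repulsion_area`.
#' @export
cell_energy <- function(xyz, type, surface, params) {
  D <- params$D
  h <- xyz[3] - surface$Hd
  if (h < D / 2 - params$delta_max - 1e-12) {
    stop("hard-wall violation: cell centre below the maximum-deformation plane")
  }
  par <- c(params, list(Hd = surface$Hd, Dd = surface$Dd))
  .mc_cell_energy(as.numeric(xyz), as.integer(type), surface$centers,
                  surface$L, par)
}

#' Area of the intersection of two circles
#'
#' Lens (two-circle intersection) area for circles of radii `r1`, `r2` at
#' centre distance `d`; the primitive behind the contact- and
#' repulsion-area calculations.
#'
#' @param r1,r2 Circle radii.
#' @param d Centre distance.
#' @return Intersection area.
#' @export
circle_lens_area <- function(r1, r2, d) {
  mapply(.circle_lens_area, r1, r2, d)
}

#' Run a Monte Carlo stage
#'
#' Advances the system by `n_moves` attempted single-cell Metropolis moves.
#' A move picks a cell uniformly, proposes a uniform displacement in a cube
#' of half-width `delta`, and accepts with probability
#' `min(1, exp(-dE / T_eff))`; moves violating the hard-sphere, hard-wall or
#' box constraints are rejected. Attached-cell fractions (cells whose centre
#' is within `rcut` of the domain-top plane) are averaged over the final
#' half of the stage.
#'
#' @param surface A [place_domains_rsa()] surface.
#' @param cells A cell configuration from [init_cells()] or a previous run.
#' @param params [mc_params()].
#' @param n_moves Number of attempted moves.
#' @param seed Integer seed.
#' @param sample_every Sampling interval (moves).
#' @param record_z Record z coordinates in the averaging window (for density
#'   profiles).
#' @param rcut Attachment cutoff from the domain-top plane; default `D/2`.
#' @return A list of class `mc_stage`: final `cells`, acceptance rate,
#'   potential-energy trace, per-type attached-percentage traces and
#'   final-half averages `frac1`, `frac2`.
#' @export
mc_stage <- function(surface, cells, params, n_moves, seed,
                     sample_every = 1000, record_z = FALSE, rcut = NULL) {
  if (is.null(rcut)) rcut <- params$D / 2
  par <- c(params, list(Hd = surface$Hd, Dd = surface$Dd))
  res <- .mc_run(surface$centers, surface$L, cells$pos,
                 as.integer(cells$type), par, as.double(n_moves),
                 as.integer(sample_every), as.integer(seed),
                 isTRUE(record_z), rcut)
  res$cells <- list(pos = res$pos, type = cells$type)
  res$pos <- NULL
  res$params <- params
  res$n_moves <- n_moves
  class(res) <- "mc_stage"
  res
}

#' @export
print.mc_stage <- function(x, ...) {
  cat(sprintf("MC stage: %g moves, acceptance %.2f, attached %.1f%% / %.1f%% (type 1/2)\n",
              x$n_moves, x$acc_rate, x$frac1, x$frac2))
  invisible(x)
}

#' Adsorption stage
#'
#' First stage of the two-stage protocol: the polymer is collapsed
#' (`B_p = 0`), cells settle under gravity and adhere to the domains. The
#' potential energy is monitored; the step at which it saturates (first
#' sample within `sat_tol` standard deviations of the final-quarter mean) is
#' reported. A warning is raised if the energy has not saturated.
#'
#' @inheritParams mc_stage
#' @param sat_tol Saturation band, in SDs of the final-quarter energy.
#' @return An `mc_stage` with an added `saturation_step` element.
#' @export
run_adsorption <- function(surface, cells, params, n_moves, seed,
                           sample_every = 1000, sat_tol = 2) {
  params$swollen <- FALSE
  params$Bp <- 0
  res <- mc_stage(surface, cells, params, n_moves, seed, sample_every)
  tr <- res$energy_trace
  nq <- length(tr)
  # smooth before band-testing so single-sample outliers do not mask
  # saturation of the underlying trend
  k <- max(1, min(5, nq %/% 10))
  trs <- as.numeric(stats::filter(tr, rep(1 / k, k), sides = 1))
  trs[seq_len(k - 1)] <- trs[k]
  tail_idx <- seq(floor(3 * nq / 4), nq)
  mu <- mean(trs[tail_idx]); sdv <- stats::sd(trs[tail_idx])
  inside <- abs(trs - mu) <= sat_tol * max(sdv, 1e-12)
  first_sat <- which(inside & rev(cumprod(rev(inside))) == 1)[1]
  res$saturation_step <- if (is.na(first_sat)) NA_real_ else first_sat * sample_every
  if (is.na(first_sat) || first_sat > 0.9 * nq) {
    warning("adsorption energy did not clearly saturate within the stage")
  }
  res
}

#' Desorption stage
#'
#' Second stage: starting from an adsorption-stage configuration, the polymer
#' is set swollen with repulsion strength `B_p` and the system is run;
#' attached counts are averaged over the final half of the stage.
#'
#' @inheritParams mc_stage
#' @param Bp Repulsion strength for this stage.
#' @return An `mc_stage`; `frac1`/`frac2` are the remaining attached
#'   percentages, and `sf` the separation factor (see
#'   [separation_factor_sim()]).
#' @export
run_desorption <- function(surface, cells, params, Bp, n_moves, seed,
                           sample_every = 1000, record_z = FALSE) {
  stopifnot(Bp >= 0)
  params$swollen <- TRUE
  params$Bp <- Bp
  res <- mc_stage(surface, cells, params, n_moves, seed, sample_every,
                  record_z = record_z)
  sf <- separation_factor_sim(res$frac1, res$frac2, initial_ratio = 1)
  res$Bp <- Bp
  res$sf <- sf$sf
  res$sf_defined <- sf$defined
  res
}

#' Simulation separation factor
#'
#' Enrichment of type-1 cells among those remaining attached, relative to the
#' initial adsorption ratio: `(attached_1 / attached_2) / initial_ratio`.
#'
#' @param attached_1,attached_2 Remaining attached counts (or percentages of
#'   equal-sized populations) of types 1 and 2.
#' @param initial_ratio Initial type-1:type-2 ratio (default 1).
#' @return List with `sf` and `defined` (FALSE when `attached_2` is 0, in
#'   which case `sf` is `NA`).
#' @export
separation_factor_sim <- function(attached_1, attached_2, initial_ratio = 1) {
  stopifnot(attached_1 >= 0, attached_2 >= 0, initial_ratio > 0)
  if (attached_2 == 0) {
    list(sf = NA_real_, defined = FALSE)
  } else {
    list(sf = (attached_1 / attached_2) / initial_ratio, defined = TRUE)
  }
}

#' Two-stage adsorption/desorption sweep over domain sizes and B_p
#'
#' Runs the full factorial of domain diameters and repulsion strengths with
#' `n_seeds` independent replicas. For each domain diameter and seed, one
#' surface is built and one adsorption stage is run; every `B_p` desorption
#' starts from that adsorbed configuration, mirroring the two-stage protocol.
#'
#' @param Dd_list Domain diameters.
#' @param Bp_grid Repulsion strengths.
#' @param params [mc_params()].
#' @param L Box side.
#' @param sigma_d Domain coverage.
#' @param N1,N2 Cell counts.
#' @param n_ads,n_des Moves per adsorption / desorption stage.
#' @param n_seeds Number of independent replicas.
#' @param seed Base seed; replica seeds are derived from it.
#' @param verbose Print progress.
#' @return A data frame of class `mc_sweep` with one row per
#'   `(Dd, Bp)`: mean attached percentages `frac1`, `frac2` with standard
#'   errors, and the separation factor `sf` computed from the mean
#'   fractions. Attribute `peaks` holds the per-`Dd` separation-factor
#'   maxima and their `Bp` locations.
#' @export
mc_sweep <- function(Dd_list, Bp_grid, params = mc_params(), L = 240,
                     sigma_d = 0.48, N1 = 100, N2 = 100,
                     n_ads = 4e5, n_des = 4e5, n_seeds = 3, seed = 1,
                     verbose = FALSE) {
  rows <- list()
  for (Dd in Dd_list) {
    frac1 <- matrix(NA_real_, n_seeds, length(Bp_grid))
    frac2 <- matrix(NA_real_, n_seeds, length(Bp_grid))
    for (s in seq_len(n_seeds)) {
      sd_i <- seed * 1000L + s * 101L + round(100 * Dd)
      surf <- place_domains_rsa(L, Dd, sigma_d, seed = sd_i)
      cells <- init_cells(surf, N1, N2, params, seed = sd_i + 1L)
      ads <- run_adsorption(surf, cells, params, n_ads, seed = sd_i + 2L)
      for (b in seq_along(Bp_grid)) {
        des <- run_desorption(surf, ads$cells, params, Bp_grid[b], n_des,
                              seed = sd_i + 3L + b)
        frac1[s, b] <- des$frac1
        frac2[s, b] <- des$frac2
        if (verbose) {
          message(sprintf("Dd=%.2f seed %d Bp=%.3f: %.1f%% / %.1f%%",
                          Dd, s, Bp_grid[b], des$frac1, des$frac2))
        }
      }
    }
    se <- function(m) apply(m, 2, stats::sd) / sqrt(max(1, n_seeds - 1))
    f1 <- colMeans(frac1); f2 <- colMeans(frac2)
    sf <- ifelse(f2 > 0, f1 / f2, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      Dd = Dd, Bp = Bp_grid, frac1 = f1, frac2 = f2,
      se1 = se(frac1), se2 = se(frac2), sf = sf)
  }
  out <- do.call(rbind, rows)
  peaks <- do.call(rbind, lapply(split(out, out$Dd), function(d) {
    i <- which.max(d$sf)
    data.frame(Dd = d$Dd[1], Bp_peak = d$Bp[i], sf_peak = d$sf[i])
  }))
  attr(out, "peaks") <- peaks
  class(out) <- c("mc_sweep", class(out))
  out
}

#' Cell density profile along z
#'
#' Histogram of cell-centre heights from the sampling window of a stage run
#' with `record_z = TRUE`, per cell type, normalized to unit area.
#'
#' @param stage An `mc_stage` run with `record_z = TRUE`.
#' @param breaks Bin boundaries (reduced units); default 80 bins over the
#'   sampled range.
#' @return A data frame with `z` (bin centres), `density1`, `density2`.
#' @export
density_profile <- function(stage, breaks = 80) {
  if (is.null(stage$z_samples)) stop("stage was not run with record_z = TRUE")
  n <- length(stage$z_types)
  z <- matrix(stage$z_samples, nrow = n)
  h <- graphics::hist(stage$z_samples, breaks = breaks, plot = FALSE)
  d1 <- graphics::hist(z[stage$z_types == 0, ], breaks = h$breaks,
                       plot = FALSE)$density
  d2 <- graphics::hist(z[stage$z_types == 1, ], breaks = h$breaks,
                       plot = FALSE)$density
  data.frame(z = h$mids, density1 = d1, density2 = d2)
}

#' Empirical Metropolis acceptance frequency
#'
#' Draws `n` acceptance decisions at a fixed energy difference using the
#' engine's own random number stream and acceptance rule, returning the
#' empirical acceptance frequency (expected `min(1, exp(-dE/T_eff))`).
#'
#' @param dE Energy difference of the proposed move.
#' @param Teff Effective temperature.
#' @param n Number of trials.
#' @param seed Integer seed.
#' @return Acceptance frequency in `[0, 1]`.
#' @export
mc_acceptance_freq <- function(dE, Teff = 1, n = 10000, seed = 1) {
  .mc_accept_freq(dE, Teff, as.integer(n), as.integer(seed))
}
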