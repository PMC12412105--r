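#' Spherical-cap domain geometry
#'
#' Constructs a spherical cap, the geometric model used for phase-separated
#' adhesive polymer domains on a microstructured surface. The cap is the part
#' of a sphere of radius `R_sp` protruding a height `H` above the basal plane.
#'
#' @param R_sp Radius of the sphere with the same curvature as the domain
#'   (nm or reduced units).
#' @param H Cap height above the basal plane, in the same units. Must satisfy
#'   `0 < H <= 2 * R_sp`.
#' @param center_xy Optional lateral position of the cap apex, length-2 numeric.
#' @return An object of class `spherical_cap` with fields `R_sp`, `H`,
#'   `center_xy`.
#' @examples
#' cap <- spherical_cap(R_sp = 100, H = 20)
#' cap_base_radius(cap)
#' @export
spherical_cap <- function(R_sp, H, center_xy = c(0, 0)) {
  stopifnot(is.numeric(R_sp), is.numeric(H), length(R_sp) == 1L, length(H) == 1L)
  if (!is.finite(R_sp) || R_sp <= 0) {
    stop("invalid cap: R_sp must be positive and finite")
  }
  if (!is.finite(H) || H < 0 || H > 2 * R_sp) {
    stop("invalid cap: H must satisfy 0 <= H <= 2*R_sp")
  }
  structure(
    list(R_sp = as.numeric(R_sp), H = as.numeric(H),
         center_xy = as.numeric(center_xy)),
    class = "spherical_cap"
  )
}

#' @export
print.spherical_cap <- function(x, ...) {
  cat(sprintf("spherical cap: R_sp = %g, H = %g, base radius R_d' = %g\n",
              x$R_sp, x$H, cap_base_radius(x)))
  invisible(x)
}

#' Base radius of a spherical cap
#'
#' The radius `R_d'` of the circle where the cap meets the basal plane,
#' `sqrt(H * (2 * R_sp - H))`. For a hemisphere (`H == R_sp`) this equals
#' `R_sp`.
#'
#' @param cap A [spherical_cap()].
#' @return Base radius, same units as the cap.
#' @export
cap_base_radius <- function(cap) {
  stopifnot(inherits(cap, "spherical_cap"))
  sqrt(cap$H * (2 * cap$R_sp - cap$H))
}

#' Radius of a horizontal slice through a spherical cap
#'
#' Radius of the circle where the horizontal plane at height `h_slice` above
#' the basal plane cuts the cap: `sqrt(R_sp^2 - (R_sp - H + h_slice)^2)`.
#' At `h_slice = 0` this is the base radius; at `h_slice = H` it is zero.
#'
#' @param cap A [spherical_cap()].
#' @param h_slice Slice height, in `[0, H]`. Vectorized.
#' @return Slice radius (or radii), same units as the cap.
#' @export
cap_slice_radius <- function(cap, h_slice) {
  stopifnot(inherits(cap, "spherical_cap"), is.numeric(h_slice))
  if (any(h_slice < 0 | h_slice > cap$H)) {
    stop("h_slice must lie within [0, H]")
  }
  d <- cap$R_sp - cap$H + h_slice
  sqrt(pmax(cap$R_sp^2 - d^2, 0))
}

#' Projected domain area exposed above the matrix level
#'
#' The projected (plan-view) area of the part of a cap protruding above a flat
#' matrix at height `matrix_level`: `pi * r^2` where `r` is the slice radius
#' at that level, or 0 if the cap is fully buried.
#'
#' @param cap A [spherical_cap()].
#' @param matrix_level Matrix surface height above the basal plane (>= 0).
#' @return Projected exposed area.
#' @export
exposed_area <- function(cap, matrix_level) {
  stopifnot(inherits(cap, "spherical_cap"),
            is.numeric(matrix_level), length(matrix_level) == 1L,
            matrix_level >= 0)
  if (matrix_level >= cap$H) return(0)
  pi * cap_slice_radius(cap, matrix_level)^2
}

#' Swelling ratio of a thermoresponsive matrix
#'
#' Ratio of the matrix height in the swollen state (in water below the LCST)
#' to its height in the collapsed/dry state, `h_below / h_air`.
#'
#' @param h_below Matrix height below the LCST (nm).
#' @param h_air Matrix height in air (nm); must be positive.
#' @param digits Decimal places for reporting; tabulated values are
#'   conventionally printed to one decimal. Use `NULL` for no rounding.
#' @return Dimensionless swelling ratio.
#' @examples
#' swelling_ratio(57.7, 16.7) # 3.5
#' @export
swelling_ratio <- function(h_below, h_air, digits = 1) {
  if (any(h_air <= 0)) stop("h_air must be positive")
  r <- h_below / h_air
  if (!is.null(digits)) r <- round(r, digits) else r
  r
}

#' Length-scale mapping between simulation and experimental units
#'
#' Calibrates reduced simulation lengths against measured nanometre scales by
#' matching cap heights and base radii separately. Phase-separation models
#' typically need a larger lateral factor than the height factor because
#' simulated domains are less immersed in the substrate than fabricated ones.
#'
#' @param H_exp_nm Experimental cap height (nm).
#' @param H_sim Simulated cap height (reduced units).
#' @param Rd_exp_nm Experimental base radius (nm).
#' @param Rd_sim Simulated base radius (reduced units).
#' @return A list of class `unit_map` with `sigma_height` and `sigma_lateral`
#'   (nm per reduced unit) and their ratio `lateral_to_height`.
#' @export
unit_map_from_heights <- function(H_exp_nm, H_sim, Rd_exp_nm, Rd_sim) {
  vals <- c(H_exp_nm, H_sim, Rd_exp_nm, Rd_sim)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive and finite")
  }
  sh <- H_exp_nm / H_sim
  sl <- Rd_exp_nm / Rd_sim
  structure(list(sigma_height = sh, sigma_lateral = sl,
                 lateral_to_height = sl / sh),
            class = "unit_map")
}

#' @export
print.unit_map <- function(x, ...) {
  cat(sprintf("unit map: sigma_height = %.3g nm, sigma_lateral = %.3g nm (ratio %.3g)\n",
              x$sigma_height, x$sigma_lateral, x$lateral_to_height))
  invisible(x)
}

#' A field of spherical-cap domains on a flat matrix
#'
#' Container describing a fabricated (or synthetic) microstructured surface:
#' a set of spherical caps plus the level of the surrounding matrix.
#'
#' @param R_sp,H Numeric vectors of per-domain sphere radii and cap heights.
#' @param centers Two-column matrix of lateral cap positions.
#' @param field_size Lateral extent `c(Lx, Ly)` of the observed field, same
#'   units as `centers`.
#' @param matrix_level Height of the surrounding matrix above the basal plane.
#' @return An object of class `cap_field`.
#' @export
cap_field <- function(R_sp, H, centers, field_size, matrix_level = 0) {
  centers <- as.matrix(centers)
  n <- length(R_sp)
  stopifnot(length(H) == n, nrow(centers) == n, ncol(centers) == 2,
            length(field_size) == 2, all(field_size > 0),
            matrix_level >= 0)
  if (n > 0 && any(H < 0 | H > 2 * R_sp)) stop("invalid cap in field")
  structure(list(R_sp = as.numeric(R_sp), H = as.numeric(H),
                 centers = centers, field_size = as.numeric(field_size),
                 matrix_level = as.numeric(matrix_level)),
            class = "cap_field")
}

#' @export
print.cap_field <- function(x, ...) {
  cat(sprintf("cap field: %d domains on %g x %g field, matrix level %g\n",
              length(x$H), x$field_size[1], x$field_size[2], x$matrix_level))
  invisible(x)
}

iqr_ <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)))

#' Structural statistics of a cap-decorated surface
#'
#' Computes the summary statistics conventionally tabulated for
#' microstructured thermoresponsive surfaces: the median cap height and its
#' interquartile range, the mean centre-to-centre distance to the four
#' nearest neighbouring domains, the domain number density, the median
#' projected area exposed above the matrix, and the exposed-coverage product
#' density x median area. Heights are assumed background-subtracted (basal
#' plane at zero). Median/IQR are used rather than mean/SD because cap height
#' distributions on these surfaces are broad and skewed.
#'
#' Domains whose four-nearest-neighbour search could reach past the field
#' border (centre closer to an edge than the 4th-neighbour distance) are
#' excluded from the neighbour-distance average, since a finite scan cannot
#' see neighbours outside it.
#'
#' @param field A [cap_field()]. Units are nm laterally and in height unless
#'   stated otherwise; densities are reported per square micron.
#' @param nm_per_unit Conversion from the field's lateral units to nm
#'   (1 if the field is already in nm).
#' @param h_air,h_below Optional matrix heights in air and below the LCST
#'   (nm); when both given, the swelling ratio is reported.
#' @return A list of class `surface_stats`.
#' @export
surface_stats <- function(field, nm_per_unit = 1, h_air = NULL, h_below = NULL) {
  stopifnot(inherits(field, "cap_field"))
  n <- length(field$H)
  if (n < 5) stop("insufficient data: need at least 5 domains for 4-nearest-neighbour statistics")

  cen_nm <- field$centers * nm_per_unit
  Lx <- field$field_size[1] * nm_per_unit
  Ly <- field$field_size[2] * nm_per_unit

  # mean distance to 4 nearest neighbours, per domain, then averaged;
  # finite-field convention: drop domains whose 4-NN ball crosses the border
  dmat <- as.matrix(stats::dist(cen_nm))
  diag(dmat) <- Inf
  d4 <- numeric(n)
  r4 <- numeric(n)
  for (i in seq_len(n)) {
    nn <- sort(dmat[i, ], partial = 4)[1:4]
    d4[i] <- mean(nn)
    r4[i] <- max(nn)
  }
  edge_dist <- pmin(cen_nm[, 1], Lx - cen_nm[, 1], cen_nm[, 2], Ly - cen_nm[, 2])
  keep <- edge_dist >= r4
  d_neighbor <- if (any(keep)) mean(d4[keep]) else NA_real_

  areas_nm2 <- vapply(seq_len(n), function(i) {
    exposed_area(spherical_cap(field$R_sp[i], field$H[i]), field$matrix_level)
  }, numeric(1))
  areas_um2 <- areas_nm2 / 1e6
  area_um2 <- Lx * Ly / 1e6
  rho <- n / area_um2
  A_med <- stats::median(areas_um2)

  sr <- if (!is.null(h_air) && !is.null(h_below)) swelling_ratio(h_below, h_air) else NA_real_

  structure(list(
    n_domains = n,
    H_median = stats::median(field$H),
    H_iqr = iqr_(field$H),
    h_matrix = field$matrix_level,
    h_air = if (is.null(h_air)) NA_real_ else h_air,
    h_below = if (is.null(h_below)) NA_real_ else h_below,
    swelling_ratio = sr,
    d_neighbor = d_neighbor,
    rho_domains = rho,
    A_exposed_median = A_med,
    A_exposed_iqr = iqr_(areas_um2),
    coverage_rhoA = rho * A_med
  ), class = "surface_stats")
}

#' @export
print.surface_stats <- function(x, ...) {
  cat("surface statistics (background-subtracted heights)\n")
  cat(sprintf("  domains: %d, density: %.2f um^-2\n", x$n_domains, x$rho_domains))
  cat(sprintf("  cap height median (IQR): %.1f (%.1f)\n", x$H_median, x$H_iqr))
  cat(sprintf("  4-NN centre distance: %.0f\n", x$d_neighbor))
  cat(sprintf("  exposed area median (IQR): %.3g (%.3g) um^2\n",
              x$A_exposed_median, x$A_exposed_iqr))
  cat(sprintf("  coverage rho x A: %.2f\n", x$coverage_rhoA))
  if (is.finite(x$swelling_ratio))
    cat(sprintf("  swelling ratio: %.1f\n", x$swelling_ratio))
  invisible(x)
}

#' Write surface statistics as a one-row table
#'
#' Serializes one or more `surface_stats` to CSV with the column layout used
#' in structural-characterization tables of microstructured surfaces.
#'
#' @param stats A `surface_stats` or list of them.
#' @param path Output CSV path.
#' @param sample_names Optional row labels.
#' @return The data frame written, invisibly.
#' @export
write_surface_stats_csv <- function(stats, path, sample_names = NULL) {
  if (inherits(stats, "surface_stats")) stats <- list(stats)
  rows <- lapply(stats, function(s) {
    data.frame(
      Sample = NA_character_,
      H_PGMA = sprintf("%.1f (%.1f)", s$H_median, s$H_iqr),
      `h_PNIPAM air` = s$h_air,
      `h_PNIPAM below LCST` = s$h_below,
      `Swelling ratio` = s$swelling_ratio,
      d = s$d_neighbor,
      rho = s$rho_domains,
      A = s$A_exposed_median,
      rhoxA = s$coverage_rhoA,
      check.names = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df$Sample <- if (is.null(sample_names)) sprintf("S%d", seq_len(nrow(df))) else sample_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
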