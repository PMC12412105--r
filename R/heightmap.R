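#' Generator specification for synthetic SPM-like height maps
#'
#' Describes the surface to emulate: spherical-cap domains with a broad
#' (lognormal) height distribution given by median and interquartile range,
#' a near-uniform matrix level, and basal roughness. Defaults correspond to a
#' mid-range fabricated surface (median cap height ~40 nm, matrix ~19 nm,
#' density ~6.5 domains per square micron).
#'
#' @param density Target domain density (per square micron); ignored when
#'   `n_domains` is given.
#' @param n_domains Optional explicit domain count.
#' @param H_median,H_iqr Median and IQR of the cap height distribution (nm),
#'   measured from the basal plane.
#' @param Rsp_median,Rsp_iqr Median and IQR of the cap sphere radius (nm).
#'   Together with the height distribution this sets the base-disk radius
#'   `sqrt(H (2 R_sp - H))`; the implied base-disk coverage
#'   `density * pi * r_base^2` must stay clearly below the disc jamming
#'   limit (~0.55) or sequential placement fails.
#' @param matrix_level Matrix surface height above the basal plane (nm); 0
#'   for a matrix-free surface.
#' @param matrix_sd Standard deviation of the matrix surface height (nm).
#' @param h_bg Basal roughness amplitude (nm), typically 3-7; must lie in
#'   `[0, 10]`.
#' @param field_size Scan side length (microns).
#' @param npix Pixels per side, between 256 and 1024.
#' @return A list of class `heightmap_spec`.
#' @export
heightmap_spec <- function(density = 6.5, n_domains = NULL,
                           H_median = 41.5, H_iqr = 7.4,
                           Rsp_median = 250, Rsp_iqr = 40,
                           matrix_level = 19.4, matrix_sd = 1.8,
                           h_bg = 5, field_size = 5, npix = 512) {
  stopifnot(H_median > 0, H_iqr >= 0, Rsp_median > 0, Rsp_iqr >= 0,
            matrix_level >= 0, matrix_sd >= 0, field_size > 0,
            npix >= 256, npix <= 1024)
  if (h_bg < 0 || h_bg > 10) stop("h_bg must lie in [0, 10] nm")
  if (is.null(n_domains)) {
    stopifnot(density >= 0)
    n_domains <- round(density * field_size^2)
  }
  structure(list(n_domains = n_domains, H_median = H_median, H_iqr = H_iqr,
                 Rsp_median = Rsp_median, Rsp_iqr = Rsp_iqr,
                 matrix_level = matrix_level, matrix_sd = matrix_sd,
                 h_bg = h_bg, field_size = field_size, npix = npix),
            class = "heightmap_spec")
}

# sdlog of a lognormal with given median and IQR
lognorm_sdlog <- function(median, iqr) {
  if (iqr <= 0) return(0)
  q <- stats::qnorm(0.75)
  f <- function(s) median * (exp(q * s) - exp(-q * s)) - iqr
  stats::uniroot(f, c(1e-8, 5))$root
}

rlognorm_med <- function(n, median, iqr) {
  s <- lognorm_sdlog(median, iqr)
  if (s == 0) rep(median, n) else stats::rlnorm(n, meanlog = log(median), sdlog = s)
}

#' Generate a synthetic SPM-like height map
#'
#' Places spherical caps by random sequential adsorption (no base-disk
#' overlap, finite non-periodic field), then rasterizes the surface: each
#' pixel height is the maximum of the basal roughness, the matrix surface
#' and any cap surface covering it. The ground-truth [cap_field()] is
#' returned alongside the raster, so analysis results can be checked against
#' known parameters.
#'
#' @param spec A [heightmap_spec()].
#' @param seed Integer seed; a fixed seed gives a bit-identical map.
#' @param max_attempts Total placement attempt budget, per domain.
#' @return A list of class `height_map` with elements `grid` (matrix, nm;
#'   rows indexed by y, columns by x, origin at the map corner),
#'   `pixel_size` (nm), `field_size` (micron), `metadata`, and
#'   `truth` (the ground-truth `cap_field`).
#' @export
generate_heightmap <- function(spec, seed = 1, max_attempts = 5000) {
  stopifnot(inherits(spec, "heightmap_spec"))
  set.seed(seed)
  L <- spec$field_size * 1000  # nm
  n <- spec$n_domains
  px <- L / spec$npix

  H <- numeric(0); R <- numeric(0); cx <- numeric(0); cy <- numeric(0)
  if (n > 0) {
    Hs <- rlognorm_med(n, spec$H_median, spec$H_iqr)
    Rs <- rlognorm_med(n, spec$Rsp_median, spec$Rsp_iqr)
    Hs <- pmin(Hs, 2 * Rs)
    rb <- sqrt(Hs * (2 * Rs - Hs))
    placed <- 0L
    attempts <- 0L
    budget <- max_attempts * n
    while (placed < n && attempts < budget) {
      attempts <- attempts + 1L
      x <- stats::runif(1, 0, L); y <- stats::runif(1, 0, L)
      i <- placed + 1L
      ok <- placed == 0L ||
        all((cx - x)^2 + (cy - y)^2 >= (rb[seq_len(placed)] + rb[i])^2)
      if (ok) {
        cx <- c(cx, x); cy <- c(cy, y)
        H <- c(H, Hs[i]); R <- c(R, Rs[i])
        placed <- i
      }
    }
    if (placed < n) {
      stop(sprintf("placement failure: %d of %d domains placed; density unreachable without overlap",
                   placed, n))
    }
  }

  # rasterize: pixel centres at (i - 0.5) * px
  xs <- (seq_len(spec$npix) - 0.5) * px
  grid <- matrix(pmax(0, stats::rnorm(spec$npix^2, mean = spec$h_bg / 2,
                                      sd = spec$h_bg / 4)),
                 spec$npix, spec$npix)
  if (spec$matrix_level > 0) {
    mat <- spec$matrix_level + stats::rnorm(spec$npix^2, sd = spec$matrix_sd)
    grid <- pmax(grid, matrix(mat, spec$npix, spec$npix))
  }
  for (i in seq_along(H)) {
    rb_i <- sqrt(H[i] * (2 * R[i] - H[i]))
    ix <- which(abs(xs - cx[i]) <= rb_i)
    iy <- which(abs(xs - cy[i]) <= rb_i)
    if (!length(ix) || !length(iy)) next
    dx <- xs[ix] - cx[i]; dy <- xs[iy] - cy[i]
    r2 <- outer(dy^2, dx^2, `+`)
    zc <- H[i] - R[i] + sqrt(pmax(R[i]^2 - r2, 0))
    zc[r2 > rb_i^2] <- 0
    sub <- grid[iy, ix, drop = FALSE]
    grid[iy, ix] <- pmax(sub, zc)
  }

  truth <- cap_field(R, H, cbind(cx, cy), field_size = c(L, L),
                     matrix_level = spec$matrix_level)
  structure(list(grid = grid, pixel_size = px, field_size = spec$field_size,
                 metadata = c(unclass(spec), list(seed = seed)),
                 truth = truth),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height map: %d x %d pixels, %.1f nm/px, %g x %g um field\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              x$field_size, x$field_size))
  invisible(x)
}

#' Analyze a height map into a spherical-cap field
#'
#' Mirrors the slicing procedure used to characterize fabricated surfaces:
#' the background is estimated as a low quantile of the heights and
#' subtracted; pixels above a detection threshold are grouped into
#' 8-connected components; per domain, the maximum height gives the cap
#' height `H` and the pixel areas above each slice level give
#' equivalent-disc radii `R_d(h) = sqrt(area / pi)`, from which the sphere
#' radius `R_sp` is estimated by least squares on the cap relation
#' `r^2(h) = R_sp^2 - (R_sp - H + h)^2` across slices. Domains touching the
#' map border are excluded (partial caps bias `H` and `R_sp`).
#'
#' @param map A [generate_heightmap()] result or an object read by
#'   [read_heightmap()].
#' @param slice_levels Optional slice heights (nm, background-subtracted).
#'   Default: per domain, 5 evenly spaced levels between the detection
#'   threshold and 90 percent of the domain's maximum height. At least 2
#'   levels are required.
#' @param background_quantile Quantile used as the zero level (default 0.1).
#' @param threshold Detection threshold above background (nm). Default: the
#'   estimated matrix level (median of background-subtracted heights) plus
#'   `min_prominence`.
#' @param min_prominence Minimum cap prominence above the matrix (nm).
#' @param min_pixels Minimum component size in pixels.
#' @param n_slices Number of slice levels when `slice_levels` is NULL.
#' @return A [cap_field()] (centres and field size in nm) with attribute
#'   `"domains"`, a per-domain data frame (centres, `H`, `R_sp`, per-slice
#'   radii consistency), and attribute `"background"`, the subtracted level.
#'   With no domains found, an empty field is returned with a warning.
#' @export
analyze_heightmap <- function(map, slice_levels = NULL,
                              background_quantile = 0.1,
                              threshold = NULL, min_prominence = 5,
                              min_pixels = 9, n_slices = 5) {
  stopifnot(inherits(map, "height_map"))
  g <- map$grid
  bg <- stats::quantile(g, background_quantile, names = FALSE)
  g <- g - bg
  matrix_est <- stats::median(g)
  if (is.null(threshold)) threshold <- matrix_est + min_prominence
  if (!is.null(slice_levels)) {
    slice_levels <- sort(slice_levels)
    if (length(slice_levels) < 2) stop("need at least 2 slice levels")
    threshold <- slice_levels[1]
  }

  lab <- .label_components(g > threshold)
  nlab <- max(lab)
  if (nlab == 0) {
    warning("no domains found above the matrix level")
    out <- cap_field(numeric(0), numeric(0), matrix(0, 0, 2),
                     field_size = rep(map$field_size * 1000, 2),
                     matrix_level = max(matrix_est, 0))
    attr(out, "domains") <- data.frame()
    attr(out, "background") <- bg
    return(out)
  }

  px <- map$pixel_size
  npr <- nrow(g); npc <- ncol(g)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  heights <- g[lab > 0]
  rows <- split(seq_along(comp), comp)

  res <- lapply(rows, function(ii) {
    ri <- idx[ii, 1]; ci <- idx[ii, 2]
    if (any(ri == 1 | ri == npr | ci == 1 | ci == npc)) return(NULL)
    if (length(ii) < min_pixels) return(NULL)
    hv <- heights[ii]
    Hmax <- max(hv)
    lv <- if (is.null(slice_levels)) {
      seq(threshold, 0.9 * Hmax, length.out = n_slices)
    } else {
      slice_levels[slice_levels < Hmax]
    }
    lv <- lv[lv < Hmax]
    if (length(lv) < 2) return(NULL)
    r <- vapply(lv, function(h) sqrt(sum(hv >= h) * px^2 / pi), numeric(1))
    d <- Hmax - lv
    Rsp <- sum((r^2 + d^2) * d) / (2 * sum(d^2))
    # consistency: per-slice Rsp from single-slice inversion
    Rsp_k <- (r^2 + d^2) / (2 * d)
    peak <- ii[which.max(hv)]
    data.frame(x = (idx[peak, 2] - 0.5) * px, y = (idx[peak, 1] - 0.5) * px,
               H = Hmax, R_sp = max(Rsp, Hmax / 2), n_pixels = length(ii),
               Rsp_spread = (max(Rsp_k) - min(Rsp_k)) / Rsp)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) {
    warning("no interior domains found above the matrix level")
    out <- cap_field(numeric(0), numeric(0), matrix(0, 0, 2),
                     field_size = rep(map$field_size * 1000, 2),
                     matrix_level = max(matrix_est, 0))
    attr(out, "domains") <- data.frame()
    attr(out, "background") <- bg
    return(out)
  }
  out <- cap_field(res$R_sp, res$H, cbind(res$x, res$y),
                   field_size = rep(map$field_size * 1000, 2),
                   matrix_level = max(matrix_est, 0))
  attr(out, "domains") <- res
  attr(out, "background") <- bg
  out
}

#' Write / read a height map as plain text
#'
#' The raster is stored as whitespace-separated rows of nm values at full
#' double precision, with a JSON sidecar holding the pixel size, field size,
#' seed and generator parameters; write followed by read restores the map
#' bit-exactly.
#'
#' @param map A `height_map`.
#' @param prefix Output path prefix; writes `<prefix>.txt` and
#'   `<prefix>.json`.
#' @return `write_heightmap`: the prefix, invisibly. `read_heightmap`: a
#'   `height_map` (without ground truth).
#' @export
write_heightmap <- function(map, prefix) {
  stopifnot(inherits(map, "height_map"))
  txt <- apply(map$grid, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, paste0(prefix, ".txt"))
  meta <- map$metadata
  meta$pixel_size <- map$pixel_size
  meta$field_size <- map$field_size
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(prefix, ".txt"))
  grid <- do.call(rbind, lapply(strsplit(lines, " +"), as.numeric))
  structure(list(grid = grid, pixel_size = meta$pixel_size,
                 field_size = meta$field_size, metadata = meta,
                 truth = NULL),
            class = "height_map")
}
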