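test_that("zero-density spec yields a flat matrix-plus-roughness map", {
  spec <- heightmap_spec(density = 0, matrix_level = 19.4, h_bg = 5,
                         field_size = 2, npix = 256)
  hm <- generate_heightmap(spec, seed = 3)
  expect_equal(dim(hm$grid), c(256, 256))
  expect_true(all(is.finite(hm$grid)))
  expect_equal(length(hm$truth$H), 0)
  expect_lt(max(hm$grid), 19.4 + 6 * spec$matrix_sd + 1)
})

test_that("generation is deterministic for a fixed seed", {
  spec <- heightmap_spec(density = 4, field_size = 3, npix = 256)
  a <- generate_heightmap(spec, seed = 11)
  b <- generate_heightmap(spec, seed = 11)
  expect_identical(a$grid, b$grid)
  expect_identical(a$truth$centers, b$truth$centers)
  c <- generate_heightmap(spec, seed = 12)
  expect_false(identical(a$grid, c$grid))
})

test_that("a noise-free single ideal cap is recovered by slicing", {
  # one cap, no matrix, no roughness: fit must recover R_sp within 2%
  spec <- heightmap_spec(n_domains = 1, H_median = 200, H_iqr = 0,
                         Rsp_median = 1000, Rsp_iqr = 0,
                         matrix_level = 0, matrix_sd = 0, h_bg = 0,
                         field_size = 3, npix = 512)
  hm <- generate_heightmap(spec, seed = 5)
  fld <- analyze_heightmap(hm, min_prominence = 10)
  expect_equal(length(fld$H), 1)
  expect_equal(fld$H, 200, tolerance = 0.02)
  expect_equal(fld$R_sp, 1000, tolerance = 0.02)
  # slice consistency: single-slice inversions agree across slices
  expect_lt(attr(fld, "domains")$Rsp_spread, 0.02)
})

test_that("pure-noise maps contain no domains", {
  spec <- heightmap_spec(density = 0, matrix_level = 0, h_bg = 5,
                         field_size = 2, npix = 256)
  hm <- generate_heightmap(spec, seed = 9)
  expect_warning(fld <- analyze_heightmap(hm, min_prominence = 8),
                 "no domains")
  expect_equal(length(fld$H), 0)
})

test_that("generate -> analyze round trip recovers cap parameters", {
  # noise-free matrix-free field: H within one pixel-height quantum,
  # R_sp within 5%
  spec <- heightmap_spec(density = 2, H_median = 150, H_iqr = 30,
                         Rsp_median = 250, Rsp_iqr = 0,
                         matrix_level = 0, matrix_sd = 0, h_bg = 0,
                         field_size = 4, npix = 512)
  hm <- generate_heightmap(spec, seed = 21)
  fld <- analyze_heightmap(hm, min_prominence = 10)
  truth <- hm$truth

  expect_gt(length(fld$H), 0.5 * length(truth$H))
  # match analyzed domains to ground truth by centre distance
  for (i in seq_along(fld$H)) {
    d2 <- (truth$centers[, 1] - fld$centers[i, 1])^2 +
      (truth$centers[, 2] - fld$centers[i, 2])^2
    j <- which.min(d2)
    expect_lt(sqrt(d2[j]), 3 * hm$pixel_size)
    expect_equal(fld$H[i], truth$H[j], tolerance = 0.02)
    expect_equal(fld$R_sp[i], truth$R_sp[j], tolerance = 0.05)
  }
})

test_that("analyzed density matches a mid-density generator spec within 10%", {
  # emulates a fabricated mid-range surface: median cap height 41.5 nm,
  # matrix 19.4 nm, 6.5 domains per square micron
  spec <- heightmap_spec(density = 6.5, H_median = 41.5, H_iqr = 7.4,
                         Rsp_median = 250, Rsp_iqr = 40,
                         matrix_level = 19.4, matrix_sd = 1.8, h_bg = 4,
                         field_size = 4, npix = 512)
  hm <- generate_heightmap(spec, seed = 31)
  fld <- analyze_heightmap(hm)
  # interior-domain density; border exclusion removes ~ perimeter share
  area_um2 <- (hm$field_size)^2
  rho <- length(fld$H) / area_um2
  interior_truth <- sum(
    hm$truth$centers[, 1] > 500 & hm$truth$centers[, 1] < 3500 &
    hm$truth$centers[, 2] > 500 & hm$truth$centers[, 2] < 3500)
  expect_equal(rho, 6.5, tolerance = 0.25)
  st <- surface_stats(fld)
  # with the basal plane hidden under the matrix, the analyzer's zero level
  # is the matrix surface: recovered heights are matrix-relative, biased by
  # less than the roughness amplitude
  expect_lt(abs(st$H_median - (41.5 - 19.4)), spec$h_bg)
})

test_that("roughness robustness: median height bias stays below h_bg", {
  spec <- heightmap_spec(density = 2, H_median = 100, H_iqr = 20,
                         Rsp_median = 300, Rsp_iqr = 0,
                         matrix_level = 0, matrix_sd = 0, h_bg = 5,
                         field_size = 4, npix = 512)
  hm <- generate_heightmap(spec, seed = 41)
  fld <- analyze_heightmap(hm, min_prominence = 15)
  truth_med <- median(hm$truth$H)
  expect_lt(abs(median(fld$H) - truth_med), 5)
})

test_that("component labeling is translation invariant away from edges", {
  spec <- heightmap_spec(density = 1.5, H_median = 100, H_iqr = 0,
                         Rsp_median = 300, Rsp_iqr = 0,
                         matrix_level = 0, matrix_sd = 0, h_bg = 0,
                         field_size = 3, npix = 256)
  hm <- generate_heightmap(spec, seed = 51)
  shift <- 7
  hm2 <- hm
  n <- nrow(hm$grid)
  hm2$grid <- hm$grid[c((shift + 1):n, 1:shift), ]
  f1 <- analyze_heightmap(hm, min_prominence = 10)
  f2 <- analyze_heightmap(hm2, min_prominence = 10)
  # domains not crossing the wrap edge keep identical H sets
  h1 <- sort(f1$H)
  h2 <- sort(f2$H)
  common <- intersect(round(h1, 6), round(h2, 6))
  expect_gte(length(common), min(length(h1), length(h2)) - 1)
})

test_that("height-map text round trip is bit exact", {
  spec <- heightmap_spec(density = 3, field_size = 2, npix = 256)
  hm <- generate_heightmap(spec, seed = 61)
  prefix <- tempfile()
  write_heightmap(hm, prefix)
  back <- read_heightmap(prefix)
  expect_identical(back$grid, unname(hm$grid))
  expect_equal(back$pixel_size, hm$pixel_size)
  expect_equal(back$metadata$seed, 61)
  unlink(paste0(prefix, c(".txt", ".json")))
})
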