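test_that("particle analysis counts 8-connected components and total area", {
  empty <- matrix(FALSE, 8, 8)
  pa <- particle_analysis(empty)
  expect_identical(pa$area_px, 0L)
  expect_identical(pa$perimeter_px, 0)
  expect_identical(pa$particle_count, 0L)
  two <- matrix(FALSE, 30, 30)
  two[2:11, 2:11] <- TRUE
  two[16:25, 16:25] <- TRUE
  pa2 <- particle_analysis(two)
  expect_identical(pa2$area_px, 200L)
  expect_identical(pa2$particle_count, 2L)
  expect_equal(pa2$perimeter_px, 2 * 36)
  # diagonally touching pixels form one particle
  diag2 <- matrix(FALSE, 5, 5); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_identical(particle_analysis(diag2)$particle_count, 1L)
  # size filter
  mixed <- matrix(FALSE, 10, 10)
  mixed[2:4, 2:4] <- TRUE
  mixed[8, 8] <- TRUE
  paf <- particle_analysis(mixed, min_particle_px = 2)
  expect_identical(paf$area_px, 9L)
  expect_identical(paf$particle_count, 1L)
})

test_that("contour perimeter matches the border-pixel-center polygon convention", {
  block <- function(w, h, pad = 2) {
    m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
    m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
    m
  }
  for (wh in list(c(10, 10), c(3, 7), c(1, 6), c(2, 2), c(12, 4)))
    expect_equal(mask_perimeter(block(wh[1], wh[2])),
                 2 * (wh[1] - 1) + 2 * (wh[2] - 1))
  # isolated pixel: degenerate contour
  expect_equal(mask_perimeter(block(1, 1)), 0)
  # annulus: outer 10x10 ring plus the inner contour around a 4x4 hole,
  # which runs 3 straight steps per side and cuts the corners diagonally
  ann <- block(10, 10)
  ann[6:9, 6:9] <- FALSE
  expect_equal(mask_perimeter(ann), 36 + 12 + 4 * sqrt(2))
  # invariance under transposition and flips
  set.seed(8)
  m <- matrix(runif(20 * 20) > 0.6, 20, 20)
  p <- mask_perimeter(m)
  expect_equal(mask_perimeter(t(m)), p)
  expect_equal(mask_perimeter(m[20:1, ]), p)
  expect_equal(mask_perimeter(m[, 20:1]), p)
})

test_that("perimeter agrees with an independent boundary-tracing oracle", {
  for (seed in 1:10) {
    m <- random_blob(24, seed)
    if (!any(m)) next
    expect_equal(mask_perimeter(m), ocontour_perimeter(m),
                 info = paste("blob seed", seed))
  }
})

test_that("box counts match analytic values and brute-force enumeration", {
  full <- matrix(TRUE, 64, 64)
  bc <- box_counts(full, c(1, 2, 4, 8, 16, 32))
  expect_identical(bc$n_boxes, as.integer((64 / c(1, 2, 4, 8, 16, 32))^2))
  one <- matrix(FALSE, 64, 64); one[10, 17] <- TRUE
  expect_true(all(box_counts(one, c(1, 2, 4, 8, 16, 32))$n_boxes == 1L))
  line <- matrix(FALSE, 64, 64); line[5, ] <- TRUE
  expect_identical(box_counts(line, c(1, 2, 4, 8, 16, 32))$n_boxes,
                   as.integer(64 / c(1, 2, 4, 8, 16, 32)))
  # brute-force oracle over random small masks
  set.seed(31)
  for (k in 1:200) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    m <- matrix(runif(h * w) > runif(1, 0.3, 0.9), h, w)
    for (d in unique(c(1, 2, 3, min(h, w)))) {
      expect_identical(box_counts(m, d)$n_boxes, brute_force_box_count(m, d),
                       info = sprintf("mask %d, delta %d", k, d))
    }
  }
  expect_error(box_counts(matrix(TRUE, 4, 4), 5), "exceed")
  expect_error(box_counts(matrix(TRUE, 4, 4), 0), "positive")
})

test_that("adding foreground pixels never decreases area or box counts", {
  set.seed(12)
  m <- matrix(runif(100) > 0.7, 10, 10)
  grown <- m
  grown[sample(which(!m), 5)] <- TRUE
  expect_gte(sum(grown), sum(m))
  for (d in c(1, 2, 5))
    expect_gte(box_counts(grown, d)$n_boxes, box_counts(m, d)$n_boxes)
})

test_that("fractal dimension recovers exact dimensions of plane, line and point", {
  sizes <- c(1, 2, 4, 8, 16, 32)
  full <- fractal_dimension(box_counts(matrix(TRUE, 64, 64), sizes))
  expect_equal(full$D_B, 2, tolerance = 1e-9)
  expect_equal(full$r_squared, 1, tolerance = 1e-9)
  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  lf <- fractal_dimension(box_counts(line, sizes))
  expect_equal(lf$D_B, 1, tolerance = 1e-9)
  expect_equal(lf$r_squared, 1, tolerance = 1e-9)
  pt <- matrix(FALSE, 64, 64); pt[7, 9] <- TRUE
  expect_equal(fractal_dimension(box_counts(pt, sizes))$D_B, 0,
               tolerance = 1e-9)
  # solid rectangles give slope exactly 2 when the box sides divide both dims
  for (dims in list(c(16, 48), c(32, 32), c(8, 24)))
    expect_equal(fractal_dimension(
      box_counts(matrix(TRUE, dims[1], dims[2]), c(1, 2, 4, 8)))$D_B,
      2, tolerance = 1e-9)
  # undefined estimates are flagged, not guessed
  und <- fractal_dimension(data.frame(delta = c(2, 4), n_boxes = c(0, 0)))
  expect_false(und$valid)
  expect_true(is.na(und$D_B))
  expect_false(fractal_dimension(data.frame(delta = 4, n_boxes = 3))$valid)
})

test_that("slice morphometrics composes the per-slice measurements", {
  empties <- replicate(3, matrix(FALSE, 16, 16), simplify = FALSE)
  tab <- slice_morphometrics(empties)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$area_px == 0))
  expect_true(all(is.na(tab$D_B)))
  filled <- matrix(TRUE, 16, 16)
  mix <- list(matrix(FALSE, 16, 16), filled, matrix(FALSE, 16, 16))
  tab2 <- slice_morphometrics(mix)
  pa <- particle_analysis(filled)
  fr <- fractal_dimension(box_counts(filled, attr(tab2, "box_sizes")))
  expect_identical(tab2$area_px[2], pa$area_px)
  expect_equal(tab2$perimeter_px[2], pa$perimeter_px)
  expect_equal(tab2$D_B[2], fr$D_B)
  # default box schedule: powers of 2 up to a quarter of the slice side
  expect_identical(attr(tab2, "box_sizes"), c(2L, 4L))
  # synthetic compact stack peaks in the middle of the depth profile
  g <- generate_stack(synthetic_stack_spec("compact", seed = 3))
  prof <- slice_morphometrics(g$ground_truth$masks)
  expect_identical(which.max(prof$area_px), 5L)
})
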