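test_that("stack generation is deterministic, also after TIFF encoding", {
  sp <- synthetic_stack_spec("compact", seed = 42)
  a <- generate_stack(sp)
  b <- generate_stack(sp)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$ground_truth$masks, b$ground_truth$masks)
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  write_stack(a$stack, f1)
  write_stack(b$stack, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  rt <- read_stack(f1)
  expect_identical(rt$voxels, a$stack$voxels)
})

test_that("invalid stack specs are rejected with informative messages", {
  expect_error(synthetic_stack_spec("compact", n_slices = 2), "3 slices")
  expect_error(synthetic_stack_spec("compact", peak_coverage = 0), "peak_coverage")
  expect_error(synthetic_stack_spec("compact", peak_coverage = 1.2), "peak_coverage")
  expect_error(synthetic_stack_spec("compact", profile_width = 0), "profile_width")
  expect_error(synthetic_stack_spec("compact", width = 4), "dimensions")
})

test_that("realized per-slice coverage follows the Gaussian depth profile", {
  for (arch in c("compact", "porous")) for (seed in c(5, 6)) {
    sp <- synthetic_stack_spec(arch, n_slices = 9, width = 64, height = 64,
                               peak_coverage = 0.5, seed = seed)
    g <- generate_stack(sp)
    gt <- g$ground_truth
    # middle slice hits the peak
    expect_lt(abs(gt$realized_coverage[5] - 0.5), 0.05)
    # every slice with an appreciable target tracks it closely
    appr <- gt$target_coverage >= 0.05
    expect_true(all(abs(gt$realized_coverage - gt$target_coverage)[appr] < 0.05))
    # masks really realize the recorded coverage
    expect_equal(vapply(gt$masks, mean, numeric(1)), gt$realized_coverage)
    # thresholding the rendered intensities recovers the masks
    m5 <- threshold_mask(to_8bit(g$stack$voxels[, , 5]), "otsu")
    expect_lt(mean(m5$pixels != gt$masks[[5]]), 0.01)
  }
})

test_that("compact patterns have a larger linear-measure ratio than porous at matched coverage", {
  mean_L <- function(arch, seed) {
    sp <- synthetic_stack_spec(arch, n_slices = 3, width = 64, height = 64,
                               peak_coverage = 0.3, profile_width = 100,
                               seed = seed)
    mean(triples_from_masks(generate_stack(sp)$ground_truth$masks)$L_ratio)
  }
  Lc <- vapply(1:20, function(s) mean_L("compact", s), numeric(1))
  Lp <- vapply(1:20, function(s) mean_L("porous", s), numeric(1))
  expect_gt(mean(Lc), mean(Lp))
  # empirical first-order stochastic dominance
  expect_true(all(sort(Lc) > sort(Lp)))
})

test_that("tessera photographs hit the requested colonized fraction", {
  p0 <- generate_tessera_photo(0, seed = 3)
  expect_identical(sum(p0$ground_truth$mask), 0L)
  p1 <- generate_tessera_photo(1, seed = 3)
  expect_true(all(p1$ground_truth$mask))
  p3 <- generate_tessera_photo(0.3, seed = 3)
  expect_gte(p3$ground_truth$coverage, 0.28)
  expect_lte(p3$ground_truth$coverage, 0.32)
  expect_error(generate_tessera_photo(-0.1), "coverage")
  expect_error(generate_tessera_photo(1.5), "coverage")
})

test_that("roughness profiles are zero-mean, seeded and length-1600 by default", {
  expect_identical(generate_roughness_profile(amplitude = 0), numeric(1600))
  z <- generate_roughness_profile(seed = 9)
  expect_length(z, 1600)
  expect_lt(abs(mean(z)), 1e-10)
  z2 <- generate_roughness_profile(seed = 10)
  expect_false(identical(z, z2))
  expect_equal(sd(z), sd(z2), tolerance = 1e-6)  # same amplitude scale
  expect_identical(z, generate_roughness_profile(seed = 9))
  expect_error(generate_roughness_profile(n = 1), "2 points")
})

test_that("strain suites follow the study layout and validate their inputs", {
  expect_error(generate_strain_suite(0, character(0)), "at least one")
  expect_error(generate_strain_suite(2, "compact"), "length")
  expect_error(generate_strain_suite(1, "fluffy"), "compact")
  suite <- generate_strain_suite(2, c("compact", "porous"), seed = 4,
                                 width = 32, height = 32, n_slices = 5)
  expect_s3_class(suite, "strain_suite")
  expect_length(suite, 2)
  for (s in suite) {
    expect_length(s$stacks, 3)  # three sampling points per tessera
    pts <- vapply(s$stacks, function(k) k$stack$sampling_point, integer(1))
    expect_identical(pts, 1:3)
    # replicates share the coverage profile but are not identical fields
    expect_false(identical(s$stacks[[1]]$stack$voxels,
                           s$stacks[[2]]$stack$voxels))
    expect_equal(s$stacks[[1]]$ground_truth$target_coverage,
                 s$stacks[[2]]$ground_truth$target_coverage)
  }
  # photo coverage tracks the stack's projected coverage
  for (s in suite) {
    mip_cov <- max(s$stacks[[1]]$ground_truth$realized_coverage)
    expect_lt(abs(s$photo_coverage - mip_cov), 0.1)
  }
})
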