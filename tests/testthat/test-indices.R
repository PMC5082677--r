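test_that("coverage fraction is A/a with unit-mismatch protection", {
  expect_identical(coverage_fraction(2500, 10000), 0.25)
  expect_identical(coverage_fraction(123, 123), 1)
  expect_identical(coverage_fraction(0, 99), 0)
  expect_error(coverage_fraction(11, 10), "units")
  expect_error(coverage_fraction(1, 0), "positive")
  expect_error(coverage_fraction(-1, 10), "non-negative")
})

test_that("linear-measure ratio normalizes area/perimeter by sqrt(a)/4", {
  # full square slice with the ideal boundary length 4*sqrt(a)
  expect_equal(as.numeric(linear_ratio(10000, 400, 10000)), 1)
  # 50x50 solid square (ideal boundary 200) in a 100x100 slice
  expect_equal(as.numeric(linear_ratio(2500, 200, 10000)), 0.5)
  expect_identical(as.numeric(linear_ratio(0, 0, 100)), 0)
  # clamping keeps the raw value available
  lr <- linear_ratio(10000, 396, 10000)  # contour-convention full slice
  expect_identical(as.numeric(lr), 1)
  expect_gt(attr(lr, "raw"), 1)
  expect_error(linear_ratio(5, 0, 100), "zero perimeter")
  expect_warning(cl <- linear_ratio(5, 0, 100, strict = FALSE), "clamped")
  expect_identical(as.numeric(cl), 1)
})

test_that("normalized fractal dimension maps [0, 2] onto [0, 1]", {
  expect_identical(normalized_fractal(2), 1)
  expect_identical(normalized_fractal(1), 0.5)
  expect_identical(normalized_fractal(2.3), 1)  # raw slopes are clamped first
  expect_identical(normalized_fractal(-0.1), 0)
  # end-to-end: a fully covered slice has normalized dimension exactly 1
  fd <- fractal_dimension(box_counts(matrix(TRUE, 64, 64), c(1, 2, 4, 8, 16, 32)))
  expect_equal(normalized_fractal(fd$D_B), 1, tolerance = 1e-9)
})

test_that("Gaussian ordinal weights match the hand-computed scheme", {
  expect_identical(gaussian_weights(1)$w, 1)
  expect_equal(gaussian_weights(2)$w, c(0.5, 0.5))
  w3 <- gaussian_weights(3)
  expect_equal(w3$mu_N, 2)
  expect_equal(w3$sigma_N, sqrt(2 / 3))
  # hand evaluation: w1 = w3 = exp(-3/4) / (1 + 2 exp(-3/4))
  e <- exp(-3 / 4)
  expect_equal(w3$w, c(e, 1, e) / (1 + 2 * e), tolerance = 1e-12)
  expect_equal(round(w3$w, 4), c(0.2429, 0.5142, 0.2429))
  expect_error(gaussian_weights(0), "positive")
  # the printed-form exponent is available but differs
  expect_false(isTRUE(all.equal(gaussian_weights(5)$w,
                                gaussian_weights(5, literal_sigma = TRUE)$w)))
})

test_that("weights sum to one and are symmetric at lambda = 0.5", {
  for (N in c(1, 2, 3, 7, 10, 123, 10000)) {
    w <- gaussian_weights(N)$w
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_equal(w, rev(w), tolerance = 1e-12)
  }
  # lambda shifts the emphasized ordinal position
  w_low <- gaussian_weights(9, lambda = 0.2)$w
  expect_identical(which.max(w_low), 2L)  # mu = 0.2 * 10 = 2
})

test_that("aggregation operators behave and are ordered", {
  s <- c(0.1, 0.3, 0.2)
  expect_identical(aggregate_series(s, "max"), 0.3)
  expect_equal(aggregate_series(s, "mean"), 0.2)
  w3 <- gaussian_weights(3)
  expect_equal(aggregate_series(s, "weighted", w3),
               sum(w3$w * s), tolerance = 1e-12)
  expect_equal(round(aggregate_series(s, "weighted", w3), 4), 0.2271)
  # a constant series is a fixed point of every operator
  const <- rep(0.42, 6)
  for (op in c("max", "mean", "weighted"))
    expect_equal(aggregate_series(const, op, gaussian_weights(6)), 0.42)
  expect_error(aggregate_series(s, "weighted", gaussian_weights(4)), "length")
  expect_error(aggregate_series(numeric(0), "max"), "empty")
  # ordering: mean and weighted never exceed max on nonnegative series
  set.seed(2)
  for (k in 1:25) {
    x <- runif(sample(2:12, 1))
    w <- gaussian_weights(length(x), lambda = runif(1, 0.1, 0.9))
    expect_lte(aggregate_series(x, "mean"), aggregate_series(x, "max"))
    expect_lte(aggregate_series(x, "weighted", w), aggregate_series(x, "max"))
  }
})

test_that("cross-strain rescaling maps each column maximum to exactly 1", {
  tab <- data.frame(strain = rep(c("a", "b", "c"), each = 1),
                    quantity = "A", operator = "max",
                    value = c(0.2, 0.4, 0.8))
  r <- rescale_across_strains(tab)
  expect_equal(r$value, c(0.25, 0.5, 1.0))
  # idempotence
  expect_equal(rescale_across_strains(r)$value, r$value)
  # single strain degenerates to all ones
  one <- data.frame(strain = "a", quantity = c("A", "L", "D"),
                    operator = "max", value = c(0.3, 0.1, 0.9))
  expect_true(all(rescale_across_strains(one)$value == 1))
  zero <- data.frame(strain = c("a", "b"), quantity = "A", operator = "max",
                     value = c(0, 0))
  expect_error(rescale_across_strains(zero), "no biomass")
})

test_that("colonization index averages the three rescaled quantities", {
  expect_identical(colonization_index(1, 1, 1), 1)
  expect_identical(colonization_index(0, 0, 0), 0)
  expect_equal(colonization_index(0.3, 0.6, 0.9), 0.6)
  expect_error(colonization_index(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("classification thresholds and majority vote follow the index bands", {
  porous <- classify_strain(c(max = 0.410930, average = 0.423024,
                              weighted = 0.425755))
  expect_identical(porous$label, "porous")
  expect_true(porous$unanimous)
  inter <- classify_strain(c(max = 0.576164, average = 0.513284,
                             weighted = 0.507068))
  expect_identical(inter$label, "intermediate")
  compact <- classify_strain(c(max = 0.988081, average = 1.0,
                               weighted = 0.996889))
  expect_identical(compact$label, "compact")
  # boundaries assign upward
  expect_identical(classify_strain(0.5)$label, "intermediate")
  expect_identical(classify_strain(0.7)$label, "compact")
  expect_identical(classify_strain(0.49999)$label, "porous")
  # majority with disagreement is reported
  split <- classify_strain(c(a = 0.4, b = 0.45, c = 0.55))
  expect_identical(split$label, "porous")
  expect_false(split$unanimous)
  expect_error(classify_strain(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("all dimensionless quantities stay in [0, 1] on synthetic stacks", {
  for (arch in c("compact", "porous")) {
    g <- generate_stack(synthetic_stack_spec(arch, n_slices = 5, width = 48,
                                             height = 48, seed = 19))
    tr <- triples_from_masks(g$ground_truth$masks)
    expect_true(all(tr >= 0 & tr <= 1))
  }
})
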