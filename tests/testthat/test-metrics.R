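test_that("spot counting finds constructed bumps and ignores flat fields", {
  f <- fixture_bumps()
  cs <- count_spots(f)
  expect_identical(cs$n_spots, 3L)
  expect_identical(max(cs$labels), 3L)
  expect_identical(count_spots(matrix(1, 32, 32))$n_spots, 0L)
  # sub-threshold speckle smaller than the minimum size is discarded
  speck <- matrix(0, 32, 32)
  speck[5, 5] <- 1
  expect_identical(count_spots(speck, min_size = 4)$n_spots, 0L)
  expect_identical(count_spots(speck, min_size = 1)$n_spots, 1L)
})

test_that("spot count is invariant under translation and affine rescaling", {
  f <- fixture_bumps(n = 40, centres = list(c(8, 8), c(8, 30), c(30, 18),
                                            c(34, 34)))
  n0 <- count_spots(f)$n_spots
  expect_identical(n0, 4L)
  roll <- function(m, di, dj) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(n) - 1 - dj) %% n) + 1]
  }
  # wrap-aware counting is invariant under periodic translation even when
  # a bump straddles the edge
  expect_identical(count_spots(roll(f, 7, 13), periodic = TRUE)$n_spots, n0)
  expect_identical(count_spots(2.5 * f - 40)$n_spots, n0)
})

test_that("pattern classification separates spots, stripes, holes, uniform", {
  expect_identical(classify_pattern(fixture_bumps()), "spots")
  expect_identical(classify_pattern(fixture_stripes()), "stripes")
  expect_identical(classify_pattern(1 - fixture_bumps()), "holes")
  expect_identical(classify_pattern(matrix(0.4, 20, 20)), "uniform")
})

test_that("gradient statistics are exact on ramps and constants", {
  g <- grid_spec(32, 32, boundary = "zero-flux")
  ramp <- matrix(rep(0.3 * (seq_len(32) - 1), each = 32), 32, 32)
  gs <- gradient_stats(ramp, g)
  expect_equal(gs$max_gradient, 0.3, tolerance = 1e-12)
  expect_equal(gs$mean_gradient, 0.3, tolerance = 1e-12)
  gs0 <- gradient_stats(matrix(2, 32, 32), g)
  expect_equal(gs0$max_gradient, 0)
})

test_that("radial spectrum recovers a pure mode and distrusts white noise", {
  n <- 64
  g <- grid_spec(n, n)
  x <- seq_len(n) - 1
  f <- matrix(rep(cos(2 * pi * 3 * x / n), each = n), n, n)
  rs <- radial_spectrum_peak(f, g)
  k_true <- 2 * pi * 3 / n
  expect_lt(abs(rs$dominant_wavenumber - k_true), 2 * pi / n + 1e-12)
  expect_true(rs$confident)
  set.seed(4)
  noise <- matrix(rnorm(n * n), n, n)
  expect_false(radial_spectrum_peak(noise, g)$confident)
  expect_identical(radial_spectrum_peak(matrix(1, n, n), g)$dominant_wavenumber,
                   0)
})

test_that("stationary pattern's spectral peak matches the linear prediction", {
  ctx <- ai_context(model_params(), 0.352, 0.248)
  g <- grid_spec(96, 96)
  sim <- simulate_ai(ctx, g, rng_seed = 21, max_steps = 1e5)
  expect_true(sim$converged)
  ps <- pattern_summary(sim$final$A, g)
  expect_identical(ps$pattern_class, "spots")
  expect_gt(ps$n_spots, 0)
  kc <- dispersion(ctx)$k_critical
  expect_lt(abs(ps$dominant_wavenumber - kc) / kc, 0.3)
})

test_that("spot patterns carry the steepest activator gradients", {
  # saturating the activator production (kappa > 0) pushes the pattern
  # repertoire to stripes and holes; at matched amplitude the spot
  # pattern's gradients dominate both
  g <- grid_spec(64, 64)
  spots <- simulate_ai(ai_context(model_params(), 0.352, 0.248), g,
                       rng_seed = 31, max_steps = 1.2e5)
  stripes <- simulate_ai(ai_context(model_params(kappa = 5), 0.610, 0.285),
                         g, rng_seed = 31, max_steps = 1.2e5)
  holes <- simulate_ai(ai_context(model_params(kappa = 5), 0.793, 0.271),
                       g, rng_seed = 31, max_steps = 1.2e5)
  expect_identical(classify_pattern(smooth_field(spots$final$A, g)), "spots")
  expect_identical(classify_pattern(smooth_field(stripes$final$A, g)),
                   "stripes")
  expect_identical(classify_pattern(smooth_field(holes$final$A, g)), "holes")
  rescale <- function(m) (m - min(m)) / diff(range(m))
  grads <- vapply(list(spots, stripes, holes), function(s) {
    gradient_stats(rescale(s$final$A), g)$max_gradient
  }, numeric(1))
  expect_gt(grads[1], grads[2])
  expect_gt(grads[1], grads[3])
})

test_that("thinning reduces a thick bar to a line with two endpoints", {
  m <- matrix(FALSE, 32, 32)
  m[5:28, 14:18] <- TRUE
  sk <- thin_mask(m)
  expect_true(all(m[sk]))  # skeleton is a subset of the mask
  expect_lt(sum(sk), sum(m) / 2)
  tips <- skeleton_endpoints(sk)
  expect_identical(nrow(tips), 2L)
})

test_that("a straight growing bar produces no branching events", {
  movie <- fixture_branch_movie(48, 24, function(i) {
    m <- matrix(FALSE, 48, 48)
    m[1:(2 * i), 23:24] <- TRUE
    which(m)
  })
  br <- classify_branch_events(movie, y_threshold = 0.5)
  expect_identical(br$overall_mode, "none")
  expect_identical(nrow(br$events), 0L)
})

test_that("a splitting tip is classified as tip bifurcation", {
  movie <- fixture_branch_movie(64, 30, function(i) {
    m <- matrix(FALSE, 64, 64)
    m[1:min(20 + i, 30), 32] <- TRUE
    if (i > 10) {
      len <- i - 10
      for (s in seq_len(len)) {   # two arms splitting from the tip
        r <- min(30 + s, 64)
        m[r, max(32 - s, 1)] <- TRUE
        m[r, min(32 + s, 64)] <- TRUE
      }
    }
    which(m)
  })
  br <- classify_branch_events(movie, y_threshold = 0.5)
  expect_gt(nrow(br$events), 0)
  expect_identical(br$overall_mode, "tip")
})

test_that("a lateral sprout far behind the tip is a side branch", {
  movie <- fixture_branch_movie(64, 30, function(i) {
    m <- matrix(FALSE, 64, 64)
    m[1:min(30 + i, 64), 32] <- TRUE
    if (i > 10) {
      len <- i - 10   # sprout leaves the stalk at row 10, far from the tip
      m[10, 33:min(32 + len, 64)] <- TRUE
    }
    which(m)
  })
  br <- classify_branch_events(movie, y_threshold = 0.5)
  expect_gt(nrow(br$events), 0)
  expect_identical(br$overall_mode, "side")
})

test_that("component labelling matches connectivity conventions", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE  # diagonal touch
  expect_identical(label_components(m, connectivity = 8)$n, 1L)
  expect_identical(label_components(m, connectivity = 4)$n, 2L)
  expect_identical(label_components(matrix(FALSE, 4, 4))$n, 0L)
})
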