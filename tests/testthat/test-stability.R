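test_that("all four Turing conditions hold at the six reference states", {
  for (ctx in ref_contexts()) {
    tc <- turing_conditions(ctx)
    expect_true(tc$overall, label = sprintf("overall at S=%g Y=%g", ctx$S, ctx$Y))
    expect_true(all(tc$conditions))
  }
})

test_that("equal diffusivities defeat condition 3 whenever the trace is negative", {
  p <- model_params(D_H = model_params()$D_A)
  tc <- turing_conditions(ai_context(p, 0.352, 0.248))
  expect_true(tc$conditions[["trace_negative"]])
  expect_false(tc$conditions[["cross_diffusion_positive"]])
  expect_false(tc$overall)
})

test_that("turing_conditions is total on degenerate contexts", {
  tc <- turing_conditions(ai_context(model_params(), 0, 0))
  expect_false(tc$overall)
  expect_identical(tc$reason, "no-positive-equilibrium")
})

test_that("dispersion at k = 0 reduces to the homogeneous kinetic eigenvalue", {
  p <- model_params()
  for (ctx in ref_contexts(p)) {
    dc <- dispersion(ctx, n_k = 200)
    eq <- ai_equilibrium(ctx)
    J <- ai_jacobian(eq)
    expect_equal(dc$re_lambda0, oracle_re_lambda(J, p, 0), tolerance = 1e-12)
    # conditions 1-2 hold here, so the homogeneous state is stable
    expect_lt(dc$re_lambda0, 0)
    # but a finite-wavenumber band grows
    expect_gt(dc$lambda_max, 0)
    expect_gt(dc$k_critical, 0)
  }
})

test_that("closed-form growth rate matches a generic eigensolver on random draws", {
  set.seed(11)
  p <- model_params()
  n_checked <- 0
  while (n_checked < 1000) {
    S <- runif(1, 0.05, 1.2)
    Y <- runif(1, 0, 0.8)
    ctx <- ai_context(p, S, Y)
    eq <- ai_equilibrium(ctx)
    J <- ai_jacobian(eq, ctx)
    k <- runif(1, 0, pi)
    closed <- turingbranch:::re_lambda(k, J, p)
    expect_equal(closed, oracle_re_lambda(J, p, k), tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
})

test_that("dispersion refinement finds the curve maximum", {
  ctx <- ai_context(model_params(), 0.352, 0.248)
  dc <- dispersion(ctx)
  expect_true(all(dc$lambda_max >= dc$re_lambda_max - 1e-12))
  expect_equal(dc$wavelength, 2 * pi / dc$k_critical)
})

test_that("Turing conditions agree with the dispersion relation across a scan", {
  p <- model_params()
  for (S in seq(0.05, 1.15, length.out = 9)) {
    for (Y in seq(0.02, 0.78, length.out = 9)) {
      ctx <- ai_context(p, S, Y)
      tc <- turing_conditions(ctx)
      dc <- dispersion(ctx, n_k = 400)
      by_dispersion <- dc$re_lambda0 < 0 &&
        max(dc$re_lambda_max[dc$k_values > 0]) > 0
      expect_identical(tc$overall, by_dispersion,
                       label = sprintf("A9 vs A8 at S=%g Y=%g", S, Y))
    }
  }
})

test_that("region scan brackets the reference states and respects resolution", {
  region <- scan_turing_region(model_params(), resolution = c(80, 80))
  expect_identical(dim(region$mask),
                   c(length(region$Y_axis), length(region$S_axis)))
  expect_gt(sum(region$mask), 0)
  ref <- reference_conditions()
  for (i in seq_len(nrow(ref))) {
    # exact re-evaluation is authoritative (the mask is advisory and the
    # crescent is thin relative to the scan step)
    expect_true(in_turing_region(region, ref$S[i], ref$Y[i]))
  }
})

test_that("equal diffusivities empty the scanned region", {
  p <- model_params(D_H = model_params()$D_A)
  region <- scan_turing_region(p, resolution = c(40, 40))
  expect_false(any(region$mask))
  expect_identical(region$n_components, 0L)
})

test_that("wavelengths decrease strictly across the reference series", {
  ws <- wavelength_series(ref_contexts())
  expect_true(all(ws$in_region))
  expect_true(all(diff(ws$wavelength) < 0))
  # side-branching wavelengths sit below every tip-bifurcation wavelength
  expect_lt(max(ws$wavelength[4:6]), min(ws$wavelength[1:3]))
})

test_that("wavelength series is deterministic and flags out-of-region items", {
  p <- model_params()
  ctx <- ai_context(p, 0.352, 0.248)
  ws <- wavelength_series(list(ctx, ctx, ctx))
  expect_identical(ws$wavelength, rep(ws$wavelength[1], 3))
  ws2 <- wavelength_series(list(ctx, ai_context(p, 1.1, 0.01)))
  expect_identical(ws2$reason, c("ok", "outside-turing-region"))
  expect_true(is.na(ws2$wavelength[2]))
})
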