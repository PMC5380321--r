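test_that("laplacian of a constant field vanishes under both boundary modes", {
  for (b in c("periodic", "zero-flux")) {
    g <- grid_spec(nx = 32, ny = 24, boundary = b)
    f <- matrix(3.7, 24, 32)
    expect_equal(laplacian(f, g), matrix(0, 24, 32))
  }
})

test_that("laplacian reproduces the exact discrete eigenvalue of a cosine mode", {
  n <- 64
  g <- grid_spec(n, n, dx = 0.5)
  x <- (seq_len(n) - 1) * g$dx
  L <- n * g$dx
  f <- matrix(rep(cos(2 * pi * x / L), each = n), n, n)
  # eigenvalue of the discrete periodic operator, not the continuum limit
  eig <- -(2 - 2 * cos(2 * pi * g$dx / L)) / g$dx^2
  expect_equal(laplacian(f, g), eig * f, tolerance = 1e-12)
})

test_that("laplacian impulse response places the stencil weights with wrap", {
  n <- 16
  g <- grid_spec(n, n)
  f <- matrix(0, n, n)
  f[1, 1] <- 1
  lap <- laplacian(f, g)
  expect_equal(lap[1, 1], -4)
  expect_equal(lap[2, 1], 1)
  expect_equal(lap[n, 1], 1)  # wrapped
  expect_equal(lap[1, 2], 1)
  expect_equal(lap[1, n], 1)  # wrapped
  expect_equal(sum(lap), 0)
  expect_error(laplacian(matrix(0, 4, 4), g), "shape")
})

test_that("the homogeneous resting state is a fixed point of the integrator", {
  p <- model_params()
  g <- grid_spec(16, 16, boundary = "zero-flux")
  st <- field_state(matrix(0, 16, 16), matrix(0, 16, 16),
                    matrix(p$c0 / p$gamma, 16, 16), matrix(0, 16, 16))
  st2 <- step_branching(st, p, g)
  expect_equal(st2$A, st$A)
  expect_equal(st2$H, st$H)
  expect_equal(st2$S, st$S)
  expect_equal(st2$Y, st$Y)
})

test_that("stepping is equivariant under translations on a periodic grid", {
  set.seed(3)
  n <- 24
  p <- model_params()
  g <- grid_spec(n, n, boundary = "periodic")
  rand <- function() matrix(runif(n * n, 0.01, 0.5), n, n)
  st <- field_state(rand(), rand(), rand(), rand())
  roll <- function(m, di, dj) {
    m[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(n) - 1 - dj) %% n) + 1]
  }
  st_shift <- field_state(roll(st$A, 3, 5), roll(st$H, 3, 5),
                          roll(st$S, 3, 5), roll(st$Y, 3, 5))
  a <- step_branching(st, p, g)
  b <- step_branching(st_shift, p, g)
  expect_equal(roll(a$A, 3, 5), b$A, tolerance = 1e-14)
  expect_equal(roll(a$Y, 3, 5), b$Y, tolerance = 1e-14)
})

test_that("compiled step matches an independent plain-R update to 1e-14", {
  set.seed(17)
  n <- 20
  p <- model_params(epsilon = 0.3, kappa = 0.25)
  for (b in c("periodic", "zero-flux")) {
    g <- grid_spec(n, n, dx = 0.7, boundary = b)
    rand <- function() matrix(runif(n * n, 0, 0.8), n, n)
    st <- field_state(rand(), rand(), rand(), rand())
    dt <- 0.05
    stepped <- step_branching(st, p, g, dt = dt)
    ora <- oracle_step_branching(st$A, st$H, st$S, st$Y, p, g$dx, dt, b)
    expect_equal(stepped$A, ora$A, tolerance = 1e-14)
    expect_equal(stepped$H, ora$H, tolerance = 1e-14)
    expect_equal(stepped$S, ora$S, tolerance = 1e-14)
    expect_equal(stepped$Y, ora$Y, tolerance = 1e-14)
  }
})

test_that("blow-up aborts with a diagnostic naming the field", {
  p <- model_params()
  g <- grid_spec(16, 16)
  st <- field_state(matrix(1, 16, 16), matrix(1e-9, 16, 16),
                    matrix(1, 16, 16), matrix(0, 16, 16))
  # enormous dt turns the stiff autocatalysis into an instant overflow
  expect_error(
    {
      cur <- st
      for (i in 1:50) cur <- step_branching(cur, p, g, dt = 50)
    },
    "instability.*field")
})

test_that("identical seeds give bit-identical activator-inhibitor runs", {
  ctx <- ai_context(model_params(), 0.352, 0.248)
  g <- grid_spec(32, 32)
  s1 <- simulate_ai(ctx, g, rng_seed = 5, max_steps = 500)
  s2 <- simulate_ai(ctx, g, rng_seed = 5, max_steps = 500)
  expect_identical(s1$final$A, s2$final$A)
  expect_identical(length(s1$snapshots), length(s2$snapshots))
  s3 <- simulate_ai(ctx, g, rng_seed = 6, max_steps = 500)
  expect_false(identical(s1$final$A, s3$final$A))
  # snapshot times strictly increase
  ts <- vapply(s1$snapshots, function(s) s$t, numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("perturbations of the equilibrium decay when diffusivities are equal", {
  p0 <- model_params()
  p <- model_params(D_H = p0$D_A)
  ctx <- ai_context(p, 0.352, 0.248)
  sim <- simulate_ai(ctx, grid_spec(48, 48), rng_seed = 2,
                     max_steps = 2e4, stat_tol = 1e-9)
  eq <- ai_equilibrium(ctx)
  expect_lt(max(abs(sim$final$A - eq$A_star)) / eq$A_star, 1e-6)
  expect_lt(max(abs(sim$final$H - eq$H_star)) / eq$H_star, 1e-6)
})

test_that("long default-step integration stays finite (stability guard)", {
  ctx <- ai_context(model_params(), 0.352, 0.248)
  g <- grid_spec(24, 24)
  sim <- simulate_ai(ctx, g, rng_seed = 9, max_steps = 1e6, stat_tol = 0)
  expect_true(all(is.finite(sim$final$A)))
  expect_true(all(is.finite(sim$final$H)))
  expect_false(sim$converged)
  expect_equal(sim$steps_taken, 1e6)
})

test_that("an unseeded noiseless branching run stays spatially homogeneous", {
  p <- model_params()
  g <- grid_spec(24, 24, boundary = "zero-flux")
  sim <- simulate_branching(p, g, run_length = 50, seed_size = 0,
                            noise_amplitude = 0)
  # every field stays uniform in space (though levels relax in time)
  for (nm in c("A", "H", "S", "Y")) {
    expect_equal(diff(range(sim$final[[nm]])), 0)
  }
  expect_lt(max(sim$final$Y), 1e-3)
  expect_error(classify_branch_events(sim), class = "no_structure")
})
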