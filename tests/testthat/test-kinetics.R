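test_that("reaction terms vanish at states where every production term is off", {
  p <- model_params()
  # A = H = Y = 0 kills every production and decay term; S sits at c0/gamma
  r <- reaction_terms(0, 0, 1, 0, p)
  expect_equal(unlist(r), c(dA = 0, dH = 0, dS = 0, dY = 0))
  # with H > 0 the only surviving term is the inhibitor's own decay
  r1 <- reaction_terms(0, 1, 1, 0, p)
  expect_equal(unlist(r1), c(dA = 0, dH = -p$v, dS = 0, dY = 0))

  # closed-form A-H equilibrium at Y = 0: A* = v/mu, H* = c A*^2 S / v;
  # only the differentiation induction d*A remains active
  A <- p$v / p$mu
  H <- p$c * A^2 * 1 / p$v
  r2 <- reaction_terms(A, H, 1, 0, p)
  expect_equal(r2$dA, 0, tolerance = 1e-14)
  expect_equal(r2$dH, 0, tolerance = 1e-14)
  expect_equal(r2$dS, 0)
  expect_equal(r2$dY, p$d * A)
})

test_that("reaction terms match term-by-term hand evaluation at (1,1,1,1)", {
  p <- model_params()
  r <- reaction_terms(1, 1, 1, 1, p)
  expect_equal(r$dA, 0.002 * 1 * 1 / 1 - 0.16 * 1 + 0.03 * 1)
  expect_equal(r$dH, 0.002 - 0.04 + 1e-4)
  expect_equal(r$dS, 0.02 - 0.02 - 1.0 * 1 * 1)
  expect_equal(r$dY, 0.008 - 0.1 + 1 / (1 + 10))
})

test_that("activator saturation reshapes the autocatalytic term in A and H", {
  p <- model_params(kappa = 0.25)
  r <- reaction_terms(2, 0.5, 1, 0, p)
  a2 <- 4 / (1 + 0.25 * 4)
  expect_equal(r$dA, 0.002 * a2 * 1 / 0.5 - 0.16 * 2)
  expect_equal(r$dH, 0.002 * a2 * 1 - 0.04 * 0.5)
})

test_that("negative concentrations are rejected, near-zero H is floored", {
  p <- model_params()
  expect_error(reaction_terms(-0.1, 1, 1, 0, p), "invalid-input")
  expect_error(reaction_terms(1, 1, 1, -1, p), "invalid-input")
  # H = 0 must not divide by zero thanks to the floor
  r <- reaction_terms(1, 0, 1, 0, p)
  expect_true(is.finite(r$dA))
})

test_that("equilibrium at Y = 0 matches the closed form A* = v/mu", {
  p <- model_params()
  for (S in c(0.3, 1, 2)) {
    eq <- ai_equilibrium(ai_context(p, S, 0))
    expect_equal(eq$A_star, p$v / p$mu, tolerance = 1e-12)
    expect_equal(eq$H_star, p$c * (p$v / p$mu)^2 * S / p$v, tolerance = 1e-12)
  }
})

test_that("equilibrium matches the brute-force bracketing oracle", {
  p <- model_params()
  eq <- ai_equilibrium(ai_context(p, 0.352, 0.248))
  roots <- oracle_equilibrium(p, 0.352, 0.248)
  expect_length(roots, 1)
  expect_equal(eq$A_star, roots[1], tolerance = 1e-9)
  expect_lt(eq$residuals[["f"]], 1e-10)
  expect_lt(eq$residuals[["g"]], 1e-10)
})

test_that("degenerate contexts raise no-positive-equilibrium", {
  p <- model_params()
  expect_error(ai_equilibrium(ai_context(p, 0, 0)),
               class = "no_positive_equilibrium")
})

test_that("equilibrium residuals stay at round-off over random contexts", {
  set.seed(42)
  p <- model_params()
  for (i in 1:50) {
    S <- runif(1, 0.05, 1.2)
    Y <- runif(1, 0, 0.8)
    eq <- ai_equilibrium(ai_context(p, S, Y))
    expect_lt(eq$residuals[["f"]], 1e-10)
    expect_lt(eq$residuals[["g"]], 1e-10)
    expect_gt(eq$A_star, 0)
    expect_gt(eq$H_star, 0)
  }
})

test_that("Jacobian matches direct substitution at the Y = 0 equilibrium", {
  p <- model_params()
  ctx <- ai_context(p, 1, 0)
  eq <- ai_equilibrium(ctx)
  J <- ai_jacobian(eq, ctx)
  A <- p$v / p$mu
  H <- p$c * A^2 / p$v
  # independent arithmetic: 2cA*S/H* = 2v/A* = 2mu, so r11 = mu
  expect_equal(J["A", "A"], 2 * p$c * A * 1 / H - p$mu)
  expect_equal(J["A", "A"], p$mu, tolerance = 1e-12)
  expect_equal(J["A", "H"], -p$c * A^2 / H^2)
  expect_equal(J["H", "A"], 2 * p$c * A)
  expect_equal(J["H", "A"], 0.001)
  expect_equal(J["H", "H"], -p$v)
})

test_that("Jacobian agrees with central finite differences of the kinetics", {
  set.seed(7)
  p <- model_params()
  for (i in 1:100) {
    S <- runif(1, 0.1, 1)
    Y <- runif(1, 0, 0.6)
    ctx <- ai_context(p, S, Y)
    eq <- ai_equilibrium(ctx)
    J <- ai_jacobian(eq, ctx)
    fd <- function(wrt, of) {
      up <- list(A = eq$A_star, H = eq$H_star)
      dn <- up
      h <- 1e-5 * abs(up[[wrt]])  # step scaled to the variable
      up[[wrt]] <- up[[wrt]] + h
      dn[[wrt]] <- dn[[wrt]] - h
      ru <- reaction_terms(up$A, up$H, S, Y, p)
      rd <- reaction_terms(dn$A, dn$H, S, Y, p)
      (ru[[of]] - rd[[of]]) / (2 * h)
    }
    expect_equal(J["A", "A"], fd("A", "dA"), tolerance = 1e-5)
    expect_equal(J["A", "H"], fd("H", "dA"), tolerance = 1e-5)
    expect_equal(J["H", "A"], fd("A", "dH"), tolerance = 1e-5)
    expect_equal(J["H", "H"], fd("H", "dH"), tolerance = 1e-5)
    # r22 is constant in (S, Y)
    expect_identical(J["H", "H"], -p$v)
  }
})

test_that("parameter round-trip through YAML preserves values", {
  p <- model_params(epsilon = 0.06, rho_H = 5e-5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_params(p, path)
  expect_equal(read_model_params(path), p)
  bundled <- read_model_params(system.file("extdata", "default_params.yaml",
                                           package = "turingbranch"))
  expect_equal(bundled, model_params())
})

test_that("invalid parameters are rejected", {
  expect_error(model_params(D_A = 0), "strictly positive")
  expect_error(model_params(mu = -1), "nonnegative")
})
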