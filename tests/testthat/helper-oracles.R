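# Independent oracles used across the test suite. These deliberately share
# no code with the package's production paths.

# Brute-force equilibrium of the decoupled subsystem: dense scan of A over
# a log grid locating sign changes of the reduced activator nullcline
# (with H eliminated through its own nullcline), refined by uniroot.
oracle_equilibrium <- function(p, S, Y, lower = 1e-6, upper = 1e3) {
  phi <- function(A) {
    H <- (p$c * A^2 * S + p$rho_H * Y) / p$v
    p$c * A^2 * S / H - p$mu * A + p$rho_A * Y
  }
  A_grid <- exp(seq(log(lower), log(upper), length.out = 20000))
  v <- vapply(A_grid, phi, numeric(1))
  sign_change <- which(v[-1] * v[-length(v)] < 0)
  roots <- vapply(sign_change, function(i) {
    stats::uniroot(phi, c(A_grid[i], A_grid[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  roots
}

# Straightforward one-step explicit Euler update of the branching model,
# written directly from the model equations with plain R arithmetic.
oracle_step_branching <- function(A, H, S, Y, p, dx, dt, boundary) {
  lap <- function(u) {
    ny <- nrow(u); nx <- ncol(u)
    ix <- function(i, n) {
      if (boundary == "periodic") ((i - 1) %% n) + 1 else pmin(pmax(i, 1), n)
    }
    (u[ix(seq_len(ny) - 1, ny), ] + u[ix(seq_len(ny) + 1, ny), ] +
       u[, ix(seq_len(nx) - 1, nx)] + u[, ix(seq_len(nx) + 1, nx)] -
       4 * u) / dx^2
  }
  Hf <- pmax(H, 1e-9)
  a2 <- if (p$kappa > 0) A^2 / (1 + p$kappa * A^2) else A^2
  auto <- p$c * a2 * S
  list(A = A + dt * (auto / Hf - p$mu * A + p$rho_A * Y + p$D_A * lap(A)),
       H = H + dt * (auto - p$v * H + p$rho_H * Y + p$D_H * lap(H)),
       S = S + dt * (p$c0 - p$gamma * S - p$epsilon * Y * S + p$D_S * lap(S)),
       Y = Y + dt * (p$d * A - p$e * Y + Y^2 / (1 + p$f * Y^2)))
}

# Re of the dominant eigenvalue of the 2x2 linearisation at wavenumber k,
# through a generic eigensolver rather than the closed-form quadratic.
oracle_re_lambda <- function(J, p, k) {
  M <- J - diag(c(k^2 * p$D_A, k^2 * p$D_H))
  max(Re(eigen(M, only.values = TRUE)$values))
}

# --- constructed pattern fixtures -------------------------------------

# Flat background with Gaussian bumps at the given centres.
fixture_bumps <- function(n = 48, centres = list(c(12, 12), c(12, 36),
                                                 c(36, 24)),
                          sigma = 2.5, amplitude = 1) {
  f <- matrix(0, n, n)
  for (ct in centres) {
    d2 <- outer((seq_len(n) - ct[1])^2, (seq_len(n) - ct[2])^2, "+")
    f <- f + amplitude * exp(-d2 / (2 * sigma^2))
  }
  f
}

fixture_stripes <- function(n = 48, wavelength = 12) {
  row_wave <- cos(2 * pi * seq_len(n) / wavelength)
  matrix(rep(row_wave, n), n, n)
}

# Synthetic branching "movie": a growing structure drawn directly into Y
# masks, wrapped as a sim_result so the event classifier can be exercised
# without a simulation. draw(i) returns the logical mask at frame i; the
# time step matches the snapshot cadence of a real run so that tissue-age
# classification applies unchanged.
fixture_branch_movie <- function(n, n_frames, draw, time_step = 50) {
  p <- model_params()
  g <- grid_spec(n, n, boundary = "zero-flux")
  snaps <- lapply(seq_len(n_frames), function(i) {
    Y <- matrix(0, n, n)
    Y[draw(i)] <- 1
    field_state(matrix(0, n, n), matrix(0, n, n), matrix(1, n, n), Y,
                t = i * time_step)
  })
  structure(list(final = snaps[[n_frames]], snapshots = snaps,
                 converged = NA, steps_taken = n_frames, params = p,
                 grid = g, model = "branching", ctx = NULL),
            class = "sim_result")
}

# Reference contexts used by several files.
ref_contexts <- function(params = model_params()) {
  ref <- reference_conditions()
  Map(function(S, Y) ai_context(params, S, Y), ref$S, ref$Y)
}
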