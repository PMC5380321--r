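# Simulation drivers for the full branching model and the decoupled
# activator-inhibitor model. The integration kernels are compiled
# (src/integrators.cpp); these wrappers own initial conditions, seeding,
# snapshot plumbing, and result containers.

# Parameter vector in the fixed order expected by the compiled kernels.
par_vector <- function(params) {
  as.numeric(unlist(params[c("c", "mu", "rho_A", "D_A", "v", "rho_H", "D_H",
                             "c0", "gamma", "epsilon", "D_S",
                             "d", "e", "f", "kappa")]))
}

new_sim_result <- function(snapshots, converged, steps_taken, params, grid,
                           model, ctx = NULL) {
  structure(list(final = snapshots[[length(snapshots)]],
                 snapshots = snapshots, converged = converged,
                 steps_taken = steps_taken, params = params, grid = grid,
                 model = model, ctx = ctx),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("%s simulation: %d steps, %d snapshots, t_final = %g\n",
              x$model, x$steps_taken, length(x$snapshots), x$final$t))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}

snap_to_state <- function(s, S = NULL, Y = NULL) {
  if (is.null(S)) {
    field_state(s$A, s$H, s$S, s$Y, t = s$t)
  } else {
    field_state(s$A, s$H, S, Y, t = s$t)
  }
}

#' One explicit Euler step of the branching model
#'
#' Advances all four fields by one forward-Euler update (the
#' differentiation state `Y` carries no diffusion term). Negative values
#' within round-off of zero are clamped; larger negatives or non-finite
#' values abort with a diagnostic naming the offending field and step.
#'
#' @param state A [field_state()] with four matrix fields.
#' @param params A [model_params()] object.
#' @param grid A [grid_spec()].
#' @param dt Time step; must respect the explicit diffusion stability
#'   bound (default rule: `0.2 dx^2 / (4 max(D_A, D_H, D_S))`).
#' @return The stepped [field_state()].
#' @export
step_branching <- function(state, params, grid,
                           dt = default_dt(params, grid, "branching")) {
  stopifnot(inherits(state, "field_state"), is.matrix(state$S),
            is.matrix(state$Y))
  res <- run_branching_cpp(state$A, state$H, state$S, state$Y,
                           par_vector(params), grid$dx, dt,
                           n_steps = 1L, snap_every = 1L,
                           periodic = grid$boundary == "periodic")
  s <- res$snapshots[[length(res$snapshots)]]
  field_state(s$A, s$H, s$S, s$Y, t = state$t + dt)
}

#' Simulate the branching model
#'
#' Grows a branched structure from a seeded patch of differentiated cells:
#' substrate starts at its undisturbed level `c0/gamma`, activator and
#' inhibitor at a small uniform baseline, and `Y` is zero except in a small
#' patch at the bottom-edge midpoint (with a matching activator bump).
#' Multiplicative noise on the activator breaks the symmetry of the
#' advancing front. The boundary default is zero-flux: a stalk growing
#' from a seeded edge is ill-posed under periodic wrap.
#'
#' The default grid uses `dx = 0.5`: at `dx = 1` the activator interface is
#' narrower than one cell and the advancing differentiation front can pin
#' on the lattice (a discrete propagation failure most visible at small
#' `epsilon`). The baseline activator level sits well below the baseline
#' inhibitor level so that the undisturbed background cannot self-ignite;
#' growth then emanates from the seed alone.
#'
#' @param params A [model_params()] object; `params$epsilon` selects the
#'   branching mode (large = tip bifurcation, small = side branching).
#' @param grid A [grid_spec()]; default 128 x 128 at `dx = 0.5`, zero-flux.
#' @param run_length Total simulated time.
#' @param dt Time step (default: explicit stability bound with safety 0.2).
#' @param n_snapshots Number of evenly spaced snapshots to retain (the
#'   initial state is always included).
#' @param seed_size Side of the square seeded patch (cells).
#' @param seed_value Initial `Y` level in the patch; the activator is
#'   bumped by the same amount.
#' @param baseline_A,baseline_H Initial uniform levels of `A` and `H`.
#' @param noise_amplitude Relative amplitude of the multiplicative
#'   activator noise.
#' @param rng_seed Integer seed for the initial noise; the integrator
#'   itself is deterministic.
#' @return A `sim_result` whose snapshots are [field_state()] objects.
#' @export
simulate_branching <- function(params, grid = grid_spec(128, 128, dx = 0.5,
                                                        boundary = "zero-flux"),
                               run_length = 4000, dt = default_dt(params, grid,
                                                                  "branching"),
                               n_snapshots = 40, seed_size = 3,
                               seed_value = 0.5, baseline_A = 0.001,
                               baseline_H = 0.01,
                               noise_amplitude = 0.01, rng_seed = 1) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "grid_spec"),
            run_length > 0, dt > 0)
  ny <- grid$ny
  nx <- grid$nx
  S <- matrix(params$c0 / params$gamma, ny, nx)
  A <- matrix(baseline_A, ny, nx)
  H <- matrix(baseline_H, ny, nx)
  Y <- matrix(0, ny, nx)
  if (seed_size > 0) {
    # seeded patch centred on the bottom-edge midpoint (row 1 = bottom)
    half <- (seed_size - 1) %/% 2
    rows <- 1:seed_size
    cols <- pmin(pmax(((nx + 1) %/% 2) + (-half:half), 1L), nx)
    Y[rows, cols] <- seed_value
    A[rows, cols] <- A[rows, cols] + seed_value
  }
  if (noise_amplitude > 0) {
    set.seed(rng_seed)
    A <- A * (1 + noise_amplitude * matrix(stats::runif(ny * nx, -1, 1),
                                           ny, nx))
  }
  n_steps <- max(1L, as.integer(ceiling(run_length / dt)))
  snap_every <- max(1L, n_steps %/% max(1L, n_snapshots))
  res <- run_branching_cpp(A, H, S, Y, par_vector(params), grid$dx, dt,
                           n_steps = n_steps, snap_every = snap_every,
                           periodic = grid$boundary == "periodic")
  snaps <- lapply(res$snapshots, snap_to_state)
  out <- new_sim_result(snaps, converged = NA, steps_taken = res$steps,
                        params = params, grid = grid, model = "branching")
  if (seed_size > 0 && max(out$final$Y) < 0.1) {
    warning("no differentiation front formed (max Y = ",
            signif(max(out$final$Y), 3), " at end of run)", call. = FALSE)
  }
  out
}

#' Simulate the decoupled activator-inhibitor model
#'
#' Integrates the two-variable subsystem at frozen `(S, Y)` from a randomly
#' perturbed uniform initial condition (the positive equilibrium times
#' `1 + noise`), on a periodic grid, until the stationary spatial structure
#' has formed: the run stops when the maximum kinetic rate `|du|/dt` stays
#' below `stat_tol` for `stat_consec` consecutive steps, or at `max_steps`.
#' Non-convergence is reported through `converged = FALSE`, never as an
#' error.
#'
#' @param ctx An [ai_context()] admitting a positive equilibrium.
#' @param grid A [grid_spec()]; default 200 x 200 periodic.
#' @param noise_amplitude Relative amplitude of the initial perturbation.
#' @param max_steps Step cap.
#' @param stat_tol Stationarity tolerance on `max |du|/dt`.
#' @param stat_consec Consecutive sub-tolerance steps required.
#' @param n_snapshots Approximate number of retained snapshots.
#' @param dt Time step (default: explicit stability bound, safety 0.2).
#' @param rng_seed Integer seed for the initial perturbation.
#' @return A `sim_result`; snapshots carry matrix `A`, `H` and the frozen
#'   scalars `S`, `Y`.
#' @export
#' @examples
#' \donttest{
#' ctx <- ai_context(model_params(), S = 0.352, Y = 0.248)
#' sim <- simulate_ai(ctx, grid_spec(64, 64), rng_seed = 7)
#' count_spots(sim$final$A)$n_spots
#' }
simulate_ai <- function(ctx, grid = grid_spec(200, 200), noise_amplitude = 0.01,
                        max_steps = 5e5, stat_tol = 1e-6, stat_consec = 100,
                        n_snapshots = 10,
                        dt = default_dt(ctx$params, grid, "ai"), rng_seed = 1) {
  stopifnot(inherits(ctx, "ai_context"), inherits(grid, "grid_spec"))
  eq <- ai_equilibrium(ctx)  # errors if no positive equilibrium
  ny <- grid$ny
  nx <- grid$nx
  set.seed(rng_seed)
  A <- eq$A_star * (1 + noise_amplitude * matrix(stats::runif(ny * nx, -1, 1),
                                                 ny, nx))
  H <- eq$H_star * (1 + noise_amplitude * matrix(stats::runif(ny * nx, -1, 1),
                                                 ny, nx))
  snap_every <- max(1L, as.integer(max_steps) %/% max(1L, n_snapshots))
  res <- run_ai_cpp(A, H, ctx$S, ctx$Y, par_vector(ctx$params), grid$dx, dt,
                    max_steps = as.integer(max_steps),
                    snap_every = snap_every, stat_tol = stat_tol,
                    stat_consec = as.integer(stat_consec),
                    periodic = grid$boundary == "periodic")
  snaps <- lapply(res$snapshots, snap_to_state, S = ctx$S, Y = ctx$Y)
  new_sim_result(snaps, converged = res$converged, steps_taken = res$steps,
                 params = ctx$params, grid = grid,
                 model = "activator-inhibitor", ctx = ctx)
}
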