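# Reaction kinetics of the branching model and the positive-equilibrium
# solver of the decoupled activator-inhibitor subsystem.

# The autocatalytic term c A^2 S / H is singular at H = 0; H is floored at
# this value inside every reaction evaluation. The attractor keeps H orders
# of magnitude above the floor, so the safeguard only matters for
# pathological inputs.
H_FLOOR <- 1e-9

# Negative concentrations larger in magnitude than this are treated as
# genuine errors rather than round-off.
NEG_TOL <- 1e-12

#' Reaction terms of the branching model
#'
#' Evaluates the local (diffusion-free) kinetics of the four-variable
#' model:
#' \deqn{dA/dt = c A^2 S / H - \mu A + \rho_A Y}
#' \deqn{dH/dt = c A^2 S - v H + \rho_H Y}
#' \deqn{dS/dt = c_0 - \gamma S - \epsilon Y S}
#' \deqn{dY/dt = d A - e Y + Y^2/(1 + f Y^2)}
#' With `kappa > 0` the autocatalytic `A^2` is replaced by
#' `A^2/(1 + kappa A^2)` in both the A and H equations (saturation of
#' activator production). Inputs may be scalars or equal-shaped arrays.
#'
#' @param A,H,S,Y Nonnegative concentrations (scalars or equal-shaped
#'   numeric arrays). `H` is floored at `1e-9` before division.
#' @param params A [model_params()] object.
#' @return A list with components `dA`, `dH`, `dS`, `dY` of the same shape
#'   as the inputs.
#' @export
#' @examples
#' reaction_terms(0, 1, 1, 0, model_params())  # all rates vanish
reaction_terms <- function(A, H, S, Y, params) {
  stopifnot(inherits(params, "model_params"))
  for (nm in c("A", "H", "S", "Y")) {
    x <- get(nm)
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop("invalid-input: ", nm, " must be finite numeric", call. = FALSE)
    }
    if (any(x < -NEG_TOL)) {
      stop("invalid-input: negative concentration in ", nm, call. = FALSE)
    }
  }
  Hf <- pmax(H, H_FLOOR)
  A2 <- if (params$kappa > 0) A^2 / (1 + params$kappa * A^2) else A^2
  auto <- params$c * A2 * S
  list(dA = auto / Hf - params$mu * A + params$rho_A * Y,
       dH = auto - params$v * H + params$rho_H * Y,
       dS = params$c0 - params$gamma * S - params$epsilon * Y * S,
       dY = params$d * A - params$e * Y + Y^2 / (1 + params$f * Y^2))
}

# Kinetic right-hand side of the decoupled subsystem only (frozen S, Y).
ai_rhs <- function(A, H, ctx) {
  p <- ctx$params
  Hf <- pmax(H, H_FLOOR)
  A2 <- if (p$kappa > 0) A^2 / (1 + p$kappa * A^2) else A^2
  auto <- p$c * A2 * ctx$S
  list(f = auto / Hf - p$mu * A + p$rho_A * ctx$Y,
       g = auto - p$v * H + p$rho_H * ctx$Y)
}

stop_custom <- function(class, message) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

# Coefficients (a0, a1, a2, a3) of the cubic in A* obtained by eliminating
# H* = (c A^2 S + rho_H Y)/v from f = 0:
#   c S v A^2 - (mu A - rho_A Y)(c A^2 S + rho_H Y) = 0
ai_cubic_coefs <- function(ctx) {
  p <- ctx$params
  c(a0 = p$rho_A * p$rho_H * ctx$Y^2,
    a1 = -p$mu * p$rho_H * ctx$Y,
    a2 = p$c * ctx$S * (p$v + p$rho_A * ctx$Y),
    a3 = -p$mu * p$c * ctx$S)
}

#' Positive equilibrium of the decoupled activator-inhibitor subsystem
#'
#' Eliminates the inhibitor through its nullcline,
#' `H* = (c A*^2 S + rho_H Y)/v`, reduces the activator nullcline to a cubic
#' polynomial in `A*`, and returns the positive root (with Newton polishing
#' so that the reported residuals are at round-off level). When several
#' positive roots exist, the root whose homogeneous (k = 0) linearization is
#' stable is returned; if that filter does not single one out, an
#' `ambiguous_equilibrium` error is raised rather than guessing.
#'
#' With `kappa = 0` the cubic is solved analytically (polynomial roots plus
#' Newton polishing); the saturated system (`kappa > 0`) has no cubic
#' reduction and its positive roots are located by a dense sign-change scan
#' refined with [stats::uniroot()].
#'
#' @param ctx An [ai_context()].
#' @return An object of class `ai_equilibrium`: list with `A_star`,
#'   `H_star`, `residuals` (named `f`, `g`), and the generating `ctx`.
#' @section Errors: `no_positive_equilibrium` if no positive root exists
#'   (e.g. S = Y = 0); `ambiguous_equilibrium` if multiple positive roots
#'   pass the stability filter.
#' @export
#' @examples
#' eq <- ai_equilibrium(ai_context(model_params(), S = 1, Y = 0))
#' eq$A_star  # = v / mu = 0.25
ai_equilibrium <- function(ctx) {
  stopifnot(inherits(ctx, "ai_context"))
  p <- ctx$params
  pos <- if (p$kappa > 0) {
    saturated_roots(ctx)
  } else {
    co <- ai_cubic_coefs(ctx)
    # trim trailing zero coefficients (degenerate cubic at Y = 0 or S = 0)
    nz <- which(co != 0)
    if (length(nz) == 0) {
      stop_custom("no_positive_equilibrium",
                  "no positive equilibrium exists at S = 0, Y = 0")
    }
    co_t <- co[seq_len(max(nz))]
    roots <- if (length(co_t) == 1) numeric(0) else polyroot(co_t)
    re <- Re(roots)[abs(Im(roots)) < 1e-8 * pmax(1, Mod(roots))]
    keep <- sort(unique(re[re > 1e-12]))
    vapply(keep, polish_root, numeric(1), co = co)
  }
  if (length(pos) == 0) {
    stop_custom("no_positive_equilibrium",
                sprintf("no positive equilibrium at S = %g, Y = %g",
                        ctx$S, ctx$Y))
  }
  sat <- function(A) if (p$kappa > 0) A^2 / (1 + p$kappa * A^2) else A^2
  make_eq <- function(A) {
    H <- (p$c * sat(A) * ctx$S + p$rho_H * ctx$Y) / p$v
    r <- ai_rhs(A, H, ctx)
    structure(list(A_star = A, H_star = H,
                   residuals = c(f = abs(r$f), g = abs(r$g)), ctx = ctx),
              class = "ai_equilibrium")
  }
  if (length(pos) == 1) return(make_eq(pos))
  eqs <- lapply(pos, make_eq)
  stable <- vapply(eqs, function(e) {
    J <- ai_jacobian(e)
    sum(diag(J)) < 0 && (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) > 0
  }, logical(1))
  if (sum(stable) == 1) return(eqs[[which(stable)]])
  stop_custom("ambiguous_equilibrium",
              sprintf("%d positive roots, %d pass the k = 0 stability filter at S = %g, Y = %g",
                      length(pos), sum(stable), ctx$S, ctx$Y))
}

# Positive roots of the saturated (kappa > 0) activator nullcline with H
# eliminated: dense log-grid sign-change scan refined by uniroot.
saturated_roots <- function(ctx, lower = 1e-6, upper = 1e3) {
  p <- ctx$params
  phi <- function(A) {
    a2 <- A^2 / (1 + p$kappa * A^2)
    H <- (p$c * a2 * ctx$S + p$rho_H * ctx$Y) / p$v
    H[H <= 0] <- NA
    ifelse(is.na(H), -p$mu * A + p$rho_A * ctx$Y,
           p$c * a2 * ctx$S / H - p$mu * A + p$rho_A * ctx$Y)
  }
  A_grid <- exp(seq(log(lower), log(upper), length.out = 1200))
  v <- phi(A_grid)
  i <- which(v[-1] * v[-length(v)] < 0)
  vapply(i, function(j) {
    stats::uniroot(phi, c(A_grid[j], A_grid[j + 1]), tol = 1e-14)$root
  }, numeric(1))
}

# Newton-polish a root of the quartic-free cubic sum(co[i] * A^(i-1)).
polish_root <- function(A, co) {
  pow <- seq_along(co) - 1
  for (i in 1:3) {
    val <- sum(co * A^pow)
    der <- sum(co[-1] * pow[-1] * A^(pow[-1] - 1))
    if (der == 0) break
    step <- val / der
    A <- A - step
    if (abs(step) < 1e-15 * max(1, abs(A))) break
  }
  A
}

#' @export
print.ai_equilibrium <- function(x, ...) {
  cat(sprintf("Positive equilibrium: A* = %.8g, H* = %.8g\n",
              x$A_star, x$H_star))
  cat(sprintf("  residuals |f| = %.2e, |g| = %.2e\n",
              x$residuals["f"], x$residuals["g"]))
  invisible(x)
}

#' Jacobian of the decoupled subsystem at an equilibrium
#'
#' Partial derivatives of the activator-inhibitor kinetics at
#' `(A*, H*)`:
#' `r11 = 2 c A* S / H* - mu`, `r12 = -c A*^2 S / H*^2`,
#' `r21 = 2 c A* S`, `r22 = -v` (constant in S and Y).
#' With saturated kinetics (`kappa > 0`) the `A^2` factor and its
#' derivative are replaced by their saturated counterparts.
#'
#' @param eq An [ai_equilibrium()].
#' @param ctx Context; defaults to the one stored in `eq`.
#' @return A 2x2 numeric matrix.
#' @export
ai_jacobian <- function(eq, ctx = eq$ctx) {
  stopifnot(inherits(eq, "ai_equilibrium"), inherits(ctx, "ai_context"))
  p <- ctx$params
  A <- eq$A_star
  H <- eq$H_star
  if (!(A > 0) || !(H > 0)) {
    stop("invalid equilibrium: A* and H* must be positive", call. = FALSE)
  }
  if (p$kappa > 0) {
    a2 <- A^2 / (1 + p$kappa * A^2)
    da2 <- 2 * A / (1 + p$kappa * A^2)^2
  } else {
    a2 <- A^2
    da2 <- 2 * A
  }
  matrix(c(p$c * da2 * ctx$S / H - p$mu, p$c * da2 * ctx$S,
           -p$c * a2 * ctx$S / H^2,      -p$v),
         nrow = 2, dimnames = list(c("A", "H"), c("A", "H")))
}
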