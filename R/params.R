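# Model parameters and the frozen-context type for the decoupled
# activator-inhibitor subsystem.

#' Kinetic and diffusion parameters of the branching model
#'
#' Bundles every constant of the four-variable branching model: activator
#' `A` (autocatalytic, inhibited by `H`, fed by substrate `S`), inhibitor
#' `H`, substrate `S` (produced uniformly, consumed by differentiated
#' cells), and the irreversible cell-differentiation state `Y`. All
#' quantities are in the model's dimensionless units. Defaults are the
#' reference parameter set used throughout the package's analyses
#' (the tip-bifurcation / side-branching study conditions).
#'
#' @param c Autocatalysis rate of the activator.
#' @param mu Activator first-order decay rate.
#' @param rho_A Activator secretion rate by differentiated cells.
#' @param D_A Activator diffusion coefficient.
#' @param v Inhibitor first-order decay rate.
#' @param rho_H Inhibitor secretion rate by differentiated cells.
#' @param D_H Inhibitor diffusion coefficient; Turing instability needs
#'   `D_H` substantially larger than `D_A`.
#' @param c0 Substrate production rate; the undisturbed substrate level is
#'   `c0/gamma`.
#' @param gamma Substrate first-order decay rate.
#' @param epsilon Substrate consumption rate by differentiated cells. This
#'   is the single knob that switches the branching mode: large values give
#'   tip bifurcation, small values side branching.
#' @param D_S Substrate diffusion coefficient.
#' @param d Differentiation induction rate by the activator.
#' @param e Differentiation-state decay rate.
#' @param f Saturation constant of the differentiation self-activation
#'   term `Y^2/(1 + f Y^2)`.
#' @param kappa Optional activator-production saturation constant. The
#'   default 0 leaves the autocatalytic term exactly `A^2`; `kappa > 0`
#'   replaces it by `A^2/(1 + kappa A^2)` in both the activator and
#'   inhibitor equations, which pushes the pattern repertoire from spots
#'   towards stripes and holes.
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [read_model_params()], [ai_context()]
#' @export
#' @examples
#' p <- model_params()
#' p$epsilon
#' model_params(epsilon = 0.06)  # side-branching regime
model_params <- function(c = 0.002, mu = 0.16, rho_A = 0.03, D_A = 0.02,
                         v = 0.04, rho_H = 1e-4, D_H = 0.3,
                         c0 = 0.02, gamma = 0.02, epsilon = 1.0, D_S = 0.06,
                         d = 0.008, e = 0.1, f = 10, kappa = 0) {
  p <- list(c = c, mu = mu, rho_A = rho_A, D_A = D_A, v = v, rho_H = rho_H,
            D_H = D_H, c0 = c0, gamma = gamma, epsilon = epsilon, D_S = D_S,
            d = d, e = e, f = f, kappa = kappa)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("model_params fields must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  neg <- vapply(p, function(x) x < 0, logical(1))
  if (any(neg)) {
    stop("model_params fields must be nonnegative: ",
         paste(names(p)[neg], collapse = ", "), call. = FALSE)
  }
  if (p$D_A <= 0 || p$D_H <= 0) {
    stop("D_A and D_H must be strictly positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Branching-model parameters (dimensionless units)\n")
  print(unlist(x))
  invisible(x)
}

#' Read / write model parameters as YAML
#'
#' One key per symbol (`c`, `mu`, `rho_A`, `D_A`, `v`, `rho_H`, `D_H`,
#' `c0`, `gamma`, `epsilon`, `D_S`, `d`, `e`, `f`, `kappa`); keys absent
#' from the file keep their defaults. The bundled default config is at
#' `system.file("extdata", "default_params.yaml", package = "turingbranch")`.
#'
#' @param path Path to a YAML file.
#' @return `read_model_params()` returns a [model_params()] object.
#' @export
read_model_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_params))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown parameter keys in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(model_params, vals)
}

#' @param params A [model_params()] object.
#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}

#' Frozen-context for the decoupled activator-inhibitor subsystem
#'
#' Decoupling treats the substrate level `S` and differentiation level `Y`
#' as fixed parameters of the two-variable activator-inhibitor model, so a
#' point in the (S, Y) plane plus the kinetic constants fully specifies the
#' subsystem.
#'
#' @param params A [model_params()] object.
#' @param S Frozen substrate concentration (>= 0).
#' @param Y Frozen differentiation level (>= 0).
#' @return An object of class `ai_context`.
#' @export
#' @examples
#' ctx <- ai_context(model_params(), S = 0.352, Y = 0.248)
ai_context <- function(params, S, Y) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(S), length(S) == 1, is.finite(S), S >= 0,
            is.numeric(Y), length(Y) == 1, is.finite(Y), Y >= 0)
  structure(list(params = params, S = S, Y = Y), class = "ai_context")
}

#' @export
print.ai_context <- function(x, ...) {
  cat(sprintf("Activator-inhibitor context: S = %g, Y = %g (rho_H = %g)\n",
              x$S, x$Y, x$params$rho_H))
  invisible(x)
}

#' Reference simulation conditions
#'
#' The six (epsilon, S, Y) combinations that anchor the package's analyses
#' at `rho_H = 1e-4`: three tip-bifurcation runs with the (S, Y) states of
#' their underlying Turing spot patterns, and three side-branching runs
#' likewise. Wavelengths decrease monotonically down the table.
#'
#' @return A data.frame with columns `regime` ("tip" or "side"),
#'   `epsilon`, `S`, `Y`.
#' @export
reference_conditions <- function() {
  data.frame(
    regime  = rep(c("tip", "side"), each = 3),
    epsilon = c(1.5, 1.0, 0.7, 0.1, 0.06, 0.045),
    S       = c(0.320, 0.352, 0.395, 0.614, 0.679, 0.716),
    Y       = c(0.185, 0.248, 0.313, 0.478, 0.510, 0.530),
    stringsAsFactors = FALSE
  )
}

#' Inhibitor-secretion levels spanning five Turing regions
#'
#' The five `rho_H` values whose (S, Y) Turing regions are compared in the
#' region-sweep analysis, bracketing the reference value 1e-4 from both
#' sides.
#'
#' @return Numeric vector of length 5.
#' @export
inhibitor_secretion_levels <- function() {
  c(5e-05, 7e-05, 1e-04, 1.3e-04, 1.5e-04)
}

#' Epsilon sweeps per Turing region
#'
#' For each inhibitor-secretion level, the substrate-consumption rates used
#' in the branching-mode sweep of that region (ordered from strongly
#' tip-bifurcating to strongly side-branching).
#'
#' @return Named list of numeric vectors; names are the `rho_H` values.
#' @export
epsilon_sweeps <- function() {
  list(`5e-05`   = c(3.0, 2.0, 1.0, 0.5, 0.1, 0.06, 0.045),
       `7e-05`   = c(1.5, 1.2, 0.9, 0.45, 0.1, 0.06, 0.045),
       `1e-04`   = c(1.5, 1.0, 0.7, 0.1, 0.06, 0.045),
       `0.00013` = c(1.1, 0.85, 0.7, 0.07, 0.06, 0.045),
       `0.00015` = c(0.9, 0.8, 0.65, 0.07, 0.06, 0.045))
}
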