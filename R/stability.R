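# Linear stability analysis of the decoupled activator-inhibitor
# subsystem: Turing conditions, dispersion relations, (S, Y) region scans,
# and critical-wavelength series.

#' Turing instability conditions at a frozen (S, Y) context
#'
#' Evaluates, at the positive equilibrium, the four inequalities that
#' characterise a diffusion-driven instability of the two-variable
#' subsystem:
#' 1. `r11 + r22 < 0` (homogeneous state stable: negative trace),
#' 2. `r11 r22 - r12 r21 > 0` (positive determinant),
#' 3. `r11 D_H + r22 D_A > 0` (differential diffusion can destabilise),
#' 4. `(r11 D_H + r22 D_A)^2 - 4 D_A D_H (r11 r22 - r12 r21) > 0`
#'    (a real band of unstable wavenumbers exists).
#'
#' The function is total: when no positive equilibrium exists (or it is
#' ambiguous) it returns `overall = FALSE` with a reason code instead of
#' raising, so parameter-plane scans never abort.
#'
#' @param ctx An [ai_context()].
#' @return List with `conditions` (named logical(4)), `overall`, and
#'   `reason` (`"ok"`, `"no-positive-equilibrium"`, or
#'   `"ambiguous-equilibrium"`).
#' @export
#' @examples
#' turing_conditions(ai_context(model_params(), S = 0.352, Y = 0.248))$overall
turing_conditions <- function(ctx) {
  eq <- tryCatch(ai_equilibrium(ctx),
                 no_positive_equilibrium = function(e) "no-positive-equilibrium",
                 ambiguous_equilibrium = function(e) "ambiguous-equilibrium")
  if (is.character(eq)) {
    return(list(conditions = stats::setNames(rep(NA, 4), cond_names()),
                overall = FALSE, reason = eq))
  }
  J <- ai_jacobian(eq)
  p <- ctx$params
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  cross <- J[1, 1] * p$D_H + J[2, 2] * p$D_A
  conds <- c(tr < 0, det > 0, cross > 0, cross^2 - 4 * p$D_A * p$D_H * det > 0)
  names(conds) <- cond_names()
  list(conditions = conds, overall = all(conds), reason = "ok")
}

cond_names <- function() {
  c("trace_negative", "det_positive", "cross_diffusion_positive",
    "real_unstable_band")
}

#' Dispersion relation of the decoupled subsystem
#'
#' For each wavenumber `k` the perturbation growth rate is the larger-real-
#' part root of `lambda^2 - tr_k lambda + Delta_k = 0` with
#' `tr_k = r11 + r22 - k^2 (D_A + D_H)` and
#' `Delta_k = r11 r22 - r12 r21 - k^2 (r11 D_H + r22 D_A) + k^4 D_A D_H`.
#' When the discriminant is negative the real part is `tr_k / 2` (a complex
#' conjugate pair). The critical wavenumber is located on the sample grid
#' and then polished by golden-section search; the associated wavelength is
#' `2 pi / k_critical`.
#'
#' @param ctx An [ai_context()] admitting a positive equilibrium.
#' @param k_max Upper wavenumber; the default `pi` is the largest
#'   wavenumber representable on a unit-spaced simulation grid.
#' @param n_k Number of samples on `[0, k_max]`.
#' @return Object of class `dispersion_curve`: `k_values`,
#'   `re_lambda_max`, `k_critical`, `wavelength`, `lambda_max`, and
#'   `re_lambda0` (the homogeneous growth rate). `k_critical` and
#'   `wavelength` are `NA` when the curve has no interior maximum.
#' @export
#' @examples
#' dc <- dispersion(ai_context(model_params(), S = 0.352, Y = 0.248))
#' dc$wavelength
dispersion <- function(ctx, k_max = pi, n_k = 2000) {
  eq <- ai_equilibrium(ctx)   # propagates no_positive_equilibrium
  J <- ai_jacobian(eq)
  p <- ctx$params
  k <- seq(0, k_max, length.out = n_k)
  re <- re_lambda(k, J, p)
  i <- which.max(re)
  k_crit <- NA_real_
  lam_max <- NA_real_
  if (i > 1) {
    lo <- k[max(1, i - 1)]
    hi <- k[min(n_k, i + 1)]
    opt <- stats::optimize(function(kk) re_lambda(kk, J, p),
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-12)
    k_crit <- opt$maximum
    lam_max <- opt$objective
  }
  structure(list(k_values = k, re_lambda_max = re,
                 k_critical = k_crit,
                 wavelength = if (is.na(k_crit)) NA_real_ else 2 * pi / k_crit,
                 lambda_max = lam_max, re_lambda0 = re[1],
                 jacobian = J, ctx = ctx),
            class = "dispersion_curve")
}

# Re of the larger-real-part eigenvalue of the linearised subsystem at
# wavenumber k (vectorised over k).
re_lambda <- function(k, J, p) {
  trk <- J[1, 1] + J[2, 2] - k^2 * (p$D_A + p$D_H)
  dk <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1] -
    k^2 * (J[1, 1] * p$D_H + J[2, 2] * p$D_A) + k^4 * p$D_A * p$D_H
  disc <- trk^2 - 4 * dk
  ifelse(disc >= 0, (trk + sqrt(pmax(disc, 0))) / 2, trk / 2)
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf("Dispersion relation at S = %g, Y = %g\n", x$ctx$S, x$ctx$Y))
  cat(sprintf("  Re lambda(0) = %.5g, max Re lambda = %.5g\n",
              x$re_lambda0, if (is.na(x$lambda_max)) max(x$re_lambda_max) else x$lambda_max))
  if (!is.na(x$k_critical)) {
    cat(sprintf("  k_critical = %.5g, wavelength = %.5g\n",
                x$k_critical, x$wavelength))
  } else {
    cat("  no interior maximum (no finite-wavenumber instability)\n")
  }
  invisible(x)
}

#' @export
plot.dispersion_curve <- function(x, ...) {
  graphics::plot(x$k_values, x$re_lambda_max, type = "l",
                 xlab = "wavenumber k", ylab = "Re lambda(k)", ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.na(x$k_critical)) {
    graphics::abline(v = x$k_critical, col = "red", lty = 2)
  }
  invisible(x)
}

#' Scan the (S, Y) plane for the Turing region
#'
#' Evaluates [turing_conditions()] on a rectangular grid of frozen
#' contexts, returning the boolean mask of the Turing region (the
#' crescent-shaped set where all four conditions hold) together with a
#' connected-component summary.
#'
#' @param params A [model_params()] object.
#' @param S_range,Y_range Axis intervals; defaults bracket the reference
#'   differentiation trajectories with margin.
#' @param resolution Per-axis sample counts `c(nS, nY)` (scalar recycled).
#' @return Object of class `turing_region_map` with `S_axis`, `Y_axis`,
#'   `mask` (`length(Y_axis)` x `length(S_axis)`), `rho_H`, `params`,
#'   `n_components` and `bbox` (S/Y ranges of the region, NA when empty).
#' @export
scan_turing_region <- function(params, S_range = c(0, 1.2),
                               Y_range = c(0, 0.8), resolution = c(200, 200)) {
  stopifnot(inherits(params, "model_params"),
            length(S_range) == 2, length(Y_range) == 2,
            diff(S_range) > 0, diff(Y_range) > 0)
  resolution <- rep(as.integer(resolution), length.out = 2)
  S_axis <- seq(S_range[1], S_range[2], length.out = resolution[1])
  Y_axis <- seq(Y_range[1], Y_range[2], length.out = resolution[2])
  mask <- matrix(FALSE, nrow = length(Y_axis), ncol = length(S_axis))
  for (iy in seq_along(Y_axis)) {
    for (ix in seq_along(S_axis)) {
      mask[iy, ix] <- turing_point(params, S_axis[ix], Y_axis[iy])
    }
  }
  lab <- label_components(mask, connectivity = 8)
  bbox <- if (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    c(S_min = S_axis[min(idx[, 2])], S_max = S_axis[max(idx[, 2])],
      Y_min = Y_axis[min(idx[, 1])], Y_max = Y_axis[max(idx[, 1])])
  } else {
    c(S_min = NA_real_, S_max = NA_real_, Y_min = NA_real_, Y_max = NA_real_)
  }
  structure(list(S_axis = S_axis, Y_axis = Y_axis, mask = mask,
                 rho_H = params$rho_H, params = params,
                 n_components = lab$n, bbox = bbox),
            class = "turing_region_map")
}

# Fast scalar Turing-condition check used by the scan (avoids the
# object-building overhead of turing_conditions on 10^4-10^5 points).
# Saturated kinetics have no cubic reduction and take the generic path.
turing_point <- function(p, S, Y) {
  if (p$kappa > 0) {
    return(isTRUE(turing_conditions(ai_context(p, S, Y))$overall))
  }
  a0 <- p$rho_A * p$rho_H * Y^2
  a1 <- -p$mu * p$rho_H * Y
  a2 <- p$c * S * (p$v + p$rho_A * Y)
  a3 <- -p$mu * p$c * S
  co <- c(a0, a1, a2, a3)
  nz <- which(co != 0)
  if (length(nz) == 0) return(FALSE)
  co <- co[seq_len(max(nz))]
  if (length(co) == 1) return(FALSE)
  roots <- polyroot(co)
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * pmax(1, Mod(roots))]
  pos <- re[re > 1e-12]
  if (length(pos) == 0) return(FALSE)
  ok <- FALSE
  for (A in pos) {
    H <- (p$c * A^2 * S + p$rho_H * Y) / p$v
    r11 <- 2 * p$c * A * S / H - p$mu
    r12 <- -p$c * A^2 * S / H^2
    r21 <- 2 * p$c * A * S
    r22 <- -p$v
    tr <- r11 + r22
    det <- r11 * r22 - r12 * r21
    if (!(tr < 0 && det > 0)) next
    cross <- r11 * p$D_H + r22 * p$D_A
    if (cross > 0 && cross^2 - 4 * p$D_A * p$D_H * det > 0) ok <- TRUE
  }
  ok
}

#' @export
print.turing_region_map <- function(x, ...) {
  cat(sprintf("Turing region scan (rho_H = %g): %d x %d grid\n",
              x$rho_H, length(x$Y_axis), length(x$S_axis)))
  cat(sprintf("  %d / %d points inside, %d connected component(s)\n",
              sum(x$mask), length(x$mask), x$n_components))
  invisible(x)
}

#' Area fraction of a Turing region
#'
#' @param region A `turing_region_map`.
#' @return Fraction of scanned grid points inside the region.
#' @export
region_area_fraction <- function(region) {
  stopifnot(inherits(region, "turing_region_map"))
  mean(region$mask)
}

#' Membership of a continuous (S, Y) point in a Turing region
#'
#' The mask is advisory (nearest-node lookup); the authoritative answer is
#' an exact re-evaluation of the Turing conditions at the point.
#'
#' @param region A `turing_region_map`.
#' @param S,Y Coordinates of the query point.
#' @return Logical.
#' @export
in_turing_region <- function(region, S, Y) {
  stopifnot(inherits(region, "turing_region_map"))
  if (S < 0 || Y < 0) return(FALSE)
  turing_point(region$params, S, Y)
}

#' Critical wavelengths along a list of contexts
#'
#' Maps [dispersion()] over an ordered list of frozen contexts (e.g. the
#' Turing states underlying a branching-mode sweep) and tabulates critical
#' wavenumbers and wavelengths for monotonicity analysis. Contexts outside
#' the Turing region are reported with a reason code instead of failing the
#' whole series.
#'
#' @param ctx_list List of [ai_context()] objects.
#' @return data.frame with columns `S`, `Y`, `in_region`, `k_critical`,
#'   `wavelength`, `reason`.
#' @export
#' @examples
#' ref <- reference_conditions()
#' p <- model_params()
#' ctxs <- Map(function(S, Y) ai_context(p, S, Y), ref$S, ref$Y)
#' wavelength_series(ctxs)$wavelength  # strictly decreasing
wavelength_series <- function(ctx_list) {
  stopifnot(is.list(ctx_list),
            all(vapply(ctx_list, inherits, logical(1), "ai_context")))
  rows <- lapply(ctx_list, function(ctx) {
    tc <- turing_conditions(ctx)
    if (!tc$overall) {
      return(data.frame(S = ctx$S, Y = ctx$Y, in_region = FALSE,
                        k_critical = NA_real_, wavelength = NA_real_,
                        reason = if (tc$reason == "ok") "outside-turing-region" else tc$reason,
                        stringsAsFactors = FALSE))
    }
    dc <- dispersion(ctx)
    data.frame(S = ctx$S, Y = ctx$Y, in_region = TRUE,
               k_critical = dc$k_critical, wavelength = dc$wavelength,
               reason = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
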