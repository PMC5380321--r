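# Cell differentiation trajectories in the (S, Y) plane and selection of
# in-region Turing states for the decoupled model.

#' Extract the (S, Y) differentiation trajectory of a cell
#'
#' Picks a cell from a branching-model run and returns its substrate and
#' differentiation levels over the snapshots. The default rule tracks a
#' cell differentiating at a growing tip: the cell whose `Y` first crosses
#' half the final maximum during the second half of the run (ties broken by
#' the largest `Y`, then lowest index). When a `region` is supplied, the
#' rule additionally prefers the first such cell whose trajectory crosses
#' the Turing region — the differentiation transient is fast relative to
#' any practical snapshot cadence, so individual cells differ in whether
#' their sampled path clips the thin crescent. An explicit
#' `cell = c(row, col)` overrides the rule.
#'
#' @param sim A `sim_result` from [simulate_branching()] with at least 10
#'   snapshots.
#' @param cell Optional `c(row, col)` of the cell to track.
#' @param region Optional `turing_region_map`; when given, the in-region
#'   sub-intervals (crossings) of the trajectory are computed.
#' @param max_candidates With a `region`, how many candidate cells to try
#'   before falling back to the first.
#' @return Object of class `differentiation_trajectory`: `times`,
#'   `S_values`, `Y_values`, `cell_index`, and `crossings` (see
#'   [trajectory_crossings()]; `NULL` when no region was supplied).
#' @section Errors: `no_differentiation` if no cell crosses the threshold.
#' @export
extract_trajectory <- function(sim, cell = NULL, region = NULL,
                               max_candidates = 50) {
  stopifnot(inherits(sim, "sim_result"), sim$model == "branching")
  ns <- length(sim$snapshots)
  if (ns < 10) stop("need at least 10 snapshots", call. = FALSE)
  times <- vapply(sim$snapshots, function(s) s$t, numeric(1))
  series_of <- function(cell) {
    list(S = vapply(sim$snapshots, function(s) s$S[cell[1], cell[2]],
                    numeric(1)),
         Y = vapply(sim$snapshots, function(s) s$Y[cell[1], cell[2]],
                    numeric(1)))
  }
  build <- function(cell, crossings) {
    ser <- series_of(cell)
    traj <- structure(list(times = times, S_values = ser$S,
                           Y_values = ser$Y,
                           cell_index = c(row = unname(cell[1]),
                                          col = unname(cell[2])),
                           crossings = NULL, params = sim$params),
                      class = "differentiation_trajectory")
    if (!is.null(region)) {
      traj$crossings <- if (is.null(crossings)) {
        trajectory_crossings(traj, region)
      } else {
        crossings
      }
    }
    traj
  }
  if (!is.null(cell)) return(build(cell, NULL))
  thr <- 0.5 * max(sim$final$Y)
  if (thr <= 0) stop_custom("no_differentiation", "Y is identically zero")
  candidates <- list()
  for (i in (ns %/% 2):ns) {
    if (i == 1) next
    Yc <- sim$snapshots[[i]]$Y
    Yp <- sim$snapshots[[i - 1]]$Y
    crossing <- which(Yc >= thr & Yp < thr)
    for (pick in crossing[order(-Yc[crossing], crossing)]) {
      candidates[[length(candidates) + 1]] <-
        c(row = ((pick - 1) %% nrow(Yc)) + 1,
          col = ((pick - 1) %/% nrow(Yc)) + 1)
    }
    if (length(candidates) >= max_candidates) break
  }
  if (length(candidates) == 0) {
    stop_custom("no_differentiation",
                "no cell crosses half the final maximum Y in the second half of the run")
  }
  if (is.null(region)) return(build(candidates[[1]], NULL))
  for (cand in candidates[seq_len(min(length(candidates), max_candidates))]) {
    traj_try <- build(cand, NULL)
    if (nrow(traj_try$crossings) > 0) return(traj_try)
  }
  build(candidates[[1]], NULL)
}

#' In-region sub-intervals of a trajectory
#'
#' Membership is evaluated on a piecewise-linear refinement of the sampled
#' trajectory (each snapshot interval subdivided), because the
#' differentiation transient traverses the thin crescent faster than any
#' practical snapshot cadence; each refined point is validated by exact
#' re-evaluation of the Turing conditions.
#'
#' @param traj A `differentiation_trajectory`.
#' @param region A `turing_region_map`.
#' @param subdivisions Interpolation points per snapshot interval.
#' @return data.frame with one row per maximal in-region stretch:
#'   `t_start`, `t_end`, and a representative interior state `S_mid`,
#'   `Y_mid` (the middle in-region refined point, itself in-region); zero
#'   rows when the trajectory misses the region.
#' @export
trajectory_crossings <- function(traj, region, subdivisions = 10) {
  stopifnot(inherits(traj, "differentiation_trajectory"),
            inherits(region, "turing_region_map"))
  np <- length(traj$times)
  alpha <- seq(0, 1, length.out = subdivisions + 1)[-(subdivisions + 1)]
  fine_t <- c(outer(alpha, diff(traj$times)) +
                rep(traj$times[-np], each = subdivisions))
  fine_S <- c(outer(alpha, diff(traj$S_values)) +
                rep(traj$S_values[-np], each = subdivisions))
  fine_Y <- c(outer(alpha, diff(traj$Y_values)) +
                rep(traj$Y_values[-np], each = subdivisions))
  fine_t <- c(fine_t, traj$times[np])
  fine_S <- c(fine_S, traj$S_values[np])
  fine_Y <- c(fine_Y, traj$Y_values[np])
  inside <- mapply(function(S, Y) in_turing_region(region, S, Y),
                   fine_S, fine_Y)
  r <- rle(as.logical(inside))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ks <- which(r$values)
  rows <- lapply(ks, function(k) {
    idx <- starts[k]:ends[k]
    mid <- idx[ceiling(length(idx) / 2)]
    data.frame(t_start = fine_t[starts[k]], t_end = fine_t[ends[k]],
               S_mid = fine_S[mid], Y_mid = fine_Y[mid])
  })
  if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(t_start = numeric(0), t_end = numeric(0),
               S_mid = numeric(0), Y_mid = numeric(0))
  }
}

#' @export
print.differentiation_trajectory <- function(x, ...) {
  cat(sprintf("Differentiation trajectory of cell (%d, %d): %d time points\n",
              x$cell_index["row"], x$cell_index["col"], length(x$times)))
  cat(sprintf("  S: %.3f -> %.3f,  Y: %.3f -> %.3f\n",
              x$S_values[1], x$S_values[length(x$S_values)],
              x$Y_values[1], x$Y_values[length(x$Y_values)]))
  if (!is.null(x$crossings)) {
    cat(sprintf("  in-region crossings: %d\n", nrow(x$crossings)))
  }
  invisible(x)
}

#' Select a Turing state on a differentiation trajectory
#'
#' Returns the frozen (S, Y) context to hand to [simulate_ai()]. The
#' default rule takes the in-region point at the midpoint of the longest
#' in-region crossing; `override = c(S, Y)` injects an explicit state
#' instead (still validated against the Turing conditions).
#'
#' @param traj A `differentiation_trajectory`.
#' @param region A `turing_region_map` (provides the kinetic parameters).
#' @param override Optional numeric `c(S, Y)` to inject.
#' @return An [ai_context()] satisfying the Turing conditions.
#' @section Errors: `trajectory_misses_region` if no trajectory point lies
#'   inside the region (and no override is given), or the override itself
#'   is out of region.
#' @export
select_turing_state <- function(traj, region, override = NULL) {
  stopifnot(inherits(region, "turing_region_map"))
  if (!is.null(override)) {
    stopifnot(is.numeric(override), length(override) == 2)
    ctx <- ai_context(region$params, override[1], override[2])
    if (!turing_conditions(ctx)$overall) {
      stop_custom("trajectory_misses_region",
                  sprintf("override point (%g, %g) is outside the Turing region",
                          override[1], override[2]))
    }
    return(ctx)
  }
  stopifnot(inherits(traj, "differentiation_trajectory"))
  cr <- if (is.null(traj$crossings)) {
    trajectory_crossings(traj, region)
  } else {
    traj$crossings
  }
  if (nrow(cr) == 0) {
    stop_custom("trajectory_misses_region",
                "trajectory has no point inside the Turing region")
  }
  longest <- which.max(cr$t_end - cr$t_start)
  ai_context(region$params, cr$S_mid[longest], cr$Y_mid[longest])
}
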