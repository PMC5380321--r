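# Spatial discretisation: grid specification, five-point Laplacian, and
# field-state containers.

#' Grid specification
#'
#' @param nx,ny Grid dimensions in cells (>= 16).
#' @param dx Spatial step in grid length units; the dimensionless diffusion
#'   coefficients assume `dx = 1`.
#' @param boundary `"periodic"` (wrap) or `"zero-flux"` (mirrored ghost
#'   cells: the ghost equals the adjacent interior cell, giving no flux
#'   across the boundary face).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(nx = 200, ny = nx, dx = 1,
                      boundary = c("periodic", "zero-flux")) {
  boundary <- match.arg(boundary)
  stopifnot(nx >= 16, ny >= 16, dx > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, boundary = boundary),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("%d x %d grid, dx = %g, %s boundary\n",
              x$ny, x$nx, x$dx, x$boundary))
  invisible(x)
}

# Row/column index shifted by `by` under the grid's boundary rule.
shift_index <- function(n, by, boundary) {
  i <- seq_len(n) + by
  if (boundary == "periodic") ((i - 1) %% n) + 1 else pmin(pmax(i, 1L), n)
}

#' Discrete Laplacian
#'
#' Five-point stencil `(up + down + left + right - 4 center) / dx^2` with
#' periodic wrap or mirrored ghost cells according to the grid's boundary
#' mode. Fields are stored as `ny x nx` matrices (rows = y).
#'
#' @param field Numeric matrix of shape `(ny, nx)`.
#' @param grid A [grid_spec()].
#' @return Matrix of the same shape.
#' @export
laplacian <- function(field, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(field) || nrow(field) != grid$ny || ncol(field) != grid$nx) {
    stop("field shape does not match grid (expected ",
         grid$ny, " x ", grid$nx, ")", call. = FALSE)
  }
  b <- grid$boundary
  up <- field[shift_index(grid$ny, -1L, b), , drop = FALSE]
  down <- field[shift_index(grid$ny, 1L, b), , drop = FALSE]
  left <- field[, shift_index(grid$nx, -1L, b), drop = FALSE]
  right <- field[, shift_index(grid$nx, 1L, b), drop = FALSE]
  (up + down + left + right - 4 * field) / grid$dx^2
}

#' Snapshot of the four concentration fields
#'
#' For the full branching model all four components are `ny x nx`
#' matrices. For the decoupled activator-inhibitor model `S` and `Y` are
#' the frozen scalar parameters.
#'
#' @param A,H,S,Y Concentration fields (matrices, or scalars for frozen
#'   S/Y).
#' @param t Simulation time of the snapshot.
#' @return Object of class `field_state`.
#' @export
field_state <- function(A, H, S, Y, t = 0) {
  stopifnot(is.matrix(A), is.matrix(H), all(dim(A) == dim(H)))
  for (x in list(S, Y)) {
    stopifnot(is.numeric(x))
    if (is.matrix(x)) stopifnot(all(dim(x) == dim(A)))
  }
  structure(list(A = A, H = H, S = S, Y = Y, t = t), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("Field state at t = %g (%d x %d)\n",
              x$t, nrow(x$A), ncol(x$A)))
  for (nm in c("A", "H", "S", "Y")) {
    v <- x[[nm]]
    cat(sprintf("  %s: [%.4g, %.4g]%s\n", nm, min(v), max(v),
                if (is.matrix(v)) "" else " (frozen)"))
  }
  invisible(x)
}

# Default explicit-Euler time step: diffusion stability bound
# dx^2 / (4 max D) with safety factor 0.2.
default_dt <- function(params, grid, which = c("branching", "ai")) {
  which <- match.arg(which)
  Dmax <- if (which == "branching") {
    max(params$D_A, params$D_H, params$D_S)
  } else {
    max(params$D_A, params$D_H)
  }
  0.2 * grid$dx^2 / (4 * Dmax)
}
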