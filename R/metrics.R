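# Pattern quantification: connected components, spot counting, pattern
# classification, gradient statistics, radial power spectra, skeletons and
# branching-event classification.

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation (vectorised over the whole mask), 8-
#' or 4-connected. Suitable for the moderate grids used here; converges in
#' O(component diameter) sweeps.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @param periodic Treat the mask as wrapping at its edges.
#' @return List with `labels` (integer matrix, 0 = background, components
#'   numbered 1..n) and `n`.
#' @export
label_components <- function(mask, connectivity = 8, periodic = FALSE) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  ny <- nrow(mask)
  nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (!any(mask)) return(list(labels = lab, n = 0L))
  lab[mask] <- seq_len(sum(mask))
  lab_num <- matrix(as.numeric(lab), ny, nx)
  lab_num[!mask] <- Inf
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  pad <- function(m, di, dj) {
    if (periodic) {
      return(m[((seq_len(ny) + di - 1) %% ny) + 1,
               ((seq_len(nx) + dj - 1) %% nx) + 1, drop = FALSE])
    }
    # shifted copy with Inf outside
    out <- matrix(Inf, ny, nx)
    ri <- seq_len(ny) + di
    cj <- seq_len(nx) + dj
    keep_i <- ri >= 1 & ri <= ny
    keep_j <- cj >= 1 & cj <= nx
    out[which(keep_i), which(keep_j)] <- m[ri[keep_i], cj[keep_j]]
    out
  }
  repeat {
    nb <- lab_num
    for (s in shifts) nb <- pmin(nb, pad(lab_num, s[1], s[2]))
    nb[!mask] <- Inf
    if (all(nb >= lab_num)) break
    lab_num <- pmin(lab_num, nb)
  }
  vals <- lab_num[mask]
  ids <- sort(unique(vals))
  lab[mask] <- match(vals, ids)
  list(labels = lab, n = length(ids))
}

#' Smooth a field with a 3x3 box filter
#'
#' One or more passes of a 3x3 mean filter, wrapping on periodic grids and
#' replicating the edge otherwise. Used before thresholding activator
#' fields whose spots are near-grid-scale spikes (the activator diffusion
#' length `sqrt(D_A/mu)` is a fraction of a cell at the default
#' parameters).
#'
#' @param field Numeric matrix.
#' @param grid A [grid_spec()] (controls the boundary rule).
#' @param passes Number of filter passes.
#' @return Smoothed matrix.
#' @export
smooth_field <- function(field, grid, passes = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  b <- grid$boundary
  for (p in seq_len(passes)) {
    acc <- matrix(0, nrow(field), ncol(field))
    for (di in -1:1) {
      ri <- shift_index(nrow(field), di, b)
      for (dj in -1:1) {
        acc <- acc + field[ri, shift_index(ncol(field), dj, b), drop = FALSE]
      }
    }
    field <- acc / 9
  }
  field
}

#' Count spots in a stationary pattern
#'
#' Thresholds at the midpoint of the field range, labels 8-connected
#' components of the high phase, and discards components of fewer than
#' `min_size` pixels. A degenerate field (range below `1e-9`) counts zero
#' spots.
#'
#' @param field Numeric matrix (typically the stationary activator field).
#' @param min_size Minimum component size in pixels.
#' @param periodic Wrap components across the field edges (use on fields
#'   from periodic simulations).
#' @return List with `n_spots`, `labels` (integer matrix) and `threshold`.
#' @export
count_spots <- function(field, min_size = 4, periodic = FALSE) {
  stopifnot(is.matrix(field))
  rng <- range(field)
  if (diff(rng) < 1e-9) {
    return(list(n_spots = 0L, labels = matrix(0L, nrow(field), ncol(field)),
                threshold = NA_real_))
  }
  thr <- mean(rng)
  lab <- label_components(field > thr, connectivity = 8, periodic = periodic)
  if (lab$n > 0) {
    sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$n)
    keep <- which(sizes >= min_size)
    new <- integer(lab$n)
    new[keep] <- seq_along(keep)
    lab$labels <- matrix(ifelse(lab$labels > 0, new[pmax(lab$labels, 1L)], 0L),
                         nrow(field), ncol(field))
    lab$n <- length(keep)
  }
  list(n_spots = lab$n, labels = lab$labels, threshold = thr)
}

# Elongation of one labelled component: sqrt of the ratio of the principal
# second moments of its pixel coordinates (1 = round, large = stripe-like).
component_elongation <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  cv <- stats::cov(idx) + diag(1 / 12, 2)  # pixel-area regularisation
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), 1e-12))
}

#' Classify a stationary Turing pattern
#'
#' Midpoint-threshold the field and inspect the phase fractions and the
#' shapes of the connected components: elongated components (median
#' major/minor axis ratio above `stripe_ratio`) are stripes; otherwise a
#' minority high phase of compact blobs is spots and the mirror case
#' (compact low-phase blobs in a high background) is holes. Degenerate
#' fields are uniform.
#'
#' @param field Numeric matrix.
#' @param stripe_ratio Elongation ratio above which components count as
#'   stripe segments.
#' @return One of `"spots"`, `"stripes"`, `"holes"`, `"uniform"`.
#' @export
classify_pattern <- function(field, stripe_ratio = 3) {
  stopifnot(is.matrix(field))
  rng <- range(field)
  if (diff(rng) < 1e-9) return("uniform")
  thr <- mean(rng)
  high <- field > thr
  high_frac <- mean(high)
  phase <- if (high_frac <= 0.5) high else !high
  lab <- label_components(phase, connectivity = 8)
  if (lab$n == 0) return("uniform")
  sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$n)
  ids <- which(sizes >= 4)
  if (length(ids) == 0) return("uniform")
  elong <- vapply(ids, function(i) component_elongation(lab$labels, i),
                  numeric(1))
  if (stats::median(elong) > stripe_ratio) return("stripes")
  if (high_frac <= 0.5) "spots" else "holes"
}

#' Spatial gradient statistics
#'
#' Central-difference gradient magnitude (one-sided at non-periodic edges,
#' wrapped on periodic grids).
#'
#' @param field Numeric matrix.
#' @param grid A [grid_spec()] matching the field.
#' @return List with `max_gradient` and `mean_gradient`.
#' @export
gradient_stats <- function(field, grid) {
  g <- gradient_field(field, grid)
  mag <- sqrt(g$gx^2 + g$gy^2)
  list(max_gradient = max(mag), mean_gradient = mean(mag))
}

gradient_field <- function(field, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(field) || nrow(field) != grid$ny || ncol(field) != grid$nx) {
    stop("field shape does not match grid", call. = FALSE)
  }
  dx <- grid$dx
  diff_axis <- function(m, along) {
    n <- if (along == "row") nrow(m) else ncol(m)
    if (grid$boundary == "periodic") {
      up <- shift_index(n, -1L, "periodic")
      dn <- shift_index(n, 1L, "periodic")
      if (along == "row") (m[dn, , drop = FALSE] - m[up, , drop = FALSE]) / (2 * dx)
      else (m[, dn, drop = FALSE] - m[, up, drop = FALSE]) / (2 * dx)
    } else {
      # central interior, one-sided at the edges
      if (along == "row") {
        out <- (m[shift_index(n, 1L, "zero-flux"), , drop = FALSE] -
                  m[shift_index(n, -1L, "zero-flux"), , drop = FALSE]) /
          (2 * dx)
        out[1, ] <- (m[2, ] - m[1, ]) / dx
        out[n, ] <- (m[n, ] - m[n - 1, ]) / dx
      } else {
        out <- (m[, shift_index(n, 1L, "zero-flux"), drop = FALSE] -
                  m[, shift_index(n, -1L, "zero-flux"), drop = FALSE]) /
          (2 * dx)
        out[, 1] <- (m[, 2] - m[, 1]) / dx
        out[, n] <- (m[, n] - m[, n - 1]) / dx
      }
      out
    }
  }
  list(gy = diff_axis(field, "row"), gx = diff_axis(field, "col"))
}

#' Dominant wavenumber from the radial power spectrum
#'
#' 2-D discrete Fourier transform, azimuthally averaged power in annular
#' wavenumber bins, peak bin excluding the mean (k = 0). A peak is flagged
#' low-confidence when it does not stand out of the background spectrum
#' (peak power below `confidence_ratio` times the median bin power), as for
#' white noise.
#'
#' @param field Numeric matrix on a periodic grid.
#' @param grid A [grid_spec()] (periodic).
#' @param confidence_ratio Peak-to-median power ratio required for a
#'   confident peak.
#' @return List with `dominant_wavenumber` (0 for degenerate fields),
#'   `confident`, `k_bins`, `power`.
#' @export
radial_spectrum_peak <- function(field, grid, confidence_ratio = 5) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(field) || nrow(field) != grid$ny || ncol(field) != grid$nx) {
    stop("field shape does not match grid", call. = FALSE)
  }
  if (diff(range(field)) < 1e-9) {
    return(list(dominant_wavenumber = 0, confident = FALSE,
                k_bins = numeric(0), power = numeric(0)))
  }
  ny <- grid$ny
  nx <- grid$nx
  P <- Mod(stats::fft(field - mean(field)))^2
  freq <- function(n) {
    m <- c(0:(n %/% 2), -((n - (n %/% 2) - 1):1))
    2 * pi * m / (n * grid$dx)
  }
  ky <- freq(ny)
  kx <- freq(nx)
  kr <- sqrt(outer(ky^2, kx^2, "+"))
  dk <- 2 * pi / (max(ny, nx) * grid$dx)
  bins <- matrix(pmax(1L, as.integer(round(kr / dk))), ny, nx)
  bins[1, 1] <- 0L  # exclude the mean
  nb <- max(bins)
  pw <- vapply(seq_len(nb), function(b) mean(P[bins == b]), numeric(1))
  ks <- seq_len(nb) * dk
  valid <- ks <= pi / grid$dx  # below the grid Nyquist wavenumber
  pw <- pw[valid]
  ks <- ks[valid]
  i <- which.max(pw)
  list(dominant_wavenumber = ks[i],
       confident = pw[i] > confidence_ratio * stats::median(pw),
       k_bins = ks, power = pw)
}

#' Summarise a stationary pattern
#'
#' Convenience bundle of [classify_pattern()], [count_spots()],
#' [radial_spectrum_peak()] and [gradient_stats()]. Thresholding-based
#' metrics (class, spot count) operate on a box-filtered copy of the field
#' by default, because the stationary activator patterns of this model are
#' near-grid-scale spikes; gradients and spectra use the raw field.
#'
#' @param field Numeric matrix (activator concentration).
#' @param grid A [grid_spec()].
#' @param presmooth Passes of the 3x3 box filter applied before
#'   thresholding (see [smooth_field()]); 0 disables.
#' @return List of class `pattern_summary` with `pattern_class`, `n_spots`,
#'   `dominant_wavenumber`, `spectrum_confident`, `max_gradient`,
#'   `mean_gradient`.
#' @export
pattern_summary <- function(field, grid, presmooth = 1) {
  sm <- if (presmooth > 0) smooth_field(field, grid, presmooth) else field
  sp <- count_spots(sm, periodic = grid$boundary == "periodic")
  cl <- classify_pattern(sm)
  gs <- gradient_stats(field, grid)
  rs <- if (grid$boundary == "periodic") {
    radial_spectrum_peak(field, grid)
  } else {
    list(dominant_wavenumber = NA_real_, confident = NA)
  }
  structure(list(pattern_class = cl, n_spots = sp$n_spots,
                 dominant_wavenumber = rs$dominant_wavenumber,
                 spectrum_confident = rs$confident,
                 max_gradient = gs$max_gradient,
                 mean_gradient = gs$mean_gradient),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("Pattern: %s, %d spot(s)\n", x$pattern_class, x$n_spots))
  cat(sprintf("  dominant wavenumber: %.4g (confident: %s)\n",
              x$dominant_wavenumber, x$spectrum_confident))
  cat(sprintf("  gradient max/mean: %.4g / %.4g\n",
              x$max_gradient, x$mean_gradient))
  invisible(x)
}

#' Morphological skeleton of a binary mask
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels that do not break
#' 8-connectivity until the one-pixel-wide skeleton remains.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask & !is.na(mask)) + 0L
  ny <- nrow(m)
  nx <- ncol(m)
  if (ny < 3 || nx < 3) return(mask & !is.na(mask))
  pad0 <- function(mm, di, dj) {
    out <- matrix(0L, ny, nx)
    ri <- seq_len(ny) + di
    cj <- seq_len(nx) + dj
    keep_i <- ri >= 1 & ri <= ny
    keep_j <- cj >= 1 & cj <= nx
    out[which(keep_i), which(keep_j)] <- mm[ri[keep_i], cj[keep_j]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north
      P2 <- pad0(m, -1, 0); P3 <- pad0(m, -1, 1); P4 <- pad0(m, 0, 1)
      P5 <- pad0(m, 1, 1);  P6 <- pad0(m, 1, 0);  P7 <- pad0(m, 1, -1)
      P8 <- pad0(m, 0, -1); P9 <- pad0(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A01 <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) +
        (P4 == 0 & P5 == 1) + (P5 == 0 & P6 == 1) +
        (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (pass == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A01 == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A01 == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Skeleton endpoints (tips)
#'
#' Pixels of a skeleton with at most one 8-connected skeleton neighbour
#' (isolated pixels count as tips).
#'
#' @param skeleton Logical matrix, typically from [thin_mask()].
#' @return Integer matrix with columns `row`, `col` (0 rows when none).
#' @export
skeleton_endpoints <- function(skeleton) {
  stopifnot(is.matrix(skeleton))
  m <- (skeleton & !is.na(skeleton)) + 0L
  ny <- nrow(m)
  nx <- ncol(m)
  mp <- matrix(0L, ny + 2, nx + 2)
  mp[2:(ny + 1), 2:(nx + 1)] <- m
  nb <- matrix(0L, ny, nx)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- nb + mp[2:(ny + 1) + di, 2:(nx + 1) + dj]
    }
  }
  which(m == 1L & nb <= 1L, arr.ind = TRUE)
}

#' Classify branching events in a branching-model run
#'
#' Per snapshot, the differentiated region (`Y` above `y_threshold`) is
#' skeletonized, short spurs are pruned, and the remaining skeleton
#' endpoints are taken as branch tips. Between successive snapshots the
#' tips are matched greedily by distance; when the tip count increases,
#' each unmatched new tip fires an event, provided a tip persists near the
#' same position in the following snapshot (which suppresses flickering
#' skeleton artifacts).
#'
#' The event kind is decided by the age of the tissue the new branch grows
#' from: a `tip_bifurcation` stands on freshly differentiated tissue (the
#' advancing front just laid it down), while a `side_branch` sprouts from
#' stalk that differentiated long before. Concretely, the maximum time
#' since threshold crossing within `attach_radius` of the event site is
#' compared against `age_threshold`. A plain nearest-tip-distance rule is
#' not discriminating in this model because both morphologies are dense
#' trees in which any new tip lies near some existing tip.
#'
#' The overall mode is decided by dominance: `tip` when at most a fraction
#' `hybrid_tolerance` of events are side branches, `side` for the mirror
#' case, `hybrid` when both kinds occur in substantial proportion, `none`
#' without events.
#'
#' @param sim A `sim_result` from [simulate_branching()] with snapshots.
#' @param y_threshold Binarisation level for `Y`; default half the maximum
#'   of the final `Y` field.
#' @param r_tip Tip-tracking radius in grid length units (converted to
#'   pixels through the grid spacing): new-tip novelty matching and
#'   next-snapshot confirmation both use it.
#' @param age_threshold Tissue age (time units) above which the attachment
#'   site counts as old stalk; calibrated on the reference morphologies
#'   (front-adjacent tissue is < 200 time units old at the default growth
#'   speeds, mother stalks of laterals are > 450 old).
#' @param attach_radius Radius (length units) of the neighbourhood whose
#'   oldest tissue defines the attachment age.
#' @param hybrid_tolerance Largest minority-kind fraction still labelled a
#'   pure mode.
#' @param prune Spur-pruning depth in pixels.
#' @param min_pixels Snapshots whose differentiated region is smaller than
#'   this are skipped (no meaningful skeleton yet).
#' @return Object of class `branch_report`: `events` (data.frame with
#'   `time`, `row`, `col`, `attach_age`, `kind`), `n_tips_over_time`
#'   (data.frame `time`, `n_tips`), `overall_mode` in
#'   `tip | side | hybrid | none`.
#' @export
classify_branch_events <- function(sim, y_threshold = NULL, r_tip = 5,
                                   age_threshold = 300, attach_radius = 2,
                                   hybrid_tolerance = 0.1,
                                   prune = 3, min_pixels = 9) {
  stopifnot(inherits(sim, "sim_result"))
  ymax <- max(sim$final$Y)
  if (is.null(y_threshold)) {
    # relative default; a run whose differentiation never switched on
    # (ymax far below the high-Y branch of the bistable switch) has no
    # structure to skeletonize
    if (ymax < 0.1) stop_custom("no_structure", "Y never switched high")
    y_threshold <- 0.5 * ymax
  }
  if (ymax < y_threshold || ymax <= 0) {
    stop_custom("no_structure", "Y never exceeds the threshold")
  }
  r_px <- r_tip / sim$grid$dx
  a_px <- max(1L, as.integer(round(attach_radius / sim$grid$dx)))
  ny <- nrow(sim$final$Y)
  nx <- ncol(sim$final$Y)
  first_t <- matrix(Inf, ny, nx)  # when each cell first crossed threshold
  times <- numeric(0)
  tip_list <- list()
  for (s in sim$snapshots) {
    mask <- s$Y > y_threshold
    newly <- mask & !is.finite(first_t)
    first_t[newly] <- s$t
    if (sum(mask) < min_pixels) next
    sk <- prune_spurs(thin_mask(mask), prune)
    times <- c(times, s$t)
    tip_list[[length(tip_list) + 1]] <- skeleton_endpoints(sk)
  }
  n_tips <- vapply(tip_list, nrow, integer(1))
  attach_age <- function(time, row, col) {
    rr <- max(1, row - a_px):min(ny, row + a_px)
    cc <- max(1, col - a_px):min(nx, col + a_px)
    a <- time - first_t[rr, cc]
    a <- a[is.finite(a) & a >= 0]
    if (length(a)) max(a) else 0
  }
  events <- list()
  for (j in seq_along(tip_list)[-1]) {
    tips <- tip_list[[j]]
    prev_tips <- tip_list[[j - 1]]
    if (nrow(tips) <= nrow(prev_tips) || nrow(prev_tips) == 0) next
    for (i in unmatched_tips(tips, prev_tips)) {
      # confirmation: a tip must persist near this position next snapshot
      if (j < length(tip_list)) {
        nxt <- tip_list[[j + 1]]
        if (nrow(nxt) == 0) next
        d_next <- sqrt(min((nxt[, 1] - tips[i, 1])^2 +
                             (nxt[, 2] - tips[i, 2])^2))
        if (d_next > r_px) next
      }
      age <- attach_age(times[j], tips[i, 1], tips[i, 2])
      events[[length(events) + 1]] <-
        data.frame(time = times[j], row = tips[i, 1], col = tips[i, 2],
                   attach_age = age,
                   kind = if (age > age_threshold) "side_branch" else "tip_bifurcation",
                   stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(time = numeric(0), row = integer(0), col = integer(0),
               attach_age = numeric(0), kind = character(0),
               stringsAsFactors = FALSE)
  }
  side_frac <- if (nrow(ev)) mean(ev$kind == "side_branch") else NA
  mode <- if (nrow(ev) == 0) "none"
  else if (side_frac <= hybrid_tolerance) "tip"
  else if (side_frac >= 1 - hybrid_tolerance) "side"
  else "hybrid"
  structure(list(events = ev,
                 n_tips_over_time = data.frame(time = times, n_tips = n_tips),
                 overall_mode = mode, side_fraction = side_frac,
                 y_threshold = y_threshold, r_tip = r_tip,
                 age_threshold = age_threshold),
            class = "branch_report")
}

# Remove skeleton spurs shorter than `depth` pixels by iteratively
# deleting endpoint pixels.
prune_spurs <- function(skeleton, depth) {
  m <- skeleton
  for (i in seq_len(depth)) {
    ep <- skeleton_endpoints(m)
    if (nrow(ep) == 0) break
    m[ep] <- FALSE
  }
  m
}

# Indices of tips in `cur` left unmatched after greedy injective
# nearest-distance matching against `prev`.
unmatched_tips <- function(cur, prev) {
  if (nrow(cur) == 0) return(integer(0))
  if (nrow(prev) == 0) return(seq_len(nrow(cur)))
  d <- outer(seq_len(nrow(cur)), seq_len(nrow(prev)),
             Vectorize(function(i, j) {
               sqrt((cur[i, 1] - prev[j, 1])^2 + (cur[i, 2] - prev[j, 2])^2)
             }))
  d <- matrix(d, nrow = nrow(cur))
  matched <- logical(nrow(cur))
  used_prev <- logical(nrow(prev))
  for (rep in seq_len(min(nrow(cur), nrow(prev)))) {
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    matched[i[1]] <- TRUE
    used_prev[i[2]] <- TRUE
    d[i[1], ] <- Inf
    d[, i[2]] <- Inf
  }
  which(!matched)
}

#' @export
print.branch_report <- function(x, ...) {
  cat(sprintf("Branching events: %d (%s mode)\n", nrow(x$events),
              x$overall_mode))
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}
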