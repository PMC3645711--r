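#' Partition lipids into upper and lower leaflets
#'
#' A lipid belongs to the upper leaflet iff the z coordinate of its headgroup
#' center atom is at or above the z centroid of all headgroup centers in the
#' reference frame. The assignment is made once on the reference frame and
#' held fixed for the whole analysis: lipid flip-flop is far slower than the
#' hundred-nanosecond timescales analysed here and is deliberately not
#' tracked.
#'
#' @param trajectory A `bl_trajectory` whose topology has assigned roles.
#' @param reference_frame 1-based frame index used for the assignment.
#' @return A `bl_leaflets` list with integer vectors `upper` and `lower` of
#'   lipid residue ids, and `reference_frame`.
#' @export
assign_leaflets <- function(trajectory, reference_frame = 1L) {
  lip <- trajectory$topology$lipids
  if (nrow(lip) == 0) stop("topology has no lipids; run assign_roles() first")
  z <- trajectory$coords[lip$head, 3, reference_frame]
  zc <- mean(z)
  structure(
    list(
      upper = lip$resid[z >= zc],
      lower = lip$resid[z < zc],
      reference_frame = as.integer(reference_frame)
    ),
    class = "bl_leaflets"
  )
}

#' @export
print.bl_leaflets <- function(x, ...) {
  cat(sprintf(
    "<leaflet assignment> upper: %d lipids, lower: %d lipids (reference frame %d)\n",
    length(x$upper), length(x$lower), x$reference_frame
  ))
  invisible(x)
}

leaflet_head_idx <- function(trajectory, leaflets) {
  lip <- trajectory$topology$lipids
  list(
    upper = lip$head[match(leaflets$upper, lip$resid)],
    lower = lip$head[match(leaflets$lower, lip$resid)]
  )
}

#' Area per lipid time series
#'
#' The per-frame area per lipid is the lateral box area divided by the number
#' of lipids in a leaflet, `Lx * Ly / n_leaflet`. When the two leaflets hold
#' different numbers of lipids the two per-leaflet values are averaged.
#'
#' @param trajectory A `bl_trajectory`.
#' @param leaflets A `bl_leaflets` from [assign_leaflets()].
#' @param window `c(start, end)` in ns, or `NULL` for the latter half of the
#'   trajectory (the conventional production window).
#' @return A `bl_timeseries` tibble (`time`, `value` in angstrom^2) with
#'   `mean`, `sd` and `window` attributes over the analysis window.
#' @export
area_per_lipid <- function(trajectory, leaflets, window = NULL) {
  n_up <- length(leaflets$upper)
  n_lo <- length(leaflets$lower)
  if (n_up == 0 || n_lo == 0) stop("both leaflets must be nonempty")
  w <- resolve_window(trajectory, window)
  lat <- trajectory$box[w$idx, 1] * trajectory$box[w$idx, 2]
  vals <- (lat / n_up + lat / n_lo) / 2
  new_timeseries(trajectory$times[w$idx], vals, w$window,
                 list(quantity = "area_per_lipid", units = "A^2"))
}

#' Membrane thickness time series
#'
#' For every lipid, the thickness contribution is the shortest 3-D Euclidean
#' distance between its headgroup center atom and the headgroup center atoms
#' of all lipids in the opposite leaflet; the per-frame thickness is the mean
#' of these shortest distances. Distances are minimum-imaged laterally (x, y)
#' only: imaging in z would wrap across the water slab and corrupt the
#' minimum.
#'
#' @inheritParams area_per_lipid
#' @param leaflet Which leaflet's lipids to average over: `"both"` (default,
#'   symmetric) or `"upper"`/`"lower"`.
#' @return A `bl_timeseries` tibble (`time`, `value` in angstrom).
#' @export
membrane_thickness <- function(trajectory, leaflets, window = NULL,
                               leaflet = c("both", "upper", "lower")) {
  leaflet <- match.arg(leaflet)
  heads <- leaflet_head_idx(trajectory, leaflets)
  if (length(heads$upper) == 0 || length(heads$lower) == 0) {
    stop("both leaflets must be nonempty")
  }
  w <- resolve_window(trajectory, window)
  vals <- vapply(w$idx, function(m) {
    up <- trajectory$coords[heads$upper, , m, drop = FALSE][, , 1, drop = TRUE]
    lo <- trajectory$coords[heads$lower, , m, drop = FALSE][, , 1, drop = TRUE]
    up <- matrix(up, ncol = 3)
    lo <- matrix(lo, ncol = 3)
    D <- pair_dist_matrix(up, lo, trajectory$box[m, ], image = c(TRUE, TRUE, FALSE))
    d_upper <- apply(D, 1, min)
    d_lower <- apply(D, 2, min)
    switch(leaflet,
      both = mean(c(d_upper, d_lower)),
      upper = mean(d_upper),
      lower = mean(d_lower)
    )
  }, numeric(1))
  new_timeseries(trajectory$times[w$idx], vals, w$window,
                 list(quantity = "membrane_thickness", units = "A"))
}

#' z-density profiles relative to the bilayer center
#'
#' Histograms the z positions of named atom groups relative to the bilayer
#' center (the per-frame z centroid of all lipid headgroup center atoms),
#' either signed (`z - z_center`) or unsigned (`|z - z_center|`), normalized
#' to mean atoms per frame per angstrom.
#'
#' @inheritParams area_per_lipid
#' @param groups Named list of atom index vectors (1-based rows of the atom
#'   table, e.g. from [select_atoms()]).
#' @param bin_width Histogram bin width in angstrom (default 0.5).
#' @param signed Signed distances (default) or absolute distances.
#' @return A `bl_density_profile` tibble with columns `group`, `z`
#'   (bin center, angstrom) and `density` (atoms per frame per angstrom).
#' @export
density_profile <- function(trajectory, groups, window = NULL,
                            bin_width = 0.5, signed = TRUE) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(groups) == 0 || any(lengths(groups) == 0)) {
    stop("groups must be a nonempty named list of nonempty atom selections")
  }
  lip <- trajectory$topology$lipids
  if (nrow(lip) == 0) stop("topology has no lipids; run assign_roles() first")
  w <- resolve_window(trajectory, window)
  nfr <- length(w$idx)

  zc <- colMeans(matrix(trajectory$coords[lip$head, 3, w$idx], nrow = length(lip$head)))

  out <- purrr::imap(groups, function(sel, gname) {
    dz <- trajectory$coords[sel, 3, w$idx, drop = FALSE][, 1, , drop = TRUE]
    dz <- matrix(dz, nrow = length(sel))
    dz <- sweep(dz, 2, zc, "-")
    if (!signed) dz <- abs(dz)
    rng <- range(dz)
    breaks <- seq(
      floor(rng[1] / bin_width) * bin_width,
      ceiling(rng[2] / bin_width) * bin_width + bin_width,
      by = bin_width
    )
    h <- graphics::hist(as.vector(dz), breaks = breaks, plot = FALSE)
    tibble::tibble(
      group = gname, z = h$mids,
      density = h$counts / (nfr * bin_width)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "bin_width") <- bin_width
  attr(res, "signed") <- signed
  attr(res, "n_frames") <- nfr
  attr(res, "window") <- w$window
  class(res) <- c("bl_density_profile", class(res))
  res
}

#' Centered moving-window average of a time series
#'
#' The smoothing used for presentation of area/thickness traces: each point
#' is replaced by the mean of all points within half a window on either
#' side; windows are truncated at the series edges.
#'
#' @param series A `bl_timeseries` (or any tibble with `time` and `value`).
#' @param window_ns Window length in ns (default 5).
#' @return The input with a `window_mean` column added.
#' @export
window_average <- function(series, window_ns = 5) {
  if (nrow(series) == 0) stop("empty series")
  if (nrow(series) > 1 && window_ns < min(diff(series$time))) {
    stop("window_ns is smaller than the frame spacing")
  }
  half <- window_ns / 2
  sm <- vapply(series$time, function(t0) {
    mean(series$value[series$time >= t0 - half & series$time <= t0 + half])
  }, numeric(1))
  series$window_mean <- sm
  attr(series, "smoothing_window_ns") <- window_ns
  series
}
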