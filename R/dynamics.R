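# Headgroup rotational dynamics, tilt statistics and lateral diffusion.

# Unit headgroup-to-choline vectors for every lipid over a set of frames:
# array n_lipids x 3 x n_frames. Bonded vectors are minimum-imaged so that
# lipids straddling a periodic boundary in wrapped coordinates give the true
# intramolecular vector.
head_vectors <- function(trajectory, frames) {
  lip <- trajectory$topology$lipids
  if (nrow(lip) == 0) stop("topology has no lipids; run assign_roles() first")
  v <- trajectory$coords[lip$choline_n, , frames, drop = FALSE] -
    trajectory$coords[lip$head, , frames, drop = FALSE]
  n <- nrow(lip)
  for (ax in 1:3) {
    L <- rep(trajectory$box[frames, ax], each = n)
    v[, ax, ] <- v[, ax, ] - L * round(as.vector(v[, ax, ]) / L)
  }
  nrm <- sqrt(v[, 1, , drop = FALSE]^2 + v[, 2, , drop = FALSE]^2 + v[, 3, , drop = FALSE]^2)
  if (any(nrm == 0)) {
    stop("zero-length headgroup-to-choline vector (coincident atoms)")
  }
  v / nrm[, rep(1, 3), , drop = FALSE]
}

#' Headgroup rotational autocorrelation function
#'
#' The rotational autocorrelation of the unit headgroup-center-to-choline-N
#' vector (P->N, or As->N for an arsenocholine lipid):
#' `RAF(t) = < v(t_o) . v(t_o + t) >`, averaged over all lipids and over
#' multiple time origins `t_o`. The maximum lag is half the analysis window,
#' so that every lag is estimated from the same number of origins (the
#' "same amount of data" convention); `RAF(0) = 1` exactly for unit vectors.
#'
#' @inheritParams area_per_lipid
#' @param origin_stride Use every `origin_stride`-th frame as a time origin
#'   (default 1 = all origins; larger strides trade variance for speed).
#' @return A `bl_raf` tibble: `lag` (ns), `raf`, `n_origins`; attributes
#'   `t_max` and `vector` (definition stamp).
#' @export
head_vector_raf <- function(trajectory, leaflets, window = NULL,
                            origin_stride = 1L) {
  w <- resolve_window(trajectory, window)
  if (length(w$idx) < 2) stop("at least 2 frames required in the window")
  dt <- frame_dt_window(trajectory, w$idx)
  U <- head_vectors(trajectory, w$idx)
  nw <- length(w$idx)
  max_lag <- floor(nw / 2)           # lags 0 .. max_lag frames
  n_origin_frames <- nw - max_lag    # every lag uses the same origins
  origins <- seq(1L, n_origin_frames, by = as.integer(origin_stride))

  raf <- vapply(0:max_lag, function(l) {
    dots <- U[, 1, origins, drop = FALSE] * U[, 1, origins + l, drop = FALSE] +
      U[, 2, origins, drop = FALSE] * U[, 2, origins + l, drop = FALSE] +
      U[, 3, origins, drop = FALSE] * U[, 3, origins + l, drop = FALSE]
    mean(dots)
  }, numeric(1))

  out <- tibble::tibble(
    lag = (0:max_lag) * dt, raf = raf,
    n_origins = length(origins)
  )
  attr(out, "t_max") <- max_lag * dt
  attr(out, "vector") <- "unit headgroup_center -> choline_N"
  attr(out, "window") <- w$window
  class(out) <- c("bl_raf", class(out))
  out
}

frame_dt_window <- function(trajectory, idx) {
  dt <- diff(trajectory$times[idx])
  if (diff(range(dt)) > 1e-6 * max(mean(dt), 1e-12)) {
    stop("non-uniform frame spacing in the analysis window")
  }
  mean(dt)
}

#' Fit a stretched-exponential (KWW) relaxation to an autocorrelation decay
#'
#' Fits `RAF(t) = exp(-(t/tau)^beta)` by the standard linearization: an
#' unweighted least-squares line of `ln(-ln RAF)` against `ln t` (t in ns)
#' over the lags where the RAF lies inside `fit_bounds`. The slope is `beta`
#' and the `t = 1 ns` intercept is `-beta ln tau`, so `tau =
#' exp(-intercept/beta)`. The early (RAF near 1) and late (RAF near 0)
#' regions are excluded by the default bounds because the stretched
#' exponential describes neither well.
#'
#' @param raf A `bl_raf` (or tibble with `lag` and `raf`).
#' @param fit_bounds RAF-value range used for fitting (default
#'   `c(0.05, 0.95)`).
#' @return A `bl_kww` object: `tau` (ns), `beta`, `fit_window` (lag range
#'   used, ns), `n_points`, `rss` (residual sum of squares on the linearized
#'   scale), `converged`.
#' @export
kww_fit <- function(raf, fit_bounds = c(0.05, 0.95)) {
  # the fit window is the contiguous lag range between the first crossing of
  # the upper bound and the first crossing of the lower bound: for a
  # monotone decay this is exactly "lags where RAF lies inside the bounds",
  # and for a noisy decay it avoids the selection bias of re-admitting
  # upward noise excursions beyond the first low-bound crossing
  below_hi <- raf$lag > 0 & raf$raf < fit_bounds[2]
  start <- match(TRUE, below_hi)
  crossed_lo <- raf$raf <= fit_bounds[1] | raf$raf <= 0
  end_candidates <- which(crossed_lo & seq_along(crossed_lo) >= (start %||% 1L))
  end <- if (length(end_candidates)) end_candidates[1] - 1L else nrow(raf)
  usable <- rep(FALSE, nrow(raf))
  if (!is.na(start) && end >= start) usable[start:end] <- TRUE
  usable <- usable & raf$lag > 0 & raf$raf > 0 & raf$raf < 1
  if (sum(usable) < 3) {
    return(structure(
      list(
        tau = NA_real_, beta = NA_real_, fit_window = c(NA_real_, NA_real_),
        n_points = sum(usable), rss = NA_real_, converged = FALSE
      ),
      class = "bl_kww"
    ))
  }
  x <- log(raf$lag[usable])
  y <- log(-log(raf$raf[usable]))
  fit <- stats::lm(y ~ x)
  beta <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tau <- exp(-intercept / beta)
  structure(
    list(
      tau = tau, beta = beta,
      fit_window = range(raf$lag[usable]),
      n_points = sum(usable),
      rss = sum(stats::residuals(fit)^2),
      converged = is.finite(tau) && beta > 0
    ),
    class = "bl_kww"
  )
}

#' @export
print.bl_kww <- function(x, ...) {
  if (!x$converged) {
    cat("<KWW fit> not converged (", x$n_points, " usable lags)\n", sep = "")
  } else {
    cat(sprintf(
      "<KWW fit> tau = %.4g ns, beta = %.4g (%d lags in [%.3g, %.3g] ns, rss = %.3g)\n",
      x$tau, x$beta, x$n_points, x$fit_window[1], x$fit_window[2], x$rss
    ))
  }
  invisible(x)
}

#' Headgroup tilt-angle statistics
#'
#' The angle between the unit headgroup-center-to-choline-N vector and the
#' outward leaflet normal (+z for the upper leaflet, -z for the lower, so
#' the two leaflets pool consistently), sampled over all lipids and frames.
#'
#' @inheritParams area_per_lipid
#' @param bin_width Histogram bin width in degrees (default 2).
#' @return A `bl_tilt` tibble histogram (`angle` bin center in degrees,
#'   `density`), with attributes `mean`, `sd`, `n_samples`.
#' @export
tilt_statistics <- function(trajectory, leaflets, window = NULL, bin_width = 2) {
  w <- resolve_window(trajectory, window)
  U <- head_vectors(trajectory, w$idx)
  lip <- trajectory$topology$lipids
  sign_z <- ifelse(lip$resid %in% leaflets$upper, 1, -1)
  cosang <- U[, 3, , drop = TRUE] * sign_z
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  breaks <- seq(0, 180 + bin_width, by = bin_width)
  h <- graphics::hist(as.vector(ang), breaks = breaks, plot = FALSE)
  out <- tibble::tibble(angle = h$mids, density = h$density)
  attr(out, "mean") <- mean(ang)
  attr(out, "sd") <- stats::sd(as.vector(ang))
  attr(out, "n_samples") <- length(ang)
  attr(out, "window") <- w$window
  class(out) <- c("bl_tilt", class(out))
  out
}

#' @export
print.bl_tilt <- function(x, ...) {
  cat(sprintf(
    "<tilt statistics> %.4g deg +/- %.4g deg (%d samples)\n",
    attr(x, "mean"), attr(x, "sd"), attr(x, "n_samples")
  ))
  NextMethod()
}

# Per-lipid mass-weighted centers of mass in x,y over a frame set, unwrapped:
# whenever a frame-to-frame COM displacement exceeds half the box edge the
# periodic jump is removed. Returns list(x, y): n_frames x n_lipids matrices.
lipid_com_xy_unwrapped <- function(trajectory, frames, warn_quarter_box = TRUE) {
  lip <- trajectory$topology$lipids
  atoms <- trajectory$topology$atoms
  nfr <- length(frames)
  nl <- nrow(lip)
  X <- matrix(0, nfr, nl)
  Y <- matrix(0, nfr, nl)
  for (li in seq_len(nl)) {
    sel <- which(atoms$resid == lip$resid[li] & atoms$resname == lip$resname[li])
    mass <- atom_mass(atoms$element[sel])
    # wrap each atom to the lipid's headgroup image before averaging, so the
    # COM of a boundary-straddling lipid is not an artifact of wrapping
    refx <- trajectory$coords[lip$head[li], 1, frames]
    refy <- trajectory$coords[lip$head[li], 2, frames]
    cx <- matrix(trajectory$coords[sel, 1, frames], nrow = length(sel))
    cy <- matrix(trajectory$coords[sel, 2, frames], nrow = length(sel))
    Lx <- trajectory$box[frames, 1]
    Ly <- trajectory$box[frames, 2]
    cx <- cx - rep(Lx, each = length(sel)) * round(sweep(cx, 2, refx, "-") / rep(Lx, each = length(sel)))
    cy <- cy - rep(Ly, each = length(sel)) * round(sweep(cy, 2, refy, "-") / rep(Ly, each = length(sel)))
    X[, li] <- colSums(cx * mass) / sum(mass)
    Y[, li] <- colSums(cy * mass) / sum(mass)
  }
  # unwrap COM tracks across frames
  unwrap <- function(M, L) {
    if (nrow(M) < 2) return(M)
    d <- diff(M)
    jump <- -L[-1] * round(d / L[-1])
    if (warn_quarter_box && any(abs(d + jump) > L[-1] / 4)) {
      warning("raw COM displacement exceeds a quarter box edge; unwrapping may be unreliable at this frame spacing")
    }
    M + rbind(0, apply(jump, 2, cumsum))
  }
  list(
    x = unwrap(X, trajectory$box[frames, 1]),
    y = unwrap(Y, trajectory$box[frames, 2])
  )
}

#' Lateral mean-square displacement of lipid centers of mass
#'
#' Per-lipid mass-weighted centers of mass in the membrane plane are
#' unwrapped across the periodic boundaries and
#' `MSD(t) = < [r(t_o + t) - r(t_o)]^2 >` is averaged over all lipids and
#' all time origins available for each lag.
#'
#' @inheritParams head_vector_raf
#' @param max_lag_fraction Longest lag as a fraction of the window length
#'   (default 0.5; longer lags average very few origins).
#' @return A `bl_msd` tibble: `lag` (ns), `msd` (angstrom^2), `n_origins`.
#' @export
msd_lateral <- function(trajectory, leaflets, window = NULL,
                        origin_stride = 1L, max_lag_fraction = 0.5) {
  w <- resolve_window(trajectory, window)
  if (length(w$idx) < 10) stop("at least 10 frames required for MSD analysis")
  dt <- frame_dt_window(trajectory, w$idx)
  com <- lipid_com_xy_unwrapped(trajectory, w$idx)
  nfr <- nrow(com$x)
  max_lag <- max(1L, floor(nfr * max_lag_fraction))

  msd <- numeric(max_lag + 1)
  n_origins <- integer(max_lag + 1)
  n_origins[1] <- nfr
  for (l in seq_len(max_lag)) {
    o <- seq(1L, nfr - l, by = as.integer(origin_stride))
    dx <- com$x[o + l, , drop = FALSE] - com$x[o, , drop = FALSE]
    dy <- com$y[o + l, , drop = FALSE] - com$y[o, , drop = FALSE]
    msd[l + 1] <- mean(dx^2 + dy^2)
    n_origins[l + 1] <- length(o)
  }
  out <- tibble::tibble(lag = (0:max_lag) * dt, msd = msd, n_origins = n_origins)
  attr(out, "com") <- "per-lipid mass-weighted COM in x,y, unwrapped"
  attr(out, "window") <- w$window
  class(out) <- c("bl_msd", class(out))
  out
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' In two dimensions `MSD(t) = 4 D t`, so `D_xy` is a quarter of the slope
#' of an unweighted least-squares line fitted over the chosen lag window
#' (default 10 percent to 50 percent of the maximum lag, skipping the
#' short-time regime and the origin-starved tail). Reported both in
#' angstrom^2/ns and in cm^2/s (`1 A^2/ns = 1e-7 cm^2/s`). Two linearity
#' diagnostics are attached: the R^2 of the fit and the log-log slope
#' `alpha` (1 for diffusive, 2 for ballistic motion); `nonlinear` is set
#' when either flags a departure from `MSD ~ t`.
#'
#' @param msd A `bl_msd` (or tibble with `lag` and `msd`).
#' @param fit_window `c(lo, hi)` fractions of the maximum lag (default
#'   `c(0.1, 0.5)`).
#' @return A `bl_diffusion` object: `D_A2_ns`, `D_cm2_s`, `r_squared`,
#'   `alpha`, `nonlinear`, `negative_slope`, `fit_window` (ns).
#' @export
diffusion_fit <- function(msd, fit_window = c(0.1, 0.5)) {
  lo <- fit_window[1] * max(msd$lag)
  hi <- fit_window[2] * max(msd$lag)
  keep <- msd$lag >= lo & msd$lag <= hi
  if (sum(keep) < 3) stop("fewer than 3 lags in the fit window")
  fit <- stats::lm(msd ~ lag, data = msd[keep, ])
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  pos <- keep & msd$lag > 0 & msd$msd > 0
  alpha <- if (sum(pos) >= 3) {
    unname(stats::coef(stats::lm(log(msd$msd[pos]) ~ log(msd$lag[pos])))[2])
  } else {
    NA_real_
  }
  D <- slope / 4
  negative <- D < -1e-10 # tolerate floating-point zero for frozen systems
  if (negative) {
    warning("negative MSD slope; reporting the negative diffusion value as a diagnostic")
  }
  structure(
    list(
      D_A2_ns = D, D_cm2_s = D * 1e-7,
      r_squared = r2, alpha = alpha,
      nonlinear = (is.finite(r2) && r2 < 0.995) ||
        (is.finite(alpha) && base::abs(alpha - 1) > 0.2),
      negative_slope = negative,
      fit_window = c(lo, hi), n_points = sum(keep)
    ),
    class = "bl_diffusion"
  )
}

#' @export
print.bl_diffusion <- function(x, ...) {
  cat(sprintf(
    "<lateral diffusion> D_xy = %.4g A^2/ns = %.4g cm^2/s (R^2 = %.4f, alpha = %.3g%s)\n",
    x$D_A2_ns, x$D_cm2_s, x$r_squared, x$alpha,
    if (x$nonlinear) ", NONLINEAR" else ""
  ))
  invisible(x)
}
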