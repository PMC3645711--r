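# Internal helpers shared across modules.

ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, AS = 74.922, NA. = 22.990, CL = 35.45, K = 39.098
)

#' @keywords internal
atom_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- ATOMIC_MASSES[key]
  m[is.na(m)] <- 12.011 # unknown elements treated as carbon-mass; only relative COM weights matter
  unname(m)
}

# Guess element from a PDB-style atom name ("OH2" -> "O", "As" -> "As", "HA12" -> "H").
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("AS", "CL", "NA"), two, substr(nm, 1, 1))
  # digits can lead in old-style hydrogen names
  lead_digit <- grepl("^[0-9]", el)
  el[lead_digit] <- substr(sub("^[0-9]+", "", nm[lead_digit]), 1, 1)
  el <- sub("^(.)(.)$", "\\1\\L\\2", el, perl = TRUE)
  el
}

# Minimum-image separation components along one axis.
min_image <- function(d, L) d - L * round(d / L)

# Pairwise minimum-image distance matrix between two coordinate sets
# (n_ref x 3 and n_oth x 3) under an orthorhombic box. `image` selects which
# axes are wrapped; unwrapped axes use the raw separation.
pair_dist_matrix <- function(ref, oth, box, image = c(TRUE, TRUE, TRUE)) {
  d2 <- matrix(0, nrow(ref), nrow(oth))
  for (ax in 1:3) {
    dd <- outer(ref[, ax], oth[, ax], "-")
    if (image[ax]) dd <- dd - box[ax] * round(dd / box[ax])
    d2 <- d2 + dd * dd
  }
  sqrt(d2)
}

# Resolve an analysis window (c(start, end) in ns, or NULL = latter half of
# the trajectory) to frame indices.
resolve_window <- function(trajectory, window = NULL) {
  times <- trajectory$times
  if (is.null(window)) {
    t0 <- times[1]
    t1 <- times[length(times)]
    window <- c(t0 + (t1 - t0) / 2, t1)
  }
  stopifnot(length(window) == 2, window[2] >= window[1])
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(idx) == 0) {
    stop("analysis window [", window[1], ", ", window[2], "] ns contains no frames")
  }
  list(idx = idx, window = c(times[idx[1]], times[idx[length(idx)]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_timeseries <- function(times, values, window, extra = list()) {
  out <- tibble::tibble(time = times, value = values)
  attr(out, "mean") <- mean(values)
  attr(out, "sd") <- stats::sd(values)
  attr(out, "window") <- window
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("bl_timeseries", class(out))
  out
}

#' @export
print.bl_timeseries <- function(x, ...) {
  cat(sprintf(
    "<bilayer time series> %d frames over [%.4g, %.4g] ns; mean = %.4g, sd = %.4g\n",
    nrow(x), min(x$time), max(x$time), attr(x, "mean"), attr(x, "sd")
  ))
  NextMethod()
}
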