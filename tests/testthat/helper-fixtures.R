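# Shared fixture builders: a minimal "micro" lipid (8 atoms: headgroup P,
# choline N, one carbon + two H per chain) gives full control over every
# vector the analyses consume.

micro_topology <- function(n_lipids, resname = "POPC") {
  per <- c("P", "N", "C31", "HA1", "HB1", "C21", "HC1", "HD1")
  atoms <- tibble::tibble(
    name = rep(per, n_lipids),
    resname = resname,
    resid = rep(seq_len(n_lipids), each = length(per))
  )
  assign_roles(
    build_topology(atoms),
    default_role_rules(resname, sn1_length = 1, sn2_length = 1)
  )
}

# P: n x 3 x F headgroup positions; u: n x 3 x F unit P->N vectors
# (default +z); ch: n x 3 x F C-H bond vectors applied to all four H
# (default +x); extra_atoms: optional tibble(name, resname, resid) with
# extra_coords n_extra x 3 x F appended after the lipids.
micro_traj <- function(P, u = NULL, ch = NULL, box = c(60, 60, 90),
                       dt = 0.005, extra_atoms = NULL, extra_coords = NULL) {
  if (length(dim(P)) == 2) P <- array(P, c(dim(P), 1))
  n <- dim(P)[1]
  F <- dim(P)[3]
  if (is.null(u)) u <- array(rep(c(0, 0, 1), each = n), c(n, 3, F))
  if (is.null(ch)) ch <- array(rep(c(1.09, 0, 0), each = n), c(n, 3, F))
  topo <- micro_topology(n)
  if (!is.null(extra_atoms)) {
    atoms <- dplyr::bind_rows(
      topo$atoms[, c("name", "resname", "resid")],
      extra_atoms
    )
    topo <- assign_roles(
      build_topology(atoms),
      default_role_rules("POPC", sn1_length = 1, sn2_length = 1)
    )
  }
  per <- 8L
  n_extra <- if (is.null(extra_atoms)) 0L else nrow(extra_atoms)
  coords <- array(NA_real_, c(n * per + n_extra, 3, F))
  starts <- (seq_len(n) - 1L) * per
  for (f in seq_len(F)) {
    Pm <- matrix(P[, , f], ncol = 3)
    um <- matrix(u[, , f], ncol = 3)
    chm <- matrix(ch[, , f], ncol = 3)
    c31 <- Pm - matrix(rep(c(0, 0, 2.0), each = n), ncol = 3)
    c21 <- Pm - matrix(rep(c(0, 0, 2.5), each = n), ncol = 3)
    coords[starts + 1, , f] <- Pm
    coords[starts + 2, , f] <- Pm + 4.5 * um
    coords[starts + 3, , f] <- c31
    coords[starts + 4, , f] <- c31 + chm
    coords[starts + 5, , f] <- c31 + chm
    coords[starts + 6, , f] <- c21
    coords[starts + 7, , f] <- c21 + chm
    coords[starts + 8, , f] <- c21 + chm
    if (n_extra > 0) {
      coords[n * per + seq_len(n_extra), , f] <- matrix(extra_coords[, , f], ncol = 3)
    }
  }
  build_trajectory(topo, coords, times = (seq_len(F) - 1) * dt, box = box)
}

# a tiny flat bilayer: n/2 lipids per leaflet on a grid at z = +/- sep/2
flat_bilayer <- function(n_per_leaflet = 4, sep = 40, box = c(60, 60, 90),
                         n_frames = 1) {
  k <- ceiling(sqrt(n_per_leaflet))
  a <- box[1] / k
  xy <- cbind(
    ((seq_len(n_per_leaflet) - 1) %% k + 0.5) * a,
    ((seq_len(n_per_leaflet) - 1) %/% k + 0.5) * a
  )
  P0 <- rbind(cbind(xy, sep / 2), cbind(xy, -sep / 2))
  P <- array(P0, c(2 * n_per_leaflet, 3, n_frames))
  sgn <- c(rep(1, n_per_leaflet), rep(-1, n_per_leaflet))
  u0 <- cbind(0, 0, sgn)
  u <- array(u0, c(2 * n_per_leaflet, 3, n_frames))
  micro_traj(P, u = u, box = box)
}

# brute-force minimum-image distance via explicit enumeration of all 27
# periodic images (the oracle the fast path is checked against)
brute_min_image_dist <- function(ref, oth, box, image = c(TRUE, TRUE, TRUE)) {
  D <- matrix(Inf, nrow(ref), nrow(oth))
  ks <- lapply(1:3, function(ax) if (image[ax]) -2:2 else 0)
  for (kx in ks[[1]]) for (ky in ks[[2]]) for (kz in ks[[3]]) {
    shift <- c(kx * box[1], ky * box[2], kz * box[3])
    for (i in seq_len(nrow(ref))) {
      d <- sqrt(colSums((t(oth) + shift - ref[i, ])^2))
      D[i, ] <- pmin(D[i, ], d)
    }
  }
  D
}

small_spec <- function(...) {
  args <- list(
    n_lipids_per_leaflet = 12, n_frames = 60, n_waters = 150,
    hydration_count = 3, bridge_count = 2, n_na = 2, n_cl = 2,
    seed = 42
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_bilayer_spec, args)
}

new_timeseries_for_test <- function(values, dt = 0.005) {
  tibble::tibble(time = (seq_along(values) - 1) * dt, value = values)
}

ideal_gas_traj <- function(n_ref = 16, n_oth = 3000, n_frames = 10, box = 30,
                           seed = 23) {
  set.seed(seed)
  k <- ceiling(sqrt(n_ref))
  P <- cbind(
    ((seq_len(n_ref) - 1) %% k + 0.5) * box / k,
    ((seq_len(n_ref) - 1) %/% k + 0.5) * box / k,
    rep(c(6, -6), length.out = n_ref)
  )
  wat <- tibble::tibble(name = "OH2", resname = "TIP3", resid = n_ref + seq_len(n_oth))
  wc <- array(runif(n_oth * 3 * n_frames, 0, box), c(n_oth, 3, n_frames))
  micro_traj(
    array(P, c(n_ref, 3, n_frames)),
    box = c(box, box, box),
    extra_atoms = wat, extra_coords = wc
  )
}
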