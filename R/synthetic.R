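#' Specification for a synthetic bilayer trajectory
#'
#' The generator emulates the statistical structure the analysis functions
#' assume — not the physics. It builds a two-leaflet bilayer of marker atoms
#' (headgroup center P/As, choline N, chain carbons with attached hydrogens),
#' surrounding water oxygens and ions, with: lateral Brownian motion of known
#' diffusion coefficient, headgroup-vector rotational diffusion (optionally
#' biased to a target tilt distribution by an Ornstein-Uhlenbeck restoring
#' term), chain C-H vectors drawn at the fixed polar angle
#' `theta* = acos(sqrt((2 S* + 1)/3))` that makes the deuterium order
#' parameter of carbon `k` exactly `S*_k`, a planted hydration shell and
#' planted inter-lipid salt bridges. Every statistic computed by the package
#' is therefore recoverable from known ground truth.
#'
#' Salt-bridge planting works by clustering: lipids move in rigid Brownian
#' clusters of `bridge_count + 1` members whose internal offsets are small
#' enough that each member's choline N is guaranteed within `bridge_cutoff`
#' of every other member's headgroup center. This leaves diffusion, tilt,
#' order-parameter, area and thickness statistics untouched.
#'
#' Defaults mirror a conventional phosphocholine bilayer study system:
#' 48 lipids per leaflet (96 total), 4863 water oxygens, 13 Na+ and 13 Cl-,
#' frames every 5 ps, a lateral box sized for ~53 A^2 per lipid, leaflet
#' separation 44.8 A, tilt distribution (75.6, 26.7) degrees, lateral
#' diffusion 0.675 A^2/ns, 16 sn-1 (palmitoyl) and 18 sn-2 (oleoyl) chain
#' carbons.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (default 48).
#' @param leaflet_sep Leaflet separation (headgroup plane to headgroup
#'   plane), angstrom.
#' @param box_xy Lateral box edge (Lx = Ly), angstrom.
#' @param box_z Box height, angstrom.
#' @param box_fluct_sd Per-frame Gaussian fluctuation of the lateral box
#'   edges, angstrom (default 0.3).
#' @param lateral_compression Total fractional lateral shrink applied
#'   linearly across the run at fixed volume (z dimensions expand as
#'   `1/s^2`); 0 disables.
#' @param n_frames,dt_ns Number of frames and frame spacing (ns).
#' @param D_lateral Lateral diffusion coefficient of the lipid COM, A^2/ns.
#' @param D_r Rotational diffusion coefficient of the headgroup vector, 1/ns.
#' @param tilt_mean_deg,tilt_sd_deg Target tilt distribution of the headgroup
#'   vector against the outward leaflet normal; set `tilt_mean_deg = NULL`
#'   for free (unbiased) rotational diffusion on the sphere.
#' @param tilt_relax_ns Relaxation time of the OU restoring term (ns).
#' @param scd_sn1,scd_sn2 Per-carbon target order parameters `S*`.
#' @param n_waters Total water oxygens (planted + bulk).
#' @param hydration_count,hydration_cutoff Waters planted within the cutoff
#'   of each lipid headgroup center (the planted hydration shell).
#' @param bridge_count,bridge_cutoff Planted inter-lipid salt bridges per
#'   lipid and their cutoff. Planting is off by default: the guarantee
#'   requires near-coincident lipid clusters, which also share their
#'   hydration shells; with planting off the lattice geometry at the default
#'   area per lipid yields a natural (unplanted) bridge count.
#' @param n_na,n_cl Ion counts.
#' @param lipid_resname `"POAC"` (arsenic headgroup) or `"POPC"` (phosphorus).
#' @param pn_length Headgroup-center-to-choline-N distance, angstrom.
#' @param z_noise_sd Gaussian z jitter of headgroup planes, angstrom
#'   (default 0 so that thickness equals `leaflet_sep` exactly).
#' @param seed RNG seed; the spec plus seed fully determines the trajectory.
#' @return A `bl_synth_spec` list.
#' @export
synthetic_bilayer_spec <- function(
    n_lipids_per_leaflet = 48,
    leaflet_sep = 44.8,
    box_xy = sqrt(48 * 53.25),
    box_z = 90,
    box_fluct_sd = 0.3,
    lateral_compression = 0,
    n_frames = 1000,
    dt_ns = 0.005,
    D_lateral = 0.675,
    D_r = 1.0,
    tilt_mean_deg = 75.6,
    tilt_sd_deg = 26.7,
    tilt_relax_ns = 0.2,
    scd_sn1 = default_scd_targets("sn1"),
    scd_sn2 = default_scd_targets("sn2"),
    n_waters = 4863,
    hydration_count = 11,
    hydration_cutoff = 4.85,
    bridge_count = 0,
    bridge_cutoff = 6.75,
    n_na = 13,
    n_cl = 13,
    lipid_resname = c("POAC", "POPC"),
    pn_length = 4.5,
    z_noise_sd = 0,
    seed = 1L) {
  lipid_resname <- match.arg(lipid_resname)
  spec <- list(
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    leaflet_sep = leaflet_sep, box_xy = box_xy, box_z = box_z,
    box_fluct_sd = box_fluct_sd, lateral_compression = lateral_compression,
    n_frames = as.integer(n_frames), dt_ns = dt_ns,
    D_lateral = D_lateral, D_r = D_r,
    tilt_mean_deg = tilt_mean_deg, tilt_sd_deg = tilt_sd_deg,
    tilt_relax_ns = tilt_relax_ns,
    scd_sn1 = scd_sn1, scd_sn2 = scd_sn2,
    n_waters = as.integer(n_waters),
    hydration_count = as.integer(hydration_count),
    hydration_cutoff = hydration_cutoff,
    bridge_count = as.integer(bridge_count), bridge_cutoff = bridge_cutoff,
    n_na = as.integer(n_na), n_cl = as.integer(n_cl),
    lipid_resname = lipid_resname, pn_length = pn_length,
    z_noise_sd = z_noise_sd, seed = as.integer(seed)
  )
  stopifnot(
    spec$n_lipids_per_leaflet >= 1, spec$leaflet_sep > 0,
    spec$leaflet_sep < spec$box_z, spec$n_frames >= 1, spec$dt_ns > 0,
    spec$D_lateral >= 0, spec$D_r >= 0, spec$n_waters >= 0
  )
  class(spec) <- "bl_synth_spec"
  spec
}

#' Default per-carbon order-parameter targets
#'
#' A realistic phosphocholine-like profile: a plateau near 0.22 over the
#' upper chain, dropping toward the disordered tail; the sn-2 profile adds
#' the characteristic dip around carbons 9-10 where the oleoyl double bond
#' sits, and is slightly less ordered than sn-1 overall.
#'
#' @param chain `"sn1"` (16 carbons) or `"sn2"` (18 carbons).
#' @return Numeric vector of `S*` targets.
#' @export
default_scd_targets <- function(chain = c("sn1", "sn2")) {
  chain <- match.arg(chain)
  if (chain == "sn1") {
    s <- c(0.20, rep(0.22, 7), seq(0.21, 0.05, length.out = 8))
  } else {
    s <- c(0.16, rep(0.18, 6), 0.12, 0.08, 0.08, 0.12,
           seq(0.13, 0.04, length.out = 7))
  }
  s
}

#' Exact stretched-exponential curve
#'
#' `exp(-(t/tau)^beta)` evaluated at the given lags; the noiseless input for
#' relaxation-fit self-consistency tests.
#'
#' @param tau Relaxation time (ns), positive.
#' @param beta Stretching exponent in (0, 1].
#' @param lags Lag times (ns).
#' @return A tibble (`lag`, `raf`) compatible with [kww_fit()].
#' @export
generate_kww_curve <- function(tau, beta, lags) {
  if (tau <= 0) stop("tau must be positive")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  tibble::tibble(lag = lags, raf = exp(-(lags / tau)^beta))
}

lipid_atom_names <- function(spec) {
  head_name <- if (spec$lipid_resname == "POAC") "As" else "P"
  n1 <- length(spec$scd_sn1)
  n2 <- length(spec$scd_sn2)
  list(
    head = head_name,
    names = c(
      head_name, "N",
      paste0("C3", seq_len(n1)), paste0("HA", seq_len(n1)), paste0("HB", seq_len(n1)),
      paste0("C2", seq_len(n2)), paste0("HC", seq_len(n2)), paste0("HD", seq_len(n2))
    )
  )
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' See [synthetic_bilayer_spec()] for the model. The returned trajectory has
#' roles already assigned (via [assign_roles()] with the default rules) and
#' carries a ground-truth tag consumed by [ground_truth_report()]. The same
#' spec and seed yield bit-identical trajectories.
#'
#' @param spec A `bl_synth_spec`.
#' @return A `bl_trajectory` with attribute `"synthetic_truth"`.
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bl_synth_spec"))
  set.seed(spec$seed)

  npl <- spec$n_lipids_per_leaflet
  nfr <- spec$n_frames
  n1 <- length(spec$scd_sn1)
  n2 <- length(spec$scd_sn2)

  # --- planting feasibility ------------------------------------------------
  r_lo <- 2.6
  r_hi <- spec$hydration_cutoff - 0.15
  if (r_hi <= r_lo) stop("hydration cutoff too small to plant a shell")
  max_h <- floor(0.74 * (r_hi^3 - r_lo^3) / 1.4^3)
  if (spec$hydration_count > max_h) {
    stop(
      "infeasible hydration planting: ", spec$hydration_count,
      " waters cannot pack in the shell [", r_lo, ", ", r_hi,
      "] A (maximum ~", max_h, " at physical water packing)"
    )
  }
  n_planted <- spec$hydration_count * 2L * npl
  if (n_planted > spec$n_waters) {
    stop("n_waters (", spec$n_waters, ") smaller than planted shell total (", n_planted, ")")
  }

  m <- spec$bridge_count + 1L
  if (npl %% m != 0) {
    stop(
      "infeasible salt-bridge planting: lipids per leaflet (", npl,
      ") must be divisible by bridge_count + 1 (", m, ") to guarantee ",
      spec$bridge_count, " bridges per lipid"
    )
  }
  # per-frame COM re-centering (below) rigidly shifts each lipid by up to
  # ~ (m_N / M_lipid) * pn_length laterally; the planting margin covers two
  # such shifts plus slack
  m_head <- if (spec$lipid_resname == "POAC") 74.922 else 30.974
  m_lipid <- m_head + 14.007 + (12.011 + 2 * 1.008) * (n1 + n2)
  com_shift <- 14.007 / m_lipid * spec$pn_length
  margin <- 0.3 + 2 * com_shift
  R0 <- (spec$bridge_cutoff - spec$pn_length - margin) / 2
  if (spec$bridge_count > 0 && R0 <= 0) {
    stop("infeasible salt-bridge planting: pn_length + margin exceeds bridge_cutoff")
  }

  # --- static layout -------------------------------------------------------
  n_clusters <- npl %/% m
  grid_k <- ceiling(sqrt(n_clusters))
  a <- spec$box_xy / grid_k
  cl_base <- cbind(
    ((seq_len(n_clusters) - 1) %% grid_k + 0.5) * a,
    ((seq_len(n_clusters) - 1) %/% grid_k + 0.5) * a
  )
  cl_base <- cl_base + matrix(stats::runif(2 * n_clusters, -0.15 * a, 0.15 * a), ncol = 2)

  # member offsets inside a cluster (member 1 at center, rest on a circle)
  if (m == 1) {
    offs <- matrix(0, 1, 2)
  } else {
    ang <- 2 * pi * (seq_len(m - 1) - 1) / (m - 1)
    offs <- rbind(c(0, 0), cbind(R0 * cos(ang), R0 * sin(ang)))
  }
  # per-leaflet lipid -> (cluster, member); lower leaflet mirrors the upper
  cluster_of <- rep(seq_len(n_clusters), each = m)
  member_of <- rep(seq_len(m), times = n_clusters)
  base_xy <- cl_base[cluster_of, , drop = FALSE] + offs[member_of, , drop = FALSE]

  n_lip <- 2L * npl
  leaflet_sign <- c(rep(1, npl), rep(-1, npl)) # resid order: upper then lower
  base_xy2 <- rbind(base_xy, base_xy)          # mirrored leaflets
  cluster_of2 <- c(cluster_of, cluster_of)     # mirrored pair shares its cluster path

  z_head <- leaflet_sign * spec$leaflet_sep / 2 +
    (if (spec$z_noise_sd > 0) stats::rnorm(n_lip, 0, spec$z_noise_sd) else 0)

  # chain carbon z offsets (toward the bilayer center)
  chain_z1 <- 3 + 1.27 * seq_len(n1)
  chain_z2 <- 3 + 1.27 * seq_len(n2)
  cos_t1 <- sqrt((2 * spec$scd_sn1 + 1) / 3)
  sin_t1 <- sqrt(1 - cos_t1^2)
  cos_t2 <- sqrt((2 * spec$scd_sn2 + 1) / 3)
  sin_t2 <- sqrt(1 - cos_t2^2)

  # --- dynamical paths -----------------------------------------------------
  dt <- spec$dt_ns
  step_sd <- sqrt(2 * spec$D_lateral * dt)
  steps_x <- matrix(stats::rnorm((nfr - 1) * n_clusters, 0, step_sd), max(nfr - 1, 0), n_clusters)
  steps_y <- matrix(stats::rnorm((nfr - 1) * n_clusters, 0, step_sd), max(nfr - 1, 0), n_clusters)
  if (nfr > 1) {
    path_x <- rbind(0, apply(steps_x, 2, cumsum))
    path_y <- rbind(0, apply(steps_y, 2, cumsum))
  } else {
    path_x <- matrix(0, 1, n_clusters)
    path_y <- matrix(0, 1, n_clusters)
  }

  # headgroup vector paths: theta against the outward normal, free or
  # OU-biased. Orientations are generated for the upper leaflet and mirrored
  # to the lower one (z reflection): the per-lipid COM re-centering applied
  # later is then identical in the two leaflets, which keeps mirrored lipid
  # pairs laterally registered and the membrane thickness exactly equal to
  # the planted leaflet separation.
  theta <- matrix(0, nfr, npl)
  phi <- matrix(0, nfr, npl)
  free_rotor <- is.null(spec$tilt_mean_deg)
  if (free_rotor) {
    # isotropic diffusion on the sphere: tangent-plane Gaussian steps.
    # Every lipid rotates independently (no leaflet mirroring): this mode
    # exists to verify rotational statistics, where independent rotors are
    # what counts; lateral leaflet registration is only exact in the
    # tilt-biased mode.
    u <- matrix(stats::rnorm(3 * n_lip), n_lip, 3)
    u <- u / sqrt(rowSums(u^2))
    sd_rot <- sqrt(2 * spec$D_r * dt)
    U_store <- array(NA_real_, c(n_lip, 3, nfr))
    U_store[, , 1] <- u
    if (nfr > 1) {
      for (f in 2:nfr) {
        xi <- matrix(stats::rnorm(2 * n_lip, 0, sd_rot), n_lip, 2)
        # orthonormal tangent basis at u
        ref <- cbind(-u[, 2], u[, 1], 0)
        small <- sqrt(rowSums(ref^2)) < 1e-8
        if (any(small)) {
          ref[small, ] <- matrix(c(1, 0, 0), sum(small), 3, byrow = TRUE)
        }
        e1 <- ref / sqrt(rowSums(ref^2))
        e2 <- cbind(
          u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
          u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
          u[, 1] * e1[, 2] - u[, 2] * e1[, 1]
        )
        u <- u + xi[, 1] * e1 + xi[, 2] * e2
        u <- u / sqrt(rowSums(u^2))
        U_store[, , f] <- u
      }
    }
  } else {
    th0 <- spec$tilt_mean_deg * pi / 180
    s_th <- spec$tilt_sd_deg * pi / 180
    k_rel <- dt / spec$tilt_relax_ns
    th1 <- stats::rnorm(npl, th0, s_th)
    th1 <- base::abs(th1)
    theta[1, ] <- pi - base::abs(pi - th1)
    phi[1, ] <- stats::runif(npl, 0, 2 * pi)
    if (nfr > 1 && spec$D_r == 0) {
      # frozen orientations: no rotational motion of any kind
      theta[2:nfr, ] <- rep(theta[1, ], each = nfr - 1)
      phi[2:nfr, ] <- rep(phi[1, ], each = nfr - 1)
    } else if (nfr > 1) {
      for (f in 2:nfr) {
        th <- theta[f - 1, ] + (th0 - theta[f - 1, ]) * k_rel +
          s_th * sqrt(2 * k_rel) * stats::rnorm(npl)
        th <- base::abs(th)               # reflect at 0
        th <- pi - base::abs(pi - th)     # reflect at pi
        theta[f, ] <- th
        sin_th <- pmax(sin(th), 0.2)
        phi[f, ] <- phi[f - 1, ] + sqrt(2 * spec$D_r * dt) / sin_th * stats::rnorm(npl)
      }
    }
    theta <- cbind(theta, theta)
    phi <- cbind(phi, phi)
  }

  # box series
  s_of <- if (spec$lateral_compression > 0 && nfr > 1) {
    1 - spec$lateral_compression * (seq_len(nfr) - 1) / (nfr - 1)
  } else {
    rep(1, nfr)
  }
  # slow AR(1) box breathing (barostat-like): large excursions but small
  # frame-to-frame changes, so COM unwrapping at boundary crossings is clean
  fluct <- numeric(nfr)
  if (spec$box_fluct_sd > 0) {
    rho_b <- 0.99
    fluct[1] <- stats::rnorm(1, 0, spec$box_fluct_sd)
    if (nfr > 1) {
      innov <- stats::rnorm(nfr - 1, 0, spec$box_fluct_sd * sqrt(1 - rho_b^2))
      for (f in 2:nfr) fluct[f] <- rho_b * fluct[f - 1] + innov[f - 1]
    }
  }
  box <- cbind(
    spec$box_xy * s_of + fluct,
    spec$box_xy * s_of + fluct,
    spec$box_z / s_of^2
  )

  # planted water radii (fixed per water) and bookkeeping
  h <- spec$hydration_count
  planted_r <- if (h > 0) {
    matrix(stats::runif(h * n_lip, r_lo, r_hi), h, n_lip)
  } else {
    matrix(0, 0, n_lip)
  }
  n_bulk <- spec$n_waters - h * n_lip
  bulk_xy <- cbind(
    stats::runif(n_bulk, 0, spec$box_xy),
    stats::runif(n_bulk, 0, spec$box_xy)
  )
  z_slab_lo <- spec$leaflet_sep / 2 + chain_z1[1] + 3 # above the headgroups
  bulk_z <- sample(c(-1, 1), n_bulk, replace = TRUE) *
    stats::runif(n_bulk, z_slab_lo, spec$box_z / 2 - 1)
  n_ions <- spec$n_na + spec$n_cl
  ion_xy <- cbind(
    stats::runif(n_ions, 0, spec$box_xy),
    stats::runif(n_ions, 0, spec$box_xy)
  )
  ion_z <- sample(c(-1, 1), n_ions, replace = TRUE) *
    stats::runif(n_ions, z_slab_lo, spec$box_z / 2 - 1)

  # --- atom table ----------------------------------------------------------
  lam <- lipid_atom_names(spec)
  per_lipid <- length(lam$names)
  atoms <- tibble::tibble(
    name = c(
      rep(lam$names, n_lip),
      rep("OH2", spec$n_waters),
      rep("SOD", spec$n_na), rep("CLA", spec$n_cl)
    ),
    resname = c(
      rep(spec$lipid_resname, per_lipid * n_lip),
      rep("TIP3", spec$n_waters),
      rep("SOD", spec$n_na), rep("CLA", spec$n_cl)
    ),
    resid = c(
      rep(seq_len(n_lip), each = per_lipid),
      n_lip + seq_len(spec$n_waters),
      n_lip + spec$n_waters + seq_len(n_ions)
    )
  )
  topo <- assign_roles(build_topology(atoms), default_role_rules(
    lipid_resnames = spec$lipid_resname,
    sn1_length = n1, sn2_length = n2
  ))

  # atom offsets inside a lipid block
  off_head <- 1L
  off_n <- 2L
  off_c1 <- 2L + seq_len(n1)
  off_ha <- 2L + n1 + seq_len(n1)
  off_hb <- 2L + 2L * n1 + seq_len(n1)
  off_c2 <- 2L + 3L * n1 + seq_len(n2)
  off_hc <- 2L + 3L * n1 + n2 + seq_len(n2)
  off_hd <- 2L + 3L * n1 + 2L * n2 + seq_len(n2)
  lip_start <- (seq_len(n_lip) - 1L) * per_lipid

  n_at <- nrow(atoms)
  lip_masses <- atom_mass(topo$atoms$element[seq_len(per_lipid)])
  m_lip_total <- sum(lip_masses)
  coords <- array(NA_real_, c(n_at, 3, nfr))
  water0 <- per_lipid * n_lip
  ion0 <- water0 + spec$n_waters
  ch_bond <- 1.09

  for (f in seq_len(nfr)) {
    s <- s_of[f]
    Lb <- box[f, ]
    px <- (base_xy2[, 1] + path_x[f, cluster_of2]) * s
    py <- (base_xy2[, 2] + path_y[f, cluster_of2]) * s
    pz <- z_head / s^2

    if (free_rotor) {
      ux <- U_store[, 1, f]
      uy <- U_store[, 2, f]
      uz <- U_store[, 3, f]
    } else {
      st <- sin(theta[f, ])
      ux <- st * cos(phi[f, ])
      uy <- st * sin(phi[f, ])
      uz <- leaflet_sign * cos(theta[f, ])
    }

    X <- numeric(n_at)
    Y <- numeric(n_at)
    Z <- numeric(n_at)

    X[lip_start + off_head] <- px
    Y[lip_start + off_head] <- py
    Z[lip_start + off_head] <- pz
    X[lip_start + off_n] <- px + spec$pn_length * ux
    Y[lip_start + off_n] <- py + spec$pn_length * uy
    Z[lip_start + off_n] <- pz + spec$pn_length * uz

    place_chain <- function(off_c, off_hA, off_hB, chain_z, cos_t, sin_t) {
      nn <- length(chain_z)
      ci <- rep(lip_start, each = nn) + off_c
      X[ci] <<- rep(px, each = nn)
      Y[ci] <<- rep(py, each = nn)
      Z[ci] <<- rep(pz, each = nn) - rep(leaflet_sign, each = nn) * chain_z / s^2
      for (offH in list(off_hA, off_hB)) {
        # azimuths shared between mirrored leaflets (lipids ordered upper
        # block then lower block), so COM re-centering stays mirror-symmetric
        phiH <- rep(stats::runif(nn * npl, 0, 2 * pi), 2)
        hi <- rep(lip_start, each = nn) + offH
        X[hi] <<- X[ci] + ch_bond * sin_t * cos(phiH)
        Y[hi] <<- Y[ci] + ch_bond * sin_t * sin(phiH)
        Z[hi] <<- Z[ci] - ch_bond * rep(leaflet_sign, each = nn) * cos_t
      }
    }
    place_chain(off_c1, off_ha, off_hb, chain_z1, cos_t1, sin_t1)
    place_chain(off_c2, off_hc, off_hd, chain_z2, cos_t2, sin_t2)

    # re-center each lipid laterally so its mass-weighted COM follows the
    # planted Brownian path exactly: the choline swing and the hydrogen
    # azimuths then contribute zero COM motion, and the lateral diffusion
    # coefficient of the COM is D_lateral by construction
    nlb <- per_lipid * n_lip
    Xl <- matrix(X[seq_len(nlb)], per_lipid, n_lip)
    Yl <- matrix(Y[seq_len(nlb)], per_lipid, n_lip)
    corr_x <- colSums(Xl * lip_masses) / m_lip_total - px
    corr_y <- colSums(Yl * lip_masses) / m_lip_total - py
    X[seq_len(nlb)] <- Xl - rep(corr_x, each = per_lipid)
    Y[seq_len(nlb)] <- Yl - rep(corr_y, each = per_lipid)
    px <- X[lip_start + off_head]
    py <- Y[lip_start + off_head]

    if (h > 0) {
      cz <- stats::runif(h * n_lip, -1, 1)
      cphi <- stats::runif(h * n_lip, 0, 2 * pi)
      sz <- sqrt(1 - cz^2)
      r <- as.vector(planted_r)
      wi <- water0 + seq_len(h * n_lip)
      X[wi] <- rep(px, each = h) + r * sz * cos(cphi)
      Y[wi] <- rep(py, each = h) + r * sz * sin(cphi)
      Z[wi] <- rep(pz, each = h) + r * cz
    }
    if (n_bulk > 0) {
      bi <- water0 + h * n_lip + seq_len(n_bulk)
      X[bi] <- bulk_xy[, 1] * s
      Y[bi] <- bulk_xy[, 2] * s
      Z[bi] <- bulk_z / s^2
    }
    if (n_ions > 0) {
      ii <- ion0 + seq_len(n_ions)
      X[ii] <- ion_xy[, 1] * s
      Y[ii] <- ion_xy[, 2] * s
      Z[ii] <- ion_z / s^2
    }

    # wrap lateral coordinates into [0, L)
    X <- X - Lb[1] * floor(X / Lb[1])
    Y <- Y - Lb[2] * floor(Y / Lb[2])
    coords[, 1, f] <- X
    coords[, 2, f] <- Y
    coords[, 3, f] <- Z
  }

  traj <- build_trajectory(topo, coords, times = (seq_len(nfr) - 1) * dt, box = box)

  # realized ground truth bookkeeping
  if (free_rotor) {
    tilt_cos <- matrix(U_store[, 3, ], n_lip, nfr) * leaflet_sign
    tilt_samples <- acos(pmin(pmax(tilt_cos, -1), 1)) * 180 / pi
  } else {
    tilt_samples <- t(theta) * 180 / pi
  }
  realized <- list(
    tilt_mean_deg = mean(tilt_samples),
    tilt_sd_deg = stats::sd(as.vector(tilt_samples)),
    tilt_n = length(tilt_samples),
    step_var_per_axis = if (nfr > 1) stats::var(c(as.vector(steps_x), as.vector(steps_y))) else NA_real_,
    expected_step_var = 2 * spec$D_lateral * dt
  )
  attr(traj, "synthetic_truth") <- list(
    spec = spec,
    upper_resids = seq_len(npl),
    lower_resids = npl + seq_len(npl),
    realized = realized
  )
  traj
}

# Independent cutoff recount by explicit periodic-image enumeration (the
# generator's own bookkeeping path, distinct from the analysis min-image
# arithmetic): for each reference atom the candidate separations dx + k*L,
# k in {-1, 0, 1} per axis, are enumerated and the minimum taken.
count_within_enum <- function(ref_xyz, oth_xyz, box, cutoff,
                              ref_resid = NULL, oth_resid = NULL,
                              exclude_same_residue = FALSE) {
  counts <- numeric(nrow(ref_xyz))
  k <- c(-1, 0, 1)
  for (i in seq_len(nrow(ref_xyz))) {
    d2min <- NULL
    for (ax in 1:3) {
      dd <- oth_xyz[, ax] - ref_xyz[i, ax]
      cand <- pmin(
        (dd + k[1] * box[ax])^2,
        (dd + k[2] * box[ax])^2,
        (dd + k[3] * box[ax])^2
      )
      d2min <- if (is.null(d2min)) cand else d2min + cand
    }
    hit <- sqrt(d2min) <= cutoff
    if (exclude_same_residue) hit <- hit & (oth_resid != ref_resid[i])
    counts[i] <- sum(hit)
  }
  counts
}

#' Realized ground truth of a generated trajectory
#'
#' Reports the exact realized values of the quantities the generator plants,
#' so tests can compare analysis output against realized truth rather than
#' only against the spec: per-frame hydration counts (planted plus strays,
#' recounted by explicit periodic-image enumeration), per-frame inter-lipid
#' salt-bridge counts, the realized tilt sample mean/sd (from the
#' generator's internal angle states, not from coordinates), the realized
#' Brownian step variance, and the order-parameter targets.
#'
#' @param spec The `bl_synth_spec` used for generation.
#' @param trajectory The trajectory returned by [generate_bilayer()].
#' @param frames Frame indices to recount (default: all frames).
#' @return A list: `leaflets` (`upper`/`lower` resids), `tilt`, `step_var`,
#'   `scd_targets`, `hydration` and `salt_bridges` tibbles of per-frame mean
#'   counts per lipid.
#' @export
ground_truth_report <- function(spec, trajectory, frames = NULL) {
  truth <- attr(trajectory, "synthetic_truth")
  if (is.null(truth)) {
    stop("trajectory was not produced by generate_bilayer() (no ground-truth tag)")
  }
  if (!identical(truth$spec[order(names(truth$spec))], spec[order(names(spec))])) {
    stop("spec does not match the one the trajectory was generated from")
  }
  frames <- frames %||% seq_len(n_frames(trajectory))
  lip <- trajectory$topology$lipids
  atoms <- trajectory$topology$atoms
  heads <- lip$head
  ns <- lip$choline_n
  waters <- which(atoms$role == "water_O")

  hyd <- numeric(length(frames))
  brg <- numeric(length(frames))
  for (j in seq_along(frames)) {
    f <- frames[j]
    hw <- matrix(trajectory$coords[heads, , f], ncol = 3)
    ww <- matrix(trajectory$coords[waters, , f], ncol = 3)
    nn <- matrix(trajectory$coords[ns, , f], ncol = 3)
    hyd[j] <- mean(count_within_enum(hw, ww, trajectory$box[f, ], spec$hydration_cutoff))
    brg[j] <- mean(count_within_enum(
      hw, nn, trajectory$box[f, ], spec$bridge_cutoff,
      ref_resid = lip$resid, oth_resid = lip$resid,
      exclude_same_residue = TRUE
    ))
  }
  list(
    leaflets = list(upper = truth$upper_resids, lower = truth$lower_resids),
    tilt = truth$realized[c("tilt_mean_deg", "tilt_sd_deg", "tilt_n")],
    step_var = truth$realized[c("step_var_per_axis", "expected_step_var")],
    scd_targets = list(sn1 = spec$scd_sn1, sn2 = spec$scd_sn2),
    hydration = tibble::tibble(frame = frames, mean_count = hyd),
    salt_bridges = tibble::tibble(frame = frames, mean_count = brg)
  )
}
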