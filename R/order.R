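# Intramolecular vector from atom b to atom a over a set of frames,
# minimum-imaged per frame so wrapped coordinates give the bonded vector.
# Returns a 3 x n_frames matrix.
segmental_vector <- function(trajectory, a, b, frames) {
  v <- matrix(
    trajectory$coords[a, , frames] - trajectory$coords[b, , frames],
    nrow = 3
  )
  for (ax in 1:3) {
    L <- trajectory$box[frames, ax]
    v[ax, ] <- v[ax, ] - L * round(v[ax, ] / L)
  }
  v
}

#' Deuterium order parameter profile of an acyl chain
#'
#' For each carbon ordinal along the chosen chain the order parameter is
#' `S_CD = 1/2 < 3 cos^2(theta) - 1 >`, where `theta` is the instantaneous
#' angle between the segmental vector and the bilayer normal (+z), and the
#' average runs over all lipids of both leaflets and all frames in the
#' window. Two segmental-vector conventions are supported:
#'
#' * `"CH_bond"` (default): the carbon-to-bonded-hydrogen vector, averaged
#'   over every hydrogen attached to that carbon — the standard deuterium
#'   order parameter for all-atom trajectories;
#' * `"C_neighbor"`: the `C(i-1) -> C(i+1)` vector; terminal carbons are
#'   skipped.
#'
#' `S_CD` lies in `[-0.5, 1]`: 1 for a vector locked along the normal, -0.5
#' for one locked in the membrane plane, 0 for isotropic orientations. The
#' sign is never flipped silently; use `abs = TRUE` for plotting parity with
#' conventions that display `|S_CD|`.
#'
#' @inheritParams area_per_lipid
#' @param chain `"sn1"` or `"sn2"` (carbon 1 is the chain carbon bonded to
#'   the glycerol ester, per the conventional labeling).
#' @param vector_convention `"CH_bond"` or `"C_neighbor"`.
#' @param abs Report `|S_CD|` (display convention only; default `FALSE`).
#' @param leaflet Pool `"both"` leaflets (default) or restrict to one.
#' @return A `bl_scd` tibble: `chain`, `carbon` (1-based ordinal), `scd`,
#'   `n_samples`; attribute `vector_convention`.
#' @export
scd_profile <- function(trajectory, leaflets, chain = c("sn1", "sn2"),
                        vector_convention = c("CH_bond", "C_neighbor"),
                        window = NULL, abs = FALSE,
                        leaflet = c("both", "upper", "lower")) {
  chain <- match.arg(chain)
  vector_convention <- match.arg(vector_convention)
  leaflet <- match.arg(leaflet)
  lip <- trajectory$topology$lipids
  if (nrow(lip) == 0) stop("topology has no lipids; run assign_roles() first")
  keep_resid <- switch(leaflet,
    both = c(leaflets$upper, leaflets$lower),
    upper = leaflets$upper,
    lower = leaflets$lower
  )
  lip <- lip[lip$resid %in% keep_resid, , drop = FALSE]
  if (nrow(lip) == 0) stop("selected leaflet contains no lipids")
  w <- resolve_window(trajectory, window)

  chain_lists <- lip[[chain]]
  n_carbons <- min(lengths(chain_lists))
  if (vector_convention == "C_neighbor" && n_carbons < 3) {
    stop("C_neighbor convention requires chains of at least 3 carbons")
  }

  ordinals <- if (vector_convention == "C_neighbor") 2:(n_carbons - 1) else seq_len(n_carbons)
  scd <- numeric(length(ordinals))
  n_samples <- integer(length(ordinals))

  for (j in seq_along(ordinals)) {
    k <- ordinals[j]
    s_sum <- 0
    s_n <- 0L
    for (li in seq_len(nrow(lip))) {
      carbons <- chain_lists[[li]]
      if (vector_convention == "CH_bond") {
        hs <- lip$h_map[[li]][[paste0(chain, "_", k)]]
        if (length(hs) == 0) {
          stop(
            "lipid residue ", lip$resid[li], ": carbon ", k, " of ", chain,
            " has no bonded hydrogens (required for the CH_bond convention)"
          )
        }
        ci <- carbons[k]
        for (h in hs) {
          v <- segmental_vector(trajectory, h, ci, w$idx)
          cz2 <- (v[3, ]^2) / (v[1, ]^2 + v[2, ]^2 + v[3, ]^2)
          s_sum <- s_sum + sum(0.5 * (3 * cz2 - 1))
          s_n <- s_n + length(cz2)
        }
      } else {
        v <- segmental_vector(trajectory, carbons[k + 1], carbons[k - 1], w$idx)
        cz2 <- (v[3, ]^2) / (v[1, ]^2 + v[2, ]^2 + v[3, ]^2)
        s_sum <- s_sum + sum(0.5 * (3 * cz2 - 1))
        s_n <- s_n + length(cz2)
      }
    }
    scd[j] <- s_sum / s_n
    n_samples[j] <- s_n
  }
  if (abs) scd <- base::abs(scd)
  out <- tibble::tibble(
    chain = chain, carbon = as.integer(ordinals),
    scd = scd, n_samples = n_samples
  )
  attr(out, "vector_convention") <- vector_convention
  attr(out, "abs") <- abs
  attr(out, "window") <- w$window
  class(out) <- c("bl_scd", class(out))
  out
}
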