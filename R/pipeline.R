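#' Analysis configuration
#'
#' Bundles every tunable of the full analysis with defaults matching the
#' conventional choices: analysis window = latter half of the trajectory,
#' hydration cutoff 4.85 A and salt-bridge cutoff 6.75 A (each chosen to
#' enclose the first peak of the corresponding radial distribution
#' function), RDF shell thickness 0.1 A, density bin width 0.5 A, KWW fit
#' bounds RAF in \[0.05, 0.95\], MSD fit window 10-50 percent of the
#' maximum lag.
#'
#' @param window `c(start, end)` ns or `NULL` (latter half).
#' @param hydration_cutoff,saltbridge_cutoff Cutoffs in angstrom.
#' @param rdf_dr RDF shell thickness (angstrom).
#' @param density_bin_width Density-profile bin width (angstrom).
#' @param scd_convention Segmental vector convention for [scd_profile()].
#' @param kww_fit_bounds RAF-value bounds for [kww_fit()].
#' @param msd_fit_window Lag-fraction window for [diffusion_fit()].
#' @param origin_stride Time-origin stride for RAF and MSD.
#' @param smoothing_window_ns Presentation smoothing window for the area and
#'   thickness traces.
#' @return A `bl_analysis_config` list.
#' @export
analysis_config <- function(window = NULL,
                            hydration_cutoff = 4.85,
                            saltbridge_cutoff = 6.75,
                            rdf_dr = 0.1,
                            density_bin_width = 0.5,
                            scd_convention = "CH_bond",
                            kww_fit_bounds = c(0.05, 0.95),
                            msd_fit_window = c(0.1, 0.5),
                            origin_stride = 1L,
                            smoothing_window_ns = 5) {
  structure(
    list(
      window = window,
      hydration_cutoff = hydration_cutoff,
      saltbridge_cutoff = saltbridge_cutoff,
      rdf_dr = rdf_dr,
      density_bin_width = density_bin_width,
      scd_convention = scd_convention,
      kww_fit_bounds = kww_fit_bounds,
      msd_fit_window = msd_fit_window,
      origin_stride = as.integer(origin_stride),
      smoothing_window_ns = smoothing_window_ns
    ),
    class = "bl_analysis_config"
  )
}

#' Run the complete bilayer analysis
#'
#' Chains every analysis stage over one trajectory: area per lipid and
#' membrane thickness (mean over the window plus smoothed traces), the
#' hydration number (water oxygens within the hydration cutoff of each
#' headgroup center), the inter-lipid salt-bridge count (choline nitrogens
#' within the salt-bridge cutoff of each headgroup center, different lipid),
#' sn-1/sn-2 order-parameter profiles, tilt statistics, the headgroup RAF
#' with its KWW relaxation fit, and the lateral MSD with its diffusion fit.
#' Each stage is a pure function of (trajectory, config): running a stage
#' individually yields numbers identical to this driver. A failing stage
#' aborts with the stage name; results of completed stages are preserved in
#' the error condition's `partial` field.
#'
#' @param trajectory A `bl_trajectory` with assigned roles.
#' @param config A [analysis_config()].
#' @param out_dir Optional directory: writes `summary.json`, per-stage TSVs
#'   and the resolved configuration beside them.
#' @return A `bl_summary` list with elements `area`, `thickness`,
#'   `hydration`, `salt_bridges`, `scd_sn1`, `scd_sn2`, `tilt`, `raf`,
#'   `kww`, `msd`, `diffusion`, plus `summary` (one-row tibble of the
#'   headline numbers) and `config`.
#' @export
run_full_analysis <- function(trajectory, config = analysis_config(),
                              out_dir = NULL) {
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      cnd <- simpleError(paste0("stage '", name, "' failed: ", conditionMessage(e)))
      cnd$partial <- results
      stop(cnd)
    })
    results[[name]] <<- res
    res
  }

  leaflets <- stage("leaflets", assign_leaflets(trajectory))
  area <- stage("area", window_average(
    area_per_lipid(trajectory, leaflets, config$window), config$smoothing_window_ns
  ))
  thickness <- stage("thickness", window_average(
    membrane_thickness(trajectory, leaflets, config$window), config$smoothing_window_ns
  ))

  topo <- trajectory$topology
  heads <- select_atoms(topo, role = "headgroup_center")
  cholines <- select_atoms(topo, role = "choline_N")
  waters <- select_atoms(topo, role = "water_O")

  hydration <- stage("hydration", coordination_number(
    trajectory, heads, waters, config$hydration_cutoff,
    exclusion = "none", window = config$window
  ))
  salt_bridges <- stage("salt_bridges", coordination_number(
    trajectory, heads, cholines, config$saltbridge_cutoff,
    exclusion = "same_residue", window = config$window
  ))
  scd_sn1 <- stage("scd_sn1", scd_profile(
    trajectory, leaflets, "sn1", config$scd_convention, config$window
  ))
  scd_sn2 <- stage("scd_sn2", scd_profile(
    trajectory, leaflets, "sn2", config$scd_convention, config$window
  ))
  tilt <- stage("tilt", tilt_statistics(trajectory, leaflets, config$window))
  raf <- stage("raf", head_vector_raf(
    trajectory, leaflets, config$window, config$origin_stride
  ))
  kww <- stage("kww", kww_fit(raf, config$kww_fit_bounds))
  msd <- stage("msd", msd_lateral(
    trajectory, leaflets, config$window, config$origin_stride
  ))
  diffusion <- stage("diffusion", diffusion_fit(msd, config$msd_fit_window))

  summary_row <- tibble::tibble(
    area_mean_A2 = attr(area, "mean"), area_sd_A2 = attr(area, "sd"),
    thickness_mean_A = attr(thickness, "mean"), thickness_sd_A = attr(thickness, "sd"),
    hydration_number = attr(hydration, "mean"),
    salt_bridges = attr(salt_bridges, "mean"),
    scd_sn1_mean = mean(scd_sn1$scd), scd_sn2_mean = mean(scd_sn2$scd),
    tilt_mean_deg = attr(tilt, "mean"), tilt_sd_deg = attr(tilt, "sd"),
    kww_tau_ns = kww$tau, kww_beta = kww$beta,
    D_xy_A2_ns = diffusion$D_A2_ns, D_xy_cm2_s = diffusion$D_cm2_s
  )

  out <- structure(
    list(
      area = area, thickness = thickness, hydration = hydration,
      salt_bridges = salt_bridges, scd_sn1 = scd_sn1, scd_sn2 = scd_sn2,
      tilt = tilt, raf = raf, kww = kww, msd = msd, diffusion = diffusion,
      leaflets = leaflets, summary = summary_row, config = config
    ),
    class = "bl_summary"
  )
  if (!is.null(out_dir)) write_summary(out, out_dir)
  out
}

#' @export
print.bl_summary <- function(x, ...) {
  s <- x$summary
  cat("<bilayer analysis summary>\n")
  cat(sprintf("  area per lipid     : %.2f +/- %.2f A^2\n", s$area_mean_A2, s$area_sd_A2))
  cat(sprintf("  membrane thickness : %.2f +/- %.2f A\n", s$thickness_mean_A, s$thickness_sd_A))
  cat(sprintf("  hydration number   : %.2f waters/lipid (cutoff %.2f A)\n",
              s$hydration_number, x$config$hydration_cutoff))
  cat(sprintf("  salt bridges       : %.2f per lipid (cutoff %.2f A)\n",
              s$salt_bridges, x$config$saltbridge_cutoff))
  cat(sprintf("  mean S_CD          : sn-1 %.3f, sn-2 %.3f\n", s$scd_sn1_mean, s$scd_sn2_mean))
  cat(sprintf("  headgroup tilt     : %.1f +/- %.1f deg\n", s$tilt_mean_deg, s$tilt_sd_deg))
  if (isTRUE(x$kww$converged)) {
    cat(sprintf("  KWW relaxation     : tau = %.4g ns, beta = %.3f\n", s$kww_tau_ns, s$kww_beta))
  } else {
    cat("  KWW relaxation     : not converged (RAF never decays into the fit window)\n")
  }
  cat(sprintf("  lateral diffusion  : %.4g A^2/ns = %.4g cm^2/s\n", s$D_xy_A2_ns, s$D_xy_cm2_s))
  invisible(x)
}

write_summary <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      schema = "bilayr-summary-1",
      summary = as.list(x$summary),
      config = x$config[!vapply(x$config, is.null, logical(1))]
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  tsv <- function(df, name, params = list()) {
    path <- file.path(out_dir, name)
    hdr <- sprintf("# %s", paste(names(params), unlist(params), sep = " = "))
    con <- file(path, "w")
    if (length(params)) writeLines(hdr, con)
    close(con)
    suppressWarnings(utils::write.table(
      as.data.frame(df), path, append = length(params) > 0,
      sep = "\t", row.names = FALSE, quote = FALSE
    ))
  }
  w <- attr(x$area, "window")
  tsv(x$area, "area.tsv", list(units = "A^2", window_ns = paste(w, collapse = ":")))
  tsv(x$thickness, "thickness.tsv", list(units = "A", window_ns = paste(w, collapse = ":")))
  tsv(x$hydration, "hydration.tsv", list(cutoff_A = x$config$hydration_cutoff))
  tsv(x$salt_bridges, "salt_bridges.tsv", list(
    cutoff_A = x$config$saltbridge_cutoff, exclusion = "same_residue"
  ))
  tsv(rbind(x$scd_sn1, x$scd_sn2), "scd.tsv", list(
    convention = attr(x$scd_sn1, "vector_convention")
  ))
  tsv(x$tilt, "tilt.tsv", list(
    mean_deg = attr(x$tilt, "mean"), sd_deg = attr(x$tilt, "sd")
  ))
  tsv(x$raf, "raf.tsv", list(t_max_ns = attr(x$raf, "t_max")))
  tsv(x$msd, "msd.tsv", list(units = "A^2"))
  invisible(out_dir)
}

#' Read / write an analysis configuration file
#'
#' Plain-text `key = value` schema; keys are the arguments of
#' [analysis_config()] (two-element values comma-separated, e.g.
#' `kww_fit_bounds = 0.05,0.95`).
#'
#' @param path File path.
#' @return `read_analysis_config()`: a `bl_analysis_config`;
#'   `write_analysis_config()`: `path`, invisibly.
#' @export
read_analysis_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  cfg <- analysis_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    cfg[[key]] <- if (anyNA(num)) val else num
  }
  cfg
}

#' @rdname read_analysis_config
#' @param config A `bl_analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  writeLines(
    paste(names(config)[keep], vapply(config[keep], function(v) {
      paste(v, collapse = ",")
    }, character(1)), sep = " = "),
    path
  )
  invisible(path)
}
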