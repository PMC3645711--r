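#' Default atom-role rules for phosphocholine-like lipids
#'
#' Role assignment is rule-driven so that POPC, its arsenate analogue POAC
#' and arbitrary lipid chemistries share one code path. A rule set maps, per
#' lipid residue name: the headgroup center atom (the phosphorus of a
#' phosphate or the arsenic of an arsenate), the choline nitrogen, the acyl
#' chain carbon naming scheme and the carbon-to-bonded-hydrogen naming
#' scheme; plus the water residue/oxygen names and ion residue names.
#'
#' Chain carbons are recognised as `<prefix><ordinal>`: with the conventional
#' labeling the sn-1 chain prefix is `"C3"` (so atom `C31` is carbon 1, `C32`
#' carbon 2, ...) and the sn-2 prefix is `"C2"` (`C21` is carbon 1). Bonded
#' hydrogens are recognised as `<h_prefix><ordinal>` for each listed prefix.
#'
#' @param lipid_resnames Character vector of lipid residue names the rules
#'   should cover.
#' @param headgroup_center Named character vector mapping residue name to the
#'   headgroup center atom name; unnamed defaults: `"As"` for `POAC`, `"P"`
#'   otherwise.
#' @param sn1_length,sn2_length Number of carbons in each chain (palmitoyl 16
#'   and oleoyl 18 by default).
#' @return A `bl_role_rules` list.
#' @export
default_role_rules <- function(lipid_resnames = c("POPC", "POAC"),
                               headgroup_center = NULL,
                               sn1_length = 16, sn2_length = 18) {
  lipids <- lapply(lipid_resnames, function(rn) {
    hg <- if (!is.null(headgroup_center) && rn %in% names(headgroup_center)) {
      headgroup_center[[rn]]
    } else if (identical(rn, "POAC")) "As" else "P"
    list(
      headgroup_center = hg, choline_N = "N",
      sn1_prefix = "C3", sn1_length = sn1_length, sn1_h_prefixes = c("HA", "HB"),
      sn2_prefix = "C2", sn2_length = sn2_length, sn2_h_prefixes = c("HC", "HD"),
      carbonyl = c("C21", "O22", "C31", "O32")
    )
  })
  names(lipids) <- lipid_resnames
  structure(
    list(
      lipids = lipids,
      water = list(resnames = c("TIP3", "HOH", "WAT", "SPC"), oxygen = c("OH2", "O", "OW")),
      ions = c("SOD", "CLA", "NA", "CL", "POT", "K")
    ),
    class = "bl_role_rules"
  )
}

#' Read / write a role-rules configuration file
#'
#' Plain-text key-value schema, one directive per line, `#` comments allowed:
#' \preformatted{
#' lipid POAC
#'   headgroup_center As
#'   choline_N N
#'   sn1 C3 16 HA,HB
#'   sn2 C2 18 HC,HD
#' water TIP3 OH2
#' ions SOD,CLA
#' }
#' `sn1`/`sn2` take the carbon-name prefix, the chain length, and a
#' comma-separated list of bonded-hydrogen name prefixes.
#'
#' @param path File path.
#' @return `read_role_rules()`: a `bl_role_rules`; `write_role_rules()`:
#'   `path`, invisibly.
#' @export
read_role_rules <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  rules <- list(lipids = list(), water = list(resnames = character(), oxygen = character()),
                ions = character())
  current <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key == "lipid") {
      current <- tok[2]
      rules$lipids[[current]] <- list()
    } else if (key %in% c("headgroup_center", "choline_N")) {
      if (is.null(current)) stop("'", key, "' outside a lipid block in ", path)
      rules$lipids[[current]][[key]] <- tok[2]
    } else if (key %in% c("sn1", "sn2")) {
      if (is.null(current)) stop("'", key, "' outside a lipid block in ", path)
      rules$lipids[[current]][[paste0(key, "_prefix")]] <- tok[2]
      rules$lipids[[current]][[paste0(key, "_length")]] <- as.integer(tok[3])
      rules$lipids[[current]][[paste0(key, "_h_prefixes")]] <-
        strsplit(tok[4], ",")[[1]]
    } else if (key == "carbonyl") {
      rules$lipids[[current]][["carbonyl"]] <- strsplit(tok[2], ",")[[1]]
    } else if (key == "water") {
      rules$water$resnames <- c(rules$water$resnames, tok[2])
      rules$water$oxygen <- c(rules$water$oxygen, tok[3])
    } else if (key == "ions") {
      rules$ions <- c(rules$ions, strsplit(tok[2], ",")[[1]])
    } else {
      stop("unknown role-rule directive '", key, "' in ", path)
    }
  }
  structure(rules, class = "bl_role_rules")
}

#' @rdname read_role_rules
#' @param rules A `bl_role_rules` object.
#' @export
write_role_rules <- function(rules, path) {
  out <- character()
  for (rn in names(rules$lipids)) {
    lp <- rules$lipids[[rn]]
    out <- c(
      out, paste("lipid", rn),
      paste("  headgroup_center", lp$headgroup_center),
      paste("  choline_N", lp$choline_N),
      paste("  sn1", lp$sn1_prefix, lp$sn1_length, paste(lp$sn1_h_prefixes, collapse = ",")),
      paste("  sn2", lp$sn2_prefix, lp$sn2_length, paste(lp$sn2_h_prefixes, collapse = ","))
    )
    if (!is.null(lp$carbonyl)) out <- c(out, paste("  carbonyl", paste(lp$carbonyl, collapse = ",")))
  }
  for (i in seq_along(rules$water$resnames)) {
    out <- c(out, paste("water", rules$water$resnames[i], rules$water$oxygen[i]))
  }
  if (length(rules$ions)) out <- c(out, paste("ions", paste(rules$ions, collapse = ",")))
  writeLines(out, path)
  invisible(path)
}

#' Assign structural roles to every atom of a topology
#'
#' Applies a rule set (see [default_role_rules()]) to label every atom as
#' headgroup center, choline nitrogen, sn-1/sn-2 chain carbon (with its
#' 1-based chain ordinal), carbonyl, water oxygen, ion or other, and builds
#' the per-lipid bookkeeping table (headgroup/choline atom indices, ordered
#' chain carbon lists, carbon-to-bonded-hydrogen map) that the analysis
#' functions consume.
#'
#' @param topology A `bl_topology`.
#' @param rules A `bl_role_rules`; defaults to [default_role_rules()].
#' @return The topology with `atoms$role`, `atoms$chain_ordinal` and
#'   `$lipids` populated.
#' @export
assign_roles <- function(topology, rules = default_role_rules()) {
  a <- topology$atoms
  role_vec <- rep("other", nrow(a))
  ord_vec <- rep(NA_integer_, nrow(a))

  # waters and ions
  w <- a$resname %in% rules$water$resnames
  role_vec[w & a$name %in% rules$water$oxygen] <- "water_O"
  role_vec[a$resname %in% rules$ions] <- "ion"

  lipid_rows <- list()
  for (rn in intersect(names(rules$lipids), unique(a$resname))) {
    lp <- rules$lipids[[rn]]
    for (rid in unique(a$resid[a$resname == rn])) {
      sel <- which(a$resname == rn & a$resid == rid)
      nm <- a$name[sel]
      head_i <- sel[nm == lp$headgroup_center]
      n_i <- sel[nm == lp$choline_N]
      if (length(head_i) != 1 || length(n_i) != 1) {
        stop(
          "lipid residue ", rid, " (", rn, ") lacks a unique headgroup center '",
          lp$headgroup_center, "' and/or choline nitrogen '", lp$choline_N, "'"
        )
      }
      role_vec[head_i] <- "headgroup_center"
      role_vec[n_i] <- "choline_N"
      chain <- function(prefix, len, h_prefixes, role) {
        idx <- integer(len)
        h_map <- vector("list", len)
        for (k in seq_len(len)) {
          ci <- sel[nm == paste0(prefix, k)]
          if (length(ci) != 1) {
            stop("lipid residue ", rid, " (", rn, "): chain carbon ",
                 paste0(prefix, k), " missing or duplicated")
          }
          role_vec[ci] <<- role
          ord_vec[ci] <<- k
          idx[k] <- ci
          h_map[[k]] <- sel[nm %in% paste0(h_prefixes, k)]
        }
        list(idx = idx, h_map = h_map)
      }
      sn1 <- chain(lp$sn1_prefix, lp$sn1_length, lp$sn1_h_prefixes, "chain_carbon_sn1")
      sn2 <- chain(lp$sn2_prefix, lp$sn2_length, lp$sn2_h_prefixes, "chain_carbon_sn2")
      if (!is.null(lp$carbonyl)) {
        cb <- sel[nm %in% lp$carbonyl & role_vec[sel] == "other"]
        role_vec[cb] <- "carbonyl"
      }
      h_map <- c(sn1$h_map, sn2$h_map)
      names(h_map) <- c(paste0("sn1_", seq_along(sn1$h_map)), paste0("sn2_", seq_along(sn2$h_map)))
      lipid_rows[[length(lipid_rows) + 1]] <- tibble::tibble(
        resid = as.integer(rid), resname = rn,
        head = head_i, choline_n = n_i,
        sn1 = list(sn1$idx), sn2 = list(sn2$idx), h_map = list(h_map)
      )
    }
  }
  a$role <- role_vec
  a$chain_ordinal <- ord_vec
  topology$atoms <- a
  topology$lipids <- if (length(lipid_rows)) {
    dplyr::bind_rows(lipid_rows)
  } else {
    empty_lipid_table()
  }
  topology
}
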