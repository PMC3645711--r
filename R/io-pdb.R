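#' Read a multi-model PDB file as a trajectory
#'
#' Parses `ATOM`/`HETATM` records grouped by `MODEL`/`ENDMDL` (a bare list of
#' `ATOM` records is treated as a single frame). Box dimensions come from
#' `CRYST1` records: a `CRYST1` line applies to every subsequent model until
#' the next `CRYST1`, so both the common single-header layout and per-frame
#' boxes from the fixture writer are understood. Only orthorhombic cells
#' (all angles 90 degrees) are accepted. Occupancy and B-factor are ignored;
#' alternate locations other than blank or `'A'` are rejected.
#'
#' @param path Path to a PDB file.
#' @param model_range Optional `c(first, last)` 1-based model numbers to keep.
#' @param box Optional length-3 box override `(Lx, Ly, Lz)` in angstrom, used
#'   when the file lacks `CRYST1`.
#' @param dt_ns Time spacing assigned to successive models (ns). Default 0.005
#'   (one stored frame every 5 ps, the conventional storage interval).
#' @return A [build_trajectory()] object with all roles set to `"other"`
#'   (pending [assign_roles()]).
#' @export
read_pdb <- function(path, model_range = NULL, box = NULL, dt_ns = 0.005) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)

  cryst_at <- which(rec == "CRYST1")
  model_at <- which(rec == "MODEL ")
  atom_at <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_at) == 0) stop("no ATOM records in ", path)

  # assign each atom line to a model
  if (length(model_at) == 0) {
    model_of_atom <- rep(1L, length(atom_at))
    n_models <- 1L
  } else {
    model_of_atom <- findInterval(atom_at, model_at)
    if (any(model_of_atom == 0)) stop("ATOM records before first MODEL in ", path)
    n_models <- length(model_at)
  }

  # box per model: last CRYST1 seen before the model's first atom line
  boxes <- matrix(NA_real_, n_models, 3)
  for (m in seq_len(n_models)) {
    first_atom <- atom_at[match(m, model_of_atom)]
    prior <- cryst_at[cryst_at < first_atom]
    if (length(prior) > 0) {
      boxes[m, ] <- parse_cryst1(lines[prior[length(prior)]])
    } else if (!is.null(box)) {
      boxes[m, ] <- box
    } else {
      stop("frame ", m, ": no CRYST1 record and no box override supplied")
    }
  }

  per_model <- split(atom_at, model_of_atom)
  counts <- lengths(per_model)
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop(
      "atom-count mismatch across models: model 1 has ", counts[1],
      " atoms but model ", names(per_model)[bad], " has ", counts[bad]
    )
  }

  al1 <- lines[per_model[[1]]]
  altloc <- substr(al1, 17, 17)
  if (any(!altloc %in% c(" ", "A"))) {
    stop("alternate location indicators other than blank/'A' are not supported")
  }
  name <- trimws(substr(al1, 13, 16))
  resname <- trimws(substr(al1, 18, 21))
  resid <- as.integer(substr(al1, 23, 26))
  element <- trimws(substr(al1, 77, 78))
  if (all(element == "")) element <- guess_element(name) else element <- ifelse(
    element == "", guess_element(name),
    sub("^(.)(.)$", "\\1\\L\\2", toupper(element), perl = TRUE)
  )
  topo <- build_topology(tibble::tibble(
    name = name, resname = resname, resid = resid, element = element
  ))

  n_at <- unname(counts[1])
  coords <- array(NA_real_, c(n_at, 3, n_models))
  for (m in seq_len(n_models)) {
    al <- lines[per_model[[m]]]
    coords[, 1, m] <- as.numeric(substr(al, 31, 38))
    coords[, 2, m] <- as.numeric(substr(al, 39, 46))
    coords[, 3, m] <- as.numeric(substr(al, 47, 54))
  }
  if (anyNA(coords)) stop("unparseable coordinate field in ", path)

  keep <- seq_len(n_models)
  if (!is.null(model_range)) {
    keep <- keep[keep >= model_range[1] & keep <= model_range[2]]
    if (length(keep) == 0) stop("model_range selects no models")
  }
  build_trajectory(
    topo, coords[, , keep, drop = FALSE],
    times = (keep - 1) * dt_ns, box = boxes[keep, , drop = FALSE]
  )
}

parse_cryst1 <- function(line) {
  a <- as.numeric(substr(line, 7, 15))
  b <- as.numeric(substr(line, 16, 24))
  c <- as.numeric(substr(line, 25, 33))
  ang <- c(
    as.numeric(substr(line, 34, 40)),
    as.numeric(substr(line, 41, 47)),
    as.numeric(substr(line, 48, 54))
  )
  ang[is.na(ang)] <- 90
  if (any(abs(ang - 90) > 1e-3)) {
    stop("triclinic unit cell (angles ", paste(ang, collapse = ", "),
         ") not supported; only orthorhombic boxes are handled")
  }
  c(a, b, c)
}

#' Write a trajectory as a multi-model PDB fixture
#'
#' Writes a `CRYST1` record before every `MODEL` (so per-frame box
#' fluctuations survive a round trip) and atom records with coordinates at
#' the standard 3-decimal PDB precision.
#'
#' @param trajectory A `bl_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(trajectory, path) {
  a <- trajectory$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nfr <- n_frames(trajectory)
  serial <- pmin(seq_len(nrow(a)), 99999L)
  for (m in seq_len(nfr)) {
    bx <- trajectory$box[m, ]
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      bx[1], bx[2], bx[3], 90, 90, 90
    ), con)
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, formatC(a$name, width = 4), a$resname, a$resid %% 10000L,
      trajectory$coords[, 1, m], trajectory$coords[, 2, m], trajectory$coords[, 3, m],
      1, 0, toupper(substr(a$element, 1, 2))
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
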