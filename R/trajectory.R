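#' Build a topology from an atom table
#'
#' A topology is the static description of the system: one row per atom with
#' its name, residue assignment and (after [assign_roles()]) its structural
#' role within a lipid, water or ion. Lipid bookkeeping (which atom is the
#' headgroup center, which the choline nitrogen, the ordered sn-1/sn-2 acyl
#' carbon lists and the carbon-to-bonded-hydrogen map) lives in the `lipids`
#' tibble and is populated by [assign_roles()].
#'
#' @param atoms A data frame with columns `name`, `resname`, `resid` and
#'   optionally `element` (guessed from `name` when absent). Row order is the
#'   atom order; 0-based `index` is derived from it.
#' @return An object of class `bl_topology`: a list with tibbles `atoms`
#'   (columns `index`, `name`, `resname`, `resid`, `element`, `role`,
#'   `chain_ordinal`) and `lipids` (empty until roles are assigned).
#' @export
build_topology <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("name", "resname", "resid") %in% names(atoms)))
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$name)
  atoms$index <- seq_len(nrow(atoms)) - 1L
  if (!"role" %in% names(atoms)) atoms$role <- rep("other", nrow(atoms))
  if (!"chain_ordinal" %in% names(atoms)) atoms$chain_ordinal <- rep(NA_integer_, nrow(atoms))
  atoms <- atoms[, c("index", "name", "resname", "resid", "element", "role", "chain_ordinal")]
  structure(
    list(atoms = atoms, lipids = empty_lipid_table()),
    class = "bl_topology"
  )
}

empty_lipid_table <- function() {
  tibble::tibble(
    resid = integer(), resname = character(),
    head = integer(), choline_n = integer(),
    sn1 = list(), sn2 = list(), h_map = list()
  )
}

#' @export
print.bl_topology <- function(x, ...) {
  cat(sprintf(
    "<bilayer topology> %d atoms, %d residues, %d lipids with assigned roles\n",
    nrow(x$atoms), length(unique(x$atoms$resid)), nrow(x$lipids)
  ))
  invisible(x)
}

#' Assemble a trajectory
#'
#' A trajectory couples a topology with a stack of coordinate frames and
#' per-frame orthorhombic box dimensions. Coordinates are in angstrom and
#' times in nanoseconds throughout the package.
#'
#' @param topology A `bl_topology`.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (angstrom).
#' @param times Numeric vector of frame times (ns), nondecreasing.
#' @param box Numeric `n_frames x 3` matrix of box edges `(Lx, Ly, Lz)`
#'   (angstrom), or a length-3 vector recycled to every frame.
#' @return An object of class `bl_trajectory`.
#' @export
build_trajectory <- function(topology, coords, times, box) {
  stopifnot(inherits(topology, "bl_topology"))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (dim(coords)[1] != nrow(topology$atoms)) {
    stop(
      "coordinate count (", dim(coords)[1], ") does not match atom count (",
      nrow(topology$atoms), ")"
    )
  }
  if (is.vector(box) && length(box) == 3) {
    box <- matrix(box, n_frames, 3, byrow = TRUE)
  }
  box <- as.matrix(box)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  if (any(box <= 0)) stop("box edges must be positive")
  stopifnot(length(times) == n_frames)
  if (is.unsorted(times)) stop("frame times must be nondecreasing")
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times), box = box),
    class = "bl_trajectory"
  )
}

#' @export
print.bl_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bilayer trajectory> %d atoms x %d frames, t = [%.4g, %.4g] ns, box[1] = (%.2f, %.2f, %.2f) A\n",
    dim(x$coords)[1], dim(x$coords)[3], x$times[1], x$times[length(x$times)],
    x$box[1, 1], x$box[1, 2], x$box[1, 3]
  ))
  invisible(x)
}

n_frames <- function(trajectory) dim(trajectory$coords)[3]
n_atoms <- function(trajectory) dim(trajectory$coords)[1]

# Frame time step, checked for uniformity (tolerance relative to the step).
frame_dt <- function(trajectory, tol = 1e-6) {
  dt <- diff(trajectory$times)
  if (length(dt) == 0) stop("at least 2 frames required")
  if (diff(range(dt)) > tol * max(mean(dt), 1e-12)) {
    stop("non-uniform frame spacing; dynamics operations require a uniform time step")
  }
  mean(dt)
}

#' Select atom indices from a topology
#'
#' A small selection helper used by the pair-statistics and density functions.
#' Selections combine residue names, atom names and roles; all given criteria
#' must match.
#'
#' @param topology A `bl_topology`.
#' @param resname,name,role Optional character vectors of accepted values.
#' @return Integer vector of 1-based atom row indices.
#' @examples
#' # water oxygens: select_atoms(topo, role = "water_O")
#' # arsenic headgroups: select_atoms(topo, resname = "POAC", name = "As")
#' @export
select_atoms <- function(topology, resname = NULL, name = NULL, role = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(role)) keep <- keep & a$role %in% role
  which(keep)
}
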