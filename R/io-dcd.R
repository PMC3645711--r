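# CHARMM/NAMD-dialect DCD binary trajectory I/O: little-endian, 4-byte
# Fortran record markers around every record. Layout written (and expected):
#   header record : 'CORD' + 20 int32 (icntrl); icntrl[1] = n frames,
#                   icntrl[2] = first step, icntrl[3] = save stride,
#                   icntrl[10] = timestep as float32 (interpreted in ps),
#                   icntrl[11] = unit-cell flag, icntrl[20] = 24 (version)
#   title record  : int32 count + count * 80 chars
#   natoms record : 1 int32
#   per frame     : [unit cell: 6 float64 (a, cos g, b, cos b, cos a, c)],
#                   x float32[n], y float32[n], z float32[n]

read_record <- function(con, what, size, expect_n = NULL) {
  head <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(head) == 0) return(NULL)
  n <- head / size
  dat <- readBin(con, what, n, size = size, endian = "little")
  tail <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(dat) < n || length(tail) == 0 || tail != head) {
    return(structure(list(), class = "bl_truncated"))
  }
  if (!is.null(expect_n) && n != expect_n) {
    stop("DCD record length ", n, " where ", expect_n, " expected")
  }
  dat
}

write_record <- function(con, dat, size) {
  writeBin(as.integer(length(dat) * size), con, size = 4, endian = "little")
  writeBin(dat, con, size = size, endian = "little")
  writeBin(as.integer(length(dat) * size), con, size = 4, endian = "little")
}

#' Read a DCD trajectory
#'
#' Reads a CHARMM/NAMD-style binary DCD (little-endian, 4-byte Fortran record
#' markers). The unit cell is taken from the per-frame cell records and must
#' be orthorhombic; frame times are `(first_step + i * stride) * timestep`
#' with the header timestep interpreted in picoseconds and converted to
#' nanoseconds.
#'
#' @param topology A `bl_topology` whose atom count must match the file.
#' @param path Path to the DCD file.
#' @param box Optional length-3 box override used when the file carries no
#'   unit-cell records.
#' @return A `bl_trajectory`.
#' @export
read_dcd <- function(topology, path, box = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))

  hd_len <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(hd_len) == 0) stop("empty DCD file: ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a DCD file (missing CORD magic): ", path)
  icntrl <- readBin(con, "integer", 20, size = 4, endian = "little")
  hd_tail <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(icntrl) < 20 || length(hd_tail) == 0 || hd_tail != hd_len) {
    stop("corrupt DCD header in ", path)
  }
  n_hdr_frames <- icntrl[1]
  first_step <- icntrl[2]
  stride <- max(icntrl[3], 1L)
  dt_ps <- readBin(writeBin(icntrl[10], raw(), size = 4, endian = "little"),
                   "numeric", 1, size = 4, endian = "little")
  has_cell <- icntrl[11] != 0

  # title record: int32 line count + 80-char lines; read as raw bytes
  t_head <- readBin(con, "integer", 1, size = 4, endian = "little")
  t_raw <- readBin(con, "raw", max(t_head, 0))
  t_tail <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(t_head) == 0 || length(t_raw) < t_head ||
      length(t_tail) == 0 || t_tail != t_head) {
    stop("corrupt DCD title record in ", path)
  }

  nat_rec <- read_record(con, "integer", 4, expect_n = 1)
  if (is.null(nat_rec) || inherits(nat_rec, "bl_truncated")) {
    stop("corrupt DCD natoms record in ", path)
  }
  n_at <- nat_rec[1]
  if (n_at != nrow(topology$atoms)) {
    stop(
      "DCD atom count (", n_at, ") does not match topology atom count (",
      nrow(topology$atoms), ")"
    )
  }
  if (!has_cell && is.null(box)) {
    stop("DCD carries no unit-cell records and no box override was supplied")
  }

  coords <- list()
  boxes <- list()
  repeat {
    if (has_cell) {
      cell <- read_record(con, "numeric", 8, expect_n = 6)
      if (is.null(cell)) break
      if (inherits(cell, "bl_truncated")) {
        stop("truncated DCD: last complete frame is ", length(coords), " in ", path)
      }
      if (abs(cell[2]) > 1e-6 || abs(cell[4]) > 1e-6 || abs(cell[5]) > 1e-6) {
        stop("triclinic DCD unit cell not supported (frame ", length(coords) + 1, ")")
      }
      bx <- cell[c(1, 3, 6)]
    } else {
      bx <- box
    }
    x <- read_record(con, "numeric", 4, expect_n = n_at)
    if (is.null(x) && !has_cell) break
    y <- read_record(con, "numeric", 4, expect_n = n_at)
    z <- read_record(con, "numeric", 4, expect_n = n_at)
    if (is.null(x) || is.null(y) || is.null(z) ||
        inherits(x, "bl_truncated") || inherits(y, "bl_truncated") ||
        inherits(z, "bl_truncated")) {
      stop("truncated DCD: last complete frame is ", length(coords), " in ", path)
    }
    coords[[length(coords) + 1]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1]] <- bx
  }
  nfr <- length(coords)
  if (nfr == 0) stop("DCD body contains no frames: ", path)
  if (n_hdr_frames > 0 && nfr < n_hdr_frames) {
    stop("truncated DCD: header declares ", n_hdr_frames,
         " frames but last complete frame is ", nfr, " in ", path)
  }
  arr <- array(unlist(coords, use.names = FALSE), c(n_at, 3, nfr))
  times_ns <- (first_step + (seq_len(nfr) - 1) * stride) * dt_ps * 1e-3
  build_trajectory(topology, arr, times_ns, do.call(rbind, boxes))
}

#' Write a DCD trajectory
#'
#' Companion writer for [read_dcd()] using the same dialect (see that page
#' for the layout). Coordinates are stored as 32-bit floats, so a round trip
#' preserves them to about 6 significant digits.
#'
#' @param trajectory A `bl_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- n_frames(trajectory)
  dt_ps <- if (nfr > 1) frame_dt(trajectory) * 1e3 else 1
  t0_steps <- as.integer(round(trajectory$times[1] * 1e3 / dt_ps))

  icntrl <- integer(20)
  icntrl[1] <- nfr
  icntrl[2] <- t0_steps
  icntrl[3] <- 1L
  icntrl[10] <- readBin(writeBin(dt_ps, raw(), size = 4, endian = "little"),
                        "integer", 1, size = 4, endian = "little")
  icntrl[11] <- 1L
  icntrl[20] <- 24L

  writeBin(84L, con, size = 4, endian = "little")
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4, endian = "little")
  writeBin(84L, con, size = 4, endian = "little")

  title <- sprintf("%-80s", "synthetic bilayer trajectory")
  writeBin(as.integer(4 + 80), con, size = 4, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(as.integer(4 + 80), con, size = 4, endian = "little")

  write_record(con, as.integer(n_atoms(trajectory)), 4)
  for (m in seq_len(nfr)) {
    bx <- trajectory$box[m, ]
    write_record(con, as.numeric(c(bx[1], 0, bx[2], 0, 0, bx[3])), 8)
    write_record(con, as.numeric(trajectory$coords[, 1, m]), 4)
    write_record(con, as.numeric(trajectory$coords[, 2, m]), 4)
    write_record(con, as.numeric(trajectory$coords[, 3, m]), 4)
  }
  invisible(path)
}
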