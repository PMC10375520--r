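# Volumetric export of density maps for contour display in molecular
# viewers. Two standards are supported: Gaussian cube (text, Bohr units)
# and MRC/CCP4 (binary, mode 2 float). One map (one element channel) per
# file.

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

element_z <- function(el) {
  z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, P = 15,
         S = 16, Cl = 17, K = 19, Ca = 20)
  out <- unname(z[el])
  out[is.na(out)] <- 0
  out
}

#' Write a density map to a volumetric file
#'
#' Dispatches on `format`: `"cube"` (Gaussian cube, text, coordinates
#' converted to Bohr) or `"mrc"` (MRC/CCP4 binary, mode 2). Both round-trip
#' through the matching readers with grid values equal within 1e-5 and
#' identical origin/spacing metadata.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @param format `"cube"` or `"mrc"`.
#' @return `path`, invisibly.
#' @export
write_volumetric <- function(map, path, format = c("cube", "mrc")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported volumetric ",
                                              "format: ", format[1],
                                              call. = FALSE))
  switch(format, cube = write_cube(map, path), mrc = write_mrc(map, path))
}

#' @rdname write_volumetric
#' @export
read_volumetric <- function(path, format = c("cube", "mrc")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported volumetric ",
                                              "format: ", format[1],
                                              call. = FALSE))
  switch(format, cube = read_cube(path), mrc = read_mrc(path))
}

#' Gaussian cube I/O
#'
#' Writes the map as an orthogonal-axes cube file (values in free units,
#' coordinates in Bohr, z fastest as the format requires). A single dummy
#' atom of the map's element is placed at the grid center so that viewers
#' display the file. `read_cube` inverts the writer.
#'
#' @param map a [density_map()].
#' @param path file path.
#' @return `path` (write) / a [density_map()] (read).
#' @export
write_cube <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  g <- map$grid
  np <- g$points
  origin <- (g$center - g$side / 2) * BOHR_PER_ANGSTROM
  step <- g$spacing * BOHR_PER_ANGSTROM
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("shiftmaps %s density map (element %s, n_envs %d)",
                       map$kind, map$element, map$n_envs),
               "atomic density on cubic grid; coordinates in Bohr"), con)
  writeLines(sprintf("%5d %15.8f %15.8f %15.8f", 1L,
                     origin[1], origin[2], origin[3]), con)
  writeLines(sprintf("%5d %15.8f %15.8f %15.8f", np, step, 0, 0), con)
  writeLines(sprintf("%5d %15.8f %15.8f %15.8f", np, 0, step, 0), con)
  writeLines(sprintf("%5d %15.8f %15.8f %15.8f", np, 0, 0, step), con)
  ctr <- g$center * BOHR_PER_ANGSTROM
  writeLines(sprintf("%5d %15.8f %15.8f %15.8f %15.8f",
                     element_z(map$element), 0, ctr[1], ctr[2], ctr[3]), con)
  # cube order: x slowest, z fastest
  v <- aperm(map$values, c(3, 2, 1))  # now [z, y, x]; write with x outer
  flat <- as.vector(v)  # z fastest within each (y, x); x slowest overall
  chunks <- split(flat, ceiling(seq_along(flat) / 6))
  writeLines(vapply(chunks, function(ch)
    paste(sprintf("%13.5E", ch), collapse = " "), character(1)), con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr3 <- scan(text = lines[3], quiet = TRUE)
  natoms <- as.integer(hdr3[1])
  origin <- hdr3[2:4] / BOHR_PER_ANGSTROM
  ax <- scan(text = lines[4], quiet = TRUE)
  ay <- scan(text = lines[5], quiet = TRUE)
  az <- scan(text = lines[6], quiet = TRUE)
  np <- as.integer(ax[1])
  if (np != as.integer(ay[1]) || np != as.integer(az[1])) {
    stop("only cubic grids are supported", call. = FALSE)
  }
  step <- ax[2] / BOHR_PER_ANGSTROM
  side <- step * (np - 1L)
  center <- origin + side / 2
  first_data <- 7L + abs(natoms)
  vals <- scan(text = lines[first_data:length(lines)], quiet = TRUE)
  if (length(vals) != np^3) {
    stop("cube data length mismatch", call. = FALSE)
  }
  arr <- aperm(array(vals, dim = c(np, np, np)), c(3, 2, 1))
  atom_line <- scan(text = lines[7], quiet = TRUE)
  zmap <- c("1" = "H", "6" = "C", "7" = "N", "8" = "O", "9" = "F",
            "11" = "Na", "12" = "Mg", "15" = "P", "16" = "S", "17" = "Cl",
            "19" = "K", "20" = "Ca")
  el <- zmap[as.character(as.integer(atom_line[1]))]
  if (is.na(el)) el <- "X"
  density_map(arr, grid_spec(np, side, center), unname(el), n_envs = 1L,
              kind = "candidate")
}

#' MRC/CCP4 I/O
#'
#' Mode-2 (32-bit float) MRC with an orthogonal cell, x fastest, and the
#' map origin stored in the ORIGIN header words (Angstrom). Values survive
#' the float32 round trip within 1e-5 for magnitudes of order 1.
#'
#' @param map a [density_map()].
#' @param path file path.
#' @return `path` (write) / a [density_map()] (read).
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  g <- map$grid
  np <- g$points
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- map$values
  wi(c(np, np, np))              # NX NY NZ
  wi(2L)                         # MODE 2 = float32
  wi(c(0L, 0L, 0L))              # NXSTART..
  wi(c(np, np, np))              # MX MY MZ
  wf(rep(g$side + g$spacing, 3)) # CELLA (sampling-consistent cell)
  wf(c(90, 90, 90))              # CELLB
  wi(c(1L, 2L, 3L))              # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v))) # DMIN DMAX DMEAN
  wi(1L)                         # ISPG
  wi(0L)                         # NSYMBT
  wi(rep(0L, 25))                # EXTRA (words 25-49)
  wf(g$center - g$side / 2)      # ORIGIN x, y, z (words 50-52, Angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(0)                          # RMS (not maintained)
  wi(1L)                         # NLABL
  lab <- sprintf("shiftmaps %s %s n_envs=%d", map$kind, map$element,
                 map$n_envs)
  lab <- substr(paste0(lab, strrep(" ", 80)), 1, 80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 720, eos = NULL)
  wf(as.vector(v))               # x fastest = R array order
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only mode-2 (float) MRC is supported", call. = FALSE)
  ri(3)                 # nxstart
  m <- ri(3)            # mx my mz
  cella <- rf(3)
  rf(3)                 # cellb
  ri(3)                 # mapc/mapr/maps
  rf(3)                 # dmin dmax dmean
  ri(2)                 # ispg nsymbt
  ri(25)                # extra
  origin <- rf(3)
  readBin(con, "raw", 8)  # MAP + machine stamp
  rf(1)                 # rms
  ri(1)                 # nlabl
  lab <- readChar(con, 80, useBytes = TRUE)
  readChar(con, 720, useBytes = TRUE)
  n <- prod(dims)
  v <- rf(n)
  np <- dims[1]
  if (dims[2] != np || dims[3] != np) {
    stop("only cubic grids are supported", call. = FALSE)
  }
  spacing <- cella[1] / m[1]
  side <- spacing * (np - 1L)
  center <- origin + side / 2
  el <- sub("^shiftmaps \\S+ (\\S+) .*$", "\\1", trimws(lab))
  if (!nzchar(el) || nchar(el) > 2) el <- "X"
  density_map(array(v, dim = dims), grid_spec(np, side, center), el,
              n_envs = 1L, kind = "candidate")
}
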