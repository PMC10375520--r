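#' @useDynLib shiftmaps, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

#' Elements supported by the environment database
#'
#' The default element set covers the twelve elements present in typical
#' molecular-crystal shift databases.
#' @export
supported_elements <- function() {
  c("H", "C", "N", "O", "S", "F", "P", "Cl", "Na", "Ca", "Mg", "K")
}

#' Construct a periodic crystal structure
#'
#' A `crystal_structure` holds a triclinic cell (lengths in Angstrom, angles
#' in degrees) and a list of atomic sites in fractional coordinates. It is the
#' unit of both database and candidate input.
#'
#' @param cell_lengths numeric(3), a, b, c in Angstrom (> 0).
#' @param cell_angles numeric(3), alpha, beta, gamma in degrees, each in
#'   (0, 180).
#' @param elements character vector of element symbols, one per site.
#' @param frac numeric matrix (n x 3) of fractional coordinates; wrapped
#'   into `[0, 1)`.
#' @param labels optional character site labels; defaults to element + index.
#' @param structure_id opaque identifier.
#' @param elements_allowed permitted element symbols; defaults to
#'   [supported_elements()].
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell_lengths, cell_angles, elements, frac,
                              labels = NULL, structure_id = "xtal",
                              elements_allowed = supported_elements()) {
  cell_lengths <- as.numeric(cell_lengths)
  cell_angles <- as.numeric(cell_angles)
  if (length(cell_lengths) != 3L || any(!is.finite(cell_lengths)) ||
      any(cell_lengths <= 0)) {
    stop("cell lengths must be three positive finite numbers", call. = FALSE)
  }
  if (length(cell_angles) != 3L || any(!is.finite(cell_angles)) ||
      any(cell_angles <= 0) || any(cell_angles >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  frac <- as.matrix(frac)
  if (is.null(dim(frac)) || ncol(frac) != 3L) {
    stop("frac must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(frac) <- "double"
  if (any(!is.finite(frac))) {
    stop("fractional coordinates must be finite", call. = FALSE)
  }
  elements <- as.character(elements)
  if (length(elements) != nrow(frac)) {
    stop("one element symbol per site required", call. = FALSE)
  }
  bad <- setdiff(unique(elements), elements_allowed)
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  frac <- frac - floor(frac)  # store in [0, 1)
  if (is.null(labels)) {
    labels <- paste0(elements, seq_along(elements))
  }
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("site labels must be unique", call. = FALSE)
  }
  structure(list(
    structure_id = as.character(structure_id),
    cell_lengths = cell_lengths,
    cell_angles = cell_angles,
    elements = elements,
    frac = frac,
    labels = labels
  ), class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("<crystal_structure> ", x$structure_id, "\n", sep = "")
  cat(sprintf("  cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f\n",
              x$cell_lengths[1], x$cell_lengths[2], x$cell_lengths[3],
              x$cell_angles[1], x$cell_angles[2], x$cell_angles[3]))
  tab <- table(x$elements)
  cat("  sites:", nrow(x$frac), "(",
      paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
  invisible(x)
}

#' Cell matrix (lower-triangular convention)
#'
#' Rows are the lattice vectors a, b, c; Cartesian coordinates are obtained
#' as `frac %*% cell_matrix(x)`. The a vector lies along x and b lies in the
#' xy plane.
#'
#' @param x a `crystal_structure`, or numeric(3) cell lengths.
#' @param angles cell angles in degrees when `x` is a length vector.
#' @return 3 x 3 numeric matrix in Angstrom.
#' @export
cell_matrix <- function(x, angles = NULL) {
  if (inherits(x, "crystal_structure")) {
    len <- x$cell_lengths
    ang <- x$cell_angles
  } else {
    len <- as.numeric(x)
    ang <- as.numeric(angles)
  }
  al <- ang[1] * pi / 180
  be <- ang[2] * pi / 180
  ga <- ang[3] * pi / 180
  a <- len[1]; b <- len[2]; c <- len[3]
  bx <- b * cos(ga); by <- b * sin(ga)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) {
    stop("degenerate cell: inconsistent angles", call. = FALSE)
  }
  rbind(c(a, 0, 0), c(bx, by, 0), c(cx, cy, sqrt(cz2)))
}

#' Convert fractional to Cartesian coordinates
#' @param structure a `crystal_structure`.
#' @param frac fractional coordinate matrix; defaults to the structure's sites.
#' @return n x 3 Cartesian matrix (Angstrom).
#' @export
frac_to_cart <- function(structure, frac = structure$frac) {
  as.matrix(frac) %*% cell_matrix(structure)
}

# Perpendicular width of the cell along each axis: V / area of the opposite
# face. Governs how many cell replicas are needed to cover a sphere.
min_perp_widths <- function(M) {
  v <- abs(det(M))
  if (v < 1e-8) stop("degenerate cell: near-zero volume", call. = FALSE)
  cross <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                            u[3] * w[1] - u[1] * w[3],
                            u[1] * w[2] - u[2] * w[1])
  areas <- c(sqrt(sum(cross(M[2, ], M[3, ])^2)),
             sqrt(sum(cross(M[3, ], M[1, ])^2)),
             sqrt(sum(cross(M[1, ], M[2, ])^2)))
  v / areas
}

#' Extract a spherical local atomic environment
#'
#' Collects every periodic image atom whose Cartesian distance to a chosen
#' central site is at most `radius`, replicating the unit cell far enough
#' that no image inside the sphere can be missed (the replication count per
#' axis is `ceiling(radius / perpendicular_width) + 1`).
#'
#' @param structure a `crystal_structure`.
#' @param center_site integer site index of the sphere center.
#' @param radius sphere radius in Angstrom (default 7, the environment
#'   radius used throughout the mapping pipeline).
#' @return A `local_env`: list with `elements`, `xyz` (absolute Cartesian,
#'   Angstrom), `site_index`, `image` (integer n x 3 lattice offsets),
#'   `center_index` (always 1), `radius` and `source`.
#' @export
expand_to_sphere <- function(structure, center_site, radius = 7) {
  stopifnot(inherits(structure, "crystal_structure"))
  n <- nrow(structure$frac)
  center_site <- as.integer(center_site)
  if (is.na(center_site) || center_site < 1L || center_site > n) {
    stop("center_site out of range", call. = FALSE)
  }
  if (!is.finite(radius) || radius <= 0) {
    stop("radius must be positive", call. = FALSE)
  }
  M <- cell_matrix(structure)
  widths <- min_perp_widths(M)
  reps <- ceiling(radius / widths) + 1
  center <- drop(structure$frac[center_site, , drop = FALSE] %*% M)

  grid <- as.matrix(expand.grid(i = -reps[1]:reps[1],
                                j = -reps[2]:reps[2],
                                k = -reps[3]:reps[3]))
  shift <- grid %*% M  # one Cartesian shift per image
  base <- structure$frac %*% M
  n_img <- nrow(grid)
  xyz <- base[rep(seq_len(n), times = n_img), , drop = FALSE] +
    shift[rep(seq_len(n_img), each = n), , drop = FALSE]
  site_index <- rep(seq_len(n), times = n_img)
  image <- grid[rep(seq_len(n_img), each = n), , drop = FALSE]

  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  keep <- d2 <= radius^2 + 1e-9
  xyz <- xyz[keep, , drop = FALSE]
  site_index <- site_index[keep]
  image <- image[keep, , drop = FALSE]
  d <- sqrt(d2[keep])
  ord <- order(d, site_index, image[, 1], image[, 2], image[, 3])
  structure(list(
    elements = structure$elements[site_index[ord]],
    xyz = xyz[ord, , drop = FALSE],
    site_index = site_index[ord],
    image = image[ord, , drop = FALSE],
    center_index = 1L,
    radius = radius,
    source = list(structure_id = structure$structure_id,
                  site_index = center_site)
  ), class = "local_env")
}

#' @export
print.local_env <- function(x, ...) {
  cat("<local_env> ", x$source$structure_id, " site ", x$source$site_index,
      ": ", length(x$elements), " atoms within ", x$radius, " A\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 coordinate matrix.
#' @param tf list with rotation `R` (3 x 3) and translation `t` (length 3),
#'   as returned by [rigid_align()]; applied as `xyz %*% R + t`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  sweep(as.matrix(xyz) %*% tf$R, 2, tf$t, "+")
}

# Transform a local environment's coordinates in place.
transform_env <- function(env, tf) {
  env$xyz <- apply_transform(env$xyz, tf)
  env
}
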