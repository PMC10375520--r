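# Per-element 3D Gaussian atomic density maps: the SIM/IIM representation.
# A map value of 1 at a point means an atom of that element sits exactly
# there in every selected environment.

#' Cubic evaluation grid specification
#'
#' @param points points per axis (default 31).
#' @param side cube side length in Angstrom (default 12). With the defaults
#'   the spacing is 12/30 = 0.4 A (31 points inclusive of both ends).
#' @param center Cartesian position of the queried site (grid center).
#' @return object of class `grid_spec` with derived `spacing` and per-axis
#'   coordinate vectors `ax`, `ay`, `az`.
#' @export
grid_spec <- function(points = 31, side = 12, center = c(0, 0, 0)) {
  points <- as.integer(points)
  if (points < 2L) stop("points must be >= 2", call. = FALSE)
  if (side <= 0) stop("side must be > 0", call. = FALSE)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("center must be a finite Cartesian triple", call. = FALSE)
  }
  spacing <- side / (points - 1L)
  half <- side / 2
  structure(list(points = points, side = side, center = center,
                 spacing = spacing,
                 ax = seq(center[1] - half, center[1] + half,
                          length.out = points),
                 ay = seq(center[2] - half, center[2] + half,
                          length.out = points),
                 az = seq(center[3] - half, center[3] + half,
                          length.out = points)),
            class = "grid_spec")
}

same_grid <- function(a, b, tol = 1e-9) {
  a$points == b$points && abs(a$side - b$side) < tol &&
    all(abs(a$center - b$center) < tol)
}

#' Construct a density map object
#' @param values 3D array (points^3).
#' @param grid a [grid_spec()].
#' @param element element symbol of the channel.
#' @param n_envs number of environments accumulated.
#' @param kind one of "IIM", "SIM", "difference", "candidate".
#' @return object of class `density_map`.
#' @export
density_map <- function(values, grid, element, n_envs,
                        kind = c("IIM", "SIM", "difference", "candidate")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (!all(dim(values) == grid$points)) {
    stop("values must be a ", grid$points, "^3 array", call. = FALSE)
  }
  structure(list(values = values, grid = grid, element = element,
                 n_envs = as.integer(n_envs), kind = kind),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", x$kind, " ", x$element, ", ", x$grid$points,
      "^3 grid, spacing ", format(x$grid$spacing), " A, n_envs = ",
      x$n_envs, "\n", sep = "")
  cat("  value range: [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Accumulate a per-element Gaussian density map
#'
#' Places an unnormalized unit-amplitude 3D Gaussian of width `sigma_space`
#' (standard deviation) at every atom of the requested element in every
#' aligned environment, sums them on the grid and divides by the number of
#' environments. An atom of the element present at the same position in all
#' environments therefore gives a value of 1 there. All atoms of each
#' environment contribute, including any falling outside the grid box (their
#' tails avoid edge discontinuities).
#'
#' @param envs list of aligned `local_env` objects (all in the reference
#'   frame).
#' @param grid a [grid_spec()].
#' @param element element symbol to accumulate.
#' @param sigma_space Gaussian standard deviation in Angstrom (default 0.5).
#' @param kind stored map kind.
#' @return a [density_map()]. All-zero when the element is absent.
#' @export
accumulate_density <- function(envs, grid, element, sigma_space = 0.5,
                               kind = "IIM") {
  stopifnot(inherits(grid, "grid_spec"))
  if (!length(envs)) stop("need at least one environment", call. = FALSE)
  if (sigma_space <= 0) stop("sigma_space must be > 0", call. = FALSE)
  acc <- numeric(grid$points^3)
  for (env in envs) {
    sel <- env$elements == element
    if (!any(sel)) next
    acc <- acc + density_accumulate_cpp(env$xyz[sel, , drop = FALSE],
                                        grid$ax, grid$ay, grid$az,
                                        sigma_space)
  }
  vals <- array(acc / length(envs), dim = rep(grid$points, 3))
  density_map(vals, grid, element, n_envs = length(envs), kind = kind)
}

#' Build per-element density maps for a set of aligned environments
#' @inheritParams accumulate_density
#' @param elements element channels; defaults to all elements occurring in
#'   `envs`.
#' @return named list of [density_map()], one per element.
#' @export
density_maps <- function(envs, grid, elements = NULL, sigma_space = 0.5,
                         kind = "IIM") {
  if (is.null(elements)) {
    elements <- sort(unique(unlist(lapply(envs, `[[`, "elements"))))
  }
  setNames(lapply(elements, function(el) {
    accumulate_density(envs, grid, el, sigma_space = sigma_space, kind = kind)
  }), elements)
}

#' SIM - IIM difference map with noise thresholding
#'
#' Subtracts the IIM from the SIM elementwise and zeroes every voxel whose
#' magnitude falls below `noise_floor` (default 0.01) to mitigate sampling
#' noise. Positive values mark density promoted by the shift constraint; set
#' `reverse = TRUE` for the IIM - SIM view (density suppressed by the
#' constraint).
#'
#' @param sim,iim [density_map()] objects on the same grid and element.
#' @param noise_floor magnitude threshold below which voxels are zeroed.
#' @param reverse return IIM - SIM instead.
#' @return a difference [density_map()] (values may be negative).
#' @export
difference_map <- function(sim, iim, noise_floor = 0.01, reverse = FALSE) {
  stopifnot(inherits(sim, "density_map"), inherits(iim, "density_map"))
  if (!same_grid(sim$grid, iim$grid)) {
    stop("grid mismatch between SIM and IIM", call. = FALSE)
  }
  if (!identical(sim$element, iim$element)) {
    stop("element mismatch between SIM and IIM", call. = FALSE)
  }
  d <- sim$values - iim$values
  if (reverse) d <- -d
  d[abs(d) < noise_floor] <- 0
  density_map(d, sim$grid, sim$element, n_envs = sim$n_envs,
              kind = "difference")
}

#' Elementwise difference maps for matched channel lists
#' @param sim_maps,iim_maps named lists of [density_map()] (per element).
#' @inheritParams difference_map
#' @return named list of difference maps over the union of channels; a
#'   channel missing on one side is treated as all zeros.
#' @export
difference_maps <- function(sim_maps, iim_maps, noise_floor = 0.01,
                            reverse = FALSE) {
  els <- sort(union(names(sim_maps), names(iim_maps)))
  grid <- (c(sim_maps, iim_maps))[[1]]$grid
  zero <- function(el, kind) {
    density_map(array(0, rep(grid$points, 3)), grid, el, 0L, kind)
  }
  setNames(lapply(els, function(el) {
    s <- if (el %in% names(sim_maps)) sim_maps[[el]] else zero(el, "SIM")
    i <- if (el %in% names(iim_maps)) iim_maps[[el]] else zero(el, "IIM")
    difference_map(s, i, noise_floor = noise_floor, reverse = reverse)
  }), els)
}
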