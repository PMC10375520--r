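# Molecular bond graphs. Bonds are perceived from interatomic distances
# (minimum over periodic images) against scaled covalent-radius sums; the
# graph lives on unit-cell site indices, with bonds across the cell boundary
# resolved to the nearest image, so connected components are molecules.

#' Covalent radii (Angstrom)
#'
#' Single-bond covalent radii for the supported elements, loaded from the
#' packaged table `extdata/covalent_radii.csv`.
#' @return named numeric vector, element -> radius in Angstrom.
#' @export
covalent_radii <- function() {
  path <- system.file("extdata", "covalent_radii.csv", package = "shiftmaps")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  setNames(tab$radius_angstrom, tab$element)
}

#' Construct a molecular bond graph
#' @param elements character element symbols, one per node.
#' @param edges 2-column integer matrix of bonds (unordered pairs, no
#'   self-edges).
#' @param labels optional node labels.
#' @return object of class `bond_graph`.
#' @export
bond_graph <- function(elements, edges, labels = NULL) {
  elements <- as.character(elements)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && (any(edges < 1L) || any(edges > length(elements)))) {
    stop("edge index out of range", call. = FALSE)
  }
  if (nrow(edges) && any(edges[, 1] == edges[, 2])) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  if (is.null(labels)) labels <- paste0(elements, seq_along(elements))
  structure(list(elements = elements, edges = edges,
                 labels = as.character(labels)),
            class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("<bond_graph> ", length(x$elements), " atoms, ", nrow(x$edges),
      " bonds\n", sep = "")
  invisible(x)
}

# adjacency list (list of integer vectors, sorted)
graph_adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Perceive covalent bonds in a crystal structure
#'
#' Two sites are bonded when their minimum-image distance does not exceed
#' `scale * (r_cov(i) + r_cov(j))`. The default scale 1.15 is the common
#' crystallographic heuristic. A hydrogen with degree != 1 and any isolated
#' atom in a multi-atom structure raise warnings (not errors): both usually
#' indicate a distorted geometry or an unsuitable radius table.
#'
#' @param structure a [crystal_structure()].
#' @param scale multiplier on the covalent-radius sum.
#' @param radii named radius table; defaults to [covalent_radii()].
#' @return a `bond_graph` over the structure's site indices.
#' @export
perceive_bonds <- function(structure, scale = 1.15, radii = covalent_radii()) {
  stopifnot(inherits(structure, "crystal_structure"))
  n <- nrow(structure$frac)
  miss <- setdiff(unique(structure$elements), names(radii))
  if (length(miss)) {
    stop("no covalent radius for element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  r <- radii[structure$elements]
  M <- cell_matrix(structure)
  cutmax <- scale * 2 * max(r)
  reps <- pmax(1, ceiling(cutmax / min_perp_widths(M)))
  grid <- as.matrix(expand.grid(-reps[1]:reps[1], -reps[2]:reps[2],
                                -reps[3]:reps[3]))
  shifts <- grid %*% M
  cart <- structure$frac %*% M
  edges <- matrix(integer(), ncol = 2)
  if (n > 1L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      dv <- sweep(shifts, 2, cart[i, ] - cart[j, ], "+")
      dmin <- sqrt(min(rowSums(dv * dv)))
      if (dmin <= scale * (r[i] + r[j])) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- bond_graph(structure$elements, edges, labels = structure$labels)
  deg <- tabulate(c(g$edges), nbins = n)
  badH <- which(structure$elements == "H" & deg != 1L)
  if (length(badH)) {
    warning("hydrogen site(s) with degree != 1: ",
            paste(structure$labels[badH], collapse = ", "), call. = FALSE)
  }
  lone <- which(deg == 0L)
  if (n > 1L && length(lone)) {
    warning("atom(s) with no bonds: ",
            paste(structure$labels[lone], collapse = ", "), call. = FALSE)
  }
  g
}

# Cartesian coordinates of one molecule (the connected component containing
# start_site), placed by a breadth-first nearest-image walk from start_site:
# each newly reached atom is put at the periodic image closest to its BFS
# predecessor. Gives a single consistent copy of the molecule even when its
# bonds cross the cell boundary.
molecule_coords <- function(structure, graph, start_site) {
  M <- cell_matrix(structure)
  cart <- structure$frac %*% M
  adj <- graph_adjacency(graph)
  reps <- pmax(1, ceiling(3 / min_perp_widths(M)))
  grid <- as.matrix(expand.grid(-reps[1]:reps[1], -reps[2]:reps[2],
                                -reps[3]:reps[3]))
  shifts <- grid %*% M
  n <- length(graph$elements)
  pos <- matrix(NA_real_, n, 3)
  pos[start_site, ] <- cart[start_site, ]
  queue <- start_site
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!is.na(pos[nb, 1])) next
      cand <- sweep(shifts, 2, cart[nb, ], "+")
      dv <- sweep(cand, 2, pos[cur, ])
      pos[nb, ] <- cand[which.min(rowSums(dv * dv)), ]
      queue <- c(queue, nb)
    }
  }
  pos  # NA rows for sites outside the component
}
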