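# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results through different algorithms
# (exhaustive enumeration, closed forms, quaternion superposition).

# --- brute-force periodic sphere enumeration --------------------------------
# Independent of expand_to_sphere: own frac->cart conversion and a generous
# fixed supercell bound.
oracle_sphere_count <- function(cell_lengths, cell_angles, frac, center_site,
                                radius, extra = 2L) {
  al <- cell_angles[1] * pi / 180
  be <- cell_angles[2] * pi / 180
  ga <- cell_angles[3] * pi / 180
  a <- cell_lengths[1]; b <- cell_lengths[2]; c <- cell_lengths[3]
  M <- rbind(c(a, 0, 0),
             c(b * cos(ga), b * sin(ga), 0),
             c(c * cos(be),
               c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
               sqrt(c^2 - (c * cos(be))^2 -
                      (c * (cos(al) - cos(be) * cos(ga)) / sin(ga))^2)))
  # conservative replication: radius over the shortest cell height, plus slack
  vol <- abs(det(M))
  hts <- c(vol / sqrt(sum(pracma_cross(M[2, ], M[3, ])^2)),
           vol / sqrt(sum(pracma_cross(M[3, ], M[1, ])^2)),
           vol / sqrt(sum(pracma_cross(M[1, ], M[2, ])^2)))
  reps <- ceiling(radius / hts) + extra
  ctr <- drop(frac[center_site, , drop = FALSE] %*% M)
  count <- 0L
  for (i in -reps[1]:reps[1]) for (j in -reps[2]:reps[2])
    for (k in -reps[3]:reps[3]) {
      img <- sweep(frac %*% M, 2, drop(c(i, j, k) %*% M), "+")
      d <- sqrt(rowSums(sweep(img, 2, ctr)^2))
      count <- count + sum(d <= radius + 1e-9)
    }
  count
}

pracma_cross <- function(u, w) {
  c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1])
}

# --- exhaustive labelled isomorphism ----------------------------------------
# All permutations of 1..n (recursive); practical for n <= 8.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character())
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  sort(paste(e[, 1], e[, 2]))
}

# Exhaustive search for an element-preserving isomorphism between two
# descriptor subgraphs that maps center to center.
oracle_descriptor_match <- function(d1, d2) {
  g1 <- d1$graph; g2 <- d2$graph
  n <- length(g1$elements)
  if (n != length(g2$elements)) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (!identical(sort(g1$elements), sort(g2$elements))) return(FALSE)
  target <- edge_key(g2$edges)
  for (p in all_perms(n)) {
    p <- unlist(p)
    if (p[d1$center] != d2$center) next
    if (any(g2$elements[p] != g1$elements)) next
    mapped <- cbind(p[g1$edges[, 1]], p[g1$edges[, 2]])
    if (identical(edge_key(mapped), target)) return(TRUE)
  }
  FALSE
}

# --- quaternion (Horn) rigid superposition ----------------------------------
oracle_superpose_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- crossprod(P0, Q0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
    c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
    c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
  moved <- P0 %*% t(R)
  sqrt(mean(rowSums((moved - Q0)^2)))
}

# --- small structure / graph builders ---------------------------------------
cubic_structure <- function(a, elements, frac, id = "cube", labels = NULL) {
  crystal_structure(rep(a, 3), c(90, 90, 90), elements, frac,
                    labels = labels, structure_id = id)
}

# random small connected labelled graph (tree plus optional extra edge)
random_molecule_graph <- function(n, extra_edge_prob = 0.3) {
  elements <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
  edges <- NULL
  for (v in seq_len(n)[-1]) {
    edges <- rbind(edges, c(sample(v - 1L, 1), v))
  }
  heavy <- which(elements != "H")
  if (length(heavy) >= 3 && runif(1) < extra_edge_prob) {
    pair <- sample(heavy, 2)
    if (!any(edges[, 1] == min(pair) & edges[, 2] == max(pair))) {
      edges <- rbind(edges, sort(pair))
    }
  }
  bond_graph(elements, edges)
}

# a linear chain graph with given element labels
chain_graph <- function(elements) {
  n <- length(elements)
  bond_graph(elements, cbind(seq_len(n - 1), 2:n))
}

# ethanol heavy+H graph: C1(H x3) - C2(H x2) - O - H
ethanol_graph <- function() {
  elements <- c("C", "C", "O", "H", "H", "H", "H", "H", "H")
  edges <- rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                 c(2, 7), c(2, 8), c(3, 9))
  bond_graph(elements, edges)
}

# environments holding atoms at fixed positions (for density tests)
point_env <- function(xyz, elements, center_index = 1L) {
  xyz <- matrix(xyz, ncol = 3)
  structure(list(elements = elements, xyz = xyz,
                 site_index = seq_along(elements),
                 image = matrix(0L, nrow(xyz), 3),
                 center_index = center_index, radius = 7,
                 source = list(structure_id = "synthetic", site_index = 1L)),
            class = "local_env")
}

write_lines_tmp <- function(lines, ext = ".cif") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

minimal_cif <- function() {
  c("data_minimal",
    "_cell_length_a 10.0",
    "_cell_length_b 10.0",
    "_cell_length_c 10.0",
    "_cell_angle_alpha 90.0",
    "_cell_angle_beta 90.0",
    "_cell_angle_gamma 90.0",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "C1 C 0.0 0.0 0.0")
}

# small fixture database shared across selection / mapping tests
toy_fixture_db <- function(n = 24, seed = 404, noise = 0.2) {
  toy <- generate_toy_crystals(n, seed = seed)
  shifts <- make_shift_table(toy$structures,
                             params = pseudo_shift_params(noise = noise),
                             seed = seed + 1L)
  list(db = build_database(toy$structures, shifts), toy = toy,
       shifts = shifts)
}

formic_assignments <- function(h2_shift = 10, h1_shift = 8) {
  assignment_table(label = c("H2", "H1"), nucleus = c("H", "H"),
                   shift_ppm = c(h2_shift, h1_shift))
}

formic_anchors <- function() {
  list(H2 = c("H2", "O2", "C1", "O1"), H1 = c("H1", "C1", "O1", "O2"))
}
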