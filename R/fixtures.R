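# Synthetic toy crystal generator: small rigid molecules (formic acid,
# methanol) packed as hydrogen-bonded dimers, translation-chain catemers or
# isolated molecules, with pseudo-shifts that encode a controllable
# structure-shift relationship (hydroxyl protons move downfield by delta
# when an intermolecular acceptor sits within a cutoff). This stands in for
# a curated structure database with machine-learning predicted shifts and
# lets every pipeline stage be validated against known ground truth.

DEG <- pi / 180

# formic acid in its molecular plane; columns x,y,z (Angstrom).
# Sites: C1, O1 (carbonyl), O2 (hydroxyl), H1 (formyl), H2 (hydroxyl).
formic_template <- function() {
  C <- c(0, 0, 0)
  O2 <- c(1.34, 0, 0)
  O1 <- 1.22 * c(cos(125 * DEG), sin(125 * DEG), 0)
  H1 <- 1.10 * c(cos(-117.5 * DEG), sin(-117.5 * DEG), 0)
  u <- c(cos(74 * DEG), sin(74 * DEG), 0)       # O2 -> H2 direction
  H2 <- O2 + 0.98 * u
  list(xyz = rbind(C, O1, O2, H1, H2),
       elements = c("C", "O", "O", "H", "H"),
       labels = c("C1", "O1", "O2", "H1", "H2"),
       donor_dir = u)
}

# methanol: C1, O1, H1-H3 (methyl), H4 (hydroxyl)
methanol_template <- function() {
  C <- c(0, 0, 0)
  O <- c(1.43, 0, 0)
  HO <- O + 0.96 * c(cos(72 * DEG), sin(72 * DEG), 0)
  r <- sqrt(8) / 3
  HM <- t(vapply(c(90, 210, 330), function(phi) {
    1.09 * c(-1 / 3, r * cos(phi * DEG), r * sin(phi * DEG))
  }, numeric(3)))
  list(xyz = rbind(C, O, HM, HO),
       elements = c("C", "O", "H", "H", "H", "H"),
       labels = c("C1", "O1", "H1", "H2", "H3", "H4"),
       donor_dir = NULL)
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# place Cartesian atoms into an orthorhombic cell as a crystal_structure
cartesian_to_structure <- function(xyz, elements, labels, cell, id,
                                   offset = c(0, 0, 0)) {
  frac <- sweep(xyz, 2, cell, "/")
  frac <- sweep(frac, 2, offset, "+")
  crystal_structure(cell, c(90, 90, 90), elements, frac, labels = labels,
                    structure_id = id)
}

# one motif structure; d_hb = designed H...O distance
build_motif <- function(motif, id, cell_range, d_hb = 1.7,
                        species = "formic") {
  tmpl <- if (species == "formic") formic_template() else methanol_template()
  cell <- runif(3, cell_range[1], cell_range[2])
  offset <- runif(3)
  if (motif == "dimer") {
    u <- tmpl$donor_dir
    H2 <- tmpl$xyz["H2", ]; O1 <- tmpl$xyz["O1", ]
    m <- (H2 + d_hb * u + O1) / 2
    molB <- sweep(-tmpl$xyz, 2, 2 * m, "+")
    xyz <- rbind(tmpl$xyz, molB)
    R <- random_rotation()
    xyz <- xyz %*% R
    labels <- c(tmpl$labels, paste0(tmpl$labels, "b"))
    cartesian_to_structure(xyz, rep(tmpl$elements, 2), labels, cell, id,
                           offset)
  } else if (motif == "chain") {
    u <- tmpl$donor_dir
    H2 <- tmpl$xyz["H2", ]; O1 <- tmpl$xyz["O1", ]
    # bend the H-bond 55 degrees in-plane: gives a clash-free translation
    # period (~4 A) while keeping H...O at d_hb
    e1 <- c(-u[2], u[1], 0)
    wdir <- cos(55 * DEG) * u - sin(55 * DEG) * e1
    v <- H2 + d_hb * wdir - O1                  # required chain translation
    a_len <- sqrt(sum(v^2))
    th <- atan2(v[2], v[1])
    Rz <- rbind(c(cos(-th), -sin(-th), 0), c(sin(-th), cos(-th), 0),
                c(0, 0, 1))
    xyz <- tmpl$xyz %*% t(Rz)                   # chain axis now along x
    cell <- c(a_len, cell[2], cell[3])
    cartesian_to_structure(xyz, tmpl$elements, tmpl$labels, cell, id,
                           offset)
  } else {  # isolated
    xyz <- tmpl$xyz %*% random_rotation()
    cartesian_to_structure(xyz, tmpl$elements, tmpl$labels, cell, id,
                           offset)
  }
}

#' Generate a toy crystal database
#'
#' Produces `n_structures` small periodic organic crystals drawn from the
#' motif mix: hydrogen-bonded formic acid dimers, formic acid catemer
#' chains (translation chains with a bent O-H...O bond), and isolated
#' (non-bonded) molecules, alternating formic acid and methanol for the
#' isolated class. Geometries use standard bond lengths; the designed
#' H...O contact is drawn uniformly from `d_hb_range`, and each motif is
#' randomly oriented and placed in a random orthorhombic cell.
#'
#' @param n_structures number of structures.
#' @param motif_mix named fractions for `dimer`, `chain`, `isolated`
#'   (must sum to 1).
#' @param cell_range min/max cell edge in Angstrom (default c(10, 14)).
#' @param d_hb_range range of designed H...O distances (default
#'   c(1.60, 1.80) Angstrom).
#' @param seed RNG seed (generation is fully reproducible).
#' @return list with `structures` (named list of [crystal_structure()]) and
#'   `motifs` (named character vector of true motif labels).
#' @export
generate_toy_crystals <- function(n_structures,
                                  motif_mix = c(dimer = 0.4, chain = 0.2,
                                                isolated = 0.4),
                                  cell_range = c(10, 14),
                                  d_hb_range = c(1.60, 1.80),
                                  seed = NULL) {
  if (abs(sum(motif_mix) - 1) > 1e-8) {
    stop("motif fractions must sum to 1", call. = FALSE)
  }
  if (any(motif_mix < 0)) stop("motif fractions must be >= 0", call. = FALSE)
  if (n_structures < 1L) stop("n_structures must be >= 1", call. = FALSE)
  kinds <- c("dimer", "chain", "isolated")
  mix <- setNames(rep(0, 3), kinds)
  mix[names(motif_mix)] <- motif_mix
  counts <- floor(mix * n_structures)
  rem <- n_structures - sum(counts)
  if (rem > 0) {
    extra <- order(mix * n_structures - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  motifs <- rep(kinds, counts)
  with_seed(seed, {
    motifs <- sample(motifs)
    iso_alt <- 0L
    structures <- vector("list", n_structures)
    for (i in seq_len(n_structures)) {
      sp <- "formic"
      if (motifs[i] == "isolated") {
        iso_alt <- iso_alt + 1L
        sp <- if (iso_alt %% 2L == 0L) "methanol" else "formic"
      }
      d <- runif(1, d_hb_range[1], d_hb_range[2])
      structures[[i]] <- build_motif(motifs[i], sprintf("toy%04d", i),
                                     cell_range, d_hb = d, species = sp)
    }
    names(structures) <- vapply(structures, `[[`, character(1),
                                "structure_id")
    list(structures = structures, motifs = setNames(motifs,
                                                    names(structures)))
  })
}

#' Pseudo-shift for a fixture site
#'
#' A minimal structure-shift coupling replacing a learned shift model:
#' `shift = class_base + delta * 1(intermolecular acceptor O within cutoff)
#' + Normal(0, noise)`, where the base depends on the site class (hydroxyl
#' H, formyl H, alkyl H, carboxylic C, alkyl C) and the acceptor term
#' applies to H sites only. Uncertainties are fixed at the prediction
#' uncertainty scale: 0.5 ppm for H, 5 ppm for C.
#'
#' @param structure a [crystal_structure()].
#' @param site site index (H or C).
#' @param params list with `base` (named: H_hydroxyl, H_formyl, H_alkyl,
#'   C_acid, C_alkyl), `delta` (ppm, default 4), `noise` (ppm sd, default
#'   0.2), `cutoff` (Angstrom, default 2.0).
#' @param graph optional precomputed bond graph.
#' @return one-row data.frame shift record.
#' @export
pseudo_shift <- function(structure, site, params = pseudo_shift_params(),
                         graph = NULL) {
  if (is.null(graph)) graph <- perceive_bonds(structure)
  el <- structure$elements[site]
  if (!el %in% c("H", "C")) {
    stop("pseudo_shift is defined for H and C sites", call. = FALSE)
  }
  adj <- graph_adjacency(graph)
  n_o <- function(i) sum(graph$elements[adj[[i]]] == "O")
  if (el == "H") {
    nb <- adj[[site]][1]
    cls <- if (!is.na(nb) && graph$elements[nb] == "O") "H_hydroxyl"
           else if (!is.na(nb) && n_o(nb) >= 2) "H_formyl"
           else "H_alkyl"
  } else {
    cls <- if (n_o(site) >= 2) "C_acid" else "C_alkyl"
  }
  base <- params$base[[cls]]
  bonded <- FALSE
  if (el == "H") {
    env <- expand_to_sphere(structure, site,
                            radius = max(3, params$cutoff + 0.5))
    # acceptors on any other molecule *instance*, including periodic images
    # of the H's own molecule (a catemer donates to its own translate)
    same <- same_molecule_instance(structure, graph, site, env)
    inter_o <- env$elements == "O" & !same
    if (any(inter_o)) {
      ctr <- env$xyz[env$center_index, ]
      d <- sqrt(rowSums(sweep(env$xyz[inter_o, , drop = FALSE], 2, ctr)^2))
      bonded <- min(d) <= params$cutoff
    }
  }
  shift <- base + (if (bonded) params$delta else 0) +
    (if (params$noise > 0) rnorm(1, 0, params$noise) else 0)
  data.frame(structure_id = structure$structure_id,
             site_index = as.integer(site), nucleus = el,
             shift_ppm = shift,
             uncertainty_ppm = if (el == "H") 0.5 else 5,
             stringsAsFactors = FALSE)
}

#' @rdname pseudo_shift
#' @param base,delta,noise,cutoff see above.
#' @export
pseudo_shift_params <- function(base = c(H_hydroxyl = 6, H_formyl = 8,
                                         H_alkyl = 3.5, C_acid = 165,
                                         C_alkyl = 50),
                                delta = 4, noise = 0.2, cutoff = 2.0) {
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  list(base = as.list(base), delta = delta, noise = noise, cutoff = cutoff)
}

# TRUE for each env atom belonging to the same molecule instance as the
# center: its position must coincide with the nearest-image BFS placement of
# that site from the center. Periodic copies of the center's own molecule
# are counted as different instances.
same_molecule_instance <- function(structure, graph, center_site, env) {
  mol_pos <- molecule_coords(structure, graph, center_site)
  vapply(seq_along(env$elements), function(k) {
    s <- env$site_index[k]
    !is.na(mol_pos[s, 1]) &&
      sum((env$xyz[k, ] - mol_pos[s, ])^2) < 1e-12
  }, logical(1))
}

# connected-component id per node
molecule_membership <- function(graph) {
  n <- length(graph$elements)
  adj <- graph_adjacency(graph)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(comp[nb])) { comp[nb] <- cid; queue <- c(queue, nb) }
      }
    }
  }
  comp
}

#' Pseudo-shift table for a set of structures
#'
#' Applies [pseudo_shift()] to every H and C site of every structure.
#' @param structures named list of [crystal_structure()].
#' @param params [pseudo_shift_params()].
#' @param seed RNG seed for the noise draws.
#' @return data.frame in [read_shift_table()] layout.
#' @export
make_shift_table <- function(structures, params = pseudo_shift_params(),
                             seed = NULL) {
  with_seed(seed, {
    rows <- list()
    for (st in structures) {
      g <- perceive_bonds(st)
      for (si in which(st$elements %in% c("H", "C"))) {
        rows[[length(rows) + 1L]] <- pseudo_shift(st, si, params, graph = g)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a candidate set with known ground truth
#'
#' One candidate realizes the hydrogen-bonded dimer motif that the
#' pseudo-shift model rewards at the H-bonded experimental shift; the
#' decoys are isolated (non-bonded) packings of the same molecule. Also
#' returns the reference conformation (an isolated formic acid structure)
#' used for alignment.
#'
#' @param n_decoys number of isolated decoy candidates (default 4).
#' @param include_truth include the H-bonded candidate (default TRUE).
#' @param d_hb designed H...O distance of the truth candidate (default
#'   1.68 Angstrom).
#' @param cell_range cell edge range.
#' @param seed RNG seed.
#' @return list with `candidates` (named list), `truth_id` (NA when
#'   `include_truth = FALSE`) and `molecule` (reference conformation).
#' @export
make_candidate_set <- function(n_decoys = 4, include_truth = TRUE,
                               d_hb = 1.68, cell_range = c(10, 14),
                               seed = NULL) {
  with_seed(seed, {
    cands <- list()
    if (include_truth) {
      cands$cand_dimer <- build_motif("dimer", "cand_dimer", cell_range,
                                      d_hb = d_hb)
    }
    for (k in seq_len(n_decoys)) {
      id <- sprintf("cand_iso%02d", k)
      cands[[id]] <- build_motif("isolated", id, cell_range)
    }
    molecule <- build_motif("isolated", "reference", cell_range)
    list(candidates = cands,
         truth_id = if (include_truth) "cand_dimer" else NA_character_,
         molecule = molecule)
  })
}
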