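# Candidate scoring: the overlap of a candidate's local environment density
# with the thresholded SIM - IIM difference map, per site; global scores are
# means over unambiguous sites and are mean-centered across a candidate set.

#' Density map of a single candidate environment
#'
#' Locates the site of the candidate structure matching the query site's
#' descriptor, extracts its spherical environment, aligns it onto the
#' reference conformation via the anchor atoms and renders per-element
#' density maps with `n_envs = 1` (so each own-atom position carries
#' value 1).
#'
#' @param candidate a [crystal_structure()].
#' @param query_desc the query site's `cov_descriptor`.
#' @param anchor_sites anchor site indices in the query molecule graph.
#' @param anchor_coords reference-frame anchor coordinates.
#' @param grid a [grid_spec()] (shared with the SIM/IIM).
#' @param elements element channels to render; default all present.
#' @param radius extraction radius (Angstrom).
#' @param sigma_space Gaussian width (Angstrom).
#' @param candidate_graph optional precomputed bond graph of the candidate.
#' @return named list of [density_map()] per element.
#' @export
candidate_site_map <- function(candidate, query_desc, anchor_sites,
                               anchor_coords, grid, elements = NULL,
                               radius = 7, sigma_space = 0.5,
                               candidate_graph = NULL) {
  stopifnot(inherits(candidate, "crystal_structure"))
  g <- if (is.null(candidate_graph)) perceive_bonds(candidate)
       else candidate_graph
  w <- query_desc$w
  # find candidate sites matching the query descriptor
  hit <- NULL
  for (si in which(g$elements == query_desc$graph$elements[query_desc$center])) {
    d <- build_descriptor(g, si, w)
    mm <- descriptors_match(query_desc, d, all_mappings = TRUE)
    if (mm$match) { hit <- list(site = si, desc = d, mm = mm); break }
  }
  if (is.null(hit)) {
    stop("assignment error: no site of candidate ", candidate$structure_id,
         " matches the query descriptor", call. = FALSE)
  }
  env <- expand_to_sphere(candidate, hit$site, radius = radius)
  mol_xyz <- molecule_coords(candidate, g, hit$site)
  sub_idx <- match(anchor_sites, query_desc$orig_ids)
  if (any(is.na(sub_idx))) {
    stop("configuration error: anchor atom(s) outside descriptor depth",
         call. = FALSE)
  }
  best <- NULL
  for (mp in hit$mm$mappings) {
    cand_sites <- hit$desc$orig_ids[mp[sub_idx]]
    P <- mol_xyz[cand_sites, , drop = FALSE]
    if (any(is.na(P))) next
    tf <- tryCatch(rigid_align(P, anchor_coords), error = function(e) NULL)
    if (!is.null(tf) && (is.null(best) || tf$rmsd < best$rmsd)) best <- tf
  }
  if (is.null(best)) {
    stop("degenerate geometry: cannot align candidate ",
         candidate$structure_id, call. = FALSE)
  }
  env <- transform_env(env, best)
  density_maps(list(env), grid, elements = elements,
               sigma_space = sigma_space, kind = "candidate")
}

#' Site score: overlap with the difference map
#'
#' `s_i = sum over elements and grid points of cand(r) * [SIM(r) - IIM(r)]`
#' with the difference thresholded at `noise_floor`. Positive values mean
#' the candidate environment is more compatible with the SIM than with the
#' IIM; zero means equally promoted by both; negative means anti-compatible.
#' The overlap is a plain voxelwise product sum (no volume factor or mass
#' normalization; any common factor cancels in the mean-centering step).
#'
#' @param cand_maps named per-element list of candidate [density_map()].
#' @param sim_maps,iim_maps named per-element SIM and IIM map lists.
#' @param noise_floor difference threshold (default 0.01).
#' @param diff_maps optional precomputed difference maps (overrides
#'   sim/iim).
#' @return scalar score `s_i`.
#' @export
site_score <- function(cand_maps, sim_maps = NULL, iim_maps = NULL,
                       noise_floor = 0.01, diff_maps = NULL) {
  if (is.null(diff_maps)) {
    diff_maps <- difference_maps(sim_maps, iim_maps,
                                 noise_floor = noise_floor)
  }
  s <- 0
  for (el in names(diff_maps)) {
    if (!el %in% names(cand_maps)) next
    dm <- diff_maps[[el]]
    cm <- cand_maps[[el]]
    if (!same_grid(dm$grid, cm$grid)) {
      stop("grid mismatch between candidate and difference maps",
           call. = FALSE)
    }
    s <- s + sum(cm$values * dm$values)
  }
  s
}

#' Global candidate score
#'
#' Arithmetic mean of the per-site scores over unambiguous sites only;
#' ambiguous assignments (e.g. CH2 protons, symmetric aromatic sites) are
#' excluded because their descriptor cannot be tied to a unique atom.
#'
#' @param per_site numeric vector of site scores (named by site label).
#' @param ambiguous logical vector, same length.
#' @return list with `global` (mean over included sites), `included`,
#'   `excluded` (data.frame label/reason).
#' @export
global_score <- function(per_site, ambiguous = rep(FALSE, length(per_site))) {
  stopifnot(length(per_site) == length(ambiguous))
  labs <- names(per_site)
  if (is.null(labs)) labs <- as.character(seq_along(per_site))
  keep <- !ambiguous & !is.na(per_site)
  if (!any(keep)) {
    stop("empty-score error: no unambiguous site scores available",
         call. = FALSE)
  }
  reasons <- ifelse(ambiguous, "ambiguous", "missing")
  list(global = mean(per_site[keep]),
       included = labs[keep],
       excluded = data.frame(label = labs[!keep],
                             reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Mean-center global scores across a candidate set
#'
#' Subtracts the mean score across all candidates from each score, removing
#' any systematic tendency shared by the whole set; the centered scores sum
#' to zero and preserve ordering.
#'
#' @param scores numeric vector of global scores (named by candidate id).
#' @return centered numeric vector. A single candidate is passed through
#'   unchanged with a warning.
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 2L) {
    warning("single candidate: normalization is a no-op", call. = FALSE)
    return(scores)
  }
  scores - mean(scores)
}

#' Flag assignments that are ambiguous at the working depth
#'
#' A site is ambiguous iff at least two distinct atoms of the molecule share
#' its covalent descriptor at depth `w` but carry different assigned
#' experimental shifts: the 2D descriptor then cannot be mapped to a unique
#' atom of the 3D conformation (the CH2 / aromatic-ring situation).
#'
#' @param graph the query molecule's [bond_graph()].
#' @param assignments an [assignment_table()]; labels must be graph node
#'   labels.
#' @param w descriptor depth at which ambiguity is assessed (default 6).
#' @return logical vector, one flag per assignment row.
#' @export
flag_ambiguous_sites <- function(graph, assignments, w = 6) {
  stopifnot(inherits(graph, "bond_graph"))
  idx <- match(assignments$label, graph$labels)
  if (any(is.na(idx))) {
    stop("assignment label(s) not in molecule graph: ",
         paste(assignments$label[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  descs <- lapply(idx, function(i) build_descriptor(graph, i, w))
  keys <- vapply(descs, `[[`, character(1), "key")
  flags <- logical(nrow(assignments))
  for (r in seq_len(nrow(assignments))) {
    same <- which(keys == keys[r])
    same <- same[same != r]
    # confirm key-equal pairs by isomorphism before declaring equivalence
    same <- same[vapply(same, function(k)
      descriptors_match(descs[[r]], descs[[k]])$match, logical(1))]
    if (!length(same)) next
    sh <- assignments$shift_ppm[c(r, same)]
    flags[r] <- length(unique(sh)) > 1L
  }
  flags
}

#' Rank candidate crystal structures against SIM - IIM maps
#'
#' End-to-end pipeline: builds the per-site SIM and IIM once via
#' [shift_maps()], scores every candidate with [predict.shift_maps()] and
#' returns the report sorted by normalized score (ties in stable candidate
#' id order).
#'
#' @param db an `env_db`.
#' @param molecule reference conformation: a [crystal_structure()] whose
#'   molecule containing the assigned sites defines the alignment frame.
#' @param assignments an [assignment_table()].
#' @param candidates named list of candidate [crystal_structure()].
#' @param anchors named list: site label -> character vector of 3-4 anchor
#'   site labels.
#' @param ... configuration passed to [shift_maps()] (n_select, w_start,
#'   min_matches, grid parameters, sigma_space, noise_floor, seed, ...).
#' @return a `score_report` data.frame (see [predict.shift_maps()]).
#' @export
rank_candidates <- function(db, molecule, assignments, candidates,
                            anchors, ...) {
  fit <- shift_maps(db, molecule, assignments, anchors, ...)
  predict(fit, candidates)
}

#' Write a score report CSV
#' @param report a `score_report` data.frame.
#' @param path output path.
#' @export
write_score_report <- function(report, path) {
  write.csv(report[, c("candidate_id", "n_sites_used", "global_score",
                       "normalized_score", "rank")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
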