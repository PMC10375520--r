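# The model-object surface: shift_maps() builds the per-site SIM/IIM pair
# (the "fit" to the assigned shifts given a database); predict() scores
# candidate crystal structures against the difference maps.

#' Build shift-dependent and shift-independent interaction maps
#'
#' For every assigned site of the query molecule: find the matching database
#' environments via the covalent descriptor (depth chosen adaptively),
#' select `n_select` of them randomly (IIM) and `n_select` under the
#' Gaussian shift constraint centered at the experimental shift (SIM; 2D
#' constraint for bonded C-H pair assignments), align each selected
#' environment onto the reference conformation via the site's anchor atoms,
#' and accumulate per-element Gaussian density maps plus their thresholded
#' difference.
#'
#' @param db an `env_db` built with [build_database()].
#' @param molecule reference conformation: a [crystal_structure()]
#'   containing the molecule under study; its site labels are the
#'   assignment labels and its geometry defines the alignment frame.
#' @param assignments an [assignment_table()] of experimental shifts.
#' @param anchors named list mapping each assigned site label to 3-4 anchor
#'   site labels (all within the descriptor neighbourhood; for rigid motifs
#'   more distant atoms are acceptable).
#' @param n_select environments per map (default 1000).
#' @param w_start starting descriptor depth (default 6).
#' @param min_matches required database match count before selection
#'   (default 3000); reduce for small databases.
#' @param grid_points,grid_side evaluation grid: points per axis (31) and
#'   cube side in Angstrom (12), i.e. 0.4 A sampling, centered at each site.
#' @param sigma_space density Gaussian width in Angstrom (default 0.5).
#' @param sigma_h,sigma_c shift-sampling widths in ppm (defaults 0.5 for 1H
#'   and 5 for 13C, the prediction-uncertainty scale).
#' @param noise_floor difference-map threshold (default 0.01).
#' @param radius environment radius in Angstrom (default 7).
#' @param seed RNG seed making selections (hence maps) reproducible.
#' @return object of class `shift_maps`: list with `sites` (per-site maps
#'   and metadata), `molecule`, `graph`, `config`.
#' @export
shift_maps <- function(db, molecule, assignments, anchors,
                       n_select = 1000, w_start = 6, min_matches = 3000,
                       grid_points = 31, grid_side = 12, sigma_space = 0.5,
                       sigma_h = 0.5, sigma_c = 5, noise_floor = 0.01,
                       radius = 7, seed = NULL) {
  stopifnot(inherits(db, "env_db"), inherits(molecule, "crystal_structure"))
  if (!inherits(assignments, "assignment_table")) {
    stop("assignments must be an assignment_table()", call. = FALSE)
  }
  graph <- perceive_bonds(molecule)
  site_idx <- match(assignments$label, graph$labels)
  if (any(is.na(site_idx))) {
    stop("assignment label(s) not found in molecule: ",
         paste(assignments$label[is.na(site_idx)], collapse = ", "),
         call. = FALSE)
  }
  mol_xyz <- NULL  # per-component cache
  get_coords <- function(start) {
    if (is.null(mol_xyz) || is.na(mol_xyz[start, 1])) {
      mol_xyz <<- molecule_coords(molecule, graph, start)
    }
    mol_xyz
  }

  # pair rows: the H row carries the 2D selection; its C partner is consumed
  pair_c_rows <- integer()
  for (pid in unique(assignments$pair_id[!is.na(assignments$pair_id)])) {
    rows <- which(!is.na(assignments$pair_id) & assignments$pair_id == pid)
    crow <- rows[assignments$nucleus[rows] == "C"]
    hrow <- rows[assignments$nucleus[rows] == "H"]
    if (!length(crow) || !length(hrow)) next
    ci <- site_idx[crow]; hi <- site_idx[hrow]
    adj <- graph_adjacency(graph)[[hi]]
    if (!(ci %in% adj)) {
      stop("paired C and H sites ", assignments$label[crow], " / ",
           assignments$label[hrow], " are not covalently bonded",
           call. = FALSE)
    }
    pair_c_rows <- c(pair_c_rows, crow)
  }

  sites <- list()
  with_seed(seed, {
    for (r in seq_len(nrow(assignments))) {
      if (r %in% pair_c_rows) next
      lab <- assignments$label[r]
      si <- site_idx[r]
      is_pair <- !is.na(assignments$pair_id[r])
      builder <- function(w) build_descriptor(graph, si, w)
      ad <- adaptive_depth(db, builder, w_start = w_start,
                           min_matches = min_matches)
      desc <- builder(ad$w)

      if (is.null(anchors[[lab]])) {
        stop("no anchor configuration for site ", lab, call. = FALSE)
      }
      anchor_sites <- match(anchors[[lab]], graph$labels)
      if (any(is.na(anchor_sites))) {
        stop("anchor label(s) not in molecule for site ", lab, call. = FALSE)
      }
      coords <- get_coords(si)
      anchor_coords <- coords[anchor_sites, , drop = FALSE]
      grid <- grid_spec(grid_points, grid_side, center = coords[si, ])

      pool <- db$entries[db$entries$entry_id %in% ad$matches, ]
      if (is_pair) {
        ppool <- pair_entries(db, ad$matches)
        crow <- which(!is.na(assignments$pair_id) &
                        assignments$pair_id == assignments$pair_id[r] &
                        assignments$nucleus == "C")
        target <- c(assignments$shift_ppm[crow], assignments$shift_ppm[r])
        sim_ids <- select_by_shift_2d(
          ppool, selection_spec("shift_2d", n = n_select, targets = target,
                                sigma = c(sigma_c, sigma_h)))
        iim_ids <- select_random(
          ppool$entry_id, selection_spec("random", n = n_select))
      } else {
        sg <- if (assignments$nucleus[r] == "H") sigma_h else sigma_c
        sim_ids <- select_by_shift_1d(
          pool, selection_spec("shift_1d", n = n_select,
                               targets = assignments$shift_ppm[r],
                               sigma = sg))
        iim_ids <- select_random(
          pool$entry_id, selection_spec("random", n = n_select))
      }

      align_all <- function(ids) {
        lapply(ids, function(id) {
          aligned_environment(desc, anchor_sites, anchor_coords, db, id,
                              ad$w, radius = radius)
        })
      }
      sim_envs <- align_all(sim_ids)
      iim_envs <- align_all(iim_ids)
      els <- sort(unique(c(unlist(lapply(sim_envs, `[[`, "elements")),
                           unlist(lapply(iim_envs, `[[`, "elements")))))
      sim_maps <- density_maps(sim_envs, grid, elements = els,
                               sigma_space = sigma_space, kind = "SIM")
      iim_maps <- density_maps(iim_envs, grid, elements = els,
                               sigma_space = sigma_space, kind = "IIM")
      dmaps <- difference_maps(sim_maps, iim_maps,
                               noise_floor = noise_floor)

      # ambiguity at the working depth: descriptor-equivalent atoms with
      # different assigned shifts cannot be assigned a priori
      amb <- assignments$ambiguous[r] ||
        flag_ambiguous_sites(graph, assignments, w = ad$w)[r]

      sites[[lab]] <- list(label = lab, site_index = si, w = ad$w,
                           n_matches = ad$n_matches,
                           exhausted = ad$exhausted,
                           ambiguous = amb, descriptor = desc,
                           anchor_sites = anchor_sites,
                           anchor_coords = anchor_coords, grid = grid,
                           sim_ids = sim_ids, iim_ids = iim_ids,
                           sim_maps = sim_maps, iim_maps = iim_maps,
                           diff_maps = dmaps)
    }
  })
  structure(list(sites = sites, molecule = molecule, graph = graph,
                 config = list(n_select = n_select, w_start = w_start,
                               min_matches = min_matches,
                               grid_points = grid_points,
                               grid_side = grid_side,
                               sigma_space = sigma_space, sigma_h = sigma_h,
                               sigma_c = sigma_c, noise_floor = noise_floor,
                               radius = radius, seed = seed)),
            class = "shift_maps")
}

#' @export
print.shift_maps <- function(x, ...) {
  cat("<shift_maps> ", length(x$sites), " site(s), n_select = ",
      x$config$n_select, "\n", sep = "")
  for (s in x$sites) {
    cat(sprintf("  %-6s w=%d matches=%d%s%s\n", s$label, s$w, s$n_matches,
                if (s$ambiguous) " [ambiguous]" else "",
                if (s$exhausted) " [match count below threshold]" else ""))
  }
  invisible(x)
}

#' @export
summary.shift_maps <- function(object, ...) {
  rows <- lapply(object$sites, function(s) {
    data.frame(label = s$label, w = s$w, n_matches = s$n_matches,
               ambiguous = s$ambiguous,
               max_abs_diff = max(vapply(s$diff_maps, function(m)
                 max(abs(m$values)), numeric(1))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score candidate structures against fitted interaction maps
#'
#' For every candidate and every unambiguous site, renders the candidate's
#' local environment density on the site grid and computes the overlap
#' score with the SIM - IIM difference map; global scores are the mean over
#' scored sites and are mean-centered across the candidate set.
#'
#' @param object a [shift_maps()] fit.
#' @param candidates named list of candidate [crystal_structure()] (or a
#'   single structure).
#' @param ... unused.
#' @return a `score_report` data.frame with columns `candidate_id`,
#'   `n_sites_used`, `global_score`, `normalized_score`, `rank`, sorted by
#'   decreasing normalized score (ties by candidate id); per-site scores in
#'   `attr(, "per_site")`, exclusions in `attr(, "excluded")`.
#' @export
predict.shift_maps <- function(object, candidates, ...) {
  if (inherits(candidates, "crystal_structure")) {
    candidates <- list(candidates)
  }
  ids <- names(candidates)
  if (is.null(ids)) {
    ids <- vapply(candidates, `[[`, character(1), "structure_id")
  }
  names(candidates) <- ids
  usable <- Filter(function(s) !s$ambiguous, object$sites)
  if (!length(usable)) {
    stop("empty-score error: all sites are ambiguous", call. = FALSE)
  }
  per_site <- matrix(NA_real_, length(candidates), length(usable),
                     dimnames = list(ids, vapply(usable, `[[`, character(1),
                                                 "label")))
  excluded <- data.frame(candidate_id = character(), label = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    cg <- perceive_bonds(cand)
    for (s in usable) {
      sc <- tryCatch({
        cm <- candidate_site_map(cand, s$descriptor, s$anchor_sites,
                                 s$anchor_coords, s$grid,
                                 radius = object$config$radius,
                                 sigma_space = object$config$sigma_space,
                                 candidate_graph = cg)
        site_score(cm, diff_maps = s$diff_maps)
      }, error = function(e) {
        excluded <<- rbind(excluded,
                           data.frame(candidate_id = ids[ci],
                                      label = s$label,
                                      reason = conditionMessage(e),
                                      stringsAsFactors = FALSE))
        NA_real_
      })
      per_site[ci, s$label] <- sc
    }
  }
  glob <- vapply(seq_along(candidates), function(ci) {
    row <- per_site[ci, ]
    if (all(is.na(row))) NA_real_ else mean(row, na.rm = TRUE)
  }, numeric(1))
  norm <- if (length(glob) >= 2L) glob - mean(glob, na.rm = TRUE) else glob
  ord <- order(-norm, ids)
  report <- data.frame(candidate_id = ids[ord],
                       n_sites_used = rowSums(!is.na(per_site))[ord],
                       global_score = glob[ord],
                       normalized_score = norm[ord],
                       rank = seq_along(ord),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  class(report) <- c("score_report", "data.frame")
  attr(report, "per_site") <- per_site
  attr(report, "excluded") <- excluded
  report
}

#' Plot a slice of a fitted difference map
#'
#' Draws the grid plane through the site (z index = middle by default) of
#' the chosen map kind and element channel as a filled contour image.
#'
#' @param x a `shift_maps` fit.
#' @param site site label (default first).
#' @param element element channel (default channel with the largest
#'   absolute difference).
#' @param kind "difference", "SIM" or "IIM".
#' @param slice z index (default middle plane through the site).
#' @param ... passed to [graphics::image()].
#' @export
plot.shift_maps <- function(x, site = NULL, element = NULL,
                            kind = c("difference", "SIM", "IIM"),
                            slice = NULL, ...) {
  kind <- match.arg(kind)
  if (is.null(site)) site <- names(x$sites)[1]
  s <- x$sites[[site]]
  if (is.null(s)) stop("unknown site ", site, call. = FALSE)
  maps <- switch(kind, difference = s$diff_maps, SIM = s$sim_maps,
                 IIM = s$iim_maps)
  if (is.null(element)) {
    element <- names(maps)[which.max(vapply(maps, function(m)
      max(abs(m$values)), numeric(1)))]
  }
  m <- maps[[element]]
  if (is.null(slice)) slice <- (m$grid$points + 1L) %/% 2L
  graphics::image(m$grid$ax, m$grid$ay, m$values[, , slice],
                  xlab = "x (A)", ylab = "y (A)",
                  main = sprintf("%s %s map, site %s (z = %.2f A)", kind,
                                 element, site, m$grid$az[slice]), ...)
  invisible(x)
}
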