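# The environment database: every H and C site with a predicted shift,
# indexed by covalent descriptor canonical key at each depth w = 1..w_max.
# Queries prefilter on the key and confirm every candidate by isomorphism.

#' Build an environment database
#'
#' @param structures named list of [crystal_structure()] (names = ids), or an
#'   unnamed list (ids are taken from the structures).
#' @param shift_records data.frame as from [read_shift_table()]: one row per
#'   (structure, site) with predicted shift and uncertainty.
#' @param w_max maximum descriptor depth to index (default 6).
#' @param bond_scale covalent-radius scale passed to [perceive_bonds()].
#' @return object of class `env_db` with fields `structures`, `graphs`,
#'   `entries` (data.frame: entry_id, structure_id, site_index, element,
#'   shift, uncertainty), `keys` (entry x w key matrix), `index`
#'   (per-w key -> entry ids), `w_max`, `schema_version`.
#' @export
build_database <- function(structures, shift_records, w_max = 6,
                           bond_scale = 1.15) {
  if (inherits(structures, "crystal_structure")) structures <- list(structures)
  ids <- vapply(structures, `[[`, character(1), "structure_id")
  if (anyDuplicated(ids)) {
    stop("duplicate structure ids", call. = FALSE)
  }
  names(structures) <- ids
  sr <- shift_records
  need <- c("structure_id", "site_index", "nucleus", "shift_ppm",
            "uncertainty_ppm")
  miss <- setdiff(need, names(sr))
  if (length(miss)) {
    stop("shift records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dangling <- setdiff(unique(sr$structure_id), ids)
  if (length(dangling)) {
    stop("shift record references unknown structure id(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sr[, c("structure_id", "site_index")])) {
    stop("duplicate (structure_id, site_index) in shift records",
         call. = FALSE)
  }
  if (any(sr$uncertainty_ppm <= 0)) {
    stop("shift uncertainties must be > 0", call. = FALSE)
  }
  graphs <- lapply(structures, perceive_bonds, scale = bond_scale)

  n <- nrow(sr)
  keys <- matrix(NA_character_, n, w_max)
  element <- character(n)
  for (r in seq_len(n)) {
    st <- structures[[sr$structure_id[r]]]
    si <- as.integer(sr$site_index[r])
    if (si < 1L || si > nrow(st$frac)) {
      stop("shift record site_index ", si, " out of range for structure ",
           st$structure_id, call. = FALSE)
    }
    element[r] <- st$elements[si]
    if (element[r] != sr$nucleus[r]) {
      stop("shift record nucleus ", sr$nucleus[r],
           " does not match site element ", element[r], " (structure ",
           st$structure_id, ", site ", si, ")", call. = FALSE)
    }
    g <- graphs[[sr$structure_id[r]]]
    for (w in seq_len(w_max)) {
      keys[r, w] <- build_descriptor(g, si, w)$key
    }
  }
  entries <- data.frame(entry_id = seq_len(n),
                        structure_id = as.character(sr$structure_id),
                        site_index = as.integer(sr$site_index),
                        element = element,
                        shift = as.numeric(sr$shift_ppm),
                        uncertainty = as.numeric(sr$uncertainty_ppm),
                        stringsAsFactors = FALSE)
  index <- lapply(seq_len(w_max), function(w) {
    split(entries$entry_id, keys[, w])
  })
  structure(list(structures = structures, graphs = graphs, entries = entries,
                 keys = keys, index = index, w_max = as.integer(w_max),
                 schema_version = 1L),
            class = "env_db")
}

#' @export
print.env_db <- function(x, ...) {
  cat("<env_db> ", length(x$structures), " structures, ", nrow(x$entries),
      " indexed sites (w_max = ", x$w_max, ")\n", sep = "")
  invisible(x)
}

# descriptor of a database entry at depth w (built on demand)
entry_descriptor <- function(db, entry_id, w) {
  e <- db$entries[entry_id, ]
  build_descriptor(db$graphs[[e$structure_id]], e$site_index, w)
}

#' Query the database with a covalent descriptor
#'
#' Entries sharing the query's canonical key at the query depth are
#' confirmed by full isomorphism; exactly the isomorphic entries are
#' returned, in ascending entry id.
#'
#' @param db an `env_db`.
#' @param descriptor a `cov_descriptor` with `w <= w_max`.
#' @return integer vector of entry ids (possibly empty).
#' @export
query_database <- function(db, descriptor) {
  stopifnot(inherits(db, "env_db"), inherits(descriptor, "cov_descriptor"))
  w <- descriptor$w
  if (w > db$w_max) {
    stop("descriptor depth ", w, " exceeds database w_max ", db$w_max,
         call. = FALSE)
  }
  cand <- db$index[[w]][[descriptor$key]]
  if (is.null(cand) || !length(cand)) return(integer())
  ok <- vapply(cand, function(id) {
    descriptors_match(descriptor, entry_descriptor(db, id, w))$match
  }, logical(1))
  sort(cand[ok])
}

#' Save / load an environment database
#'
#' The database is persisted as a single serialized container holding the
#' structures, bond graphs, entry table and key index, tagged with a schema
#' version; loading checks the version.
#' @param db an `env_db`.
#' @param path file path.
#' @return `path` (save) or the `env_db` (load).
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "env_db"))
  saveRDS(db, path)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  db <- readRDS(path)
  if (!inherits(db, "env_db") || !identical(db$schema_version, 1L)) {
    stop("not a version-1 environment database: ", path, call. = FALSE)
  }
  db
}

# --- selection ---------------------------------------------------------------

#' Selection specification
#'
#' @param mode one of "random", "shift_1d", "shift_2d".
#' @param n number of environments to select (default 1000).
#' @param targets experimental shift target(s), ppm: one value for
#'   shift_1d, `c(carbon, proton)` for shift_2d. Ignored for random.
#' @param sigma Gaussian sampling width(s), ppm. Defaults to the prediction
#'   uncertainty scale: 0.5 ppm for 1H, 5 ppm for 13C; for shift_2d supply
#'   `c(sigma_C, sigma_H)` (default `c(5, 0.5)`).
#' @param seed optional RNG seed for reproducible selection.
#' @return list of class `selection_spec`.
#' @export
selection_spec <- function(mode = c("random", "shift_1d", "shift_2d"),
                           n = 1000, targets = NULL, sigma = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (mode == "shift_1d") {
    if (length(targets) != 1L) {
      stop("shift_1d requires exactly one target shift", call. = FALSE)
    }
    if (is.null(sigma)) sigma <- 0.5
    if (length(sigma) != 1L || sigma <= 0) {
      stop("shift_1d requires one positive sigma", call. = FALSE)
    }
  }
  if (mode == "shift_2d") {
    if (length(targets) != 2L) {
      stop("shift_2d requires two targets: c(carbon, proton)", call. = FALSE)
    }
    if (is.null(sigma)) sigma <- c(5, 0.5)
    if (length(sigma) != 2L || any(sigma <= 0)) {
      stop("shift_2d requires two positive sigmas", call. = FALSE)
    }
  }
  structure(list(mode = mode, n = n, targets = as.numeric(targets),
                 sigma = as.numeric(sigma), seed = seed),
            class = "selection_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

check_pool <- function(n_pool, n) {
  if (n_pool < n) {
    stop("insufficient matches: need ", n, " environments but only ",
         n_pool, " are available", call. = FALSE)
  }
}

#' Random (shift-independent) environment selection
#'
#' Uniform sampling without replacement; the basis of the shift-independent
#' interaction map (IIM), which captures the average packing around a site
#' class regardless of chemical shift.
#'
#' @param entries data.frame with at least an `entry_id` column (e.g. a
#'   subset of `db$entries`), or an integer vector of entry ids.
#' @param spec a [selection_spec()] with mode "random".
#' @return integer vector of `n` distinct entry ids.
#' @export
select_random <- function(entries, spec) {
  stopifnot(inherits(spec, "selection_spec"), spec$mode == "random")
  ids <- if (is.data.frame(entries)) entries$entry_id else as.integer(entries)
  check_pool(length(ids), spec$n)
  with_seed(spec$seed, ids[sample.int(length(ids), spec$n)])
}

#' Shift-targeted 1D environment selection
#'
#' Repeats `n` times: draw x ~ Normal(target, sigma) and select the
#' not-yet-selected entry whose predicted shift is closest to x (ties broken
#' by ascending entry id). This is the selection behind the
#' shift-dependent interaction map (SIM): the selected-shift distribution
#' reproduces a Gaussian of width sigma around the experimental shift as far
#' as the database density allows.
#'
#' @param entries data.frame with columns `entry_id` and `shift`.
#' @param spec a [selection_spec()] with mode "shift_1d".
#' @return integer vector of `n` distinct entry ids (selection order).
#' @export
select_by_shift_1d <- function(entries, spec) {
  stopifnot(inherits(spec, "selection_spec"), spec$mode == "shift_1d")
  stopifnot(is.data.frame(entries), all(c("entry_id", "shift") %in%
                                          names(entries)))
  check_pool(nrow(entries), spec$n)
  with_seed(spec$seed, {
    ord <- order(entries$entry_id)
    ids <- entries$entry_id[ord]
    shifts <- entries$shift[ord]
    avail <- rep(TRUE, length(ids))
    out <- integer(spec$n)
    draws <- rnorm(spec$n, mean = spec$targets, sd = spec$sigma)
    for (k in seq_len(spec$n)) {
      d <- abs(shifts - draws[k])
      d[!avail] <- Inf
      pick <- which.min(d)  # ids ascending, so first minimum = smallest id
      out[k] <- ids[pick]
      avail[pick] <- FALSE
    }
    out
  })
}

#' Normalized distance in the 2D shift plane
#'
#' Distance between a sampled point `(c, h)` and an environment's bonded
#' C-H shift pair, with each axis scaled by its sampling width:
#' `d = sqrt(((c - dC)/sigma_C)^2 + ((h - dH)/sigma_H)^2)`.
#'
#' @param delta_c,delta_h environment 13C and 1H shifts (ppm).
#' @param point numeric(2): sampled `(c, h)` point (ppm).
#' @param sigma_c,sigma_h axis widths (ppm).
#' @return nonnegative distance; zero iff both components coincide.
#' @export
shift_distance_2d <- function(delta_c, delta_h, point, sigma_c = 5,
                              sigma_h = 0.5) {
  if (sigma_c <= 0 || sigma_h <= 0) stop("widths must be > 0", call. = FALSE)
  sqrt(((point[1] - delta_c) / sigma_c)^2 +
         ((point[2] - delta_h) / sigma_h)^2)
}

#' Shift-targeted 2D environment selection for bonded C-H pairs
#'
#' Repeats `n` times: draw `(c, h)` from an axis-aligned 2D Gaussian centered
#' at the experimental 13C/1H shifts (widths sigma_C, sigma_H, no
#' correlation) and select the not-yet-selected pair entry minimizing
#' [shift_distance_2d()] (ties by ascending entry id).
#'
#' @param entries data.frame with columns `entry_id`, `shift_c`, `shift_h`
#'   (bonded-pair shifts), e.g. from [pair_entries()].
#' @param spec a [selection_spec()] with mode "shift_2d",
#'   `targets = c(carbon, proton)`.
#' @return integer vector of `n` distinct entry ids (selection order).
#' @export
select_by_shift_2d <- function(entries, spec) {
  stopifnot(inherits(spec, "selection_spec"), spec$mode == "shift_2d")
  stopifnot(is.data.frame(entries),
            all(c("entry_id", "shift_c", "shift_h") %in% names(entries)))
  check_pool(nrow(entries), spec$n)
  with_seed(spec$seed, {
    ord <- order(entries$entry_id)
    ids <- entries$entry_id[ord]
    sc <- entries$shift_c[ord]
    sh <- entries$shift_h[ord]
    avail <- rep(TRUE, length(ids))
    out <- integer(spec$n)
    cs <- rnorm(spec$n, spec$targets[1], spec$sigma[1])
    hs <- rnorm(spec$n, spec$targets[2], spec$sigma[2])
    for (k in seq_len(spec$n)) {
      d <- ((cs[k] - sc) / spec$sigma[1])^2 + ((hs[k] - sh) / spec$sigma[2])^2
      d[!avail] <- Inf
      pick <- which.min(d)
      out[k] <- ids[pick]
      avail[pick] <- FALSE
    }
    out
  })
}

#' Attach bonded-carbon shifts to H entries
#'
#' For each H entry, finds the covalently bonded C site in the same structure
#' and its shift record; entries whose bonded carbon has no shift record are
#' dropped. The result feeds [select_by_shift_2d()].
#'
#' @param db an `env_db`.
#' @param entry_ids H-entry ids (e.g. a query result).
#' @return data.frame with `entry_id`, `shift_c`, `shift_h`.
#' @export
pair_entries <- function(db, entry_ids) {
  rows <- db$entries[db$entries$entry_id %in% entry_ids, ]
  if (any(rows$element != "H")) {
    stop("pair_entries expects H-centered entries", call. = FALSE)
  }
  out <- data.frame(entry_id = integer(), shift_c = numeric(),
                    shift_h = numeric())
  for (r in seq_len(nrow(rows))) {
    e <- rows[r, ]
    g <- db$graphs[[e$structure_id]]
    adj <- graph_adjacency(g)[[e$site_index]]
    cs <- adj[g$elements[adj] == "C"]
    if (!length(cs)) next
    crec <- db$entries[db$entries$structure_id == e$structure_id &
                         db$entries$site_index == cs[1], ]
    if (!nrow(crec)) next
    out <- rbind(out, data.frame(entry_id = e$entry_id,
                                 shift_c = crec$shift[1],
                                 shift_h = e$shift))
  }
  out
}
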