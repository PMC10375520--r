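# Covalent environment descriptors: the labelled bond-graph neighbourhood of
# an atomic site up to w bonds away. Purely topological (element labels and
# connectivity; no bond orders, charges or geometry), so descriptors can be
# built directly from a 2D molecular structure. Matching is exact labelled
# graph isomorphism with the centers pinned to each other; a deterministic
# Weisfeiler-Lehman refinement key serves as a fast prefilter and database
# index.

#' Build a covalent environment descriptor
#'
#' Breadth-first truncation of the molecular graph at `w` bonds from the
#' central site, with all induced edges, plus a canonical key for indexing.
#'
#' @param graph a [bond_graph()].
#' @param center node index of the central atomic site.
#' @param w neighbourhood depth in bonds (>= 1).
#' @return object of class `cov_descriptor` with fields `graph` (the induced
#'   subgraph), `center` (index within the subgraph), `w`, `key`
#'   (canonical string) and `orig_ids` (subgraph node -> original node).
#' @export
build_descriptor <- function(graph, center, w) {
  stopifnot(inherits(graph, "bond_graph"))
  n <- length(graph$elements)
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > n) {
    stop("descriptor center not in graph", call. = FALSE)
  }
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1", call. = FALSE)
  adj <- graph_adjacency(graph)
  dist <- rep(NA_integer_, n)
  dist[center] <- 0L
  frontier <- center
  d <- 0L
  while (length(frontier) && d < w) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  keep <- which(!is.na(dist))
  keep <- keep[order(keep)]
  remap <- match(seq_len(n), keep)
  sub_edges <- graph$edges[graph$edges[, 1] %in% keep &
                             graph$edges[, 2] %in% keep, , drop = FALSE]
  sub <- bond_graph(graph$elements[keep],
                    cbind(remap[sub_edges[, 1]], remap[sub_edges[, 2]]),
                    labels = graph$labels[keep])
  desc <- structure(list(graph = sub, center = match(center, keep),
                         w = w, orig_ids = keep, key = NA_character_),
                    class = "cov_descriptor")
  desc$key <- descriptor_key(desc)
  desc
}

#' @export
print.cov_descriptor <- function(x, ...) {
  cat("<cov_descriptor> center ", x$graph$labels[x$center], ", w = ", x$w,
      ", ", length(x$graph$elements), " atoms\n", sep = "")
  invisible(x)
}

# Content-deterministic compression of label strings: two independent
# polynomial hashes over prime moduli (< 2^25 so double-precision modular
# arithmetic stays exact). Identical strings always hash identically across
# graphs; a cross-hash collision of distinct strings is ~2^-49.
string_hash <- function(s) {
  vapply(s, function(x) {
    cs <- utf8ToInt(x)
    h1 <- 17; h2 <- 19
    for (c in cs) {
      h1 <- (h1 * 33 + c) %% 33554393
      h2 <- (h2 * 53 + c) %% 16777213
    }
    paste0(h1, "-", h2)
  }, character(1), USE.NAMES = FALSE)
}

# Canonical key: iterative neighbourhood-label (Weisfeiler-Lehman) refinement
# seeded with element symbols and a center marker. Isomorphic descriptors
# always share a key; distinct keys are a sound fast-reject. Rounds = w + 1
# (enough to propagate labels across the whole truncated neighbourhood).
# Refined labels are re-encoded each round by a content hash, so keys are
# comparable across independently built descriptors.
descriptor_key <- function(desc) {
  g <- desc$graph
  n <- length(g$elements)
  adj <- graph_adjacency(g)
  lab <- g$elements
  lab[desc$center] <- paste0("*", lab[desc$center])
  for (round in seq_len(desc$w + 1L)) {
    nxt <- vapply(seq_len(n), function(i) {
      paste0(lab[i], "(", paste(sort(lab[adj[[i]]]), collapse = ","), ")")
    }, character(1))
    lab <- paste0(ifelse(seq_len(n) == desc$center, "*", ""),
                  string_hash(nxt))
  }
  paste0("w", desc$w, ":n", n, ":e", nrow(g$edges), ":",
         paste(sort(lab), collapse = "."), ":c", lab[desc$center])
}

# igraph form of a descriptor with vertex colors encoding element (+ center
# pin). Returns list(g, color).
descriptor_igraph <- function(desc, palette) {
  g <- desc$graph
  n <- length(g$elements)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, t(g$edges))
  }
  color <- match(g$elements, palette)
  if (any(is.na(color))) stop("element not in palette", call. = FALSE)
  color[desc$center] <- color[desc$center] + length(palette)
  list(g = ig, color = as.integer(color))
}

#' Test two descriptors for a match
#'
#' A match is an element-label-preserving graph isomorphism between the two
#' descriptor subgraphs that maps center to center. The canonical keys give a
#' fast reject; candidate matches are confirmed by VF2 isomorphism search.
#'
#' @param d1,d2 `cov_descriptor` objects built at the same `w`.
#' @param all_mappings return every witness isomorphism (needed to resolve
#'   local symmetry such as methyl rotors) instead of just the first.
#' @return list with `match` (logical) and `mapping` (integer vector, node i
#'   of `d1` -> `mapping[i]` of `d2`; NULL if no match). With
#'   `all_mappings = TRUE`, `mappings` is a list of all witnesses.
#' @export
descriptors_match <- function(d1, d2, all_mappings = FALSE) {
  stopifnot(inherits(d1, "cov_descriptor"), inherits(d2, "cov_descriptor"))
  if (d1$w != d2$w) {
    stop("descriptors must be built at the same w", call. = FALSE)
  }
  no <- if (all_mappings) list(match = FALSE, mappings = list())
        else list(match = FALSE, mapping = NULL)
  if (length(d1$graph$elements) != length(d2$graph$elements)) return(no)
  if (nrow(d1$graph$edges) != nrow(d2$graph$edges)) return(no)
  if (d1$key != d2$key) return(no)
  palette <- sort(unique(c(d1$graph$elements, d2$graph$elements)))
  a <- descriptor_igraph(d1, palette)
  b <- descriptor_igraph(d2, palette)
  maps <- igraph::isomorphisms(a$g, b$g, method = "vf2",
                               vertex.color1 = a$color,
                               vertex.color2 = b$color)
  if (!length(maps)) return(no)
  maps <- lapply(maps, as.integer)
  if (all_mappings) {
    list(match = TRUE, mappings = maps)
  } else {
    list(match = TRUE, mapping = maps[[1]])
  }
}

#' Choose the descriptor depth adaptively
#'
#' Starts from `w_start` and reduces `w` until the database match count
#' exceeds `min_matches`. Deep descriptors are maximally specific but can be
#' too rare for stable density statistics; the adaptive reduction trades
#' specificity for sample size exactly when needed.
#'
#' @param db an [build_database()] environment database.
#' @param builder function(w) returning the query `cov_descriptor` at depth
#'   w (e.g. `function(w) build_descriptor(graph, site, w)`).
#' @param w_start initial depth (default 6).
#' @param min_matches required match count (default 3000); the chosen depth
#'   is the largest `w <= w_start` with strictly more matches than this.
#' @return list with `w`, `matches` (entry ids), `n_matches` and `exhausted`
#'   (TRUE when even `w = 1` failed to clear `min_matches`; the `w = 1`
#'   matches are then returned with a warning).
#' @export
adaptive_depth <- function(db, builder, w_start = 6, min_matches = 3000) {
  w_start <- as.integer(w_start)
  if (w_start < 1L) stop("w_start must be >= 1", call. = FALSE)
  for (w in seq(w_start, 1L)) {
    ids <- query_database(db, builder(w))
    if (length(ids) > min_matches) {
      return(list(w = w, matches = ids, n_matches = length(ids),
                  exhausted = FALSE))
    }
  }
  ids <- query_database(db, builder(1L))
  if (!length(ids)) {
    stop("no database matches for this site even at w = 1", call. = FALSE)
  }
  warning("match count ", length(ids), " at w = 1 does not exceed ",
          min_matches, "; using all w = 1 matches", call. = FALSE)
  list(w = 1L, matches = ids, n_matches = length(ids), exhausted = TRUE)
}
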