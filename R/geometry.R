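# Rigid-body superposition of local environments onto a reference
# conformation via 3-4 anchor atoms.

#' Optimal rigid superposition (proper rotation + translation)
#'
#' Kabsch algorithm: returns the proper rotation (det = +1) and translation
#' minimizing the RMSD of `P` onto `Q`. Reflections are never applied, so a
#' mirror-image point set keeps a nonzero residual.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3), row-paired.
#' @return list with `R` (3 x 3, applied as `x %*% R`), `t` (length 3) and
#'   `rmsd` (the achieved minimum). The transform maps P onto Q:
#'   `apply_transform(P, tf) ~ Q`.
#' @export
rigid_align <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L || nrow(P) < 3L) {
    stop("P and Q must be matched n x 3 matrices with n >= 3", call. = FALSE)
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  # collinearity check on the anchor geometry
  sp <- svd(P0)$d
  if (sp[2] < 1e-6 * max(sp[1], 1e-12)) {
    stop("degenerate geometry: anchor atoms are (near-)collinear",
         call. = FALSE)
  }
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)  # x %*% R rotates row vectors
  t <- cq - drop(cp %*% R)
  moved <- sweep(P0 %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Map query anchors into a matched database environment
#'
#' Given the witness isomorphism(s) between the query site's descriptor and a
#' database entry's descriptor, finds the database atoms corresponding to the
#' query anchor atoms and returns their Cartesian coordinates in the database
#' structure frame. When local symmetry (e.g. a methyl rotor) yields several
#' witness isomorphisms, all are enumerated and the pairing with the lowest
#' post-alignment RMSD onto the query anchors is kept.
#'
#' @param query_desc the query site's `cov_descriptor` (on the query
#'   molecule's bond graph).
#' @param anchor_sites integer site indices of the anchor atoms in the query
#'   molecule graph (3-4 atoms; must lie within the descriptor depth).
#' @param anchor_coords matched anchor coordinates in the reference frame
#'   (n_anchor x 3).
#' @param db an `env_db`.
#' @param entry_id matched database entry.
#' @param w descriptor depth of the match.
#' @return list with `db_anchor_xyz` (anchor coordinates in the database
#'   frame), `db_anchor_sites`, `tf` (rigid transform database -> reference)
#'   and `rmsd`.
#' @export
anchor_correspondence <- function(query_desc, anchor_sites, anchor_coords,
                                  db, entry_id, w) {
  sub_idx <- match(anchor_sites, query_desc$orig_ids)
  if (any(is.na(sub_idx))) {
    stop("configuration error: anchor atom(s) outside descriptor depth w = ",
         query_desc$w, call. = FALSE)
  }
  ed <- entry_descriptor(db, entry_id, w)
  mm <- descriptors_match(query_desc, ed, all_mappings = TRUE)
  if (!mm$match) {
    stop("entry ", entry_id, " does not match the query descriptor",
         call. = FALSE)
  }
  e <- db$entries[entry_id, ]
  st <- db$structures[[e$structure_id]]
  g <- db$graphs[[e$structure_id]]
  mol_xyz <- molecule_coords(st, g, e$site_index)
  best <- NULL
  for (mp in mm$mappings) {
    db_sites <- ed$orig_ids[mp[sub_idx]]
    P <- mol_xyz[db_sites, , drop = FALSE]
    if (any(is.na(P))) next
    tf <- tryCatch(rigid_align(P, anchor_coords), error = function(e) NULL)
    if (is.null(tf)) next
    if (is.null(best) || tf$rmsd < best$rmsd) {
      best <- list(db_anchor_xyz = P, db_anchor_sites = db_sites, tf = tf,
                   rmsd = tf$rmsd)
    }
  }
  if (is.null(best)) {
    stop("degenerate geometry: no usable anchor correspondence for entry ",
         entry_id, call. = FALSE)
  }
  best
}

#' Extract and align a database environment onto the reference frame
#'
#' Convenience wrapper: extracts the 7 A spherical environment of a database
#' entry, resolves the anchor correspondence and applies the rigid transform,
#' returning the environment expressed in the reference (query) frame.
#'
#' @inheritParams anchor_correspondence
#' @param radius extraction radius in Angstrom.
#' @return a `local_env` in the reference frame (with `alignment_rmsd`).
#' @export
aligned_environment <- function(query_desc, anchor_sites, anchor_coords,
                                db, entry_id, w, radius = 7) {
  e <- db$entries[entry_id, ]
  env <- expand_to_sphere(db$structures[[e$structure_id]], e$site_index,
                          radius = radius)
  ac <- anchor_correspondence(query_desc, anchor_sites, anchor_coords,
                              db, entry_id, w)
  env <- transform_env(env, ac$tf)
  env$alignment_rmsd <- ac$rmsd
  env
}
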