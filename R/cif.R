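# Minimal CIF reader/writer for small-molecule crystal structures: one data
# block, cell parameters, an atom_site loop in fractional coordinates and
# (optionally) symmetry operators which are applied to give a P1 site list.

strip_su <- function(x) {
  # "1.234(5)" -> 1.234 ; "." and "?" -> NA
  x <- sub("\\(\\d+\\)$", "", trimws(x))
  x[x %in% c(".", "?")] <- NA
  suppressWarnings(as.numeric(x))
}

cif_tokens <- function(line) {
  # split a CIF data line into tokens, honouring single/double quotes
  out <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", out)
}

#' Read a crystal structure from a CIF file
#'
#' Parses a single-block CIF with cell parameters and an `_atom_site` loop in
#' fractional coordinates. If symmetry operators
#' (`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`) are
#' present they are applied and duplicate images merged, so the returned
#' structure always lists all sites of the P1-expanded unit cell. Sites with
#' partial occupancy are rejected: the mapping pipeline assumes ordered
#' crystals and silently accepting disorder would corrupt the density maps.
#'
#' @param path path to a CIF file.
#' @param elements_allowed permitted element symbols.
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path, elements_allowed = supported_elements()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop("CIF format error: empty file (line 1)", call. = FALSE)
  }

  items <- list()      # scalar data items
  loops <- list()      # list of list(tags=, rows=list of token vectors)
  i <- 1L
  n <- length(lines)
  block_seen <- 0L
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
    if (grepl("^data_", ln, ignore.case = TRUE)) {
      block_seen <- block_seen + 1L
      if (block_seen > 1L) break  # only the first block is read
      i <- i + 1L; next
    }
    if (tolower(ln) == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", trimws(lines[[i]]))) {
        tags <- c(tags, tolower(trimws(lines[[i]])))
        i <- i + 1L
      }
      if (!length(tags)) {
        stop("CIF format error: loop_ without tags (line ", i, ")",
             call. = FALSE)
      }
      rows <- list()
      while (i <= n) {
        ln2 <- trimws(lines[[i]])
        if (!nzchar(ln2) || startsWith(ln2, "#")) { i <- i + 1L; next }
        if (grepl("^(_|loop_|data_)", ln2, ignore.case = TRUE)) break
        toks <- cif_tokens(ln2)
        if (length(toks) != length(tags)) {
          stop("CIF format error: loop row has ", length(toks),
               " values for ", length(tags), " tags (line ", i, ")",
               call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- toks
        i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      if (length(toks) >= 2L) {
        items[[tolower(toks[1])]] <- paste(toks[-1], collapse = " ")
      } else {
        # value on the following line
        i <- i + 1L
        items[[tolower(toks[1])]] <- trimws(lines[[i]])
      }
      i <- i + 1L
      next
    }
    i <- i + 1L
  }

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  missing_items <- need[!need %in% names(items)]
  if (length(missing_items)) {
    stop("CIF format error: missing ", paste(missing_items, collapse = ", "),
         " (line 1)", call. = FALSE)
  }
  lengths <- strip_su(unlist(items[need[1:3]], use.names = FALSE))
  angles <- strip_su(unlist(items[need[4:6]], use.names = FALSE))

  # locate the atom_site loop
  site_loop <- NULL
  for (lp in loops) {
    if (any(grepl("^_atom_site_fract_x$", lp$tags))) { site_loop <- lp; break }
  }
  if (is.null(site_loop)) {
    stop("CIF format error: no _atom_site loop with fractional coordinates",
         call. = FALSE)
  }
  tg <- site_loop$tags
  col <- function(tag) {
    k <- match(tag, tg)
    if (is.na(k)) return(NULL)
    vapply(site_loop$rows, `[[`, character(1), k)
  }
  fx <- strip_su(col("_atom_site_fract_x"))
  fy <- strip_su(col("_atom_site_fract_y"))
  fz <- strip_su(col("_atom_site_fract_z"))
  if (any(is.na(fx)) || any(is.na(fy)) || any(is.na(fz))) {
    stop("CIF validation error: non-numeric fractional coordinate",
         call. = FALSE)
  }
  occ <- col("_atom_site_occupancy")
  if (!is.null(occ)) {
    occ_n <- strip_su(occ)
    if (any(!is.na(occ_n) & abs(occ_n - 1) > 1e-4)) {
      stop("CIF validation error: partial occupancy / disorder is not ",
           "supported; supply an ordered model", call. = FALSE)
    }
  }
  sym <- col("_atom_site_type_symbol")
  lab <- col("_atom_site_label")
  if (is.null(sym)) {
    if (is.null(lab)) {
      stop("CIF format error: atom_site loop has neither type_symbol nor ",
           "label", call. = FALSE)
    }
    sym <- sub("^([A-Za-z]{1,2}).*$", "\\1", lab)
  }
  # normalise element capitalisation ("CL" -> "Cl"); trailing digits stripped
  sym <- sub("[0-9+-]+$", "", sym)
  sym <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 10)))
  if (is.null(lab)) lab <- paste0(sym, seq_along(sym))

  frac <- cbind(fx, fy, fz)

  # symmetry operators -> P1 expansion
  ops <- character()
  for (lp in loops) {
    k <- grep("^_(symmetry_equiv_pos_as_xyz|space_group_symop_operation_xyz)$",
              lp$tags)
    if (length(k)) {
      ops <- vapply(lp$rows, `[[`, character(1), k[1])
      break
    }
  }
  if (!length(ops)) {
    for (tag in c("_symmetry_equiv_pos_as_xyz",
                  "_space_group_symop_operation_xyz")) {
      if (tag %in% names(items)) ops <- items[[tag]]
    }
  }
  if (length(ops) > 1L || (length(ops) == 1L &&
                           !identical(gsub(" ", "", tolower(ops)), "x,y,z"))) {
    expanded <- apply_symmetry(frac, sym, lab, ops)
    frac <- expanded$frac
    sym <- expanded$elements
    lab <- expanded$labels
  }

  sid <- items[["_chemical_name_common"]]
  if (is.null(sid)) sid <- sub("\\.cif$", "", basename(path))
  crystal_structure(lengths, angles, sym, frac, labels = lab,
                    structure_id = sid, elements_allowed = elements_allowed)
}

# Evaluate symmetry operator strings like "-x, y+1/2, -z+1/2" on fractional
# coordinates and merge duplicates (tolerance 1e-4 on wrapped coordinates).
apply_symmetry <- function(frac, elements, labels, ops) {
  ops <- tolower(gsub("[ '\"]", "", ops))
  bad <- grepl("[^xyz0-9+./,-]", ops)
  if (any(bad)) {
    stop("CIF format error: unparseable symmetry operator '",
         ops[which(bad)[1]], "'", call. = FALSE)
  }
  out_frac <- NULL
  out_el <- character()
  out_lab <- character()
  for (op in ops) {
    parts <- strsplit(op, ",", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop("CIF format error: symmetry operator '", op,
           "' does not have three components", call. = FALSE)
    }
    ex <- lapply(parts, function(p) parse(text = p)[[1]])
    for (s in seq_len(nrow(frac))) {
      env <- list2env(list(x = frac[s, 1], y = frac[s, 2], z = frac[s, 3]))
      pos <- vapply(ex, eval, numeric(1), envir = env)
      pos <- pos - floor(pos)
      if (!is.null(out_frac)) {
        dd <- abs(sweep(out_frac, 2, pos))
        dd <- pmin(dd, 1 - dd)  # periodic distance per component
        dup <- apply(dd < 1e-4, 1, all) & out_el == elements[s]
        if (any(dup)) next
      }
      out_frac <- rbind(out_frac, pos)
      out_el <- c(out_el, elements[s])
      out_lab <- c(out_lab, labels[s])
    }
  }
  # make labels unique after expansion
  out_lab <- make.unique(out_lab, sep = "_")
  list(frac = out_frac, elements = out_el, labels = out_lab)
}

#' Write a crystal structure to a CIF file
#'
#' Writes the P1 site list (no symmetry reduction) with cell parameters and
#' an `_atom_site` loop. Round-trips with [read_cif()] to 1e-5 in fractional
#' coordinates and 1e-4 in cell parameters.
#'
#' @param structure a [crystal_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  id <- gsub("[^A-Za-z0-9_-]", "_", structure$structure_id)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_%s", id)
  w("_symmetry_space_group_name_H-M   'P 1'")
  w("_cell_length_a   %.6f", structure$cell_lengths[1])
  w("_cell_length_b   %.6f", structure$cell_lengths[2])
  w("_cell_length_c   %.6f", structure$cell_lengths[3])
  w("_cell_angle_alpha   %.6f", structure$cell_angles[1])
  w("_cell_angle_beta    %.6f", structure$cell_angles[2])
  w("_cell_angle_gamma   %.6f", structure$cell_angles[3])
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  for (s in seq_len(nrow(structure$frac))) {
    w("%s %s %.6f %.6f %.6f", structure$labels[s], structure$elements[s],
      structure$frac[s, 1], structure$frac[s, 2], structure$frac[s, 3])
  }
  invisible(path)
}

#' Read a directory of CIF files
#' @param dir directory containing `.cif` files.
#' @param ... passed to [read_cif()].
#' @return named list of [crystal_structure()] keyed by structure id.
#' @export
read_cif_dir <- function(dir, ...) {
  files <- sort(list.files(dir, pattern = "\\.cif$", full.names = TRUE))
  structs <- lapply(files, read_cif, ...)
  setNames(structs, vapply(structs, `[[`, character(1), "structure_id"))
}
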