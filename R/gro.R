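# Box geometry ---------------------------------------------------------------

BOX_SHAPE_TOL <- 1e-5  # nm; below .gro print precision, above double noise

#' Classify a simulation box
#'
#' GROMACS stores the periodic cell as a lower-triangular 3x3 matrix of box
#' vectors (rows v1, v2, v3, in nm) with v1y = v1z = v2z = 0. A box is
#' `cubic` when all off-diagonal elements are zero (within `tol`) and the
#' three diagonal lengths agree within `tol`; `rectangular` when only the
#' off-diagonals vanish; otherwise `triclinic` (the general case, covering
#' rhombic-dodecahedral and truncated-octahedral cells).
#'
#' @param vectors 3x3 numeric matrix of box vectors in nm.
#' @param tol Tolerance in nm for treating elements as zero/equal.
#' @return `"cubic"`, `"rectangular"` or `"triclinic"`.
#' @export
classify_box <- function(vectors, tol = BOX_SHAPE_TOL) {
  stopifnot(is.numeric(vectors), all(dim(vectors) == c(3, 3)))
  upper <- c(vectors[1, 2], vectors[1, 3], vectors[2, 3])
  if (any(abs(upper) > tol)) {
    stop(sprintf(
      "box vectors violate the lower-triangular convention: |upper| max = %g nm (tol %g)",
      max(abs(upper)), tol))
  }
  off <- c(vectors[2, 1], vectors[3, 1], vectors[3, 2])
  d <- diag(vectors)
  if (all(abs(off) <= tol)) {
    if (abs(d[1] - d[2]) <= tol && abs(d[1] - d[3]) <= tol) return("cubic")
    return("rectangular")
  }
  "triclinic"
}

#' Construct a box geometry
#'
#' Computes shape, diagonal dimensions and volume from the box vectors. For a
#' lower-triangular cell the volume is the product of the diagonal elements
#' (equal to the determinant of the full matrix).
#'
#' @param vectors 3x3 numeric lower-triangular matrix in nm.
#' @param tol Shape-classification tolerance in nm.
#' @return A `box_geometry` list with `vectors`, `shape`, `dimensions` (x, y,
#'   z diagonal, nm) and `volume` (nm^3).
#' @export
box_geometry <- function(vectors, tol = BOX_SHAPE_TOL) {
  vectors <- matrix(as.numeric(vectors), 3, 3)
  shape <- classify_box(vectors, tol)
  structure(list(vectors = vectors, shape = shape,
                 dimensions = diag(vectors),
                 volume = vectors[1, 1] * vectors[2, 2] * vectors[3, 3]),
            class = "box_geometry")
}

canonicalize_box <- function(box) {
  box <- as.list(box)
  v <- box$vectors
  if (is.list(v)) v <- do.call(rbind, lapply(v, function(r) as.numeric(unlist(r))))
  box_geometry(v)
}

# .gro parsing ----------------------------------------------------------------

#' Parse a GROMACS .gro structure file
#'
#' Reads the title, the atom count and the final box line. Atom records are
#' counted against the declared count but not retained: only box properties
#' are metadata. The box line holds either 3 floats (the diagonal of a
#' rectangular/cubic cell) or 9 floats in GROMACS order
#' (v1x v2y v3z v1y v1z v2x v2z v3x v3y).
#'
#' @param text Character scalar (file content) or character vector of lines.
#' @return A `gro_file` list with `title`, `atom_count` and `box`
#'   (a [box_geometry()]).
#' @export
parse_gro <- function(text) {
  lines <- split_lines(text)
  if (length(lines) < 3) {
    stop("a .gro file needs at least a title, an atom count and a box line")
  }
  title <- trimws(lines[[1]])
  atom_count <- suppressWarnings(as.integer(trimws(lines[[2]])))
  if (is.na(atom_count) || atom_count < 0) {
    stop(sprintf(".gro atom-count line is not a non-negative integer: '%s'",
                 trimws(lines[[2]])))
  }
  box_line <- trimws(lines[[length(lines)]])
  n_atom_lines <- length(lines) - 3L
  if (n_atom_lines != atom_count) {
    stop(sprintf(".gro declares %d atoms but contains %d atom lines",
                 atom_count, n_atom_lines))
  }
  fields <- strsplit(box_line, "[[:space:]]+")[[1]]
  vals <- suppressWarnings(as.numeric(fields))
  if (anyNA(vals) || !(length(vals) %in% c(3L, 9L))) {
    stop(sprintf(".gro box line is not 3 or 9 numbers: '%s'", box_line))
  }
  vectors <- matrix(0, 3, 3)
  if (length(vals) == 3L) {
    diag(vectors) <- vals
  } else {
    # GROMACS order: v1x v2y v3z v1y v1z v2x v2z v3x v3y
    vectors[1, 1] <- vals[1]; vectors[2, 2] <- vals[2]; vectors[3, 3] <- vals[3]
    vectors[1, 2] <- vals[4]; vectors[1, 3] <- vals[5]
    vectors[2, 1] <- vals[6]; vectors[2, 3] <- vals[7]
    vectors[3, 1] <- vals[8]; vectors[3, 2] <- vals[9]
  }
  structure(list(title = title, atom_count = atom_count,
                 box = box_geometry(vectors)),
            class = "gro_file")
}

#' Partial metadata record from a parsed .gro file
#'
#' @param gro A [parse_gro()] result.
#' @param source_file Filename used in the provenance tag.
#' @return A partial [metadata_record()] carrying the box.
#' @export
gro_to_record <- function(gro, source_file = "structure.gro") {
  metadata_record(
    system = list(box = gro$box),
    provenance = list(
      "system.box" = provenance_tag(source_file, "parsed")))
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE, useBytes = TRUE)) {
    strsplit(text, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  } else {
    as.character(text)
  }
}
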