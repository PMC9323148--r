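#' Head-scan classes
#'
#' The closed set of diagnostic labels handled by the pipeline: controls
#' (including positional plagiocephaly) and the three craniosynostosis types.
#'
#' @return character vector of the four class labels.
#' @export
scan_classes <- function() c("control", "coronal", "sagittal", "metopic")

#' Construct a head scan (mesh + landmarks + metadata)
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()].
#' @param label class label, one of [scan_classes()].
#' @param age_days nonnegative integer age at acquisition.
#' @param mirrored logical; `TRUE` for the mirrored twin of an original scan.
#' @param id optional scan identifier.
#' @return object of class `head_scan`.
#' @export
head_scan <- function(mesh, landmarks, label, age_days = 0L,
                      mirrored = FALSE, id = NULL) {
  label <- match.arg(label, scan_classes())
  stopifnot(age_days >= 0)
  structure(list(mesh = mesh, landmarks = landmarks, label = label,
                 age_days = as.integer(age_days), mirrored = isTRUE(mirrored),
                 id = id),
            class = "head_scan")
}

#' @export
print.head_scan <- function(x, ...) {
  cat("head_scan", if (!is.null(x$id)) paste0("'", x$id, "'"), ": ",
      n_vertices(x$mesh), " vertices, label=", x$label,
      if (x$mirrored) " (mirrored)", "\n", sep = "")
  invisible(x)
}

#' Mirror a scan across the midsagittal plane
#'
#' Reflects vertices and landmarks across the plane, reverses face winding so
#' normals stay outward, swaps lateralized landmark names (left/right) and
#' toggles the `mirrored` flag. Mirroring doubles the effective sample size
#' and removes laterality bias for asymmetric (coronal) cases.
#'
#' @param scan a [head_scan()].
#' @param plane optional plane `list(point, normal)`; by default fitted from
#'   the scan's midline landmarks via [midsagittal_plane()].
#' @return the mirrored `head_scan`.
#' @export
mirror_scan <- function(scan, plane = NULL) {
  if (is.null(plane)) plane <- midsagittal_plane(scan$landmarks)
  v <- reflect_points(scan$mesh$vertices, plane)
  f <- scan$mesh$faces[, c(1, 3, 2), drop = FALSE]
  lc <- as.matrix(scan$landmarks[, c("x", "y", "z")])
  lref <- reflect_points(lc, plane)
  lms <- scan$landmarks
  lms$x <- lref[, 1]; lms$y <- lref[, 2]; lms$z <- lref[, 3]
  lms <- swap_laterality(lms)
  head_scan(surface_mesh(v, f, validate = FALSE), lms, scan$label,
            scan$age_days, mirrored = !scan$mirrored,
            id = if (!is.null(scan$id)) paste0(scan$id, "_m"))
}

#' Extract a submesh from a vertex mask
#'
#' Returns the submesh of masked vertices and the faces lying fully inside the
#' mask, plus the map from submesh vertex indices back to parent indices.
#' Used to cut the cranial part out of the (corresponded) template so facial
#' variation cannot influence the cranial model.
#'
#' @param mesh a [surface_mesh()].
#' @param mask integer vector of parent vertex indices (1-based) to keep.
#' @return list with `mesh` (the submesh) and `index_map` (integer vector:
#'   `index_map[i]` is the parent index of submesh vertex `i`).
#' @export
extract_submesh <- function(mesh, mask) {
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) == 0L) stop("empty vertex mask")
  p <- n_vertices(mesh)
  if (any(mask < 1L) || any(mask > p)) stop("mask indices out of range")
  keep <- logical(p)
  keep[mask] <- TRUE
  f <- mesh$faces
  inside <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  new_id <- integer(p)
  new_id[mask] <- seq_along(mask)
  sub_f <- matrix(new_id[f[inside, , drop = FALSE]], ncol = 3)
  list(mesh = surface_mesh(mesh$vertices[mask, , drop = FALSE], sub_f,
                           validate = FALSE),
       index_map = mask)
}

#' Rows of a shape vector belonging to a vertex subset
#'
#' Maps vertex indices to the xyz-interleaved coordinate rows of a 3p shape
#' vector (rows 3(i-1)+1..3 for vertex i).
#'
#' @param vertex_ids integer vertex indices.
#' @return integer vector of coordinate-row indices.
#' @export
coordinate_rows <- function(vertex_ids) {
  as.vector(t(outer(3L * (as.integer(vertex_ids) - 1L), 1:3, `+`)))
}

#' Read / write a vertex mask (plain-text list of template vertex indices)
#'
#' One 1-based vertex index per line; `#` comments allowed.
#'
#' @param path text file path.
#' @return integer vector of vertex indices.
#' @export
read_vertex_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  as.integer(lines[nzchar(lines)])
}

#' @rdname read_vertex_mask
#' @param mask integer vector of vertex indices.
#' @export
write_vertex_mask <- function(mask, path) {
  writeLines(as.character(as.integer(mask)), path)
  invisible(path)
}
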