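#' Construct a triangular surface mesh
#'
#' A `surface_mesh` holds the vertex coordinates (in mm) and triangular face
#' connectivity of one head scan or template. Faces are stored with
#' counterclockwise winding so that face normals point outward.
#'
#' @param vertices numeric p x 3 matrix of vertex coordinates (mm).
#' @param faces integer t x 3 matrix of vertex indices (1-based).
#' @param validate check invariants (indices in range, no degenerate or
#'   duplicate faces). Default `TRUE`.
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a p x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) {
    stop("faces must be a t x 3 matrix of triangles")
  }
  if (validate && nrow(faces) > 0L) {
    p <- nrow(vertices)
    if (any(faces < 1L) || any(faces > p)) {
      stop("face indices out of range [1, ", p, "]")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen)) {
      stop("degenerate face(s) with repeated vertex: ",
           paste(which(degen)[seq_len(min(5, sum(degen)))], collapse = ", "))
    }
    key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
    if (anyDuplicated(key)) {
      stop("duplicate face(s): ", paste(which(duplicated(key))[1], collapse = ", "))
    }
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh: ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Unique undirected edges of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return integer e x 2 matrix, each row an edge with first index < second.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Per-face area and (unit) normals
#'
#' @param mesh a `surface_mesh`.
#' @return `face_areas`: numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3(ab, ac)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @return `face_normals`: t x 3 matrix of unit outward normals (zero rows for
#'   zero-area faces).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3(ab, ac)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' Area-weighted per-vertex unit normals
#'
#' @param mesh a `surface_mesh`.
#' @return p x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3(ab, ac)  # length = 2 * area, so area weighting is built in
  p <- nrow(v)
  n <- matrix(0, p, 3)
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1] <- n[, 1] + as.vector(tapply_sum(cr[, 1], idx, p))
    n[, 2] <- n[, 2] + as.vector(tapply_sum(cr[, 2], idx, p))
    n[, 3] <- n[, 3] + as.vector(tapply_sum(cr[, 3], idx, p))
  }
  nrm <- sqrt(rowSums(n^2))
  nrm[nrm == 0] <- 1
  n / nrm
}

# fast grouped sum onto 1..p
tapply_sum <- function(x, idx, p) {
  out <- numeric(p)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Vectorize a mesh into an xyz-interleaved shape vector (and back)
#'
#' Shape vectors stack vertex coordinates as (x1, y1, z1, x2, y2, z2, ...),
#' the convention used by the observation matrix and the shape model.
#'
#' @param vertices p x 3 coordinate matrix.
#' @return `as_shape_vector`: numeric vector of length 3p.
#' @export
as_shape_vector <- function(vertices) as.vector(t(vertices))

#' @rdname as_shape_vector
#' @param x shape vector of length 3p.
#' @return `as_vertex_matrix`: p x 3 coordinate matrix.
#' @export
as_vertex_matrix <- function(x) matrix(x, ncol = 3, byrow = TRUE)

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle projection of query points onto a triangulated
#' surface (brute force over faces, compiled).
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a `surface_mesh`.
#' @return list with `point` (n x 3 closest surface points), `distance`
#'   (n distances, mm) and `face` (n face indices).
#' @export
closest_on_mesh <- function(points, mesh) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  cpp_closest_on_mesh(points, mesh$vertices, mesh$faces)
}
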