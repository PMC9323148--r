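#' The default cranial/facial landmark schema
#'
#' Ten named anatomical landmarks with a laterality flag each. Midline
#' landmarks define a fittable midsagittal plane; left/right pairs are swapped
#' when a scan is mirrored. The schema is configurable: any schema with >= 3
#' midline landmarks and matched left/right pairs works throughout the
#' package.
#'
#' @return data.frame with columns `name` and `laterality`
#'   (`"left"`, `"right"`, `"midline"`).
#' @export
default_landmark_schema <- function() {
  data.frame(
    name = c("nasion", "sellion", "exocanthion_left", "exocanthion_right",
             "tragus_left", "tragus_right", "euryon_left", "euryon_right",
             "opisthocranion", "vertex_point"),
    laterality = c("midline", "midline", "left", "right", "left", "right",
                   "left", "right", "midline", "midline"),
    stringsAsFactors = FALSE
  )
}

#' Construct a named landmark set
#'
#' @param coords n x 3 numeric matrix of landmark coordinates (mm), with
#'   rownames, or a data.frame with columns `name`, `x`, `y`, `z`.
#' @param schema landmark schema (see [default_landmark_schema()]).
#' @param require_complete if `TRUE` (default) every schema name must be
#'   present exactly once.
#' @return object of class `landmark_set`: a data.frame `name,x,y,z` with the
#'   schema attached as an attribute.
#' @export
landmark_set <- function(coords, schema = default_landmark_schema(),
                         require_complete = TRUE) {
  if (is.data.frame(coords)) {
    df <- coords[, c("name", "x", "y", "z")]
  } else {
    if (is.null(rownames(coords))) stop("landmark coords need rownames")
    df <- data.frame(name = rownames(coords), x = coords[, 1], y = coords[, 2],
                     z = coords[, 3], stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  if (anyDuplicated(df$name)) {
    stop("duplicate landmark name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  if (require_complete) {
    missing <- setdiff(schema$name, df$name)
    if (length(missing) > 0L) {
      stop("missing landmark(s): ", paste(missing, collapse = ", "))
    }
    df <- df[match(schema$name, df$name), ]
    rownames(df) <- NULL
  }
  structure(df, schema = schema, class = c("landmark_set", "data.frame"))
}

#' Landmark coordinates as a matrix
#' @param lms a `landmark_set`.
#' @param names optional subset/order of landmark names.
#' @return n x 3 matrix with rownames.
#' @export
landmark_coords <- function(lms, names = NULL) {
  if (!is.null(names)) {
    idx <- match(names, lms$name)
    if (anyNA(idx)) {
      stop("missing landmark(s): ", paste(names[is.na(idx)], collapse = ", "))
    }
    lms <- lms[idx, ]
  }
  m <- as.matrix(lms[, c("x", "y", "z")])
  rownames(m) <- lms$name
  m
}

#' Read / write landmark files
#'
#' CSV files have columns `name,x,y,z`; JSON files map names to 3-vectors.
#'
#' @param path file ending in `.csv` or `.json`.
#' @param schema landmark schema.
#' @param require_complete passed to [landmark_set()].
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path, schema = default_landmark_schema(),
                           require_complete = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- data.frame(name = names(lst),
                     do.call(rbind, lapply(lst, function(v) {
                       stats::setNames(as.numeric(v[1:3]), c("x", "y", "z"))
                     })),
                     stringsAsFactors = FALSE)
  } else {
    stop("unsupported landmark format '.", ext, "'")
  }
  landmark_set(df, schema = schema, require_complete = require_complete)
}

#' @rdname read_landmarks
#' @param lms a `landmark_set`.
#' @export
write_landmarks <- function(lms, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(lms)[, c("name", "x", "y", "z")], path,
                     row.names = FALSE)
  } else if (ext == "json") {
    lst <- stats::setNames(
      lapply(seq_len(nrow(lms)), function(i) as.numeric(lms[i, c("x", "y", "z")])),
      lms$name)
    jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA)
  } else {
    stop("unsupported landmark format '.", ext, "'")
  }
  invisible(path)
}

#' Swap left/right landmark names (laterality swap after mirroring)
#'
#' @param lms a `landmark_set`.
#' @return a `landmark_set` with left and right names exchanged (coordinates
#'   untouched).
#' @export
swap_laterality <- function(lms) {
  schema <- attr(lms, "schema")
  nm <- lms$name
  swapped <- nm
  for (i in seq_len(nrow(schema))) {
    if (schema$laterality[i] == "left") {
      partner <- schema$name[schema$laterality == "right" &
        gsub("_right$", "", schema$name) == gsub("_left$", "", schema$name[i])]
      if (length(partner) == 1L) {
        swapped[nm == schema$name[i]] <- partner
        swapped[nm == partner] <- schema$name[i]
      }
    }
  }
  out <- lms
  out$name <- swapped
  # restore schema order
  out <- out[match(schema$name, out$name), ]
  rownames(out) <- NULL
  structure(out, schema = schema, class = class(lms))
}

#' Fit the midsagittal plane from midline landmarks
#'
#' Least-squares plane through the midline landmarks (smallest principal
#' direction of their scatter is the plane normal). The normal is oriented
#' toward the right-side landmarks when any are present.
#'
#' @param lms a `landmark_set`.
#' @return list with `point` (3-vector on the plane) and `normal`
#'   (unit 3-vector).
#' @export
midsagittal_plane <- function(lms) {
  schema <- attr(lms, "schema")
  mid <- lms[lms$name %in% schema$name[schema$laterality == "midline"], ]
  if (nrow(mid) < 3L) stop("need >= 3 midline landmarks to fit a plane")
  P <- as.matrix(mid[, c("x", "y", "z")])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("midline landmarks are collinear; midsagittal plane undetermined")
  }
  normal <- sv$v[, 3]
  right <- lms[lms$name %in% schema$name[schema$laterality == "right"], ]
  if (nrow(right) > 0L) {
    d <- colMeans(as.matrix(right[, c("x", "y", "z")])) - ctr
    if (sum(d * normal) < 0) normal <- -normal
  }
  list(point = ctr, normal = normal)
}

reflect_points <- function(P, plane) {
  d <- (P - matrix(plane$point, nrow(P), 3, byrow = TRUE)) %*% plane$normal
  P - 2 * d %*% t(plane$normal)
}
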