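#' Read a triangular mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (ASCII) and Stanford PLY (ASCII and
#' binary_little_endian). Only triangular faces are accepted; a quad or
#' polygon face raises a parse error naming the face. OBJ indices are 1-based
#' on disk and kept 1-based in memory; PLY indices are 0-based on disk and
#' converted.
#'
#' @param path file path ending in `.obj` or `.ply`.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unsupported mesh format '.", ext, "' (use .obj or .ply)")
  )
}

#' Write a triangular mesh to OBJ or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path ending in `.obj` or `.ply`.
#' @param binary for PLY, write binary_little_endian instead of ASCII.
#'   Coordinates are written as double precision so round trips are lossless
#'   well below the 1e-6 mm contract.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stop("unsupported mesh format '.", ext, "' (use .obj or .ply)")
  )
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("OBJ parse error: no vertices in ", path)
  vparts <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(s) as.numeric(s[1:3])))
  if (anyNA(verts)) stop("OBJ parse error: malformed vertex line in ", path)
  faces <- NULL
  if (length(flines) > 0L) {
    fparts <- strsplit(sub("^f\\s+", "", flines), "\\s+")
    nvert <- lengths(fparts)
    if (any(nvert != 3L)) {
      bad <- which(nvert != 3L)[1]
      stop("OBJ parse error: face ", bad, " has ", nvert[bad],
           " vertices; only triangles are supported")
    }
    # entries may be v, v/vt, v/vt/vn or v//vn; keep the vertex index
    faces <- do.call(rbind, lapply(fparts, function(s) {
      as.integer(vapply(strsplit(s, "/"), `[`, character(1), 1L))
    }))
    if (anyNA(faces)) stop("OBJ parse error: malformed face line in ", path)
    if (any(faces < 0L)) stop("OBJ parse error: negative indices unsupported")
  }
  surface_mesh(verts, if (is.null(faces)) matrix(integer(), 0, 3) else faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# craniomorph OBJ", con)
  v <- mesh$vertices
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(mesh$faces) > 0L) {
    f <- mesh$faces
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines terminated by \n
  read_hline <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("PLY parse error: unexpected end of header")
      if (ch == "\n") break
      chars <- c(chars, ch)
    }
    sub("\r$", "", paste(chars, collapse = ""))
  }
  if (read_hline() != "ply") stop("PLY parse error: missing 'ply' magic")
  fmt <- NULL
  elements <- list()  # list of list(name, count, props = data.frame(type,name) )
  cur <- NULL
  repeat {
    line <- read_hline()
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = "list", count_type = tok[3],
               item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex)) stop("PLY parse error: no vertex element")
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("PLY parse error: unsupported format '", fmt, "'")
  }
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    pos <- 0L
    read_element_ascii <- function(el) {
      lines <- rest[(pos + 1L):(pos + el$count)]
      pos <<- pos + el$count
      lines
    }
    out <- list()
    for (el in elements) {
      lines <- read_element_ascii(el)
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, character(1), "name")
        vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                                      as.numeric))
        out$vertices <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        fl <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
        nv <- vapply(fl, `[`, integer(1), 1L)
        if (any(nv != 3L)) {
          bad <- which(nv != 3L)[1]
          stop("PLY parse error: face ", bad, " has ", nv[bad],
               " vertices; only triangles are supported")
        }
        out$faces <- do.call(rbind, lapply(fl, function(s) s[2:4])) + 1L
      }
    }
    surface_mesh(out$vertices,
                 if (is.null(out$faces)) matrix(integer(), 0, 3) else out$faces)
  } else {
    type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)
    read_scalar <- function(type, n = 1L) {
      sz <- type_size[[type]]
      if (type %in% c("float", "float32", "double", "float64")) {
        readBin(con, "double", n = n, size = sz, endian = "little")
      } else {
        readBin(con, "integer", n = n, size = sz, endian = "little",
                signed = !(sz < 4 && grepl("^u", type)))
      }
    }
    out <- list()
    for (el in elements) {
      if (el$name == "vertex" &&
          all(vapply(el$props, `[[`, character(1), "type") != "list")) {
        types <- vapply(el$props, `[[`, character(1), "type")
        pn <- vapply(el$props, `[[`, character(1), "name")
        if (length(unique(types)) == 1L) {
          vals <- matrix(read_scalar(types[1], el$count * length(pn)),
                         ncol = length(pn), byrow = TRUE)
        } else {
          vals <- matrix(0, el$count, length(pn))
          for (i in seq_len(el$count)) {
            for (j in seq_along(pn)) vals[i, j] <- read_scalar(types[j])
          }
        }
        out$vertices <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        lp <- el$props[[1]]
        faces <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          nv <- read_scalar(lp$count_type)
          if (nv != 3L) {
            stop("PLY parse error: face ", i, " has ", nv,
                 " vertices; only triangles are supported")
          }
          faces[i, ] <- read_scalar(lp$item_type, 3L)
        }
        out$faces <- faces + 1L
      } else {
        # skip unknown fixed-size element
        for (pr in el$props) {
          if (pr$type == "list") stop("PLY parse error: unsupported list property")
        }
        types <- vapply(el$props, `[[`, character(1), "type")
        invisible(lapply(seq_len(el$count),
                         function(i) lapply(types, read_scalar)))
      }
    }
    surface_mesh(out$vertices,
                 if (is.null(out$faces)) matrix(integer(), 0, 3) else out$faces)
  }
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment craniomorph",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
              eos = NULL, useBytes = TRUE)
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    if (nrow(f) > 0L) {
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    if (nrow(f) > 0L) {
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
                 con)
    }
  }
  invisible(path)
}
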