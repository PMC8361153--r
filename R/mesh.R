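#' @useDynLib serialface, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a triangulated surface mesh
#'
#' The universal geometry carrier of the package: vertices in millimetres,
#' triangular faces as 1-based vertex index triples. On construction the mesh
#' is validated (finite coordinates, in-range indices), degenerate faces
#' (repeated indices) are dropped with a message, and derived quantities are
#' computed: unit face normals, area-weighted unit vertex normals, per-face
#' edge adjacency, and the set of boundary vertices (vertices incident to an
#' edge shared by fewer than two faces).
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param mesh_id optional identifier carried along and recorded in masks.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `vertex_normals`, `face_normals`, `face_areas`,
#'   `boundary_vertices` (integer indices), `edge_adjacency` (faces x 3
#'   integer matrix, `NA` where edge `j`, opposite vertex `j`, has no
#'   neighbouring face) and `mesh_id`.
#' @export
surface_mesh <- function(vertices, faces, mesh_id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  nv <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nv) {
      stop("face indices out of range [1, ", nv, "]")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen)) {
      message("dropped ", sum(degen), " degenerate face(s)")
      faces <- faces[!degen, , drop = FALSE]
    }
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL

  fg <- face_geometry(vertices, faces)
  edges <- edge_structure(faces)

  structure(
    list(
      vertices = vertices,
      faces = faces,
      vertex_normals = vertex_normals_from(vertices, faces, fg$raw_normals),
      face_normals = fg$unit_normals,
      face_areas = fg$areas,
      boundary_vertices = edges$boundary_vertices,
      edge_adjacency = edges$adjacency,
      mesh_id = mesh_id %||% NA_character_
    ),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces,", length(x$boundary_vertices), "boundary vertices\n")
  invisible(x)
}

# cross products of face edge vectors: raw normals have length 2*area
face_geometry <- function(vertices, faces) {
  if (nrow(faces) == 0L) {
    return(list(raw_normals = matrix(0, 0, 3), unit_normals = matrix(0, 0, 3),
                areas = numeric(0)))
  }
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  raw <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- sqrt(rowSums(raw^2))
  unit <- raw / pmax(nrm, .Machine$double.xmin)
  list(raw_normals = raw, unit_normals = unit, areas = nrm / 2)
}

vertex_normals_from <- function(vertices, faces, raw_face_normals) {
  nv <- nrow(vertices)
  vn <- matrix(0, nv, 3)
  if (nrow(faces) > 0L) {
    idx <- c(faces[, 1], faces[, 2], faces[, 3])
    acc <- rowsum(rbind(raw_face_normals, raw_face_normals, raw_face_normals),
                  group = idx)
    vn[as.integer(rownames(acc)), ] <- acc
  }
  nrm <- sqrt(rowSums(vn^2))
  zero <- nrm < 1e-300
  nrm[zero] <- 1
  vn <- vn / nrm
  vn[zero, 3] <- 1  # isolated vertices get an arbitrary unit normal
  vn
}

# Undirected edge table. Edge slot j of a face is the edge opposite vertex j,
# i.e. between local vertices j+1 and j+2 (mod 3).
edge_structure <- function(faces) {
  nf <- nrow(faces)
  if (nf == 0L) {
    return(list(adjacency = matrix(NA_integer_, 0, 3),
                boundary_vertices = integer(0)))
  }
  ea <- rbind(faces[, c(2, 3)], faces[, c(3, 1)], faces[, c(1, 2)])
  lo <- pmin(ea[, 1], ea[, 2])
  hi <- pmax(ea[, 1], ea[, 2])
  key <- as.double(lo) * 2^26 + as.double(hi)
  face_of <- rep.int(seq_len(nf), 3L)
  o <- order(key)
  k <- key[o]
  runs <- rle(k)
  if (any(runs$lengths > 2L)) {
    warning("non-manifold edges present (shared by more than two faces)")
  }
  partner <- rep(NA_integer_, 3L * nf)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  two <- which(runs$lengths == 2L)
  if (length(two)) {
    i1 <- o[starts[two]]
    i2 <- o[starts[two] + 1L]
    partner[i1] <- face_of[i2]
    partner[i2] <- face_of[i1]
  }
  adjacency <- matrix(partner, nf, 3L)
  bnd_rows <- o[starts[runs$lengths == 1L]]
  boundary_vertices <- sort(unique(c(ea[bnd_rows, ])))
  list(adjacency = adjacency, boundary_vertices = boundary_vertices)
}

#' Merge duplicate vertices
#'
#' Vertices closer than `tol` (snapped to a grid of that pitch) are merged and
#' faces re-indexed, so triangle soups (as read from STL) become topologically
#' connected and boundary detection is meaningful.
#'
#' @param vertices,faces as in [surface_mesh()].
#' @param tol merge tolerance in mm.
#' @return list with merged `vertices` and re-indexed `faces`.
#' @export
merge_duplicate_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3L))
}

#' Read a surface mesh from STL or PLY
#'
#' STL (binary or ASCII, auto-detected) and ASCII PLY are supported. STL
#' stores independent facets; duplicate vertices within 1e-6 mm are merged so
#' shared edges are connected. Coordinates are taken to be millimetres.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"stl"` or `"ply"`.
#' @param mesh_id optional identifier stored on the mesh.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply"),
                      mesh_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else "stl"
  }
  if (format == "stl") read_stl(path, mesh_id) else read_ply(path, mesh_id)
}

read_stl <- function(path, mesh_id = NULL) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(84, sz))
  close(con)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.double(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    rec <- readBin(con, "raw", n = 50 * ntri)
    m <- matrix(rec, nrow = 50)
    tri <- vapply(seq_len(ntri), function(i) {
      readBin(m[1:48, i], "numeric", n = 12, size = 4, endian = "little")
    }, numeric(12))
    v <- t(tri)[, 4:12, drop = FALSE]  # skip facet normal
    verts <- matrix(NA_real_, 3 * ntri, 3)
    verts[seq(1, 3 * ntri, by = 3), ] <- v[, 1:3, drop = FALSE]
    verts[seq(2, 3 * ntri, by = 3), ] <- v[, 4:6, drop = FALSE]
    verts[seq(3, 3 * ntri, by = 3), ] <- v[, 7:9, drop = FALSE]
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("vertex", lines, fixed = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("STL parse error in ", path, ": found ", length(vl),
           " vertex lines (must be a positive multiple of 3)")
    }
    toks <- strsplit(trimws(lines[vl]), "\\s+")
    bad <- which(vapply(toks, length, 1L) != 4L)
    if (length(bad)) {
      stop("STL parse error at line ", vl[bad[1]], ": malformed vertex record")
    }
    verts <- matrix(
      suppressWarnings(as.numeric(unlist(lapply(toks, `[`, 2:4)))),
      ncol = 3, byrow = TRUE
    )
    if (anyNA(verts)) {
      bad <- vl[which(rowSums(is.na(verts)) > 0)[1]]
      stop("STL parse error at line ", bad, ": non-numeric coordinate")
    }
    faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  }
  mg <- merge_duplicate_vertices(verts, faces, tol = 1e-6)
  surface_mesh(mg$vertices, mg$faces, mesh_id = mesh_id)
}

read_ply <- function(path, mesh_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop("PLY parse error in ", path, ": missing 'ply' magic at line 1")
  }
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY parse error in ", path, ": no end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  nv <- nf <- NA_integer_
  vprops <- character(0)
  cur <- ""
  for (h in hdr) {
    t <- strsplit(h, "\\s+")[[1]]
    if (t[1] == "element") {
      cur <- t[2]
      if (cur == "vertex") nv <- as.integer(t[3])
      if (cur == "face") nf <- as.integer(t[3])
    } else if (t[1] == "property" && cur == "vertex" &&
               t[2] != "list") {
      vprops <- c(vprops, t[length(t)])
    }
  }
  if (is.na(nv) || is.na(nf)) {
    stop("PLY parse error in ", path, ": missing vertex/face elements")
  }
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) {
    stop("PLY parse error in ", path, ": expected ", nv + nf,
         " data rows, found ", length(body))
  }
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vmat <- matrix(suppressWarnings(as.numeric(unlist(vtok))),
                 nrow = nv, byrow = TRUE)
  if (anyNA(vmat)) stop("PLY parse error in ", path, ": bad vertex row")
  ix <- match(c("x", "y", "z"), vprops)
  if (anyNA(ix)) stop("PLY parse error in ", path, ": missing x/y/z")
  verts <- vmat[, ix, drop = FALSE]
  colors <- NULL
  ic <- match(c("red", "green", "blue"), vprops)
  if (!anyNA(ic)) colors <- vmat[, ic, drop = FALSE]
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(ftok, function(t) {
    n <- as.integer(t[1])
    if (is.na(n) || n != 3L) stop("PLY parse error: non-triangular face")
    as.integer(t[2:4]) + 1L
  }, integer(3)))
  mesh <- surface_mesh(verts, faces, mesh_id = mesh_id)
  if (!is.null(colors)) attr(mesh, "vertex_colors") <- colors
  mesh
}

#' Write a surface mesh to STL or PLY
#'
#' STL is written as ASCII with full double precision (STL carries no colour
#' channel; requesting colours with STL is an error). PLY is ASCII and can
#' carry per-vertex RGB colours losslessly.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"auto"` (from extension), `"stl"` or `"ply"`.
#' @param vertex_colors optional matrix of per-vertex RGB (0-255).
#' @param header_comment optional comment line embedded in the file header.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       vertex_colors = NULL, header_comment = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else "stl"
  }
  if (format == "stl") {
    if (!is.null(vertex_colors)) {
      stop("STL has no colour channel; use format = \"ply\" for colours")
    }
    write_stl_ascii(mesh, path)
  } else {
    write_ply_ascii(mesh, path, vertex_colors, header_comment)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- mesh$face_normals
  fmt3 <- function(m) sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3])
  if (nrow(f) > 0L) {
    blocks <- paste0(
      " facet normal ", fmt3(n), "\n  outer loop\n",
      "   vertex ", fmt3(v[f[, 1], , drop = FALSE]), "\n",
      "   vertex ", fmt3(v[f[, 2], , drop = FALSE]), "\n",
      "   vertex ", fmt3(v[f[, 3], , drop = FALSE]), "\n",
      "  endloop\n endfacet"
    )
  } else {
    blocks <- character(0)
  }
  writeLines(c("solid mesh", blocks, "endsolid mesh"), path)
}

write_ply_ascii <- function(mesh, path, vertex_colors = NULL,
                            header_comment = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  has_col <- !is.null(vertex_colors)
  if (has_col) {
    vertex_colors <- as.matrix(vertex_colors)
    if (nrow(vertex_colors) != nrow(v) || ncol(vertex_colors) != 3L) {
      stop("vertex_colors must be an n_vertices x 3 RGB matrix")
    }
    vertex_colors <- round(pmin(pmax(vertex_colors, 0), 255))
  }
  hdr <- c(
    "ply", "format ascii 1.0",
    if (!is.null(header_comment)) paste("comment", header_comment),
    paste("element vertex", nrow(v)),
    "property double x", "property double y", "property double z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vl <- sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3])
  if (has_col) {
    vl <- paste(vl, sprintf("%d %d %d", vertex_colors[, 1],
                            vertex_colors[, 2], vertex_colors[, 3]))
  }
  fl <- if (nrow(f) > 0L) {
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  } else {
    character(0)
  }
  writeLines(c(hdr, vl, fl), path)
}

#' Extract a sub-mesh by vertex selection
#'
#' Keeps the selected vertices and every face whose three vertices are all
#' selected; re-indexes faces and recomputes derived quantities.
#'
#' @param mesh a [surface_mesh()].
#' @param keep logical or integer vertex selection.
#' @return list with the new `mesh` and `index_map` giving, for each kept
#'   vertex, its index in the original mesh.
#' @export
submesh <- function(mesh, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  map <- rep(NA_integer_, nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  f <- mesh$faces
  ok <- !is.na(map[f[, 1]]) & !is.na(map[f[, 2]]) & !is.na(map[f[, 3]])
  newf <- matrix(map[f[ok, , drop = FALSE]], ncol = 3L)
  list(
    mesh = surface_mesh(mesh$vertices[keep, , drop = FALSE], newf,
                        mesh_id = mesh$mesh_id),
    index_map = keep
  )
}

#' Exact closest points on a triangulated surface
#'
#' For each query point, returns the exactly closest point on the target
#' surface (vertex, edge or face interior), the unsigned distance, the normal
#' of the supporting face (averaged across the two incident faces on an edge,
#' area-weighted vertex normal at a vertex), and whether the contact lies on a
#' boundary edge or boundary vertex of the target (used for overhang
#' exclusion).
#'
#' @param points numeric matrix of query points (n x 3, mm).
#' @param mesh target [surface_mesh()].
#' @return list with `point` (n x 3), `dist` (n), `normal` (n x 3),
#'   `face` (supporting face index, 1-based) and `on_boundary` (logical n).
#' @export
closest_on_surface <- function(points, mesh) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  res <- cpp_closest_on_mesh(points, mesh$vertices, mesh$faces - 1L)
  face <- res$face + 1L
  bary <- res$bary
  tol <- 1e-12
  nzero <- (bary[, 1] <= tol) + (bary[, 2] <= tol) + (bary[, 3] <= tol)
  normal <- mesh$face_normals[face, , drop = FALSE]
  on_boundary <- rep(FALSE, nrow(points))

  is_bnd_vertex <- rep(FALSE, nrow(mesh$vertices))
  is_bnd_vertex[mesh$boundary_vertices] <- TRUE

  vtx <- which(nzero == 2L)
  if (length(vtx)) {
    # contact at the triangle corner whose barycentric coordinate is ~1
    corner <- max.col(bary[vtx, , drop = FALSE])
    vid <- mesh$faces[cbind(face[vtx], corner)]
    normal[vtx, ] <- mesh$vertex_normals[vid, , drop = FALSE]
    on_boundary[vtx] <- is_bnd_vertex[vid]
  }
  edg <- which(nzero == 1L)
  if (length(edg)) {
    # edge slot = index of the (single) zero barycentric coordinate
    slot <- apply(bary[edg, , drop = FALSE] <= tol, 1L, which)
    nb <- mesh$edge_adjacency[cbind(face[edg], slot)]
    has_nb <- !is.na(nb)
    if (any(has_nb)) {
      i <- edg[has_nb]
      avg <- mesh$face_normals[face[i], , drop = FALSE] +
        mesh$face_normals[nb[has_nb], , drop = FALSE]
      avg <- avg / pmax(sqrt(rowSums(avg^2)), .Machine$double.xmin)
      normal[i, ] <- avg
    }
    on_boundary[edg[!has_nb]] <- TRUE
  }
  list(point = res$point, dist = res$dist, normal = normal,
       face = face, on_boundary = on_boundary)
}
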