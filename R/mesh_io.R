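#' Triangle surface mesh
#'
#' Constructs a validated `TriMesh`: vertices in millimetre world
#' coordinates plus a triangle index matrix. Triangle indices are 1-based in
#' memory (idiomatic R); all supported file formats store 0-based indices
#' and are converted at the read/write boundary. Validation enforces the
#' type invariants: every index in range, no repeated vertex within a
#' triangle, and no triangle with area below `area_floor` (degenerate
#' triangles are dropped; a mesh left with no triangles is an error).
#' Triangle winding is preserved but never relied upon: the varifold
#' representation used throughout the package is orientation-free.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param name optional text label.
#' @param area_floor degeneracy floor in mm^2 (default `1e-12`).
#' @return an object of class `TriMesh` with fields `vertices`, `triangles`,
#'   `name`.
#' @export
tri_mesh <- function(vertices, triangles, name = NULL, area_floor = 1e-12) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle index out of range [1, ", n, "]")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("triangle with repeated vertex index")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         name = name), class = "TriMesh")
  areas <- triangle_areas(mesh)
  keep <- areas >= area_floor
  if (!any(keep)) stop("validation error: all triangles degenerate (area < ",
                       area_floor, " mm^2)")
  mesh$triangles <- triangles[keep, , drop = FALSE]
  mesh
}

#' @export
print.TriMesh <- function(x, ...) {
  cat("TriMesh", if (!is.null(x$name)) paste0("'", x$name, "'") else "",
      ": ", nrow(x$vertices), " vertices, ", nrow(x$triangles),
      " triangles\n", sep = "")
  invisible(x)
}

#' Triangle areas of a mesh
#' @param mesh a `TriMesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  ct <- triangle_centres_and_tangents(mesh)
  sqrt(rowSums(ct$tangents^2))
}

#' Triangle centres and area-weighted tangents
#'
#' For each triangle returns its centre (vertex mean) and the unnormalised
#' area-weighted normal `tau = 0.5 * cross(v1 - v0, v2 - v0)`, whose norm
#' equals the triangle area. These are the atoms of the varifold
#' representation of the surface.
#'
#' @param mesh a `TriMesh`.
#' @return list with `centres` (m x 3) and `tangents` (m x 3).
#' @export
triangle_centres_and_tangents <- function(mesh) {
  tr <- mesh$triangles
  V <- mesh$vertices
  v0 <- V[tr[, 1], , drop = FALSE]
  v1 <- V[tr[, 2], , drop = FALSE]
  v2 <- V[tr[, 3], , drop = FALSE]
  list(centres = (v0 + v1 + v2) / 3,
       tangents = 0.5 * row_cross(v1 - v0, v2 - v0))
}

#' Mirror a mesh across a sagittal plane
#'
#' Reflects x-coordinates across the plane `x = plane_x` (`x -> 2c - x`),
#' used to bring left and right bilateral structures into one common side
#' before averaging. Vertex order within triangles is not re-wound: the
#' varifold metric is orientation-free, so winding is immaterial.
#'
#' @param mesh a `TriMesh`.
#' @param plane_x plane offset c (mm).
#' @return mirrored `TriMesh`.
#' @export
mirror_mesh <- function(mesh, plane_x = 0) {
  stopifnot(is.finite(plane_x))
  v <- mesh$vertices
  v[, 1] <- 2 * plane_x - v[, 1]
  mesh$vertices <- v
  mesh
}

#' Estimate the cohort mirroring plane
#'
#' The mid-sagittal mirror plane is estimated as the mean x-coordinate over
#' all vertices of all supplied meshes (configurable by passing an explicit
#' plane to [mirror_mesh()] instead).
#'
#' @param meshes list of `TriMesh`.
#' @return scalar plane offset (mm).
#' @export
estimate_mirror_plane <- function(meshes) {
  xs <- unlist(lapply(meshes, function(m) m$vertices[, 1]))
  mean(xs)
}

# ------------------------------------------------------------------ file IO

.ply_scalar_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                      short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                      int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                      float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  sz <- .ply_scalar_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  } else {
    signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
    readBin(con, "integer", n = 1L, size = sz, signed = signed,
            endian = "little")
  }
}

.split_polygon <- function(idx) {
  # fan triangulation along the 0-2 (then 0-k) diagonal; quads split 0-2
  k <- length(idx)
  if (k == 3L) return(matrix(idx, 1L))
  t(vapply(2:(k - 1L), function(j) idx[c(1L, j, j + 1L)], integer(3)))
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("format error: PLY header truncated")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop("format error: not a PLY file")
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("format error: unsupported PLY format (need ascii or binary_little_endian)")

  elements <- list()
  cur <- NULL
  for (ln in header) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) == 0L) next
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      if (toks[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[5], list = TRUE, count_type = toks[3],
               item_type = toks[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[3], list = FALSE, type = toks[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("format error: PLY without vertex/face elements")

  if (!binary) {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    ptr <- 0L
    next_line <- function() {
      ptr <<- ptr + 1L
      as.numeric(strsplit(trimws(body[ptr]), "\\s+")[[1]])
    }
    nv <- elements$vertex$count
    pnames <- vapply(elements$vertex$props, `[[`, "", "name")
    verts <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      vals <- next_line()
      verts[i, ] <- vals[match(c("x", "y", "z"), pnames)]
    }
    faces <- list()
    for (i in seq_len(elements$face$count)) {
      vals <- next_line()
      k <- vals[1]
      faces[[i]] <- .split_polygon(as.integer(vals[2:(1 + k)]) + 1L)
    }
  } else {
    nv <- elements$vertex$count
    props <- elements$vertex$props
    pnames <- vapply(props, `[[`, "", "name")
    verts <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      vals <- vapply(props, function(p) .ply_read_scalar(con, p$type),
                     numeric(1))
      verts[i, ] <- vals[match(c("x", "y", "z"), pnames)]
    }
    fprops <- elements$face$props
    lp <- Filter(function(p) p$list, fprops)[[1]]
    faces <- list()
    for (i in seq_len(elements$face$count)) {
      k <- .ply_read_scalar(con, lp$count_type)
      idx <- vapply(seq_len(k), function(j) .ply_read_scalar(con, lp$item_type),
                    numeric(1))
      faces[[i]] <- .split_polygon(as.integer(idx) + 1L)
    }
  }
  if (anyNA(verts)) stop("format error: PLY vertex properties lack x/y/z")
  list(vertices = verts, triangles = do.call(rbind, faces))
}

.read_off <- function(path) {
  toks <- scan(path, what = "", quiet = TRUE, comment.char = "#")
  if (toupper(toks[1]) != "OFF") stop("format error: not an OFF file")
  toks <- toks[-1]
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  ptr <- 3L
  verts <- matrix(as.numeric(toks[ptr + seq_len(3 * nv)]), nv, 3, byrow = TRUE)
  ptr <- ptr + 3L * nv
  faces <- list()
  for (i in seq_len(nf)) {
    ptr <- ptr + 1L
    k <- as.integer(toks[ptr])
    idx <- as.integer(toks[ptr + seq_len(k)]) + 1L
    ptr <- ptr + k
    faces[[i]] <- .split_polygon(idx)
  }
  list(vertices = verts, triangles = do.call(rbind, faces))
}

.read_vtk <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("DATASET\\s+POLYDATA", lines, ignore.case = TRUE)))
    stop("format error: legacy VTK file is not POLYDATA")
  toks <- unlist(strsplit(trimws(lines), "\\s+"))
  toks <- toks[nzchar(toks)]
  ip <- which(toupper(toks) == "POINTS")[1]
  if (is.na(ip)) stop("format error: VTK POINTS section missing")
  nv <- as.integer(toks[ip + 1L])
  verts <- matrix(as.numeric(toks[ip + 2L + seq_len(3 * nv)]), nv, 3,
                  byrow = TRUE)
  ic <- which(toupper(toks) == "POLYGONS")[1]
  if (is.na(ic)) stop("format error: VTK POLYGONS section missing")
  nf <- as.integer(toks[ic + 1L])
  ptr <- ic + 3L
  faces <- list()
  for (i in seq_len(nf)) {
    k <- as.integer(toks[ptr])
    idx <- as.integer(toks[ptr + seq_len(k)]) + 1L
    ptr <- ptr + k + 1L
    faces[[i]] <- .split_polygon(idx)
  }
  list(vertices = verts, triangles = do.call(rbind, faces))
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "vtk", "off")) return(ext)
  stop("cannot guess mesh format from extension '", ext,
       "'; pass format= explicitly")
}

#' Read a triangle mesh from file
#'
#' Supported formats: PLY (ascii and binary little-endian), legacy VTK
#' POLYDATA (ascii), and OFF. Polygonal faces with more than three vertices
#' are split deterministically by fan triangulation along the 0-2 (then
#' 0-k) diagonal. The result is validated (see [tri_mesh()]).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"vtk"`, `"off"`.
#' @param area_floor degeneracy floor forwarded to [tri_mesh()].
#' @return a `TriMesh`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "vtk", "off"),
                      area_floor = 1e-12) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  raw <- switch(format,
                ply = .read_ply(path),
                vtk = .read_vtk(path),
                off = .read_off(path))
  tri_mesh(raw$vertices, raw$triangles,
           name = tools::file_path_sans_ext(basename(path)),
           area_floor = area_floor)
}

#' Write a triangle mesh to file
#'
#' Format chosen by extension unless given. PLY is written in ascii by
#' default, or binary little-endian (with double-precision coordinates)
#' with `binary = TRUE`. Indices are converted to the formats' 0-based
#' convention.
#'
#' @param mesh a `TriMesh`.
#' @param path output path.
#' @param format one of `"auto"`, `"ply"`, `"vtk"`, `"off"`.
#' @param binary write binary PLY (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "vtk", "off"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  V <- mesh$vertices
  Tr <- mesh$triangles - 1L
  if (format == "ply" && binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply", "format binary_little_endian 1.0",
             paste("element vertex", nrow(V)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(Tr)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(V)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(Tr))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(Tr[i, ]), con, size = 4, endian = "little")
    }
  } else if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(V)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(Tr)),
             "property list uchar int vertex_indices", "end_header")
    vl <- apply(V, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
    fl <- apply(Tr, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c(hdr, vl, fl), path)
  } else if (format == "off") {
    vl <- apply(V, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
    fl <- apply(Tr, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c("OFF", paste(nrow(V), nrow(Tr), 0L), vl, fl), path)
  } else {
    vl <- apply(V, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
    fl <- apply(Tr, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c("# vtk DataFile Version 3.0", "shapetraj surface", "ASCII",
                 "DATASET POLYDATA",
                 paste("POINTS", nrow(V), "double"), vl,
                 paste("POLYGONS", nrow(Tr), 4L * nrow(Tr)), fl), path)
  }
  invisible(path)
}

# --------------------------------------------------------------- cohort IO

#' Subject record
#'
#' Bundles one subject's bilateral meshes with its time label and
#' covariates. `eyo` is the estimated years to expected symptom onset
#' (subject age minus mean familial onset age), the pipeline's time axis.
#'
#' @param subject_id text id.
#' @param left_mesh,right_mesh `TriMesh` objects.
#' @param eyo years to expected onset (finite, typically in `[-40, 20]`).
#' @param group `"carrier"` or `"noncarrier"`.
#' @param sex `"M"` or `"F"`.
#' @param site site label.
#' @param family_id family label (random-effect grouping).
#' @return an object of class `SubjectRecord`.
#' @export
subject_record <- function(subject_id, left_mesh, right_mesh, eyo, group,
                           sex, site, family_id) {
  stopifnot(is.finite(eyo), nzchar(group), nzchar(sex), nzchar(site),
            nzchar(family_id), nzchar(subject_id))
  if (!group %in% c("carrier", "noncarrier"))
    stop("group must be 'carrier' or 'noncarrier'")
  structure(list(subject_id = as.character(subject_id),
                 left_mesh = left_mesh, right_mesh = right_mesh,
                 eyo = as.numeric(eyo), group = group, sex = sex,
                 site = as.character(site),
                 family_id = as.character(family_id)),
            class = "SubjectRecord")
}

#' Read a cohort table
#'
#' Reads a CSV with header
#' `subject_id,left_mesh,right_mesh,eyo,group,sex,site,family_id`, where
#' the mesh columns are file paths (relative paths resolved against the CSV
#' directory), and loads the meshes.
#'
#' @param path CSV path.
#' @return list of `SubjectRecord`.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "left_mesh", "right_mesh", "eyo", "group", "sex",
            "site", "family_id")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ","))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(seq_len(nrow(df)), function(i) {
    subject_record(df$subject_id[i],
                   read_mesh(resolve(df$left_mesh[i])),
                   read_mesh(resolve(df$right_mesh[i])),
                   df$eyo[i], df$group[i], df$sex[i], df$site[i],
                   df$family_id[i])
  })
}
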