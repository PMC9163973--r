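# Mesh and landmark I/O. ASCII STL and PLY writers/readers are implemented
# here directly (no mesh-format package is used); binary STL is also read.

#' Write a mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file; the extension selects the format (`.stl` ASCII
#'   STL, `.ply` ASCII PLY).
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    v1 <- face_corner(mesh, 1); v2 <- face_corner(mesh, 2); v3 <- face_corner(mesh, 3)
    n <- mesh_face_normals(mesh)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid tibtunnel", con)
    fmt <- paste0(" facet normal %.9g %.9g %.9g\n  outer loop\n",
                  "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
                  "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
    writeLines(sprintf(fmt, n[, 1], n[, 2], n[, 3],
                       v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
                       v3[, 1], v3[, 2], v3[, 3]), con)
    writeLines("endsolid tibtunnel", con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                       mesh$faces[, 3] - 1L), con)
  } else {
    abort(sprintf("unsupported mesh format '%s' (use .stl or .ply)", ext),
          class = "tibtunnel_error_io")
  }
  invisible(path)
}

#' Read a mesh from STL or PLY
#'
#' Reads ASCII PLY and both ASCII and binary STL. STL soup is welded into an
#' indexed mesh.
#'
#' @param path input file.
#' @param weld_tol vertex merge tolerance for STL soup (mm).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) abort(paste("file not found:", path), class = "tibtunnel_error_io")
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    read_stl(path, weld_tol)
  } else if (ext == "ply") {
    read_ply_ascii(path)
  } else {
    abort(sprintf("unsupported mesh format '%s'", ext), class = "tibtunnel_error_io")
  }
}

read_stl <- function(path, weld_tol = 1e-6) {
  head_raw <- readBin(path, "raw", n = 80)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_raw[head_raw != as.raw(0)]))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    if (is.null(nums) || nrow(nums) %% 3 != 0) {
      abort("malformed ASCII STL", class = "tibtunnel_error_io")
    }
    faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
    return(mesh_weld(nums, faces, tol = weld_tol))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  raw_all <- readBin(con, "raw", n = n_tri * 50)
  # 50-byte records: 12 little-endian floats then a 2-byte attribute count
  sel <- rep((seq_len(n_tri) - 1) * 50, each = 48) + rep(1:48, n_tri)
  data <- readBin(raw_all[sel], "numeric", n = n_tri * 12, size = 4,
                  endian = "little")
  m <- matrix(data, ncol = 12, byrow = TRUE)
  verts <- rbind(m[, 4:6], m[, 7:9], m[, 10:12])
  ord <- as.vector(t(matrix(seq_len(3 * n_tri), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  mesh_weld(verts, faces, tol = weld_tol)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") {
    abort("not a PLY file", class = "tibtunnel_error_io")
  }
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) abort("PLY header not terminated", class = "tibtunnel_error_io")
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header))) {
    abort("only ASCII PLY is supported", class = "tibtunnel_error_io")
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  body <- lines[(endh + 1):length(lines)]
  vs <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(p) as.numeric(p[1:3])))
  fs <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(p) as.integer(p[2:4]) + 1L))
  triangle_mesh(vs, fs)
}

#' Write / read a landmark sidecar
#'
#' JSON sidecar carrying the landmarks that accompany a mesh file. Keys:
#' `pcl_attachment_center` (required for measurement), optionally
#' `plateau_rim_curve`, `true_plane_M_normal`, `side` ("left"/"right"),
#' `subject_id` and any plateau-plane serialisation.
#'
#' @param landmarks named list (a `ground_truth_landmarks` works directly).
#' @param path JSON path.
#' @return the path (write) or a named list (read).
#' @export
write_landmarks <- function(landmarks, path) {
  keep <- landmarks[!vapply(landmarks, is.function, TRUE)]
  class(keep) <- NULL
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(paste("sidecar not found:", path), class = "tibtunnel_error_io")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("pcl_attachment_center", "true_plane_M_normal")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(x[[nm]])
  }
  if (!is.null(x$plateau_rim_curve)) x$plateau_rim_curve <- as.matrix(x$plateau_rim_curve)
  x
}

#' Serialise plane M to the sidecar format
#'
#' @param plane a [plateau_plane()].
#' @return named list with keys E, F, G, normal, center, radius.
#' @export
plane_to_list <- function(plane) {
  list(E = plane$E, F = plane$F, G = plane$G, normal = plane$normal,
       center = plane$circle_center, radius = plane$circle_radius)
}

#' Load an externally supplied mesh with its landmark sidecar
#'
#' Reads a watertight triangle mesh (STL/PLY) and its JSON sidecar, mirrors
#' left knees into the right-knee anatomical frame, and validates the mesh.
#' A non-watertight mesh triggers one weld-repair attempt before failing.
#'
#' @param path mesh file.
#' @param sidecar JSON landmark file; must provide `pcl_attachment_center`.
#' @return list with `mesh` and `landmarks`, as [generate_subject()] returns
#'   (ground-truth fields absent from the sidecar are `NULL`).
#' @export
load_external_mesh <- function(path, sidecar) {
  mesh <- read_mesh(path)
  lm <- read_landmarks(sidecar)
  if (is.null(lm$pcl_attachment_center)) {
    abort("sidecar lacks required key 'pcl_attachment_center'",
          class = "tibtunnel_error_io")
  }
  if (identical(lm$side, "left")) {
    mesh <- mesh_mirror_x(mesh)
    lm$pcl_attachment_center[1] <- -lm$pcl_attachment_center[1]
    if (!is.null(lm$plateau_rim_curve)) lm$plateau_rim_curve[, 1] <- -lm$plateau_rim_curve[, 1]
    if (!is.null(lm$true_plane_M_normal)) lm$true_plane_M_normal[1] <- -lm$true_plane_M_normal[1]
    lm$side <- "right"
  }
  wt <- mesh_is_watertight(mesh)
  if (!isTRUE(wt)) {
    mesh <- mesh_weld(mesh$vertices, mesh$faces, tol = 1e-4)
    wt <- mesh_is_watertight(mesh)
    if (!isTRUE(wt)) {
      abort(paste("mesh is not watertight after repair:", attr(wt, "reason")),
            class = "tibtunnel_error_mesh")
    }
  }
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  list(mesh = mesh, landmarks = lm, subject_id = lm$subject_id %||% "external")
}
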