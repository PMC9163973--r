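#' Triangle surface mesh
#'
#' Minimal container for a watertight triangle surface in the anatomical frame
#' (+x medial, +y anterior, +z proximal; right-knee convention; units mm).
#'
#' @param vertices numeric matrix (n x 3).
#' @param faces integer matrix (m x 3) of 1-based vertex indices with
#'   consistent outward winding.
#' @param validate check index bounds and face degeneracy.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (validate) {
    if (any(faces < 1L) || any(faces > nrow(vertices))) {
      abort("face indices out of range", class = "tibtunnel_error_mesh")
    }
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3])) {
      abort("degenerate faces (repeated vertex index)", class = "tibtunnel_error_mesh")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

face_corner <- function(mesh, j) mesh$vertices[mesh$faces[, j], , drop = FALSE]

mesh_face_normals <- function(mesh, normalize = TRUE) {
  v1 <- face_corner(mesh, 1); v2 <- face_corner(mesh, 2); v3 <- face_corner(mesh, 3)
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- pmax(row_norms(n), .Machine$double.xmin)
    n <- n / len
  }
  n
}

mesh_face_areas <- function(mesh) row_norms(mesh_face_normals(mesh, normalize = FALSE)) / 2

mesh_face_centroids <- function(mesh) {
  (face_corner(mesh, 1) + face_corner(mesh, 2) + face_corner(mesh, 3)) / 3
}

# Signed volume via the divergence theorem; positive for outward winding.
mesh_volume <- function(mesh) {
  v1 <- face_corner(mesh, 1); v2 <- face_corner(mesh, 2); v3 <- face_corner(mesh, 3)
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

edge_keys <- function(i, j) pmin(i, j) * 2^21 + pmax(i, j)

#' Watertightness and orientation check
#'
#' A mesh is watertight when every edge is shared by exactly two faces with
#' opposite orientation (consistent winding) and the surface forms a single
#' connected component.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical; attributes `reason` explains a failure.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  fail <- function(msg) structure(FALSE, reason = msg)
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  und <- edge_keys(i, j)
  cnt <- table(und)
  if (any(cnt != 2L)) return(fail("edges not shared by exactly two faces"))
  dir_key <- i * 2^21 + j
  if (anyDuplicated(dir_key)) return(fail("inconsistent winding (duplicated directed edge)"))
  # connectivity over vertices used by faces
  used <- sort(unique(as.vector(f)))
  idx <- integer(max(used)); idx[used] <- seq_along(used)
  nb <- split(idx[j], idx[i])
  visited <- logical(length(used))
  queue <- 1L; visited[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nxt <- nb[[as.character(v)]]
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  if (!all(visited)) return(fail("multiple connected components"))
  TRUE
}

#' Rigid motion and scaling of meshes
#'
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return the transformed mesh.
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  triangle_mesh(apply_rigid(mesh$vertices, rotation, translation), mesh$faces,
                validate = FALSE)
}

#' @param s isotropic scale factor.
#' @rdname mesh_transform
#' @export
mesh_scale <- function(mesh, s) {
  triangle_mesh(mesh$vertices * s, mesh$faces, validate = FALSE)
}

# Mirror across the sagittal plane (x -> -x) and flip winding so the surface
# stays outward-oriented. Used to map left knees into the right-knee frame.
mesh_mirror_x <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  triangle_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], validate = FALSE)
}

# Merge vertices closer than `tol` and drop collapsed faces. Used by the
# fixture builders and as the repair step for external meshes.
mesh_weld <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = "_")
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- vertices[first, , drop = FALSE]
  new_f <- matrix(map[faces], ncol = 3)
  keep <- new_f[, 1] != new_f[, 2] & new_f[, 2] != new_f[, 3] & new_f[, 1] != new_f[, 3]
  triangle_mesh(new_v, new_f[keep, , drop = FALSE], validate = FALSE)
}

# Ear-clipping triangulation of a simple CCW 2D polygon; returns index
# triples into the input ring. Robust for non-convex rings (e.g. a plateau
# ring with a posterior fossa notch), unlike a centroid fan.
triangulate_polygon <- function(xy) {
  n <- nrow(xy)
  if (polygon_signed_area(xy) < 0) {
    idx <- rev(seq_len(n))
  } else {
    idx <- seq_len(n)
  }
  tris <- matrix(0L, 0, 3)
  cross_z <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  in_tri <- function(p, a, b, c_) {
    d1 <- cross_z(a, b, p); d2 <- cross_z(b, c_, p); d3 <- cross_z(c_, a, p)
    (d1 >= -1e-12 && d2 >= -1e-12 && d3 >= -1e-12)
  }
  guard <- 0
  while (length(idx) > 3 && guard < 10 * n) {
    guard <- guard + 1
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[((k - 2) %% m) + 1]; i1 <- idx[k]; i2 <- idx[(k %% m) + 1]
      a <- xy[i0, ]; b <- xy[i1, ]; c_ <- xy[i2, ]
      if (cross_z(a, b, c_) <= 1e-12) next       # reflex or degenerate corner
      others <- setdiff(idx, c(i0, i1, i2))
      blocked <- FALSE
      for (j in others) {
        if (in_tri(xy[j, ], a, b, c_)) { blocked <- TRUE; break }
      }
      if (!blocked) {
        tris <- rbind(tris, c(i0, i1, i2))
        idx <- idx[-k]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) break   # numerically stuck: fall back to a fan for the rest
  }
  if (length(idx) >= 3) {
    for (k in 2:(length(idx) - 1)) {
      tris <- rbind(tris, c(idx[1], idx[k], idx[k + 1]))
    }
  }
  tris
}

# Triangulated bilinear patch between four corner points (rows of a 4 x 3
# matrix ordered p00, p10, p11, p01), subdivided nu x nv, winding p00->p10->p11.
grid_patch <- function(p00, p10, p11, p01, nu, nv) {
  us <- seq(0, 1, length.out = nu + 1)
  vs <- seq(0, 1, length.out = nv + 1)
  uu <- rep(us, times = nv + 1)
  vv <- rep(vs, each = nu + 1)
  verts <- outer((1 - uu) * (1 - vv), p00) + outer(uu * (1 - vv), p10) +
    outer(uu * vv, p11) + outer((1 - uu) * vv, p01)
  id <- function(iu, iv) (iv - 1) * (nu + 1) + iu
  f <- matrix(0L, 0, 3)
  for (iv in seq_len(nv)) {
    iu <- seq_len(nu)
    a <- id(iu, iv); b <- id(iu + 1, iv); c_ <- id(iu + 1, iv + 1); d <- id(iu, iv + 1)
    f <- rbind(f, cbind(a, b, c_), cbind(a, c_, d))
  }
  list(vertices = verts, faces = f)
}

# Assemble several patches into one welded mesh.
assemble_patches <- function(patches, tol = 1e-9) {
  verts <- do.call(rbind, lapply(patches, `[[`, "vertices"))
  off <- cumsum(c(0, vapply(patches, function(p) nrow(p$vertices), 1)))
  faces <- do.call(rbind, lapply(seq_along(patches), function(i) patches[[i]]$faces + off[i]))
  mesh_weld(verts, faces, tol = max(tol, 1e-9))
}
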