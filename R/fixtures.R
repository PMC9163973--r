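# Synthetic validation fixtures with closed-form answers. These are not
# anatomical models: they exist so the solver and measurement stages can be
# checked against analytic geometry.

#' Slab fixture with a planar posterior cortex
#'
#' Builds a rectangular slab whose posterior face lies in the plane y = 0 and
#' spans z in `[-z_len, -m]`, i.e. the cortex "starts" a free height `m` below
#' the tunnel exit point B = (0, 0, 0), which lies on the extension of the
#' cortex plane. For a cylinder of radius `r` exiting at B, the maximal
#' inclination against the horizontal plane satisfies `cos(angle) = r / m`:
#' the cylinder is then tangent to the top edge of the cortex.
#'
#' @param m free height between the exit point and the start of the cortex (mm).
#' @param width medial-lateral extent of the slab (mm).
#' @param depth anterior-posterior thickness (mm).
#' @param z_len total height of the slab below the exit plane (mm).
#' @param grid target edge length of the surface triangulation (mm).
#' @return a list with `mesh`, `exit_B`, `plane_M` (the z = 0 plane as a
#'   [plateau_plane] object), and `track` (a vertical anterior entry track).
#' @export
#' @examples
#' fx <- make_slab_fixture(m = 10)
#' fx$exit_B
make_slab_fixture <- function(m, width = 50, depth = 30, z_len = 130, grid = 2) {
  if (m >= z_len) abort("m must be smaller than z_len", class = "tibtunnel_error_params")
  x0 <- -width / 2; x1 <- width / 2
  y0 <- 0; y1 <- depth
  z0 <- -z_len; z1 <- -m
  # even subdivision counts put grid vertices exactly on the mid-sagittal
  # plane x = 0, where the tangency to the cortex top edge occurs
  nx <- 2L * max(1L, ceiling(width / grid / 2))
  ny <- 2L * max(1L, ceiling(depth / grid / 4))
  nz <- max(2L, ceiling((z1 - z0) / grid))
  corner <- function(x, y, z) c(x, y, z)
  patches <- list(
    # posterior face (outward -y): winding chosen so normals point -y
    grid_patch(corner(x0, y0, z0), corner(x0, y0, z1), corner(x1, y0, z1), corner(x1, y0, z0), nz, nx),
    # anterior face (+y)
    grid_patch(corner(x0, y1, z0), corner(x1, y1, z0), corner(x1, y1, z1), corner(x0, y1, z1), nx, nz),
    # bottom (-z)
    grid_patch(corner(x0, y0, z0), corner(x1, y0, z0), corner(x1, y1, z0), corner(x0, y1, z0), nx, ny),
    # top (+z)
    grid_patch(corner(x0, y0, z1), corner(x0, y1, z1), corner(x1, y1, z1), corner(x1, y0, z1), ny, nx),
    # lateral (-x)
    grid_patch(corner(x0, y0, z0), corner(x0, y1, z0), corner(x0, y1, z1), corner(x0, y0, z1), ny, nz),
    # medial (+x)
    grid_patch(corner(x1, y0, z0), corner(x1, y0, z1), corner(x1, y1, z1), corner(x1, y1, z0), nz, ny)
  )
  mesh <- assemble_patches(patches)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]

  track_z <- seq(-1, -(z_len - 5), by = -1)
  track <- entry_track("T3", cbind(0, depth, track_z))
  plane <- plateau_plane(E = c(0, 20, 0), F_pt = c(20, 0, 0), G = c(0, -20, 0),
                         normal = c(0, 0, 1),
                         circle_center = c(0, 0, 0), circle_radius = 20)
  # the fixture's cortex never meets the exit aperture (the surface is absent
  # above z = -m), so no exclusion ball is needed around B
  list(mesh = mesh, exit_B = c(0, 0, 0), plane_M = plane, track = track,
       exclusion_radius = 0)
}

#' Axis-aligned box mesh
#'
#' @param xlim,ylim,zlim coordinate ranges (mm).
#' @param grid target triangle edge length (mm).
#' @return a [triangle_mesh()].
#' @export
make_box_mesh <- function(xlim = c(0, 1), ylim = c(0, 1), zlim = c(0, 1), grid = 0.5) {
  n <- function(a) max(1L, ceiling(diff(a) / grid))
  nx <- n(xlim); ny <- n(ylim); nz <- n(zlim)
  x0 <- xlim[1]; x1 <- xlim[2]; y0 <- ylim[1]; y1 <- ylim[2]; z0 <- zlim[1]; z1 <- zlim[2]
  patches <- list(
    grid_patch(c(x0, y0, z0), c(x0, y0, z1), c(x1, y0, z1), c(x1, y0, z0), nz, nx),
    grid_patch(c(x0, y1, z0), c(x1, y1, z0), c(x1, y1, z1), c(x0, y1, z1), nx, nz),
    grid_patch(c(x0, y0, z0), c(x1, y0, z0), c(x1, y1, z0), c(x0, y1, z0), nx, ny),
    grid_patch(c(x0, y0, z1), c(x0, y1, z1), c(x1, y1, z1), c(x1, y0, z1), ny, nx),
    grid_patch(c(x0, y0, z0), c(x0, y1, z0), c(x0, y1, z1), c(x0, y0, z1), ny, nz),
    grid_patch(c(x1, y0, z0), c(x1, y0, z1), c(x1, y1, z1), c(x1, y1, z0), nz, ny)
  )
  mesh <- assemble_patches(patches)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Cylinder capped by flat disks
#'
#' Used to validate rim extraction: the top cap's boundary is a known circle.
#'
#' @param radius,height cylinder dimensions (mm); axis +z, base at z = 0.
#' @param n_seg circumferential segments.
#' @param n_lev wall levels.
#' @return a [triangle_mesh()].
#' @export
make_capped_cylinder <- function(radius = 25, height = 60, n_seg = 64, n_lev = 10) {
  ang <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  circ <- cbind(radius * cos(ang), radius * sin(ang))
  zs <- seq(0, height, length.out = n_lev + 1)
  verts <- do.call(rbind, lapply(zs, function(z) cbind(circ, z)))
  idx <- function(i, k) (k - 1L) * n_seg + ((i - 1L) %% n_seg) + 1L
  i_seq <- seq_len(n_seg)
  faces <- do.call(rbind, lapply(seq_len(n_lev), function(k) {
    a <- idx(i_seq, k); b <- idx(i_seq + 1L, k)
    c_ <- idx(i_seq + 1L, k + 1L); d <- idx(i_seq, k + 1L)
    rbind(cbind(a, b, c_), cbind(a, c_, d))
  }))
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, height))
  i_bot <- nrow(verts) - 1L; i_top <- nrow(verts)
  faces <- rbind(faces,
                 cbind(idx(i_seq + 1L, 1L), idx(i_seq, 1L), i_bot),
                 cbind(idx(i_seq, n_lev + 1L), idx(i_seq + 1L, n_lev + 1L), i_top))
  mesh <- triangle_mesh(verts, faces, validate = FALSE)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}
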