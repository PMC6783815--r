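#' Iso-surface mesh of a binary body
#'
#' Extracts the closed triangulated surface of a binary voxel body at the
#' 0.5 level, scaled by the voxel spacing. The binary field is first
#' smoothed with a small Gaussian (default `sigma = 0.6` voxels) and the
#' mesh is then relaxed by shrink-free Taubin smoothing (default 10
#' iterations, `lambda = 0.5`, `mu = -0.53`): meshing the raw binary field
#' overestimates curved surface areas by tens of percent (voxel
#' staircase), which would bias the convexity descriptor, while heavy
#' field smoothing alone rounds away edges and corners. The combination
#' keeps a 10-voxel cube within 5%/10% of its analytic volume/area and a
#' radius-20 ball within 2%/3%. If the object is so thin that field
#' smoothing pushes it entirely below the level, the raw field is meshed
#' instead, with a warning. Masks touching the grid boundary are handled
#' by padding with background.
#'
#' The mesher is marching tetrahedra on the face-consistent Kuhn 6-tet cell
#' decomposition, so the mesh is watertight and consistently outward
#' oriented by construction. Vertex coordinates are physical: voxel
#' `(z, y, x)` (1-based) has its center at `(c(x, y, z) - 0.5) * spacing`,
#' and mesh columns are ordered `x, y, z`.
#'
#' @param b a [binary_volume()] with at least one foreground voxel.
#' @param smooth_sigma Gaussian field-smoothing bandwidth in voxels; 0
#'   disables.
#' @param level iso-level (default 0.5).
#' @param taubin_iters Taubin mesh-smoothing iterations; 0 disables.
#' @param taubin_lambda,taubin_mu Taubin step sizes (`0 < lambda < -mu`).
#' @return A `surface_mesh`: list with `vertices` (n x 3), `faces` (m x 3,
#'   1-based), `spacing`.
#' @export
mesh_surface <- function(b, smooth_sigma = 0.6, level = 0.5,
                         taubin_iters = 10L, taubin_lambda = 0.5,
                         taubin_mu = -0.53) {
  if (!is_binary_volume(b)) stop("`b` must be a binary_volume")
  if (!any(b$data)) stop("empty mask: nothing to mesh")
  pad <- max(2L, as.integer(ceiling(3 * smooth_sigma)) + 1L)
  d <- dim(b$data)
  a <- array(0, d + 2L * pad)
  a[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    b$data * 1.0
  f <- if (smooth_sigma > 0) .gaussian_smooth3d(a, smooth_sigma) else a
  if (max(f) <= level) {
    warning("object too thin for smoothing sigma = ", smooth_sigma,
            "; meshing the raw binary field")
    f <- a
  }
  mt <- .marching_tets(f, level)
  v <- mt$vertices  # columns (z, y, x), 0-based padded node indices
  # node index n (0-based) corresponds to voxel n - pad + 1 (1-based),
  # whose center is at (n - pad + 0.5) * spacing
  phys <- (v - pad + 0.5) * b$spacing
  vertices <- phys[, c(3L, 2L, 1L), drop = FALSE]  # -> (x, y, z)
  colnames(vertices) <- c("x", "y", "z")
  faces <- mt$faces[, c(1L, 3L, 2L), drop = FALSE]  # axis swap flips parity
  if (taubin_iters > 0 && nrow(vertices) > 4L)
    vertices <- .taubin_smooth(vertices, faces, taubin_lambda, taubin_mu,
                               as.integer(taubin_iters))
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces, spacing = b$spacing),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

mesh_edge_counts <- function(m) {
  f <- m$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is a mesh closed?
#'
#' A mesh is closed (watertight) iff every undirected edge is shared by
#' exactly two faces.
#'
#' @param m a `surface_mesh`.
#' @return logical.
#' @export
mesh_is_closed <- function(m) {
  if (nrow(m$faces) == 0L) return(FALSE)
  all(mesh_edge_counts(m) == 2L)
}

check_closed <- function(m) {
  if (!inherits(m, "surface_mesh") && !is.list(m))
    stop("expected a surface_mesh")
  if (!mesh_is_closed(m)) stop("non-closed mesh: edges not shared by 2 faces")
  invisible(m)
}

triangle_geometry <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  signed6 <- rowSums(a * cr)
  u <- b - a; w <- c_ - a
  cr2 <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  areas <- 0.5 * sqrt(rowSums(cr2^2))
  list(signed6 = signed6, areas = areas)
}

#' Mesh volume and surface area
#'
#' Volume is the sum of signed tetrahedra against the origin (positive for
#' a closed, outward-oriented mesh, and translation invariant); area is the
#' sum of triangle areas.
#'
#' @param m a closed, oriented `surface_mesh` (or any list with `vertices`
#'   and `faces` in the same layout, e.g. the triangulation of a hull).
#' @return A single number (volume in spacing^3 units / area in spacing^2
#'   units).
#' @export
mesh_volume <- function(m) {
  check_closed(m)
  sum(triangle_geometry(m$vertices, m$faces)$signed6) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(m) {
  check_closed(m)
  sum(triangle_geometry(m$vertices, m$faces)$areas)
}

#' Export a mesh or hull as ASCII PLY
#'
#' @param m a `surface_mesh` or `convex_hull3`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(m, path) {
  if (inherits(m, "convex_hull3")) m <- hull_mesh(m)
  v <- m$vertices; f <- m$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 9),
                                           collapse = " ")), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
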