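#' 3D convex hull of a point set
#'
#' Quickhull with triangulated, outward-oriented facets. Every input point
#' lies inside or on every facet plane within `tol * bounding-box diagonal`,
#' and hull vertices are a subset of the input points. Degenerate input
#' (fewer than 4 points, or all points collinear/coplanar) fails explicitly
#' rather than silently returning a lower-dimensional hull.
#'
#' @param points numeric n x 3 matrix of coordinates (n >= 4).
#' @param tol relative tolerance for facet-plane tests (default 1e-10 of
#'   the bounding-box diagonal). Points within `tol * diag` of the hull
#'   boundary may be excluded from the vertex set, so the hull volume can
#'   undershoot the exact hull by up to about `eps * hull area`; consumers
#'   that compare mesh and hull volumes must allow for that slack (see
#'   [measure()]).
#' @return A `convex_hull3`: list with `vertices` (hull vertex coordinates),
#'   `vertex_index` (their rows in `points`), `faces` (m x 3, 1-based rows
#'   of `points`), `points` (the input).
#' @export
convex_hull <- function(points, tol = 1e-10) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("`points` must be a numeric n x 3 matrix")
  if (nrow(points) < 4L)
    stop("convex hull needs at least 4 points")
  if (anyNA(points) || any(!is.finite(points)))
    stop("`points` must be finite")
  storage.mode(points) <- "double"
  qh <- NULL
  for (t in tol * c(1, 100, 1e4)) {
    qh <- tryCatch(.quickhull3(points, t), error = function(e) e)
    if (!inherits(qh, "error")) break
    if (grepl("degenerate", conditionMessage(qh))) stop(qh)
  }
  if (inherits(qh, "error")) stop(qh)
  structure(list(vertices = points[qh$vertex_index, , drop = FALSE],
                 vertex_index = qh$vertex_index,
                 faces = qh$faces,
                 points = points,
                 eps = qh$eps),
            class = "convex_hull3")
}

#' @export
print.convex_hull3 <- function(x, ...) {
  cat(sprintf("<convex_hull3> %d vertices, %d facets, volume %.6g\n",
              length(x$vertex_index), nrow(x$faces), hull_volume(x)))
  invisible(x)
}

hull_mesh <- function(h) {
  structure(list(vertices = h$points, faces = h$faces, spacing = NA_real_),
            class = "surface_mesh")
}

#' Hull volume and surface area
#'
#' Computed from the hull's outward-oriented triangulation exactly as
#' [mesh_volume()] / [mesh_area()].
#'
#' @param h a `convex_hull3` from [convex_hull()].
#' @return A single number.
#' @export
hull_volume <- function(h) {
  if (!inherits(h, "convex_hull3")) stop("`h` must be a convex_hull3")
  sum(triangle_geometry(h$points, h$faces)$signed6) / 6
}

#' @rdname hull_volume
#' @export
hull_area <- function(h) {
  if (!inherits(h, "convex_hull3")) stop("`h` must be a convex_hull3")
  sum(triangle_geometry(h$points, h$faces)$areas)
}

#' Does a hull contain a set of points?
#'
#' Utility for invariant checking: verifies every point is inside or on
#' every facet plane within the hull's tolerance.
#'
#' @param h a `convex_hull3`.
#' @param points n x 3 matrix.
#' @param tol absolute tolerance; defaults to the hull's construction
#'   epsilon.
#' @return logical.
#' @export
hull_contains <- function(h, points, tol = NULL) {
  if (is.null(tol)) tol <- h$eps
  points <- as.matrix(points)
  for (r in seq_len(nrow(h$faces))) {
    a <- h$points[h$faces[r, 1], ]
    b <- h$points[h$faces[r, 2], ]
    c_ <- h$points[h$faces[r, 3], ]
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nl <- sqrt(sum(n^2))
    if (nl == 0) next
    n <- n / nl
    d <- points %*% n - sum(n * a)
    if (any(d > tol)) return(FALSE)
  }
  TRUE
}
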