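#' Convexity
#'
#' `C = Ac / A`: the ratio of the convex-hull surface area to the object
#' surface area. Close to 1 for convex bodies; decreases as the surface
#' folds and undulates (the object area grows faster than the hull area).
#' Not clamped to `[0, 1]`: for flat objects with in-plane concavities the
#' hull area can exceed the object area (e.g. a plus-pentomino prism has
#' C ~ 1.075).
#'
#' @param Ac convex-hull surface area, > 0.
#' @param A object surface area, > 0.
#' @return `Ac / A`.
#' @export
convexity <- function(Ac, A) {
  if (!is.finite(Ac) || Ac <= 0) stop("`Ac` must be positive")
  if (!is.finite(A) || A <= 0) stop("`A` must be positive")
  Ac / A
}

#' Solidity
#'
#' `S = V / Vc`: the ratio of object volume to convex-hull volume. Equal to
#' 1 for convex bodies and decreases as the body curls away from its hull.
#' Because the hull is computed over the surface-mesh vertices, `V <= Vc`
#' holds by construction and `S <= 1` up to numerical tolerance; a larger
#' violation signals inconsistent mesh/hull conventions and is an error.
#'
#' @param V object volume, > 0.
#' @param Vc convex-hull volume, >= V within tolerance.
#' @param tol relative tolerance on the `V <= Vc` check.
#' @return `V / Vc`.
#' @export
solidity <- function(V, Vc, tol = 1e-9) {
  if (!is.finite(V) || V <= 0) stop("`V` must be positive")
  if (!is.finite(Vc) || Vc <= 0) stop("`Vc` must be positive")
  if (V > Vc * (1 + tol))
    stop("V > Vc beyond tolerance: inconsistent hull/mesh conventions")
  V / Vc
}

new_descriptors <- function(name, V, Vc, A, Ac, C, S, label = NA_character_) {
  df <- data.frame(name = name, V = V, Vc = Vc, A = A, Ac = Ac, C = C, S = S,
                   label = label, stringsAsFactors = FALSE)
  class(df) <- c("morph_descriptors", "data.frame")
  df
}

#' Measure the shape descriptors of a binary body
#'
#' Meshes the body's iso-surface, takes the convex hull over the mesh
#' vertices, and evaluates object volume `V`, hull volume `Vc`, object
#' area `A`, hull area `Ac`, convexity `C = Ac/A` and solidity `S = V/Vc`.
#' Volumes are in `spacing^3` units and areas in `spacing^2` units.
#'
#' @param b a [binary_volume()] plant body.
#' @param name record identifier (defaults to the volume's name).
#' @param label optional group tag (e.g. `"WT"`).
#' @param smooth_sigma passed to [mesh_surface()].
#' @return A one-row `morph_descriptors` data frame with columns
#'   `name, V, Vc, A, Ac, C, S, label`.
#' @examples
#' b <- make_body(phantom_spec("sphere", size = list(r = 8)))$volume
#' measure(b)
#' @export
measure <- function(b, name = NULL, label = NA_character_,
                    smooth_sigma = 0.6) {
  if (!is_binary_volume(b)) stop("`b` must be a binary_volume")
  if (is.null(name)) name <- b$name
  m <- mesh_surface(b, smooth_sigma = smooth_sigma)
  V <- mesh_volume(m)
  A <- mesh_area(m)
  h <- convex_hull(m$vertices)
  Vc <- hull_volume(h)
  Ac <- hull_area(h)
  # the hull may exclude vertices within eps of its boundary, so for a
  # convex body V can exceed Vc by up to ~eps * Ac; within that slack the
  # body is numerically convex and S is exactly 1
  slack <- max(1e-9, h$eps * Ac / Vc)
  S <- min(solidity(V, Vc, tol = slack), 1)
  new_descriptors(name, V, Vc, A, Ac,
                  C = convexity(Ac, A),
                  S = S,
                  label = label)
}

#' Measure a list of bodies
#'
#' @param bodies a list of [binary_volume()]s, or of `list(volume=, label=)`
#'   pairs as returned by [sample_population()].
#' @param labels optional character vector of group tags.
#' @inheritParams measure
#' @return A `morph_descriptors` data frame, one row per body.
#' @export
measure_population <- function(bodies, labels = NULL, smooth_sigma = 0.6) {
  rows <- lapply(seq_along(bodies), function(i) {
    item <- bodies[[i]]
    if (is_binary_volume(item)) {
      vol <- item
      lab <- if (!is.null(labels)) labels[i] else NA_character_
    } else {
      vol <- item$volume
      lab <- if (!is.null(labels)) labels[i]
             else if (!is.null(item$label)) item$label else NA_character_
    }
    measure(vol, label = lab, smooth_sigma = smooth_sigma)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morph_descriptors", "data.frame")
  out
}
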