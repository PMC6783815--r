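#' Extraction pipeline configuration
#'
#' Houses the tunable parameters of the plant-extraction pipeline
#' ([extract_plant()]). Thresholds default to `"auto"`: when both are
#' automatic they are set jointly by three-class Otsu ([multi_otsu3()]),
#' which separates background | plant-like | pedestal/case intensity
#' classes (plain two-class Otsu fails here because the plant is a small
#' fraction of the scene). With one threshold fixed, the other falls back
#' to two-class Otsu on the matching intensity range.
#'
#' @param high_threshold intensity above which voxels belong to the
#'   pedestal/case class, or `"auto"`.
#' @param plant_threshold intensity above which voxels are candidate plant
#'   material, or `"auto"`.
#' @param edge_threshold gradient-magnitude threshold used by
#'   [build_edge_mask()]. The gradient of a binary field has magnitude 0.5
#'   across a flat interface, so the default 0.25 marks every interface
#'   voxel.
#' @param min_component_size connected components smaller than this voxel
#'   count are treated as specks (default 27 = a 3x3x3 cube).
#' @param connectivity voxel adjacency for the plant component: 6, 18 or 26.
#'   26 keeps thin sheets connected across voxel staircases.
#' @param mask_dilation_radius dilation (in voxels, 26-neighbourhood per
#'   iteration) applied to the high-intensity mask before subtraction.
#'   Default 0: dilation also eats the plant's contact layer, and the rim
#'   that dilation would remove is exactly what [build_edge_mask()] removes.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(high_threshold = "auto",
                              plant_threshold = "auto",
                              edge_threshold = 0.25,
                              min_component_size = 27L,
                              connectivity = 26L,
                              mask_dilation_radius = 0L) {
  chk_thr <- function(t, what) {
    if (identical(t, "auto")) return(t)
    if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
      stop("`", what, "` must be a finite number or \"auto\"")
    as.numeric(t)
  }
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  if (min_component_size < 1) stop("`min_component_size` must be >= 1")
  if (mask_dilation_radius < 0) stop("`mask_dilation_radius` must be >= 0")
  structure(list(high_threshold = chk_thr(high_threshold, "high_threshold"),
                 plant_threshold = chk_thr(plant_threshold, "plant_threshold"),
                 edge_threshold = chk_thr(edge_threshold, "edge_threshold"),
                 min_component_size = as.integer(min_component_size),
                 connectivity = as.integer(connectivity),
                 mask_dilation_radius = as.integer(mask_dilation_radius)),
            class = "extraction_config")
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing the between-class variance.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return The threshold intensity (a bin edge); voxels `>=` the threshold
#'   form the upper class.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("no threshold separates the histogram")
  edges <- seq(lo, hi, length.out = nbins + 1L)
  counts <- as.numeric(
    tabulate(pmin(nbins, findInterval(x, edges, left.open = FALSE)), nbins))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[nbins]; mtot <- mu[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) stop("no threshold separates the histogram")
  m0 <- mu[-nbins] / w0
  m1 <- (mtot - mu[-nbins]) / w1
  bcv <- ifelse(valid, w0 * w1 * (m0 - m1)^2, -Inf)
  edges[which.max(bcv) + 1L]
}

#' Three-class Otsu thresholds
#'
#' Two thresholds maximizing the three-class between-class variance:
#' background | intermediate (plant-like) | high (pedestal/case). This is
#' the automatic threshold rule of the extraction pipeline, where plain
#' two-class Otsu fails because the plant class is a small fraction of the
#' scene.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return `c(t1, t2)`, `t1 < t2` (bin edges).
#' @export
multi_otsu3 <- function(x, nbins = 128L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("no threshold separates the histogram")
  edges <- seq(lo, hi, length.out = nbins + 1L)
  cnt <- as.numeric(
    tabulate(pmin(nbins, findInterval(x, edges, left.open = FALSE)), nbins))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  W <- cumsum(cnt); M <- cumsum(cnt * mids)
  n <- W[nbins]; mtot <- M[nbins]; mbar <- mtot / n
  best <- -Inf; bi <- c(NA_integer_, NA_integer_)
  for (i in 1:(nbins - 2L)) {
    w0 <- W[i]
    if (w0 == 0) next
    j <- (i + 1L):(nbins - 1L)
    w1 <- W[j] - w0; w2 <- n - W[j]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    m0 <- M[i] / w0
    m1 <- (M[j] - M[i]) / w1
    m2 <- (mtot - M[j]) / w2
    v <- w0 * (m0 - mbar)^2 + w1 * (m1 - mbar)^2 + w2 * (m2 - mbar)^2
    v[!ok] <- -Inf
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; bi <- c(i, j[k]) }
  }
  if (!is.finite(best)) stop("no threshold separates the histogram")
  edges[bi + 1L]
}

resolve_thresholds <- function(v, cfg) {
  pt <- cfg$plant_threshold
  ht <- cfg$high_threshold
  if (identical(pt, "auto") && identical(ht, "auto")) {
    t <- multi_otsu3(v$data)
    pt <- t[1]; ht <- t[2]
  } else if (identical(pt, "auto")) {
    lower <- v$data[v$data < ht]
    if (!length(lower)) stop("no threshold separates the histogram")
    pt <- otsu_threshold(lower)
  } else if (identical(ht, "auto")) {
    upper <- v$data[v$data >= pt]
    if (!length(upper)) stop("no threshold separates the histogram")
    ht <- otsu_threshold(upper)
  }
  if (ht <= pt) stop("high threshold must exceed the plant threshold")
  list(plant = pt, high = ht)
}

#' Binarize a volume at a fixed or automatic threshold
#'
#' @param v a [volume3d()].
#' @param t intensity threshold, or `"auto"` for Otsu's criterion over all
#'   voxels. A voxel is foreground iff its intensity is `>= t`.
#' @return A [binary_volume()]; the threshold used is attached as
#'   `attr(, "threshold")`.
#' @export
threshold_volume <- function(v, t = "auto") {
  stopifnot_volume(v)
  if (identical(t, "auto")) t <- otsu_threshold(v$data)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a finite number or \"auto\"")
  out <- binary_volume(v$data >= t, spacing = v$spacing, name = v$name)
  attr(out, "threshold") <- t
  out
}

#' High-intensity (pedestal) mask - Mask1
#'
#' Binarizes the scene at the high threshold, optionally dilates the result,
#' and restricts it to the original volume's nonzero support. Subtracting
#' this mask removes the pedestal and the tube-case wall.
#'
#' @param v a [volume3d()] scene.
#' @param cfg an [extraction_config()].
#' @return A [binary_volume()].
#' @export
build_pedestal_mask <- function(v, cfg = extraction_config()) {
  stopifnot_volume(v)
  thr <- resolve_thresholds(v, cfg)
  m <- v$data >= thr$high
  if (cfg$mask_dilation_radius > 0)
    m <- .dilate3d(m, 26L, cfg$mask_dilation_radius)
  m <- m & (v$data != 0)
  dim(m) <- dim(v$data)
  out <- binary_volume(m, spacing = v$spacing, name = paste0(v$name, "_mask1"))
  attr(out, "threshold") <- thr$high
  out
}

#' Zero out masked voxels
#'
#' @param v a [volume3d()].
#' @param m a [binary_volume()] of the same shape.
#' @return A [volume3d()] with masked voxels set to 0, others unchanged.
#' @export
subtract_mask <- function(v, m) {
  stopifnot_volume(v)
  if (!is_binary_volume(m)) stop("`m` must be a binary_volume")
  if (!identical(dim(v$data), dim(m$data)))
    stop("shape mismatch between volume and mask")
  d <- v$data
  d[m$data] <- 0
  volume3d(d, spacing = v$spacing, name = v$name)
}

gradient_magnitude3 <- function(a) {
  d <- dim(a)
  g2 <- array(0, d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2) next
    fwd <- bwd <- a
    idx_to <- lapply(d, seq_len)
    idx_from <- idx_to
    # shifted copies with edge replication
    idx_from[[axis]] <- pmin(seq_len(n) + 1L, n)
    fwd <- do.call(`[`, c(list(a), idx_from))
    idx_from[[axis]] <- pmax(seq_len(n) - 1L, 1L)
    bwd <- do.call(`[`, c(list(a), idx_from))
    g2 <- g2 + ((fwd - bwd) / 2)^2
  }
  sqrt(g2)
}

drop_small_components <- function(mask, min_size, connectivity = 6L) {
  if (!any(mask)) return(mask)
  lab <- .label_components3d(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out <- array(lab %in% keep, dim(mask))
  out
}

#' Edge/rim noise mask - Mask2
#'
#' Finds edges of a binary image and marks the residual thin rim and speck
#' structures (e.g. the retained pedestal edge) for removal, while leaving
#' voxels of thick bodies such as the plant untouched. Concretely: the
#' gradient magnitude of the binary field is binarized at
#' `cfg$edge_threshold`; the candidate noise set is the foreground removed
#' by a morphological opening (erosion then dilation, 3x3x3 box), i.e.
#' structures with no interior, intersected with the dilated edge zone;
#' candidate components smaller than `cfg$min_component_size` are then
#' dropped (they are picked up later by component selection anyway).
#'
#' @param b a [binary_volume()].
#' @param cfg an [extraction_config()].
#' @param near optional [binary_volume()] (in the pipeline: the pedestal
#'   mask, Mask1). When given, the noise mask is restricted to the 1-voxel
#'   neighbourhood of `near`, so only the *pedestal's* edge is flagged and
#'   thin parts of the plant far from the pedestal are spared.
#' @return A [binary_volume()] marking rim/speck noise; always a subset of
#'   the foreground of `b`.
#' @export
build_edge_mask <- function(b, cfg = extraction_config(), near = NULL) {
  if (!is_binary_volume(b)) stop("`b` must be a binary_volume")
  et <- cfg$edge_threshold
  if (identical(et, "auto")) et <- 0.25
  if (!any(b$data)) {
    return(binary_volume(array(FALSE, dim(b$data)), spacing = b$spacing,
                         name = paste0(b$name, "_mask2")))
  }
  g <- gradient_magnitude3(b$data * 1.0)
  edge <- g >= et
  dim(edge) <- dim(b$data)
  interior <- .erode3d(b$data, 26L, 1L)
  opened <- .dilate3d(interior, 26L, 1L)
  thin <- b$data & !opened
  near_edge <- .dilate3d(edge, 26L, 1L)
  mask <- thin & near_edge
  if (!is.null(near)) {
    if (!identical(dim(near$data), dim(b$data)))
      stop("shape mismatch between `b` and `near`")
    mask <- mask & .dilate3d(near$data, 26L, 1L)
  }
  dim(mask) <- dim(b$data)
  if (any(mask))
    mask <- drop_small_components(mask, cfg$min_component_size, 6L)
  binary_volume(mask, spacing = b$spacing, name = paste0(b$name, "_mask2"))
}

#' Select one connected component (3D flood fill)
#'
#' Returns exactly one connected component of the foreground under the
#' configured connectivity: the component containing `seed_point`, or the
#' largest by voxel count when `seed_point = "largest"`. Size ties break to
#' the component whose lexicographically smallest (z, y, x) voxel is
#' smallest.
#'
#' @param b a [binary_volume()] with at least one foreground voxel.
#' @param cfg an [extraction_config()] (supplies the connectivity).
#' @param seed_point `"largest"` or a 1-based voxel index `c(z, y, x)` that
#'   must lie on the foreground.
#' @return A [binary_volume()] containing the selected component only.
#' @export
select_plant_component <- function(b, cfg = extraction_config(),
                                   seed_point = "largest") {
  if (!is_binary_volume(b)) stop("`b` must be a binary_volume")
  if (!any(b$data)) stop("empty foreground: no component to select")
  lab <- .label_components3d(b$data, cfg$connectivity)
  if (identical(seed_point, "largest")) {
    sizes <- tabulate(lab[lab > 0L])
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie-break: smallest (z, y, x) of each component's minimum voxel
      key <- vapply(best, function(k) {
        w <- which(lab == k, arr.ind = TRUE)
        o <- order(w[, 1], w[, 2], w[, 3])[1]
        sum(w[o, ] * c(1e12, 1e6, 1))
      }, 0)
      best <- best[which.min(key)]
    }
    sel <- best[1]
  } else {
    sp <- as.integer(seed_point)
    if (length(sp) != 3L) stop("`seed_point` must be \"largest\" or c(z,y,x)")
    d <- dim(b$data)
    if (any(sp < 1L) || any(sp > d)) stop("seed_point outside the grid")
    sel <- lab[sp[1], sp[2], sp[3]]
    if (sel == 0L) stop("seed_point lies on the background")
  }
  out <- array(lab == sel, dim(b$data))
  binary_volume(out, spacing = b$spacing, name = b$name)
}

#' Extract the binary plant body from a micro-CT scene
#'
#' The full pipeline: high-intensity pedestal mask (Mask1) -> subtraction
#' from the scene -> binarization at the plant threshold -> edge/rim noise
#' mask (Mask2) and its subtraction -> connected-component (flood fill)
#' selection of the plant body. Voxel counts after each stage are reported
#' via `message()` when `verbose = TRUE`.
#'
#' @param v a [volume3d()] scene.
#' @param cfg an [extraction_config()].
#' @param seed_point passed to [select_plant_component()].
#' @param verbose log per-stage voxel counts.
#' @param debug if `TRUE`, attach the intermediate masks as
#'   `attr(result, "stages")`.
#' @return A [binary_volume()] plant body.
#' @export
extract_plant <- function(v, cfg = extraction_config(),
                          seed_point = "largest", verbose = FALSE,
                          debug = FALSE) {
  stopifnot_volume(v)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("extraction stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  log <- function(name, n) if (verbose)
    message(sprintf("  [%s] %d foreground voxels", name, n))

  thr <- stage("thresholds", resolve_thresholds(v, cfg))
  cfg_res <- cfg
  cfg_res$plant_threshold <- thr$plant
  cfg_res$high_threshold <- thr$high
  if (verbose)
    message(sprintf("  thresholds: plant >= %.4g, pedestal >= %.4g",
                    thr$plant, thr$high))

  m1 <- stage("pedestal_mask", build_pedestal_mask(v, cfg_res))
  log("mask1", sum(m1$data))
  v2 <- stage("subtract_mask1", subtract_mask(v, m1))
  b <- stage("plant_threshold", threshold_volume(v2, thr$plant))
  log("binarized", sum(b$data))
  m2 <- stage("edge_mask", build_edge_mask(b, cfg_res, near = m1))
  log("mask2", sum(m2$data))
  b2 <- binary_volume(b$data & !m2$data, spacing = v$spacing, name = v$name)
  log("denoised", sum(b2$data))
  if (!any(b2$data)) stop("no plant component found")
  plant <- stage("flood_fill", select_plant_component(b2, cfg_res, seed_point))
  n <- sum(plant$data)
  log("plant", n)
  if (n < cfg$min_component_size) stop("no plant component found")
  if (debug)
    attr(plant, "stages") <- list(mask1 = m1, binarized = b, mask2 = m2,
                                  denoised = b2,
                                  thresholds = thr)
  plant
}
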