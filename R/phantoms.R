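# Synthetic thallus phantoms with analytic ground truth. The generator
# emulates the imaging scene the original experiment engineered: a thin
# sheet-like "plant" of intermediate intensity resting on a high-intensity
# pedestal block inside a cylindrical tube shell, with additive Gaussian
# noise. Flat sheets stand in for the wild type; twisted/undulating sheets
# for the mutant.

#' Phantom body specification
#'
#' @param shape one of `"sphere"`, `"cuboid"`, `"slab"`, `"twisted_slab"`,
#'   `"l_prism"`, `"plus_prism"`, `"shell"`.
#' @param size named list of size parameters (length units): `sphere`:
#'   `r`; `cuboid`: `a, b, c` (z, y, x extents); `slab`/`twisted_slab`:
#'   `length, width, thickness`; `l_prism`/`plus_prism`: `cell, height`;
#'   `shell` (hemispherical): `r, thickness`.
#' @param twist total rotation (degrees) of the cross-section about the
#'   long axis, linear along the length (`twisted_slab` only).
#' @param undulation_amplitude,undulation_period sinusoidal out-of-plane
#'   displacement of the cross-section (length units; `twisted_slab` only).
#' @param grid integer `c(nz, ny, nx)`; auto-sized to contain the shape
#'   when `NULL`.
#' @param spacing voxel edge length.
#' @param seed optional seed recorded in the spec (generation itself is
#'   deterministic; the seed matters for [sample_population()] jitter).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("sphere", "cuboid", "slab",
                                   "twisted_slab", "l_prism", "plus_prism",
                                   "shell"),
                         size = list(), twist = 0,
                         undulation_amplitude = 0, undulation_period = 30,
                         grid = NULL, spacing = 1.0, seed = NULL) {
  shape <- match.arg(shape)
  if (any(unlist(size) <= 0)) stop("all size parameters must be > 0")
  if (twist < 0) stop("`twist` must be >= 0")
  if (undulation_amplitude < 0) stop("`undulation_amplitude` must be >= 0")
  if (undulation_period <= 0) stop("`undulation_period` must be > 0")
  if (spacing <= 0) stop("`spacing` must be > 0")
  structure(list(shape = shape, size = size, twist = twist,
                 undulation_amplitude = undulation_amplitude,
                 undulation_period = undulation_period,
                 grid = grid, spacing = spacing, seed = seed),
            class = "phantom_spec")
}

# voxel centers along one axis of an n-long grid, centered on 0
centered_axis <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

voxelize <- function(grid, spacing, inside_fn) {
  z <- centered_axis(grid[1], spacing)
  y <- centered_axis(grid[2], spacing)
  x <- centered_axis(grid[3], spacing)
  Z <- array(rep(z, times = grid[2] * grid[3]), grid)
  Y <- array(rep(rep(y, each = grid[1]), times = grid[3]), grid)
  X <- array(rep(x, each = grid[1] * grid[2]), grid)
  inside_fn(Z, Y, X)
}

default_grid <- function(extent, spacing, pad = 4L) {
  as.integer(ceiling(extent / spacing) + 2L * pad)
}

#' Generate a phantom body and its analytic ground truth
#'
#' Voxelization is by center inclusion: a voxel is foreground iff its
#' center lies inside the analytic solid. The attached ground truth gives
#' the analytic `V`, `Vc`, `A`, `Ac`, `C`, `S` where closed forms exist
#' (sphere, cuboid/slab, L-tromino prism, plus-pentomino prism,
#' hemispherical shell); for the twisted slab only `V` (approximate) is
#' attached.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [binary_volume()]) and `truth` (named
#'   list of analytic values; may be partially `NA`).
#' @export
make_body <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  s <- spec$size
  sp <- spec$spacing
  shape <- spec$shape
  truth <- list(V = NA_real_, Vc = NA_real_, A = NA_real_, Ac = NA_real_,
                C = NA_real_, S = NA_real_)

  if (shape == "sphere") {
    r <- s$r
    grid <- spec$grid %||% rep(default_grid(2 * r, sp), 3L)
    body <- voxelize(grid, sp, function(Z, Y, X) Z^2 + Y^2 + X^2 <= r^2)
    truth$V <- truth$Vc <- 4 / 3 * pi * r^3
    truth$A <- truth$Ac <- 4 * pi * r^2
    truth$C <- truth$S <- 1
  } else if (shape == "cuboid") {
    a <- s$a; b <- s$b; cc <- s$c
    grid <- spec$grid %||% c(default_grid(a, sp), default_grid(b, sp),
                             default_grid(cc, sp))
    body <- voxelize(grid, sp, function(Z, Y, X)
      abs(Z) <= a / 2 & abs(Y) <= b / 2 & abs(X) <= cc / 2)
    truth$V <- truth$Vc <- a * b * cc
    truth$A <- truth$Ac <- 2 * (a * b + b * cc + cc * a)
    truth$C <- truth$S <- 1
  } else if (shape == "slab" || shape == "twisted_slab") {
    if (shape == "slab") {
      spec$twist <- 0
      spec$undulation_amplitude <- 0
    }
    body <- twisted_slab_mask(s$length, s$width, s$thickness, spec$twist,
                              spec$undulation_amplitude,
                              spec$undulation_period, spec$grid, sp)
    truth$V <- s$length * s$width * s$thickness  # approximate (shear-free)
    if (spec$twist == 0 && spec$undulation_amplitude == 0) {
      truth$Vc <- truth$V
      truth$A <- truth$Ac <-
        2 * (s$length * s$width + s$width * s$thickness +
               s$thickness * s$length)
      truth$C <- truth$S <- 1
    }
    return(list(volume = binary_volume(body, spacing = sp,
                                       name = phantom_name(spec)),
                truth = truth))
  } else if (shape == "l_prism") {
    cell <- s$cell; h <- s$height
    grid <- spec$grid %||% c(default_grid(h, sp), default_grid(2 * cell, sp),
                             default_grid(2 * cell, sp))
    # L-tromino footprint in (y, x): cells (0,0), (1,0), (0,1) of a 2x2
    body <- voxelize(grid, sp, function(Z, Y, X) {
      Yc <- Y + cell; Xc <- X + cell  # footprint origin at corner
      inL <- (Yc >= 0 & Yc <= 2 * cell & Xc >= 0 & Xc <= cell) |
             (Yc >= 0 & Yc <= cell & Xc >= 0 & Xc <= 2 * cell)
      inL & abs(Z) <= h / 2
    })
    truth$V <- 3 * cell^2 * h
    truth$Vc <- 3.5 * cell^2 * h
    truth$A <- 2 * 3 * cell^2 + 8 * cell * h
    truth$Ac <- 2 * 3.5 * cell^2 + (6 + sqrt(2)) * cell * h
    truth$C <- truth$Ac / truth$A
    truth$S <- 6 / 7
  } else if (shape == "plus_prism") {
    cell <- s$cell; h <- s$height
    grid <- spec$grid %||% c(default_grid(h, sp), default_grid(3 * cell, sp),
                             default_grid(3 * cell, sp))
    body <- voxelize(grid, sp, function(Z, Y, X) {
      inP <- (abs(Y) <= cell / 2 & abs(X) <= 1.5 * cell) |
             (abs(X) <= cell / 2 & abs(Y) <= 1.5 * cell)
      inP & abs(Z) <= h / 2
    })
    truth$V <- 5 * cell^2 * h
    truth$Vc <- 7 * cell^2 * h
    truth$A <- 2 * 5 * cell^2 + 12 * cell * h
    truth$Ac <- 2 * 7 * cell^2 + (4 + 4 * sqrt(2)) * cell * h
    truth$C <- truth$Ac / truth$A
    truth$S <- 5 / 7
  } else if (shape == "shell") {
    r <- s$r; th <- s$thickness
    if (th >= r) stop("shell thickness must be < r")
    grid <- spec$grid %||% rep(default_grid(2 * r, sp), 3L)
    body <- voxelize(grid, sp, function(Z, Y, X) {
      rho2 <- Z^2 + Y^2 + X^2
      Z >= 0 & rho2 <= r^2 & rho2 >= (r - th)^2
    })
    ri <- r - th
    truth$V <- 2 / 3 * pi * (r^3 - ri^3)
    truth$Vc <- 2 / 3 * pi * r^3
    truth$A <- 2 * pi * r^2 + 2 * pi * ri^2 + pi * (r^2 - ri^2)
    truth$Ac <- 3 * pi * r^2
    truth$C <- truth$Ac / truth$A
    truth$S <- 1 - (ri / r)^3
  }
  if (!any(body)) stop("shape does not intersect the grid")
  if (touches_boundary(body))
    stop("shape exceeds the grid: enlarge `grid`")
  list(volume = binary_volume(body, spacing = sp, name = phantom_name(spec)),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phantom_name <- function(spec) {
  paste0(spec$shape,
         if (spec$twist > 0) paste0("_t", round(spec$twist)) else "",
         if (spec$undulation_amplitude > 0)
           paste0("_u", signif(spec$undulation_amplitude, 3)) else "")
}

touches_boundary <- function(body) {
  d <- dim(body)
  any(body[c(1, d[1]), , ]) || any(body[, c(1, d[2]), ]) ||
    any(body[, , c(1, d[3])])
}

twisted_slab_mask <- function(length, width, thickness, twist = 0,
                              undulation_amplitude = 0,
                              undulation_period = 30, grid = NULL,
                              spacing = 1.0) {
  if (!(thickness < width && width < length))
    stop("need thickness < width < length")
  R <- sqrt((width / 2)^2 + (thickness / 2)^2) + undulation_amplitude
  pad <- 4L
  if (is.null(grid)) {
    n <- as.integer(ceiling(2 * R / spacing) + 2L * pad)
    n <- n + n %% 2L  # even: centers at half-integers, exact box counts
    grid <- c(default_grid(length, spacing), n, n)
  }
  mask <- voxelize(grid, spacing, function(Z, Y, X) {
    t <- Z / length + 0.5              # 0..1 along the long (z) axis
    th <- (twist * pi / 180) * t
    u <- cos(th) * Y + sin(th) * X     # width coordinate in rotated frame
    v <- -sin(th) * Y + cos(th) * X    # thickness coordinate
    if (undulation_amplitude > 0)
      v <- v - undulation_amplitude *
        sin(2 * pi * (t * length) / undulation_period)
    t >= 0 & t <= 1 & abs(u) < width / 2 & abs(v) < thickness / 2
  })
  if (!any(mask)) stop("shape does not intersect the grid")
  if (touches_boundary(mask))
    stop("twisted slab self-clips at the grid boundary: enlarge `grid`")
  mask
}

#' Twisted/undulating slab body
#'
#' A sheet whose rectangular cross-section rotates linearly along the long
#' axis by a total `twist` degrees, with optional sinusoidal out-of-plane
#' undulation - the synthetic analogue of a mutant thallus twisted along
#' the growth axis with an undulating surface.
#'
#' @param length,width,thickness slab dimensions (length units), with
#'   `thickness < width < length`.
#' @inheritParams phantom_spec
#' @return A [binary_volume()].
#' @export
make_twisted_slab <- function(length, width, thickness, twist = 0,
                              undulation_amplitude = 0,
                              undulation_period = 30, grid = NULL,
                              spacing = 1.0) {
  mask <- twisted_slab_mask(length, width, thickness, twist,
                            undulation_amplitude, undulation_period,
                            grid, spacing)
  binary_volume(mask, spacing = spacing,
                name = sprintf("twisted_slab_t%g", twist))
}

#' Scene specification
#'
#' Describes a full synthetic micro-CT scene: the plant body resting on a
#' high-intensity pedestal block inside a cylindrical tube shell, with
#' additive Gaussian noise. Default intensities 0/100/200/230
#' (background/plant/pedestal/tube wall) reproduce the contrast regime the
#' eraser pedestal was chosen for. A 1-voxel partial-volume rim at plant
#' intensity on the pedestal's air-exposed boundary emulates the rim noise
#' the edge mask (Mask2) exists to remove.
#'
#' @param plant a [phantom_spec()] for the plant body (slab or
#'   twisted_slab).
#' @param plant_intensity,pedestal_intensity,tube_wall_intensity,background_intensity
#'   scene intensities; must satisfy pedestal > plant > background.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param pedestal_rim add the partial-volume rim (default `TRUE`).
#' @param seed RNG seed for the noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(plant = phantom_spec("slab",
                                            size = list(length = 60,
                                                        width = 24,
                                                        thickness = 5)),
                       plant_intensity = 100, pedestal_intensity = 200,
                       tube_wall_intensity = 230, background_intensity = 0,
                       noise_sd = 5, pedestal_rim = TRUE, seed = 1L) {
  if (!(pedestal_intensity > plant_intensity &&
        plant_intensity > background_intensity))
    stop("need pedestal_intensity > plant_intensity > background_intensity")
  structure(list(plant = plant, plant_intensity = plant_intensity,
                 pedestal_intensity = pedestal_intensity,
                 tube_wall_intensity = tube_wall_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, pedestal_rim = pedestal_rim,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic micro-CT scene with ground truth
#'
#' Builds the plant body from its spec, lays it flat (thickness vertical)
#' on the pedestal, adds the tube-case wall and optional pedestal rim, and
#' applies seeded Gaussian noise. The returned ground truth is the
#' noise-free plant mask.
#'
#' @param spec a [scene_spec()].
#' @return list with `scene` (a [volume3d()]) and `truth` (a
#'   [binary_volume()] of the plant).
#' @export
make_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec")
  ps <- spec$plant
  body <- make_body(ps)$volume$data
  # slab bodies are generated with the long axis along z; lay them flat
  # (long horizontal, thickness vertical)
  if (ps$shape %in% c("slab", "twisted_slab"))
    body <- aperm(body, c(3L, 2L, 1L))
  # trim background padding to the tight bounding box
  idx <- which(body, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  body <- body[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
               rng[1, 3]:rng[2, 3], drop = FALSE]
  bd <- dim(body)

  ped_h <- 10L
  margin <- 10L
  nx <- bd[3] + 2L * margin
  ny <- max(bd[2] + 2L * margin, 40L)
  side <- max(nx, ny)
  nx <- ny <- side  # square cross-section so the tube fits
  nz <- ped_h + 2L + bd[1] + 8L
  grid <- c(nz, ny, nx)

  # tube-case wall cross-section (computed first so the pedestal can be
  # clipped to the case interior)
  yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
  r_out <- side / 2 - 1
  r_in <- r_out - 2
  Y <- matrix(rep(seq_len(ny), nx), ny, nx)
  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ring <- (Y - yc)^2 + (X - xc)^2

  # rectangular eraser block, kept fully inside the case so its rim is a
  # clean 1-voxel shell
  ped <- array(FALSE, grid)
  ped_w <- min(floor((r_in - 3) * sqrt(2)), side - 8L,
               max(bd[3] + 8L, bd[2] + 8L))
  py <- floor((ny - ped_w) / 2)
  px <- floor((nx - ped_w) / 2)
  ped[1:ped_h, py + seq_len(ped_w), px + seq_len(ped_w)] <- TRUE

  plant <- array(FALSE, grid)
  z0 <- ped_h + 1L  # resting directly on the pedestal top
  y0 <- floor((ny - bd[2]) / 2)
  x0 <- floor((nx - bd[3]) / 2)
  plant[z0 + seq_len(bd[1]) - 1L, y0 + seq_len(bd[2]),
        x0 + seq_len(bd[3])] <- body

  # tube-case wall: hollow cylinder along z
  wall2d <- ring <= r_out^2 & ring > r_in^2
  tube <- array(rep(wall2d, each = nz), grid)

  overlap <- sum(plant & ped)
  if (overlap > 0) stop("plant overlaps the pedestal beyond contact")

  sc <- array(spec$background_intensity, grid)
  sc[tube] <- spec$tube_wall_intensity
  sc[ped] <- spec$pedestal_intensity
  if (spec$pedestal_rim) {
    # partial-volume shell where the pedestal borders air: plant-like
    # intensity, the rim noise the edge mask exists to remove
    rim <- .dilate3d(ped, 6L, 1L) & !ped & !plant & !tube
    dim(rim) <- grid
    sc[rim] <- spec$plant_intensity
  }
  sc[plant] <- spec$plant_intensity
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    sc <- sc + rnorm(length(sc), 0, spec$noise_sd)
    dim(sc) <- grid
  }
  list(scene = volume3d(sc, spacing = ps$spacing,
                        name = paste0("scene_", phantom_name(ps))),
       truth = binary_volume(plant, spacing = ps$spacing,
                             name = paste0("truth_", phantom_name(ps))))
}

#' Sample a jittered phantom population
#'
#' Draws `n` bodies around a base spec with lognormal multiplicative
#' jitter (relative sd `jitter`) on every size parameter and on the twist
#' and undulation amplitude when nonzero - the synthetic stand-in for a
#' sample of individuals from one line. Lognormal jitter keeps all lengths
#' positive. Reproducible from `seed`.
#'
#' @param n number of individuals (>= 1).
#' @param base a [phantom_spec()].
#' @param jitter relative standard deviation (default 0.1).
#' @param label group tag attached to every body.
#' @param seed RNG seed.
#' @return list of `list(volume = binary_volume, label = label,
#'   spec = phantom_spec)` entries.
#' @export
sample_population <- function(n, base, jitter = 0.1, label = "group",
                              seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  if (!is.numeric(jitter) || jitter < 0) stop("invalid jitter")
  if (!inherits(base, "phantom_spec")) stop("`base` must be a phantom_spec")
  set.seed(seed)
  sdlog <- sqrt(log(1 + jitter^2))
  draw <- function(x) if (jitter > 0) x * rlnorm(1, -sdlog^2 / 2, sdlog)
                      else x
  lapply(seq_len(n), function(i) {
    sp <- base
    sp$size <- lapply(base$size, draw)
    if (sp$twist > 0) sp$twist <- draw(sp$twist)
    if (sp$undulation_amplitude > 0)
      sp$undulation_amplitude <- draw(sp$undulation_amplitude)
    sp$grid <- NULL  # re-fit the grid to the jittered size
    body <- make_body(sp)$volume
    body$name <- sprintf("%s_%02d", label, i)
    list(volume = body, label = label, spec = sp)
  })
}
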