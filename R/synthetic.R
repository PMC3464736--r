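#' Rasterize a filled rotated ellipse
#'
#' Returns the pixels whose centers satisfy the rotated-ellipse inequality
#' `(u/a)^2 + (w/b)^2 <= 1`, where `u` is the displacement along the major
#' axis and `w` across it. `angle` is the orientation of the major axis,
#' in radians, measured from the row axis (so `angle = 0` runs down the
#' rows and `angle = pi/2` along the columns). For `a >= 10` the pixel
#' count is within 5% of the continuous area `pi * a * b`.
#'
#' @param center numeric `(row, col)` of the ellipse center.
#' @param a,b semi-major and semi-minor axes, pixels (`a >= b >= 1`).
#' @param angle orientation, radians.
#' @return two-column integer matrix of (row, col) pixel coordinates.
#' @export
rasterize_ellipse <- function(center, a, b, angle = 0) {
  stopifnot(a >= b, b >= 1)
  ext <- ceiling(a) + 1L
  rr <- seq.int(floor(center[1L]) - ext, ceiling(center[1L]) + ext)
  cc <- seq.int(floor(center[2L]) - ext, ceiling(center[2L]) + ext)
  dr <- rep(rr - center[1L], times = length(cc))
  dc <- rep(cc - center[2L], each = length(rr))
  ca <- cos(angle); sa <- sin(angle)
  if (abs(ca) < 1e-12) ca <- 0
  if (abs(sa) < 1e-12) sa <- 0
  u <- dr * ca + dc * sa
  w <- -dr * sa + dc * ca
  inside <- (u / a)^2 + (w / b)^2 <= 1
  cbind(row = rep(rr, times = length(cc))[inside],
        col = rep(cc, each = length(rr))[inside])
}

dedupe_pixels <- function(rr, cc) {
  rmin <- min(rr); span <- max(rr) - rmin + 1L
  keep <- !duplicated((cc - min(cc)) * span + (rr - rmin))
  cbind(row = rr[keep], col = cc[keep])
}

# Chebyshev dilation of a pixel set by radius m (pixels kept in-bounds only
# when shape is given).
dilate_pixels <- function(pix, m, shape = NULL) {
  if (m < 1L) return(pix)
  off <- expand.grid(dr = -m:m, dc = -m:m)
  n <- nrow(pix)
  rr <- rep(pix[, 1L], times = nrow(off)) + rep(off$dr, each = n)
  cc <- rep(pix[, 2L], times = nrow(off)) + rep(off$dc, each = n)
  if (!is.null(shape)) {
    ok <- rr >= 1L & rr <= shape[1L] & cc >= 1L & cc <= shape[2L]
    rr <- rr[ok]; cc <- cc[ok]
  }
  dedupe_pixels(rr, cc)
}

pix_index <- function(pix, shape) (pix[, 2L] - 1L) * shape[1L] + pix[, 1L]

#' Specification of a synthetic egg-batch scene
#'
#' Describes everything the generator draws: a near-white paper background
#' with faint dashed grid lines, dark elongated single eggs, piles of
#' overlapping eggs rendered with a one-pixel shadow fringe, dark debris
#' blobs wrapped in a yellow-brown chromatic halo, and sub-egg noise
#' speckles. All intensities are in `[0, 1]`.
#'
#' @param image_shape `c(H, W)` in pixels.
#' @param n_single_eggs number of isolated eggs.
#' @param n_piles number of egg piles.
#' @param pile_sizes integer vector of eggs per pile (values 2-5), length
#'   `n_piles`; `NULL` samples each from `{2, 3}`.
#' @param egg_axes `c(a, b)` nominal semi-axes, pixels. The default
#'   `c(16, 4)` (4:1 elongation, area about 200 px, eccentricity about
#'   0.968) mimics the elongated silhouette of an Anopheles egg at the
#'   recommended >= 5-megapixel imaging scale.
#' @param scale_jitter relative half-width of the uniform per-egg size
#'   jitter applied to both axes (default 0.05).
#' @param ratio_jitter relative half-width of the uniform jitter on the
#'   semi-major axis alone (default 0.075), perturbing elongation.
#' @param egg_intensity dark egg luminance (default 0.15).
#' @param intensity_jitter uniform half-width on per-object intensity.
#' @param background_intensity paper luminance (default 0.95).
#' @param grid_spacing spacing of the paper's grid lines, pixels; `0`
#'   disables the grid.
#' @param grid_intensity upper luminance of the grid dashes; each dash draws
#'   its own level uniformly from `[grid_intensity - 0.2, grid_intensity]`
#'   (default 0.55), emulating the uneven darkness of printed grid lines, so
#'   at least the darker dashes binarize as foreground fragments, which the
#'   noise rule must then discard.
#' @param pixel_jitter half-width of the uniform per-pixel intensity jitter
#'   applied to every drawn dark feature (default 0.02), smoothing the
#'   histogram as sensor noise does in photographs.
#' @param n_debris number of debris blobs.
#' @param debris_halo_rgb color of the chromatic halo around debris
#'   (default `c(0.85, 0.72, 0.55)`, chroma 0.30, luminance bright enough
#'   to stay background).
#' @param noise_speck_count number of tiny dark speckles.
#' @param speck_area `c(min, max)` speckle areas in pixels (well below half
#'   an egg).
#' @param noise_sd standard deviation of optional additive Gaussian
#'   luminance noise, applied identically to all three channels so the
#'   paper and eggs stay achromatic; `0` (default) disables it.
#' @param seed RNG seed for reproducible scenes.
#' @return a classed list of validated generator settings.
#' @export
scene_spec <- function(image_shape = c(1024L, 1024L),
                       n_single_eggs = 30L, n_piles = 3L, pile_sizes = NULL,
                       egg_axes = c(a = 16, b = 4),
                       scale_jitter = 0.05, ratio_jitter = 0.075,
                       egg_intensity = 0.15, intensity_jitter = 0.03,
                       background_intensity = 0.95,
                       grid_spacing = 64L, grid_intensity = 0.55,
                       pixel_jitter = 0.02, n_debris = 2L,
                       debris_halo_rgb = c(0.85, 0.72, 0.55),
                       noise_speck_count = 20L, speck_area = c(1L, 4L),
                       noise_sd = 0, seed = 1L) {
  s <- list(image_shape = as.integer(image_shape),
            n_single_eggs = as.integer(n_single_eggs),
            n_piles = as.integer(n_piles), pile_sizes = pile_sizes,
            egg_axes = as.numeric(egg_axes),
            scale_jitter = scale_jitter, ratio_jitter = ratio_jitter,
            egg_intensity = egg_intensity,
            intensity_jitter = intensity_jitter,
            background_intensity = background_intensity,
            grid_spacing = as.integer(grid_spacing),
            grid_intensity = grid_intensity, pixel_jitter = pixel_jitter,
            n_debris = as.integer(n_debris),
            debris_halo_rgb = as.numeric(debris_halo_rgb),
            noise_speck_count = as.integer(noise_speck_count),
            speck_area = as.integer(speck_area), noise_sd = noise_sd,
            seed = seed)
  stopifnot(all(s$image_shape >= 64L),
            s$n_single_eggs >= 0L, s$n_piles >= 0L, s$n_debris >= 0L,
            s$noise_speck_count >= 0L,
            s$egg_axes[1L] > s$egg_axes[2L], s$egg_axes[2L] >= 1,
            s$egg_intensity < s$background_intensity,
            length(s$debris_halo_rgb) == 3L)
  if (!is.null(s$pile_sizes)) {
    s$pile_sizes <- as.integer(s$pile_sizes)
    stopifnot(length(s$pile_sizes) == s$n_piles,
              all(s$pile_sizes >= 2L & s$pile_sizes <= 5L))
  }
  structure(s, class = "scene_spec")
}

#' Render a synthetic egg-batch scene with ground truth
#'
#' Draws the scene described by a [scene_spec()] and records exact ground
#' truth for every object. Placement is by rejection sampling against an
#' occupancy mask: distinct top-level objects never touch (at least two
#' background pixels between them, so 8-connected components stay
#' separate), and eggs keep at least 8 px clearance from debris halos so
#' the chromatic-neighborhood debris rule cannot reach them. Piles are
#' built from 2-5 member ellipses sharing an orientation, each offset from
#' the previous by 0.5-1.0 minor-axis lengths roughly perpendicular to the
#' major axis; the union is dilated by one pixel and the fringe drawn dark,
#' emulating the shadowed overlap regions that enlarge a pile's silhouette
#' in photographs. Reproducible for a fixed `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return object of class `"egg_scene"`: list with `image` (`H x W x 3`
#'   array in `[0, 1]`), `truth` (list: `objects` data frame with `id`,
#'   `kind` in single/pile/debris/speck, `true_count`, `area`, bounding
#'   box; `total_eggs`; `true_single_egg_area`, the median rendered
#'   single-egg area; `footprints`, list of per-object pixel matrices), and
#'   `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(spec$seed))
  }
  H <- spec$image_shape[1L]; W <- spec$image_shape[2L]
  canvas <- matrix(spec$background_intensity, H, W)
  jit <- function(base, n) pmin(pmax(base + runif(n, -spec$pixel_jitter,
                                                  spec$pixel_jitter),
                                     0.01), 0.99)

  # faint dashed grid (dash 12 on / 6 off, 1 px wide, per-dash darkness)
  if (spec$grid_spacing > 0L) {
    draw_dashes <- function(fixed, len, horizontal) {
      starts <- seq.int(1L, len, by = 18L)
      for (s in starts) {
        run <- s:min(s + 11L, len)
        lev <- jit(runif(1, spec$grid_intensity - 0.2, spec$grid_intensity),
                   length(run))
        if (horizontal) canvas[fixed, run] <<- lev else canvas[run, fixed] <<- lev
      }
    }
    for (r in seq.int(spec$grid_spacing, H - 1L, by = spec$grid_spacing))
      draw_dashes(r, W, TRUE)
    for (cl in seq.int(spec$grid_spacing, W - 1L, by = spec$grid_spacing))
      draw_dashes(cl, H, FALSE)
  }

  occ <- rep(FALSE, H * W)
  halo_sets <- list()
  objects <- list(); footprints <- list(); id <- 0L

  place <- function(make_fn, margin, what, max_tries = 2000L) {
    for (i in seq_len(max_tries)) {
      obj <- make_fn()
      pix <- obj$footprint
      if (any(pix[, 1L] < 3L | pix[, 1L] > H - 2L |
                pix[, 2L] < 3L | pix[, 2L] > W - 2L)) next
      if (any(occ[pix_index(pix, c(H, W))])) next
      zone <- dilate_pixels(pix, margin, c(H, W))
      occ[pix_index(zone, c(H, W))] <<- TRUE
      return(obj)
    }
    stop("generate_scene: could not place ", what,
         " without violating the non-overlap constraint; reduce object",
         " counts or enlarge image_shape", call. = FALSE)
  }
  rand_center <- function(ext) c(runif(1, 1 + ext, H - ext),
                                 runif(1, 1 + ext, W - ext))
  a0 <- spec$egg_axes[1L]; b0 <- spec$egg_axes[2L]

  egg_geom <- function() {
    sc <- runif(1, 1 - spec$scale_jitter, 1 + spec$scale_jitter)
    list(a = a0 * sc * runif(1, 1 - spec$ratio_jitter, 1 + spec$ratio_jitter),
         b = b0 * sc, angle = runif(1, 0, pi))
  }

  # debris first (largest clearance)
  for (k in seq_len(spec$n_debris)) {
    obj <- place(function() {
      rad <- runif(1, 8, 14); ratio <- runif(1, 1, 1.4)
      g <- list(a = rad * sqrt(ratio), b = rad / sqrt(ratio),
                angle = runif(1, 0, pi))
      ctr <- rand_center(g$a + 13)
      blob <- rasterize_ellipse(ctr, g$a, g$b, g$angle)
      halo <- dilate_pixels(blob, 4L, c(H, W))
      halo <- halo[!pix_index(halo, c(H, W)) %in% pix_index(blob, c(H, W)), , drop = FALSE]
      list(blob = blob, halo = halo, footprint = rbind(blob, halo))
    }, margin = 8L, what = "a debris blob")
    canvas[pix_index(obj$blob, c(H, W))] <-
      jit(pmax(0.05, spec$egg_intensity + 0.05 +
                 runif(1, -spec$intensity_jitter, spec$intensity_jitter)),
          nrow(obj$blob))
    halo_sets[[length(halo_sets) + 1L]] <- obj$halo
    id <- id + 1L
    objects[[id]] <- list(kind = "debris", true_count = 0L, footprint = obj$footprint)
  }

  # piles
  if (spec$n_piles > 0L) {
    sizes <- if (is.null(spec$pile_sizes)) sample(2:3, spec$n_piles, replace = TRUE)
             else spec$pile_sizes
    for (k in seq_len(spec$n_piles)) {
      nk <- sizes[k]
      obj <- place(function() {
        g <- egg_geom()
        ext <- g$a + nk * 2 * g$b + 3
        ctr <- rand_center(ext)
        members <- list(ctr)
        union <- rasterize_ellipse(ctr, g$a, g$b, g$angle)
        for (j in seq_len(nk - 1L)) {
          d <- runif(1, 0.5, 1.0) * 2 * g$b
          dir <- g$angle + pi / 2 + runif(1, -pi / 6, pi / 6)
          ctr_j <- members[[j]] + d * c(cos(dir), sin(dir))
          members[[j + 1L]] <- ctr_j
          union <- rbind(union,
                         rasterize_ellipse(ctr_j, g$a, g$b,
                                           g$angle + runif(1, -pi / 18, pi / 18)))
        }
        union <- dedupe_pixels(union[, 1L], union[, 2L])
        blob <- dilate_pixels(union, 1L, c(H, W))
        list(union = union, blob = blob, footprint = blob)
      }, margin = 2L, what = sprintf("a pile of %d eggs", nk))
      shade <- obj$blob[!pix_index(obj$blob, c(H, W)) %in%
                          pix_index(obj$union, c(H, W)), , drop = FALSE]
      canvas[pix_index(obj$union, c(H, W))] <-
        jit(spec$egg_intensity +
              runif(1, -spec$intensity_jitter, spec$intensity_jitter),
            nrow(obj$union))
      canvas[pix_index(shade, c(H, W))] <- jit(0.45, nrow(shade))
      id <- id + 1L
      objects[[id]] <- list(kind = "pile", true_count = nk, footprint = obj$footprint)
    }
  }

  # single eggs
  single_areas <- integer(0L)
  for (k in seq_len(spec$n_single_eggs)) {
    obj <- place(function() {
      g <- egg_geom()
      ctr <- rand_center(g$a + 2)
      list(footprint = rasterize_ellipse(ctr, g$a, g$b, g$angle))
    }, margin = 2L, what = "a single egg")
    canvas[pix_index(obj$footprint, c(H, W))] <-
      jit(spec$egg_intensity +
            runif(1, -spec$intensity_jitter, spec$intensity_jitter),
          nrow(obj$footprint))
    single_areas <- c(single_areas, nrow(obj$footprint))
    id <- id + 1L
    objects[[id]] <- list(kind = "single", true_count = 1L, footprint = obj$footprint)
  }

  # noise speckles
  for (k in seq_len(spec$noise_speck_count)) {
    obj <- place(function() {
      n_px <- sample(spec$speck_area[1L]:spec$speck_area[2L], 1L)
      ctr <- round(rand_center(4))
      pix <- matrix(ctr, 1L, 2L)
      while (nrow(pix) < n_px) {
        grow <- pix[sample.int(nrow(pix), 1L), ] + sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
        pix <- unique(rbind(pix, grow))
      }
      list(footprint = pix)
    }, margin = 2L, what = "a noise speckle")
    canvas[pix_index(obj$footprint, c(H, W))] <- jit(0.3, nrow(obj$footprint))
    id <- id + 1L
    objects[[id]] <- list(kind = "speck", true_count = 0L, footprint = obj$footprint)
  }

  img <- array(rep(canvas, 3L), dim = c(H, W, 3L))
  for (halo in halo_sets) {
    i <- pix_index(halo, c(H, W))
    for (ch in 1:3) img[i + (ch - 1L) * H * W] <- spec$debris_halo_rgb[ch]
  }
  if (spec$noise_sd > 0) {
    nz <- matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] + nz, 0), 1)
  }

  obj_df <- do.call(rbind, lapply(seq_along(objects), function(i) {
    o <- objects[[i]]
    data.frame(id = i, kind = o$kind, true_count = o$true_count,
               area = nrow(o$footprint),
               min_row = min(o$footprint[, 1L]), min_col = min(o$footprint[, 2L]),
               max_row = max(o$footprint[, 1L]), max_col = max(o$footprint[, 2L]))
  }))
  if (is.null(obj_df))
    obj_df <- data.frame(id = integer(), kind = character(),
                         true_count = integer(), area = integer(),
                         min_row = integer(), min_col = integer(),
                         max_row = integer(), max_col = integer())
  truth <- list(objects = obj_df,
                total_eggs = sum(obj_df$true_count),
                true_single_egg_area =
                  if (length(single_areas)) stats::median(single_areas) else NA_real_,
                footprints = lapply(objects, `[[`, "footprint"))
  structure(list(image = img, truth = truth, spec = spec),
            class = "egg_scene")
}
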