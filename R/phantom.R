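# Synthetic B-mode-like phantom generator.
#
# Each phantom is a rotated superellipse (exponent 1.5-3, mimicking the
# bean-shaped longissimus cross-section) embedded in a tissue field:
# darker interior, bright partially-broken rim, optional bright streak
# artifacts, Gaussian boundary feathering, and multiplicative unit-mean
# Gamma speckle followed by a light blur - a desk-scale surrogate for fully
# developed ultrasound speckle. Ground-truth masks and pixel spacing are
# known exactly, so the whole measurement pipeline can be validated without
# animal data.

#' Phantom generation parameters
#'
#' @param size image side length in pixels.
#' @param spacing_mm `(row, col)` mm per pixel. The default (0.7 mm at
#'   size 128) gives a ~90 mm field of view that accommodates the whole
#'   default area range.
#' @param area_range_mm2 target muscle area range in mm^2 (default matches
#'   the 356-1490 mm^2 span of adult sheep eye-muscle cross-sections).
#' @param axis_ratio_range range of major/minor axis ratios.
#' @param rotation_range rotation range in radians.
#' @param exponent_range superellipse exponent range.
#' @param feather_sigma boundary feathering Gaussian sigma in pixels.
#' @param speckle_strength relative standard deviation of the multiplicative
#'   speckle (0 disables all stochastic texture).
#' @param rim_break_prob probability that the bright rim is partially broken.
#' @param artifact_range integer range for the number of bright streaks.
#' @param interior_intensity,background_intensity,rim_intensity gray levels.
#' @param rim_width_px rim half-width in pixels.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(size = 128L, spacing_mm = c(0.7, 0.7),
                           area_range_mm2 = c(356, 1490),
                           axis_ratio_range = c(1.2, 2.2),
                           rotation_range = c(-pi / 2, pi / 2),
                           exponent_range = c(1.5, 3),
                           feather_sigma = 1.0, speckle_strength = 0.35,
                           rim_break_prob = 0.4, artifact_range = c(0L, 3L),
                           interior_intensity = 0.25,
                           background_intensity = 0.5,
                           rim_intensity = 0.85, rim_width_px = 2L) {
  if (any(area_range_mm2 <= 0) || diff(area_range_mm2) < 0)
    err_validation("area range must be positive and ordered")
  if (feather_sigma < 0 || speckle_strength < 0)
    err_validation("feather sigma and speckle strength must be >= 0")
  structure(as.list(environment()), class = "phantom_params")
}

superellipse_shape_factor <- function(p) {
  gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)   # area = 4 a b * factor
}

rasterize_superellipse <- function(size, spacing, a, b, theta, p, cx, cy) {
  row_mm <- spacing[1]; col_mm <- spacing[2]
  v <- (seq_len(size) - cy) * row_mm
  u <- (seq_len(size) - cx) * col_mm
  U <- matrix(u, size, size, byrow = TRUE)
  V <- matrix(v, size, size)
  ur <- cos(theta) * U + sin(theta) * V
  vr <- -sin(theta) * U + cos(theta) * V
  (abs(ur / a)^p + abs(vr / b)^p <= 1) * 1L
}

gauss_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  x <- array(m, dim = c(nrow(m), ncol(m), 1L))
  kr <- array(k, dim = c(2L * r + 1L, 1L, 1L))
  kc <- array(k, dim = c(1L, 2L * r + 1L, 1L))
  pad <- function(a, pr, pc) {
    ri <- pmin(pmax(seq_len(nrow(a) + 2 * pr) - pr, 1L), nrow(a))
    ci <- pmin(pmax(seq_len(ncol(a) + 2 * pc) - pc, 1L), ncol(a))
    array(a[ri, ci, , drop = FALSE], dim = c(length(ri), length(ci), 1L))
  }
  x <- .cpp_dwconv_fwd(pad(x, r, 0L), kr, 1L, 0L, 1L)
  x <- .cpp_dwconv_fwd(pad(x, 0L, r), kc, 1L, 0L, 1L)
  matrix(x, nrow(m))
}

binary_dilate <- function(m, r) {
  k <- array(1, dim = c(2L * r + 1L, 2L * r + 1L, 1L))
  (matrix(.cpp_dwconv_fwd(array(m, dim = c(dim(m), 1L)), k, 1L, r, 1L), nrow(m)) > 0.5) * 1L
}

binary_erode <- function(m, r) {
  k <- array(1, dim = c(2L * r + 1L, 2L * r + 1L, 1L))
  n <- (2L * r + 1L)^2
  (matrix(.cpp_dwconv_fwd(array(m, dim = c(dim(m), 1L)), k, 1L, r, 1L), nrow(m)) > n - 0.5) * 1L
}

#' Generate one synthetic phantom
#'
#' @param params a [phantom_params()] list.
#' @param seed integer seed; the output is bit-identical for equal
#'   `(params, seed)`.
#' @param id frame/mask identifier.
#' @return list with `frame` ([ultrasound_frame()]), `mask`
#'   ([binary_mask()]) and `record` (an `area_record` with the ground-truth
#'   pixel count and mm^2 area).
#' @export
generate_phantom <- function(params, seed = 1L, id = sprintf("phantom_%04d", seed)) {
  p <- params
  withr::with_seed(seed, {
    size <- p$size
    px_area <- p$spacing_mm[1] * p$spacing_mm[2]
    target <- stats::runif(1, p$area_range_mm2[1], p$area_range_mm2[2])
    q <- stats::runif(1, p$axis_ratio_range[1], p$axis_ratio_range[2])
    theta <- stats::runif(1, p$rotation_range[1], p$rotation_range[2])
    pe <- stats::runif(1, p$exponent_range[1], p$exponent_range[2])
    sf <- superellipse_shape_factor(pe)
    ab <- target / (4 * sf)
    a <- sqrt(ab * q); b <- sqrt(ab / q)
    fov <- c(size * p$spacing_mm[1], size * p$spacing_mm[2])
    if (2 * max(a, b) > 0.85 * min(fov))
      err_validation("requested area does not fit the image field of view")
    cx <- size / 2 + stats::runif(1, -0.05, 0.05) * size
    cy <- size / 2 + stats::runif(1, -0.05, 0.05) * size
    mask <- rasterize_superellipse(size, p$spacing_mm, a, b, theta, pe, cx, cy)
    # nudge the axes until the rasterized area honours the configured range
    for (it in 1:8) {
      measured <- sum(mask) * px_area
      goal <- min(max(target, p$area_range_mm2[1]), p$area_range_mm2[2])
      if (measured >= p$area_range_mm2[1] && measured <= p$area_range_mm2[2] &&
          abs(measured - goal) / goal < 0.005) break
      s <- sqrt(goal / max(measured, px_area))
      a <- a * s; b <- b * s
      mask <- rasterize_superellipse(size, p$spacing_mm, a, b, theta, pe, cx, cy)
    }

    het <- 0.4 * p$speckle_strength
    img <- matrix(p$background_intensity, size, size)
    if (het > 0) {
      field <- gauss_blur_mat(matrix(stats::rnorm(size^2), size), size / 16)
      field <- field / max(abs(field), 1e-9)
      img <- img + het * field
    }
    img[mask == 1L] <- p$interior_intensity
    rim <- binary_dilate(mask, p$rim_width_px) - binary_erode(mask, p$rim_width_px)
    if (stats::runif(1) < p$rim_break_prob) {
      nb <- sample(1:3, 1)
      ang <- atan2(row(mask) - cy, col(mask) - cx)
      for (i in seq_len(nb)) {
        a0 <- stats::runif(1, -pi, pi); w <- stats::runif(1, pi / 9, pi / 3)
        d <- abs(((ang - a0 + pi) %% (2 * pi)) - pi)
        rim[d < w / 2] <- 0L
      }
    }
    img[rim == 1L] <- p$rim_intensity
    art_choices <- seq(p$artifact_range[1], p$artifact_range[2])
    n_art <- if (length(art_choices) == 1L) art_choices else sample(art_choices, 1)
    if (n_art > 0) {
      xs <- matrix(rep(seq_len(size), each = size), size)
      ys <- matrix(rep(seq_len(size), size), size)
      for (i in seq_len(n_art)) {
        x0 <- stats::runif(1, 1, size); slope <- stats::runif(1, -0.4, 0.4)
        wdt <- stats::runif(1, 1, 3); amp <- stats::runif(1, 0.15, 0.35)
        d <- abs(xs - x0 - slope * ys)
        img <- img + amp * exp(-(d / wdt)^2 / 2)
      }
    }
    img <- gauss_blur_mat(img, p$feather_sigma)
    if (p$speckle_strength > 0) {
      k <- 1 / p$speckle_strength^2
      mult <- matrix(stats::rgamma(size^2, shape = k, rate = k), size)
      img <- gauss_blur_mat(img * mult, 0.6)
    }
    img <- pmin(pmax(img, 0), 1)
    frame <- ultrasound_frame(img, p$spacing_mm, id = id)
    bm <- binary_mask(mask, id = id)
    rec <- area_record(id, sum(mask), sum(mask) * px_area)
    list(frame = frame, mask = bm, record = rec)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs plus a manifest CSV (and an
#' `areas.csv` with the ground-truth pixel counts and mm^2 areas);
#' per-item seeds are derived deterministically from the master seed.
#'
#' @param n number of phantoms (>= 1).
#' @param params a [phantom_params()] list.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return the manifest path, invisibly.
#' @export
generate_dataset <- function(n, params, out_dir, seed = 1L) {
  if (n < 1L) err_validation("n must be >= 1")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) err_io(paste("cannot create directory:", out_dir))
  item_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  rows <- vector("list", n); areas <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("phantom_%03d", i)
    ph <- generate_phantom(params, seed = item_seeds[i], id = id)
    ip <- file.path(out_dir, paste0(id, ".png"))
    mp <- file.path(out_dir, paste0(id, "_mask.png"))
    png::writePNG(ph$frame$pixels, ip)
    write_mask(ph$mask, mp)
    rows[[i]] <- data.frame(id = id, image_path = basename(ip),
                            mask_path = basename(mp),
                            row_mm_per_px = params$spacing_mm[1],
                            col_mm_per_px = params$spacing_mm[2])
    areas[[i]] <- data.frame(id = id, pixel_count = ph$record$pixel_count,
                             area_mm2 = ph$record$area_mm2)
  }
  man <- file.path(out_dir, "manifest.csv")
  write_manifest(do.call(rbind, rows), man)
  utils::write.csv(do.call(rbind, areas), file.path(out_dir, "areas.csv"),
                   row.names = FALSE)
  invisible(man)
}
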