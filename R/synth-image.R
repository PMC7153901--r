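#' Configure a synthetic gonad image stack
#'
#' Describes a tube-shaped gonad lying along a polyline axis: DAPI nuclei
#' placed one per cell diameter along the axis, a marker (antibody) channel
#' whose expected intensity at a pixel follows a per-cd profile evaluated at
#' the pixel's cell-diameter coordinate, and an smFISH channel of punctate
#' Gaussian foci at a configurable per-cd density. A z focus envelope
#' (normalized to 1 at the best slice) modulates the marker channel so that
#' slice selection in [linescan()] is exercised; noise is Poisson shot noise
#' plus Gaussian camera noise.
#'
#' @param n_cd Cell diameters covered by the tube (default 25).
#' @param nucleus_spacing Pixels per cell diameter (default 20).
#' @param tube_radius Tube radius in px; must exceed `nucleus_radius`.
#' @param nucleus_radius Nucleus blob radius in px.
#' @param z_slices Number of z slices (>= 2).
#' @param z_envelope Optional numeric of length `z_slices`: marker focus
#'   weight per slice; default is a Gaussian through-focus profile,
#'   normalized to max 1.
#' @param pixel_size Microns per pixel (metadata only).
#' @param marker A [profile_config()] giving the marker per-cd levels and
#'   staining background; `NULL` for a background-only channel.
#' @param curve_amp Amplitude (px) of a gentle sine bend of the tube axis;
#'   0 gives a straight tube.
#' @param foci_density Expected smFISH foci per cd: scalar or length-`n_cd`.
#' @param foci_amplitude,foci_sd Peak intensity and lateral Gaussian sd (px)
#'   of each rendered focus.
#' @param foci_z_range Optional `c(lo, hi)` slice range for focus centres
#'   ("surface-layer" imaging mode); default spans the interior slices.
#' @param dapi_amplitude Peak DAPI intensity of a nucleus.
#' @param camera_sd,camera_offset Gaussian read-noise sd and constant offset.
#' @param shot_noise Apply Poisson shot noise to the expected signal?
#'   `FALSE` (with `camera_sd = 0`) gives an exactly noise-free stack.
#' @param dims Optional `c(z, y, x)` image size; computed from the geometry
#'   when `NULL`. A tube that does not fit in `dims` is a configuration
#'   error.
#' @return An `image_config` list.
#' @export
image_config <- function(n_cd = 25L, nucleus_spacing = 20, tube_radius = 40,
                         nucleus_radius = 8, z_slices = 6L,
                         z_envelope = NULL, pixel_size = 0.1,
                         marker = NULL, curve_amp = 6,
                         foci_density = 0, foci_amplitude = 150,
                         foci_sd = 1.2, foci_z_range = NULL,
                         dapi_amplitude = 200, camera_sd = 2,
                         camera_offset = 0, shot_noise = TRUE, dims = NULL) {
  check_number(z_slices, "z_slices", min = 2)
  check_number(tube_radius, "tube_radius", min = nucleus_radius,
               allow_zero = FALSE)
  if (any(foci_density < 0)) stop_config("foci densities must be >= 0")
  if (length(foci_density) == 1L) foci_density <- rep(foci_density, n_cd)
  if (length(foci_density) != n_cd) {
    stop_config("foci_density must be scalar or length n_cd")
  }
  if (is.null(z_envelope)) {
    zc <- (z_slices + 1) / 2 + 0.35   # slightly off-centre: unique best slice
    z_envelope <- exp(-0.5 * ((seq_len(z_slices) - zc) / (z_slices / 4))^2)
  }
  z_envelope <- z_envelope / max(z_envelope)

  # tube axis: distal tip at the left, gentle sine bend of amplitude curve_amp
  margin <- tube_radius + 10
  len <- (n_cd + 1.5) * nucleus_spacing
  xs <- seq(0, len, by = 4)
  axis_pts <- cbind(y = margin + curve_amp + curve_amp * sin(xs / len * 2 * pi),
                    x = 12 + xs)
  ny <- ceiling(max(axis_pts[, 1]) + margin)
  nx <- ceiling(max(axis_pts[, 2]) + 14)
  if (is.null(dims)) dims <- c(z_slices, ny, nx)
  if (dims[1] < z_slices || dims[2] < ny || dims[3] < nx ||
      min(axis_pts[, 1]) - tube_radius < 1 || min(axis_pts[, 2]) < 1) {
    stop_config("tube leaves image bounds; enlarge dims or shrink geometry")
  }
  structure(
    list(n_cd = as.integer(n_cd), nucleus_spacing = nucleus_spacing,
         tube_radius = tube_radius, nucleus_radius = nucleus_radius,
         z_slices = as.integer(z_slices), z_envelope = z_envelope,
         pixel_size = pixel_size, marker = marker, axis = axis_pts,
         foci_density = foci_density, foci_amplitude = foci_amplitude,
         foci_sd = foci_sd, foci_z_range = foci_z_range,
         dapi_amplitude = dapi_amplitude, camera_sd = camera_sd,
         camera_offset = camera_offset, shot_noise = isTRUE(shot_noise),
         dims = as.integer(dims)),
    class = "image_config")
}

# nearest-axis arc length and perpendicular distance for every (y, x) pixel,
# computed in chunks to bound memory
pixel_axis_coords <- function(dims, axis_samples, chunk = 4000L) {
  dy <- dims[2]; dx <- dims[3]
  py <- rep(seq_len(dy), times = dx)
  px <- rep(seq_len(dx), each = dy)
  s <- d <- numeric(dy * dx)
  ay <- axis_samples$y; ax <- axis_samples$x; apos <- axis_samples$position
  for (start in seq(1, length(py), by = chunk)) {
    i <- start:min(start + chunk - 1L, length(py))
    d2 <- outer(py[i], ay, "-")^2 + outer(px[i], ax, "-")^2
    j <- max.col(-d2, ties.method = "first")
    s[i] <- apos[j]
    d[i] <- sqrt(d2[cbind(seq_along(i), j)])
  }
  list(s = s, d = d)   # in pixel-grid (column-major y-fastest) order
}

#' Generate a synthetic gonad image stack with recorded ground truth
#'
#' @param cfg An [image_config()].
#' @param seed Integer seed; output is bit-identical for a fixed
#'   `(config, seed)` pair.
#' @param genotype,tagged,replicate Metadata attached to the image.
#' @return A list with elements `image` (a `germline_image`: `channels`
#'   `dapi`/`marker`/`smfish`, each `[z, y, x]`, plus metadata) and `truth`
#'   (nucleus centroids, focus centroids with generating cd, the generating
#'   axis polyline, distal tip and cd marker arc positions).
#' @export
generate_gonad_image <- function(cfg, seed, genotype = "synthetic",
                                 tagged = TRUE, replicate = 1L) {
  stopifnot(inherits(cfg, "image_config"))
  set.seed(as.integer(seed))
  dims <- cfg$dims
  samp <- resample_polyline(cfg$axis, step = 2)
  coords <- pixel_axis_coords(dims, samp)
  sp <- cfg$nucleus_spacing
  cd_of_s <- pmin(floor(coords$s / sp) + 1L, cfg$n_cd)
  inside <- coords$d <= cfg$tube_radius

  # marker channel: per-cd profile inside the tube, staining background all over
  if (!is.null(cfg$marker)) {
    stopifnot(inherits(cfg$marker, "profile_config"))
    level <- cfg$marker$means[cd_of_s]
    bg <- cfg$marker$background_level
    sig <- if (cfg$marker$tagged) ifelse(inside, level, 0) else 0
    marker2d <- bg + sig
  } else {
    marker2d <- rep(0, dims[2] * dims[3])
  }

  # nuclei: one per cd row, centred within its cd interval along the axis
  n_nuc <- floor(max(samp$position) / sp)
  s_nuc <- (seq_len(n_nuc) - 0.5) * sp
  nuc_y <- approx(samp$position, samp$y, xout = s_nuc)$y
  nuc_x <- approx(samp$position, samp$x, xout = s_nuc)$y
  nuc_z <- rep(ceiling(dims[1] / 2), n_nuc)

  # smFISH foci: Poisson count per cd, uniform within the tube stripe
  zr <- cfg$foci_z_range %||% c(1.5, dims[1] - 0.5)
  counts <- rpois(cfg$n_cd, cfg$foci_density)
  foci <- NULL
  if (sum(counts) > 0) {
    cd_idx <- rep(seq_len(cfg$n_cd), counts)
    fs <- (cd_idx - 1) * sp + runif(sum(counts)) * sp
    off <- runif(sum(counts), -1, 1) * min(cfg$tube_radius - 2, 30)
    base_y <- approx(samp$position, samp$y, xout = fs)$y
    base_x <- approx(samp$position, samp$x, xout = fs)$y
    nrm_y <- approx(samp$position, samp$ny, xout = fs)$y
    nrm_x <- approx(samp$position, samp$nx, xout = fs)$y
    foci <- tibble::tibble(
      z = runif(sum(counts), zr[1], zr[2]),
      y = base_y + off * nrm_y,
      x = base_x + off * nrm_x,
      s = fs, cd = cd_idx)
  }

  blank <- function() array(0, dim = dims)
  marker <- blank(); dapi <- blank(); smfish <- blank()
  for (z in seq_len(dims[1])) {
    marker[z, , ] <- matrix(marker2d, dims[2], dims[3]) * cfg$z_envelope[z]
  }
  add_blob <- function(arr, z0, y0, x0, amp, sd_xy, sd_z, cut = 3) {
    zi <- max(1, floor(z0 - 2 * sd_z)):min(dims[1], ceiling(z0 + 2 * sd_z))
    yi <- max(1, floor(y0 - cut * sd_xy)):min(dims[2], ceiling(y0 + cut * sd_xy))
    xi <- max(1, floor(x0 - cut * sd_xy)):min(dims[3], ceiling(x0 + cut * sd_xy))
    g <- amp * exp(-0.5 * (
      outer(outer((zi - z0)^2 / sd_z^2, (yi - y0)^2 / sd_xy^2, "+"),
            (xi - x0)^2 / sd_xy^2, "+")))
    arr[zi, yi, xi] <- arr[zi, yi, xi] + g
    arr
  }
  for (i in seq_len(n_nuc)) {
    dapi <- add_blob(dapi, nuc_z[i], nuc_y[i], nuc_x[i],
                     cfg$dapi_amplitude, cfg$nucleus_radius / 2, 1.0, cut = 2.5)
  }
  if (!is.null(foci)) {
    for (i in seq_len(nrow(foci))) {
      smfish <- add_blob(smfish, foci$z[i], foci$y[i], foci$x[i],
                         cfg$foci_amplitude, cfg$foci_sd, 0.8)
    }
  }
  noisy <- function(arr) {
    shot <- if (cfg$shot_noise) {
      array(rpois(length(arr), lambda = arr), dim = dims)
    } else arr
    out <- shot + cfg$camera_offset
    if (cfg$camera_sd > 0) {
      out <- out + array(rnorm(length(arr), sd = cfg$camera_sd), dim = dims)
    }
    pmax(out, 0)
  }
  image <- structure(
    list(channels = list(dapi = noisy(dapi), marker = noisy(marker),
                         smfish = noisy(smfish)),
         pixel_size = cfg$pixel_size, genotype = genotype, tagged = tagged,
         replicate = as.integer(replicate), n_cd = cfg$n_cd,
         nucleus_spacing = sp),
    class = "germline_image")
  truth <- list(
    axis = cfg$axis, tip = cfg$axis[1, ],
    cd_markers = (0:cfg$n_cd) * sp,
    nuclei = tibble::tibble(z = nuc_z, y = nuc_y, x = nuc_x, s = s_nuc),
    foci = foci %||% tibble::tibble(z = numeric(), y = numeric(),
                                    x = numeric(), s = numeric(),
                                    cd = integer()),
    config = cfg)
  list(image = image, truth = truth)
}

#' Write / read a gonad image as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z of `dapi`, then `marker`, then
#' `smfish`); the sidecar records dimensions, channel order, the intensity
#' scale used for float storage, and the image metadata.
#'
#' @param image A `germline_image`.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path` (write) or a `germline_image` (read).
#' @export
write_gonad_image <- function(image, path) {
  stopifnot(inherits(image, "germline_image"))
  chans <- names(image$channels)
  scale <- max(1, vapply(image$channels, max, numeric(1)))
  pages <- list()
  for (ch in chans) {
    arr <- image$channels[[ch]] / scale
    for (z in seq_len(dim(arr)[1])) pages <- c(pages, list(arr[z, , ]))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(dims = dim(image$channels[[1]]), channels = chans,
               scale = scale, pixel_size = image$pixel_size,
               genotype = image$genotype, tagged = image$tagged,
               replicate = image$replicate, n_cd = image$n_cd,
               nucleus_spacing = image$nucleus_spacing)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gonad_image
#' @export
read_gonad_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- meta$dims
  channels <- list()
  i <- 1L
  for (ch in meta$channels) {
    arr <- array(0, dim = dims)
    for (z in seq_len(dims[1])) {
      arr[z, , ] <- pages[[i]] * meta$scale
      i <- i + 1L
    }
    channels[[ch]] <- arr
  }
  structure(
    list(channels = channels, pixel_size = meta$pixel_size,
         genotype = meta$genotype, tagged = meta$tagged,
         replicate = meta$replicate, n_cd = meta$n_cd,
         nucleus_spacing = meta$nucleus_spacing),
    class = "germline_image")
}
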