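#' Extract a wide-band intensity linescan along an axis
#'
#' Walks the axis in 1-px arc-length steps; at each step collects the pixels
#' lying on the perpendicular band of width `width_px` centred on the axis.
#' Each pixel's intensity is the maximum over the selected z-slices (the
#' through-focus rule for gonads that drift out of focus along their length),
#' and the position's value is the mean over the band. Pixels falling outside
#' the image are excluded with a warning.
#'
#' @param image A `germline_image` (see [generate_gonad_image()]) or a bare
#'   3D array `[z, y, x]`.
#' @param channel Channel name (ignored when `image` is a bare array).
#' @param axis An `axis_trace`.
#' @param width_px Band width in pixels (default 75).
#' @param slices `"brightest2"` (default: the two slices with the highest
#'   band-mean intensity) or an integer vector of at least two slice indices.
#' @return A tibble with columns `position` (arc length, px) and `value`,
#'   with attributes `width_px`, `slices_used` and any genotype metadata
#'   carried by the image.
#' @export
linescan <- function(image, channel = "marker", axis, width_px = 75,
                     slices = "brightest2") {
  stopifnot(inherits(axis, "axis_trace"))
  stack <- if (is.array(image) && length(dim(image)) == 3L) image
           else get_channel(image, channel)
  dz <- dim(stack)[1]; dy <- dim(stack)[2]; dx <- dim(stack)[3]
  samp <- resample_polyline(axis$polyline, step = 1)
  w <- as.integer(width_px)
  u <- seq_len(w) - (w + 1) / 2
  Y <- round(outer(samp$y, rep(1, w)) + outer(samp$ny, u))
  X <- round(outer(samp$x, rep(1, w)) + outer(samp$nx, u))
  inb <- Y >= 1 & Y <= dy & X >= 1 & X <= dx
  if (!all(inb)) {
    warn(sprintf("linescan band exits the image: %d of %d pixels excluded",
                 sum(!inb), length(inb)))
  }
  idx <- (pmin(pmax(X, 1), dx) - 1L) * dy + pmin(pmax(Y, 1), dy)

  slice_vals <- function(z) {
    m <- matrix(stack[z, , ][idx], nrow = nrow(idx))
    m[!inb] <- NA_real_
    m
  }
  if (identical(slices, "brightest2")) {
    band_means <- vapply(seq_len(dz), function(z) {
      mean(slice_vals(z), na.rm = TRUE)
    }, numeric(1))
    slices <- order(-band_means)[1:2]
  }
  slices <- as.integer(slices)
  if (length(slices) < 2L) abort("at least two z-slices must be selected")
  if (any(slices < 1L | slices > dz)) abort("slice index out of range")

  vals <- slice_vals(slices[1])
  for (z in slices[-1]) vals <- pmax(vals, slice_vals(z), na.rm = TRUE)
  out <- tibble::tibble(position = samp$position,
                        value = rowMeans(vals, na.rm = TRUE))
  attr(out, "width_px") <- w
  attr(out, "slices_used") <- sort(slices)
  if (!is.array(image)) {
    attr(out, "genotype") <- image$genotype
    attr(out, "tagged") <- image$tagged
    attr(out, "replicate") <- image$replicate %||% 1L
  }
  out
}

#' Average a linescan into per-cell-diameter intensity values
#'
#' Each cd interval `[m_{k-1}, m_k)` of the axis receives the mean of the
#' scan values whose arc-length position falls inside it, yielding a raw
#' intensity profile in cd coordinates.
#'
#' @param scan Result of [linescan()].
#' @param axis The `axis_trace` the scan was collected along.
#' @param genotype,tagged,replicate Profile metadata; default to what the
#'   scan carries from its source image.
#' @return A raw profile tibble (`genotype`, `tagged`, `replicate`, `cd`,
#'   `value`, `state = "raw"`).
#' @export
profile_by_cd <- function(scan, axis, genotype = NULL, tagged = NULL,
                          replicate = NULL) {
  stopifnot(inherits(axis, "axis_trace"))
  m <- axis$cd_markers
  cd <- findInterval(scan$position, m)
  keep <- cd >= 1L & scan$position < m[length(m)]
  cd <- cd[keep]
  vals <- scan$value[keep]
  if (!setequal(unique(cd), seq_len(axis$n_cd))) {
    abort("empty cd interval: axis markers do not match the scan geometry",
          class = "gonadscan_axis_error")
  }
  means <- vapply(split(vals, cd), mean, numeric(1))
  tibble::tibble(
    genotype = genotype %||% attr(scan, "genotype") %||% "unknown",
    tagged = tagged %||% attr(scan, "tagged") %||% TRUE,
    replicate = as.integer(replicate %||% attr(scan, "replicate") %||% 1L),
    cd = as.integer(names(means)),
    value = unname(means),
    state = "raw")
}
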