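# Cell-diameter coordinate system along the gonad axis.
#
# An axis trace is a polyline in pixel coordinates (columns y, x) starting at
# the distal tip, plus cd_markers: arc-length positions delimiting successive
# cell-diameter intervals. Marker k sits at the midpoint between nucleus k
# and nucleus k+1, with the first marker at the tip (arc length 0), so cd k
# is the interval [m_{k-1}, m_k) containing nucleus k.

new_axis_trace <- function(polyline, cd_markers) {
  polyline <- as.matrix(polyline)
  colnames(polyline) <- c("y", "x")
  if (cd_markers[1] != 0) abort("first cd marker must be at arc length 0")
  if (is.unsorted(cd_markers, strictly = TRUE)) {
    abort("cd marker positions must be strictly increasing")
  }
  structure(list(polyline = polyline, cd_markers = as.numeric(cd_markers),
                 n_cd = length(cd_markers) - 1L),
            class = "axis_trace")
}

# cumulative arc length of polyline vertices
polyline_arc <- function(poly) {
  seg <- sqrt(rowSums(diff(poly)^2))
  c(0, cumsum(seg))
}

# resample a polyline at fixed arc-length steps; returns a tibble with
# position (arc length), point coordinates and unit normals
resample_polyline <- function(poly, step = 1) {
  poly <- as.matrix(poly)
  arc <- polyline_arc(poly)
  pos <- seq(0, arc[length(arc)], by = step)
  y <- approx(arc, poly[, 1], xout = pos)$y
  x <- approx(arc, poly[, 2], xout = pos)$y
  # tangents by central differences (one-sided at the ends)
  n <- length(pos)
  i0 <- pmax(seq_len(n) - 1L, 1L); i1 <- pmin(seq_len(n) + 1L, n)
  ty <- y[i1] - y[i0]; tx <- x[i1] - x[i0]
  len <- sqrt(ty^2 + tx^2)
  tibble::tibble(position = pos, y = y, x = x,
                 ny = -tx / len, nx = ty / len)
}

#' Build a cell-diameter axis from DAPI nucleus centroids
#'
#' Chains nucleus centroids by greedy nearest-neighbour walking from the
#' distal tip, then places cd markers at the arc-length midpoints between
#' successive nuclei (the first marker at the tip itself). One cell diameter
#' is the axis interval owned by one nucleus row.
#'
#' @param nuclei Data frame of nucleus centroids with columns `y`, `x`
#'   (pixels; a `z` column is ignored), e.g. from [detect_nuclei()].
#' @param distal_tip Length-2 numeric `(y, x)`: the distal end of the gonad.
#' @param n_cd Number of cell diameters to mark; requires at least
#'   `n_cd + 1` chainable nuclei.
#' @return An `axis_trace`: polyline through the tip and chained centroids,
#'   `cd_markers` (length `n_cd + 1`, starting at 0) and `n_cd`.
#' @export
trace_axis <- function(nuclei, distal_tip, n_cd) {
  stopifnot(is.data.frame(nuclei), all(c("y", "x") %in% names(nuclei)))
  n_cd <- as.integer(n_cd)
  pts <- cbind(nuclei$y, nuclei$x)
  need <- n_cd + 1L
  if (nrow(pts) < need) {
    abort(sprintf("insufficient axis length: need %d chainable nuclei, have %d",
                  need, nrow(pts)), class = "gonadscan_axis_error")
  }
  current <- as.numeric(distal_tip)
  remaining <- seq_len(nrow(pts))
  chain <- integer(need)
  for (k in seq_len(need)) {
    d2 <- (pts[remaining, 1] - current[1])^2 + (pts[remaining, 2] - current[2])^2
    pick <- remaining[which.min(d2)]
    chain[k] <- pick
    remaining <- setdiff(remaining, pick)
    current <- pts[pick, ]
  }
  poly <- rbind(distal_tip, pts[chain, , drop = FALSE])
  arc <- polyline_arc(poly)
  s_nuc <- arc[-1]                      # arc positions of chained nuclei
  markers <- c(0, (s_nuc[seq_len(n_cd)] + s_nuc[seq_len(n_cd) + 1L]) / 2)
  new_axis_trace(poly, markers)
}

#' Use a hand-drawn polyline and markers as an axis verbatim
#'
#' Mirrors the manual Fiji workflow: a user-supplied line (starting at the
#' distal tip) and cd marker positions are taken as-is.
#'
#' @param polyline Matrix/data frame of `(y, x)` vertices, distal tip first.
#' @param cd_markers Strictly increasing arc-length positions (px), first 0.
#' @return An `axis_trace`.
#' @export
manual_axis <- function(polyline, cd_markers) {
  axis <- new_axis_trace(as.matrix(polyline), cd_markers)
  total <- polyline_arc(axis$polyline)
  if (max(cd_markers) > total[length(total)] + 1e-8) {
    abort("cd markers extend beyond the polyline")
  }
  axis
}

#' Export / import an axis as CSV (Fiji-compatible exchange)
#'
#' The CSV has columns `kind` (`"vertex"` or `"marker"`), `y`, `x` (vertices)
#' and `position` (marker arc lengths), so lines drawn in Fiji can be used.
#'
#' @param axis An `axis_trace`.
#' @param path CSV path.
#' @return `path` (write) or an `axis_trace` (read).
#' @export
write_axis <- function(axis, path) {
  stopifnot(inherits(axis, "axis_trace"))
  tb <- dplyr::bind_rows(
    tibble::tibble(kind = "vertex", y = axis$polyline[, 1],
                   x = axis$polyline[, 2], position = NA_real_),
    tibble::tibble(kind = "marker", y = NA_real_, x = NA_real_,
                   position = axis$cd_markers))
  readr::write_csv(tb, path)
  invisible(path)
}

#' @rdname write_axis
#' @export
read_axis <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  v <- tb[tb$kind == "vertex", ]
  m <- tb[tb$kind == "marker", ]
  manual_axis(cbind(v$y, v$x), m$position)
}
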