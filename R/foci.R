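# 3D smFISH focus detection and per-cell-diameter assignment.

# 26-connectivity neighbour offsets restricted to a half-space so each
# unordered voxel pair is generated once
half_neighbourhood <- function(connectivity = 26L) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  } else if (connectivity != 26L) {
    stop_config("connectivity must be 6 or 26")
  }
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  offs[keep, ]
}

#' Detect smFISH foci as 3D connected components above a threshold
#'
#' Foci are connected components (26-connectivity by default) of voxels with
#' intensity strictly above `threshold`, keeping components of at least
#' `min_voxels` voxels; each focus centroid is the intensity-weighted mean
#' voxel position. A threshold above the stack maximum yields an empty focus
#' table, not an error.
#'
#' @param stack 3D numeric array `[z, y, x]` (an smFISH channel).
#' @param threshold Intensity threshold; `NULL` selects one automatically by
#'   Otsu's method (requires the EBImage package). Automatic selection is a
#'   convenience: published workflows chose thresholds manually to include
#'   most foci.
#' @param min_voxels Minimum component size (default 2, suppressing
#'   single-voxel shot noise).
#' @param connectivity 26 (default) or 6.
#' @return A `foci_tbl` tibble: `focus_id`, `z`, `y`, `x` (centroid),
#'   `voxel_count`, `peak_intensity`; attributes `threshold_used`,
#'   `min_voxels`, `connectivity`.
#' @export
detect_foci <- function(stack, threshold = NULL, min_voxels = 2L,
                        connectivity = 26L) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (is.null(threshold)) threshold <- otsu_threshold(stack)
  dims <- dim(stack)
  idx <- which(stack > threshold)
  empty <- tibble::tibble(focus_id = integer(), z = numeric(), y = numeric(),
                          x = numeric(), voxel_count = integer(),
                          peak_intensity = numeric())
  out <- if (length(idx) == 0L) {
    empty
  } else {
    co <- arrayInd(idx, dims)
    # map every above-threshold voxel's linear index to its rank
    rank_of <- integer(0)
    rank_of[idx] <- seq_along(idx)
    offs <- half_neighbourhood(connectivity)
    edges <- list()
    for (k in seq_len(nrow(offs))) {
      nz <- co[, 1] + offs$dz[k]; nyy <- co[, 2] + offs$dy[k]
      nxx <- co[, 3] + offs$dx[k]
      ok <- nz >= 1 & nz <= dims[1] & nyy >= 1 & nyy <= dims[2] &
        nxx >= 1 & nxx <= dims[3]
      nidx <- (nxx[ok] - 1) * dims[1] * dims[2] + (nyy[ok] - 1) * dims[1] + nz[ok]
      nb <- rank_of[nidx]
      hit <- !is.na(nb) & nb > 0
      if (any(hit)) {
        edges[[length(edges) + 1L]] <-
          cbind(which(ok)[hit], nb[hit])
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges) > 0L) {
      g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    }
    comp <- igraph::components(g)$membership
    w <- stack[idx]
    agg <- tibble::tibble(comp = comp, z = co[, 1], y = co[, 2], x = co[, 3],
                          w = w) |>
      dplyr::group_by(.data$comp) |>
      dplyr::summarise(
        z = sum(.data$z * .data$w) / sum(.data$w),
        y = sum(.data$y * .data$w) / sum(.data$w),
        x = sum(.data$x * .data$w) / sum(.data$w),
        voxel_count = dplyr::n(),
        peak_intensity = max(.data$w), .groups = "drop") |>
      dplyr::filter(.data$voxel_count >= min_voxels) |>
      dplyr::arrange(.data$z, .data$y, .data$x)
    if (nrow(agg) == 0L) empty else
      dplyr::mutate(dplyr::select(agg, -"comp"),
                    focus_id = dplyr::row_number(), .before = 1)
  }
  attr(out, "threshold_used") <- threshold
  attr(out, "min_voxels") <- as.integer(min_voxels)
  attr(out, "connectivity") <- as.integer(connectivity)
  class(out) <- c("foci_tbl", class(out))
  out
}

# Otsu threshold on a 256-bin histogram via EBImage
otsu_threshold <- function(stack) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("automatic thresholding needs the EBImage package; pass `threshold`")
  }
  rng <- range(stack)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (stack - rng[1]) / diff(rng)
  EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * diff(rng) + rng[1]
}

#' Convenience: nucleus centroids from a DAPI channel
#'
#' Thresholds the DAPI stack at half its maximum (or a given threshold) and
#' returns blob centroids, ready for [trace_axis()].
#'
#' @param dapi_stack 3D array `[z, y, x]`.
#' @param threshold Intensity threshold; default `max(stack) / 2`.
#' @param min_voxels Minimum blob size.
#' @return Tibble of centroids (`z`, `y`, `x`).
#' @export
detect_nuclei <- function(dapi_stack, threshold = NULL, min_voxels = 10L) {
  threshold <- threshold %||% (max(dapi_stack) / 2)
  detect_foci(dapi_stack, threshold, min_voxels = min_voxels)[c("z", "y", "x")]
}

#' Assign detected foci to cell-diameter bins along an axis
#'
#' Each focus is projected (in the `y`/`x` plane) onto its nearest axis
#' point. Foci whose perpendicular distance is at most `band_px / 2` are
#' counted in the cd interval containing that arc-length position; foci
#' farther away, or projecting beyond the last marker, are excluded. A focus
#' landing exactly on a marker is counted toward the distal (lower) cd.
#'
#' @param foci A `foci_tbl` from [detect_foci()].
#' @param axis An `axis_trace`.
#' @param band_px Assignment band width in pixels (default 100,
#'   roughly 10 microns).
#' @return The `foci_tbl` with a `cd_bin` column (`NA` = excluded) and
#'   attributes `per_cd_counts` (tibble `cd`, `count` over `1..n_cd`) and
#'   `excluded_count`.
#' @export
assign_foci_to_cd <- function(foci, axis, band_px = 100) {
  stopifnot(inherits(axis, "axis_trace"))
  samp <- resample_polyline(axis$polyline, step = 1)
  m <- axis$cd_markers
  cd_bin <- rep(NA_integer_, nrow(foci))
  if (nrow(foci) > 0L) {
    d2 <- outer(foci$y, samp$y, "-")^2 + outer(foci$x, samp$x, "-")^2
    j <- max.col(-d2, ties.method = "first")
    perp <- sqrt(d2[cbind(seq_len(nrow(foci)), j)])
    s <- samp$position[j]
    cd <- findInterval(s, m)
    at_marker <- cd >= 2L & s == m[pmin(cd, length(m))]
    cd[at_marker] <- cd[at_marker] - 1L   # tie toward the distal cd
    ok <- perp <= band_px / 2 & cd >= 1L & cd <= axis$n_cd
    cd_bin[ok] <- cd[ok]
  }
  out <- dplyr::mutate(foci, cd_bin = cd_bin)
  counts <- tibble::tibble(cd = seq_len(axis$n_cd)) |>
    dplyr::left_join(
      dplyr::count(dplyr::filter(out, !is.na(.data$cd_bin)), .data$cd_bin),
      by = c(cd = "cd_bin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("cd", "count")
  attr(out, "per_cd_counts") <- counts
  attr(out, "excluded_count") <- sum(is.na(cd_bin))
  attr(out, "threshold_used") <- attr(foci, "threshold_used")
  class(out) <- unique(c("foci_tbl", class(out)))
  out
}

#' Spatial mRNA density summary across germlines
#'
#' Combines per-germline per-cd focus counts into a mean/SD density profile
#' and compares per-germline mean counts between two cd windows with
#' [compare_levels()] (default: distal 1-10 vs proximal 11-25, probing
#' whether the mRNA is uniformly distributed).
#'
#' @param foci_sets List of assigned `foci_tbl`s (one per germline), or a
#'   list of per-cd count tibbles (`cd`, `count`).
#' @param windows List of two non-overlapping integer cd vectors.
#' @return A `foci_density` list: `summary` (tibble `cd`, `mean`, `sd`,
#'   `n`), `comparison` (a `gonad_comparison`), `windows`.
#' @export
foci_density_summary <- function(foci_sets,
                                 windows = list(1:10, 11:25)) {
  stopifnot(length(foci_sets) >= 2L)
  if (length(intersect(windows[[1]], windows[[2]])) > 0L) {
    abort("comparison windows overlap")
  }
  counts <- purrr::imap(foci_sets, function(fs, i) {
    tb <- if (is.data.frame(fs) && all(c("cd", "count") %in% names(fs))) fs
          else attr(fs, "per_cd_counts")
    dplyr::mutate(tb, germline = i)
  }) |> dplyr::bind_rows()
  summary <- counts |>
    dplyr::group_by(.data$cd) |>
    dplyr::summarise(mean = mean(.data$count),
                     sd = ifelse(dplyr::n() > 1, sd(.data$count), 0),
                     n = dplyr::n(), .groups = "drop")
  per_germline <- function(win) {
    counts |>
      dplyr::filter(.data$cd %in% win) |>
      dplyr::group_by(.data$germline) |>
      dplyr::summarise(m = mean(.data$count), .groups = "drop") |>
      dplyr::pull("m")
  }
  comparison <- compare_levels(per_germline(windows[[1]]),
                               per_germline(windows[[2]]))
  structure(list(summary = summary, comparison = comparison,
                 windows = windows),
            class = "foci_density")
}

#' Write an assigned foci table to CSV
#'
#' Columns `z`, `y`, `x`, `voxels`, `cd_bin` (empty = excluded).
#'
#' @param foci Assigned `foci_tbl`.
#' @param path CSV path.
#' @export
write_foci <- function(foci, path) {
  readr::write_csv(
    dplyr::select(tibble::as_tibble(foci), "z", "y", "x",
                  voxels = "voxel_count", "cd_bin"),
    path)
  invisible(path)
}
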