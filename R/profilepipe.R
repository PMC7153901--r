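#' Subtract untagged staining background from raw profiles
#'
#' Antibody staining of strains lacking the epitope tag measures non-specific
#' signal; its per-cd mean is subtracted from every raw profile. Negative
#' corrected values are clipped to 0 but the unclipped values are retained in
#' `value_unclipped` for audit.
#'
#' @param profiles Raw profile tibble.
#' @param untagged Raw profiles of the untagged strain(s); same `max_cd`.
#' @return Profile tibble in state `"corrected"`.
#' @export
subtract_background <- function(profiles, untagged) {
  check_profiles(profiles, "raw")
  check_profiles(untagged, "raw", arg = "untagged")
  if (nrow(untagged) == 0L) abort("untagged set is empty")
  if (!identical(sort(unique(profiles$cd)), sort(unique(untagged$cd)))) {
    abort("profiles and untagged set cover different cd ranges")
  }
  bg <- untagged |>
    dplyr::group_by(.data$cd) |>
    dplyr::summarise(bg = mean(.data$value), .groups = "drop")
  profiles |>
    dplyr::inner_join(bg, by = "cd") |>
    dplyr::mutate(value_unclipped = .data$value - .data$bg,
                  value = pmax(.data$value_unclipped, 0),
                  state = "corrected") |>
    dplyr::select(-"bg")
}

#' Normalize a co-processed batch to the internal wild-type control
#'
#' The tagged strain in an otherwise wild-type background serves as internal
#' control: one scale factor, `100 / mean(control over the peak window)`, is
#' applied uniformly to every profile of the batch, anchoring the control's
#' mean peak intensity at 100.
#'
#' @param profiles Corrected profile tibble (the whole co-stained batch,
#'   usually including the control genotype itself).
#' @param control Corrected profiles of the control genotype.
#' @param peak_window Integer cd positions of the peak window (e.g. `4`, or
#'   `8:13`).
#' @return Profile tibble in state `"normalized"` (units: % of control
#'   peak), with the scale factor as attribute `"scale_factor"`.
#' @export
normalize_to_control <- function(profiles, control, peak_window) {
  check_profiles(profiles, "corrected")
  check_profiles(control, "corrected", arg = "control")
  ctrl_peak <- mean(control$value[control$cd %in% peak_window])
  if (!is.finite(ctrl_peak) || ctrl_peak <= 0) {
    abort("control mean over the peak window must be positive")
  }
  factor <- 100 / ctrl_peak
  out <- dplyr::mutate(profiles, value = .data$value * factor,
                       state = "normalized")
  attr(out, "scale_factor") <- factor
  out
}

#' Per-cd mean, SD and n of a set of profiles
#'
#' @param profiles Profile tibble in a uniform state.
#' @return A `profile_summary` tibble: `genotype`, `cd`, `mean`, `sd`
#'   (sample SD, n-1 denominator; reported as 0 when n = 1), `n`, `state`.
#' @export
summarize_profiles <- function(profiles) {
  check_profiles(profiles)
  out <- profiles |>
    dplyr::group_by(.data$genotype, .data$cd) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1L, sd(.data$value), 0),
      n = dplyr::n(),
      state = .data$state[1],
      .groups = "drop")
  class(out) <- c("profile_summary", class(out))
  out
}

#' Peak and base statistics of a summarized profile
#'
#' The peak is the mean of the per-cd means over the peak window
#' (`peak_stat = "mean"`, the single-cd anchor used for LAG-1-like profiles)
#' or the maximum per-cd mean within the window (`peak_stat = "max"`, used
#' for the broad 8-13 cd FBF-2 peak). The base is the mean at `base_cd`, and
#' `fold_ratio = peak / base` (infinite, flagged, when the base is 0).
#'
#' @param summary A `profile_summary` for a single genotype.
#' @param peak_window Integer cd vector.
#' @param base_cd Single cd of the proximal base (25 or 35).
#' @param peak_stat `"mean"` or `"max"`.
#' @return One-row tibble: `genotype`, `peak_mean`, `base_mean`,
#'   `fold_ratio`, `infinite_ratio`.
#' @export
peak_base <- function(summary, peak_window, base_cd, peak_stat = c("mean", "max")) {
  peak_stat <- match.arg(peak_stat)
  stopifnot(is.data.frame(summary), all(c("genotype", "cd", "mean") %in% names(summary)))
  if (dplyr::n_distinct(summary$genotype) != 1L) {
    abort("peak_base expects a single-genotype summary; filter first")
  }
  if (!all(peak_window %in% summary$cd) || !base_cd %in% summary$cd) {
    abort("peak window or base cd outside the summarized cd range")
  }
  win <- summary$mean[summary$cd %in% peak_window]
  peak <- if (peak_stat == "mean") mean(win) else max(win)
  base <- summary$mean[summary$cd == base_cd]
  tibble::tibble(
    genotype = summary$genotype[1],
    peak_mean = peak, base_mean = base,
    fold_ratio = if (base == 0) Inf else peak / base,
    infinite_ratio = base == 0)
}

#' Map a p-value to the significance tier used in figure legends
#'
#' `p <= 0.0001` is `"***"`, `p <= 0.001` is `"**"`, `p <= 0.01` is `"*"`,
#' larger p is `"NS"`.
#'
#' @param p P-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    p <= 0.0001 ~ "***",
    p <= 0.001 ~ "**",
    p <= 0.01 ~ "*",
    TRUE ~ "NS")
}

#' Compare two samples of per-germline levels
#'
#' Uses a two-tailed Welch t-test when the smaller sample has n < 30, and a
#' two-sample Z-test with per-sample SDs when both have n >= 30 (the
#' large-sample rule used for germline quantitation). When both samples have
#' zero variance and equal means the comparison is reported as p = 1, NS.
#'
#' @param values_a,values_b Numeric samples (n >= 2 each).
#' @return A one-row `gonad_comparison` tibble: `statistic`, `p_value`,
#'   `test_used` (`"t"` or `"Z"`), `n_a`, `n_b`, `tier`.
#' @export
compare_levels <- function(values_a, values_b) {
  n_a <- length(values_a); n_b <- length(values_b)
  stopifnot(n_a >= 2L, n_b >= 2L)
  use_t <- min(n_a, n_b) < 30
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    equal <- mean(values_a) == mean(values_b)
    stat <- if (equal) 0 else Inf
    p <- if (equal) 1 else 0
  } else if (use_t) {
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    stat <- (mean(values_a) - mean(values_b)) / sqrt(va / n_a + vb / n_b)
    p <- 2 * pnorm(-abs(stat))
  }
  out <- tibble::tibble(statistic = stat, p_value = p,
                        test_used = if (use_t) "t" else "Z",
                        n_a = n_a, n_b = n_b,
                        tier = significance_tier(p))
  class(out) <- c("gonad_comparison", class(out))
  out
}

#' @export
tidy.gonad_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = ifelse(x$test_used == "t",
                                 "Welch two-sample t-test",
                                 "two-sample Z-test"),
                 tier = x$tier)
}

#' @export
glance.gonad_comparison <- function(x, ...) {
  tibble::tibble(p.value = x$p_value, n_a = x$n_a, n_b = x$n_b,
                 significant = x$tier != "NS")
}

#' Run the full profile pipeline on a figure panel
#'
#' Generates (or accepts) raw replicate profiles for every genotype of a
#' panel, subtracts the untagged background, normalizes the batch to the
#' internal control's peak window, and summarizes per genotype.
#'
#' @param panel A `gonad_panel` from [load_panel()].
#' @param seed Seed for profile generation (ignored when `profiles` given).
#' @param profiles Optional raw profile tibble to process instead of
#'   generating from the panel configs.
#' @return A list: `summary` (normalized `profile_summary` for all tagged
#'   genotypes), `profiles` (normalized replicate profiles), `panel`.
#' @export
run_panel <- function(panel, seed = 1L, profiles = NULL) {
  stopifnot(inherits(panel, "gonad_panel"))
  raw <- profiles %||% generate_panel_profiles(panel, seed)
  parts <- split_panel_profiles(raw, panel)
  corrected <- subtract_background(parts$tagged, parts$untagged)
  control <- dplyr::filter(corrected, .data$genotype == parts$control_label)
  normalized <- normalize_to_control(corrected, control, panel$peak_window)
  list(summary = summarize_profiles(normalized),
       profiles = normalized, panel = panel)
}
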