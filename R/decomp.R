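#' Genetic percent-contribution decomposition of a peak protein level
#'
#' Splits a reference peak level (typically the meiotic-entry-defective
#' background with signaling intact) into three additive percentages using
#' two loss-of-function peaks from the same normalized batch:
#' \describe{
#'   \item{independent}{`100 * pathway_null / ref` - the fraction that
#'     remains with the signaling pathway removed.}
#'   \item{via_targets}{`100 * (ref - targets_null) / ref` - the fraction
#'     lost when only the pathway's transcriptional targets are removed.}
#'   \item{other_dependent}{the remainder - pathway-dependent accumulation
#'     not explained by the targets.}
#' }
#' The three raw percentages sum to exactly 100. Values outside `[0, 100]`
#' (e.g. when the targets null falls below the pathway null) are clipped and
#' flagged rather than silently adjusted.
#'
#' @param ref_peak Reference peak level (> 0).
#' @param pathway_null_peak Peak with signaling removed (>= 0).
#' @param targets_null_peak Peak with only the targets removed (>= 0).
#' @return One-row `gonad_decomp` tibble: `independent_pct`,
#'   `via_targets_pct`, `other_dependent_pct`, `dependent_pct`
#'   (= 100 - independent), `clipped`; unclipped values as attribute
#'   `"raw_pct"`.
#' @export
#' @examples
#' decompose_peak(125, 48.75, 87.5)  # 39% independent, 61% pathway-dependent
decompose_peak <- function(ref_peak, pathway_null_peak, targets_null_peak) {
  check_number(ref_peak, "ref_peak", min = 0, allow_zero = FALSE)
  check_number(pathway_null_peak, "pathway_null_peak", min = 0)
  check_number(targets_null_peak, "targets_null_peak", min = 0)
  independent <- 100 * pathway_null_peak / ref_peak
  via_targets <- 100 * (ref_peak - targets_null_peak) / ref_peak
  other <- 100 - independent - via_targets
  raw <- c(independent = independent, via_targets = via_targets,
           other_dependent = other)
  clipped <- any(raw < 0 | raw > 100)
  cl <- pmin(pmax(raw, 0), 100)
  out <- tibble::tibble(
    independent_pct = cl[["independent"]],
    via_targets_pct = cl[["via_targets"]],
    other_dependent_pct = cl[["other_dependent"]],
    dependent_pct = 100 - cl[["independent"]],
    clipped = clipped)
  attr(out, "raw_pct") <- raw
  class(out) <- c("gonad_decomp", class(out))
  out
}

#' @export
tidy.gonad_decomp <- function(x, ...) {
  tibble::tibble(
    component = c("independent", "via_targets", "other_dependent"),
    percent = c(x$independent_pct, x$via_targets_pct, x$other_dependent_pct),
    percent_rounded = round(percent))
}

#' @export
glance.gonad_decomp <- function(x, ...) {
  tibble::tibble(dependent_pct = x$dependent_pct, clipped = x$clipped)
}

#' Fold change between two genotype summaries at one cd position
#'
#' @param summary_a,summary_b `profile_summary` tibbles (single genotype
#'   each, same processing state).
#' @param cd The cd position at which to take the ratio of means.
#' @return One-row tibble: `cd`, `mean_a`, `mean_b`, `fold`,
#'   `infinite_ratio`.
#' @export
fold_at <- function(summary_a, summary_b, cd) {
  for (s in list(summary_a, summary_b)) {
    stopifnot(is.data.frame(s), all(c("cd", "mean", "state") %in% names(s)))
  }
  if (!identical(summary_a$state[1], summary_b$state[1])) {
    abort("summaries must be in the same processing state")
  }
  ma <- summary_a$mean[summary_a$cd == cd]
  mb <- summary_b$mean[summary_b$cd == cd]
  if (length(ma) != 1L || length(mb) != 1L) abort("cd not present in both summaries")
  tibble::tibble(cd = cd, mean_a = ma, mean_b = mb,
                 fold = if (mb == 0) Inf else ma / mb,
                 infinite_ratio = mb == 0)
}

#' Decompose a panel's peak levels directly from its normalized summary
#'
#' Convenience wrapper: extracts the three genotype peaks (reference,
#' pathway null, targets null) from a [run_panel()] summary using the
#' panel's peak window and statistic, then calls [decompose_peak()].
#'
#' @param summary Normalized `profile_summary` covering the three genotypes.
#' @param panel The `gonad_panel` (for peak window/statistic).
#' @param ref,pathway_null,targets_null Genotype labels.
#' @return A `gonad_decomp` tibble (see [decompose_peak()]).
#' @export
decompose_panel <- function(summary, panel, ref, pathway_null, targets_null) {
  peak_of <- function(label) {
    s <- dplyr::filter(summary, .data$genotype == label)
    if (nrow(s) == 0L) abort(sprintf("genotype '%s' not in summary", label))
    peak_base(s, panel$peak_window, panel$base_cd,
              peak_stat = panel$peak_stat)$peak_mean
  }
  decompose_peak(peak_of(ref), peak_of(pathway_null), peak_of(targets_null))
}
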