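# Expression-side pipeline: CPM, differential tables, dependence filters,
# bound-gene intersection, time-course target classification, half-life
# bounds and delta-delta-Ct quantitation.

#' Counts per million
#'
#' @param counts Non-negative gene x sample matrix (or data frame with gene
#'   ids in the first column).
#' @return Matrix of `1e6 * count / column sum`, same dimnames.
#' @export
cpm <- function(counts) {
  m <- as_count_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) abort("zero column sum: empty library")
  t(t(m) / totals) * 1e6
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, -1])
    rownames(m) <- counts[[1]]
    counts <- m
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  counts
}

#' Differential expression table for a two-group contrast
#'
#' A deliberately simple, fully documented test: per-gene Welch t-test on
#' `log2(CPM + 0.5)` with Benjamini-Hochberg correction across all genes.
#' `log2fc` is mean(log2 CPM of `group_b`) - mean(`group_a`), so name the
#' groups to match the contrast direction you want to report.
#'
#' @param counts Gene x sample count matrix.
#' @param group_a,group_b Column names or indices (>= 2 samples each).
#' @param contrast Label stored in the `contrast` column.
#' @return A `GeneTable` tibble: `gene_id`, `mean_cpm` (across both
#'   groups), `log2fc`, `p_value`, `fdr`, `contrast`.
#' @export
de_table <- function(counts, group_a, group_b, contrast = "b_vs_a") {
  m <- as_count_matrix(counts)
  a <- m[, group_a, drop = FALSE]; b <- m[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) abort("need >= 2 samples per group")
  la <- log2(cpm(a) + 0.5); lb <- log2(cpm(b) + 0.5)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * pt(-abs(stat), df)
  p[se2 == 0] <- ifelse(mb[se2 == 0] == ma[se2 == 0], 1, 0)
  tibble::tibble(
    gene_id = rownames(m),
    mean_cpm = unname(rowMeans(cbind(cpm(a), cpm(b)))),
    log2fc = unname(mb - ma),
    p_value = unname(p),
    fdr = unname(p.adjust(p, method = "BH")),
    contrast = contrast)
}

#' Filter a differential table for regulated genes
#'
#' Applies the three published criteria with their printed strictness: linear
#' fold change at least `fc_min` in the stated direction (`2^|log2fc| >=
#' fc_min`), FDR strictly below `fdr_max`, and mean CPM strictly above
#' `cpm_min`. Relaxing any threshold can only grow the returned set.
#'
#' @param table A [de_table()] result.
#' @param direction `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @param fc_min,fdr_max,cpm_min Thresholds (defaults 2.0, 0.05, 2.0).
#' @return Sorted character vector of regulated gene ids.
#' @export
filter_regulated <- function(table, direction = c("up", "down"),
                             fc_min = 2.0, fdr_max = 0.05, cpm_min = 2.0) {
  direction <- match.arg(direction)
  signed_ok <- if (direction == "up") table$log2fc > 0 else table$log2fc < 0
  pass <- signed_ok &
    2^abs(table$log2fc) >= fc_min &
    table$fdr < fdr_max &
    table$mean_cpm > cpm_min
  sort(table$gene_id[pass])
}

#' Intersect a bound-gene list with a dependence gene set
#'
#' The primary-target candidates: genes both bound by the transcription
#' factor (ChIP) and requiring the signaling pathway for RNA accumulation.
#'
#' @param bound_genes,dependent_genes Character vectors.
#' @return Sorted intersection.
#' @export
intersect_targets <- function(bound_genes, dependent_genes) {
  sort(intersect(bound_genes, dependent_genes))
}

#' Classify primary vs secondary targets from a degradation time course
#'
#' After acute loss of the transcription factor, direct (primary) targets
#' lose expression first while indirect (secondary) targets respond later:
#' \itemize{
#'   \item primary: regulated (down, by [filter_regulated()]) at the
#'     earliest analyzed time point AND bound;
#'   \item secondary: not regulated at the earliest time, regulated at a
#'     later time, AND not bound;
#'   \item everything else: unclassified.
#' }
#' When a signaling-ON vs targets-null contrast is supplied, genes regulated
#' there get `targets_dependent = TRUE` (their accumulation requires the
#' primary targets), strengthening the secondary call.
#'
#' @param tables Named list of [de_table()]s, names = treatment duration in
#'   hours (each contrast: t0 as group a, treated as group b, so regulated
#'   genes are "down").
#' @param bound_genes Character vector of ChIP-bound genes.
#' @param targets_dependence Optional [de_table()] of signaling-ON vs
#'   targets-null (dependence appears as "down" in the null).
#' @param earliest Earliest analyzed time in hours (default: smallest name);
#'   an error if that time point is missing.
#' @param ... Threshold overrides passed to [filter_regulated()].
#' @return A `TargetCallSet` tibble: `gene_id`, `class`, `bound`,
#'   `regulated_at` (earliest regulated time, `NA` if never),
#'   `targets_dependent`.
#' @export
classify_timecourse <- function(tables, bound_genes,
                                targets_dependence = NULL, earliest = NULL,
                                ...) {
  times <- as.numeric(names(tables))
  if (anyNA(times)) abort("`tables` must be named by time in hours")
  ord <- order(times)
  tables <- tables[ord]; times <- times[ord]
  earliest <- earliest %||% min(times)
  if (!earliest %in% times) {
    abort(sprintf("earliest analyzed time point (%g h) is missing", earliest))
  }
  regulated <- purrr::map(tables, filter_regulated, direction = "down", ...)
  genes <- tables[[1]]$gene_id
  reg_at <- purrr::map(regulated, ~ genes %in% .x)
  first_reg <- rep(NA_real_, length(genes))
  for (i in rev(seq_along(times))) first_reg[reg_at[[i]]] <- times[i]
  bound <- genes %in% bound_genes
  reg_earliest <- reg_at[[which(times == earliest)]]
  reg_later <- !reg_earliest & !is.na(first_reg)
  tdep <- rep(NA, length(genes))
  if (!is.null(targets_dependence)) {
    tdep <- genes %in% filter_regulated(targets_dependence,
                                        direction = "down", ...)
  }
  class <- dplyr::case_when(
    reg_earliest & bound ~ "primary",
    reg_later & !bound ~ "secondary",
    TRUE ~ "unclassified")
  tibble::tibble(gene_id = genes, class = class, bound = bound,
                 regulated_at = first_reg, targets_dependent = tdep)
}

#' Upper bound on a half-life from time-course fold drops
#'
#' If a species has dropped `fold >= 2` by time `t`, its half-life is at
#' most `t`; the earliest sampled time reaching a 2-fold drop is returned as
#' the bound. If no sampled time reaches 2-fold the result is flagged
#' `no_bound` rather than an error.
#'
#' @param fold_drop_by_time Named numeric (names = hours, values = fold
#'   drop, >= 1 where measured) or a data frame with columns `time_hr`,
#'   `fold_drop`.
#' @return One-row tibble: `bound_hr` (`NA` if no bound), `fold_at_bound`,
#'   `no_bound`.
#' @export
#' @examples
#' half_life_bound(c(`1` = 3))             # bound: 1 h
#' half_life_bound(c(`2` = 5, `4` = 10))   # bound: 2 h
half_life_bound <- function(fold_drop_by_time) {
  if (is.data.frame(fold_drop_by_time)) {
    times <- fold_drop_by_time$time_hr
    folds <- fold_drop_by_time$fold_drop
  } else {
    times <- as.numeric(names(fold_drop_by_time))
    folds <- as.numeric(fold_drop_by_time)
  }
  if (anyNA(times)) abort("times must be numeric (hours)")
  ord <- order(times)
  times <- times[ord]; folds <- folds[ord]
  if (is.unsorted(times, strictly = TRUE)) abort("duplicate time points")
  hit <- which(folds >= 2)
  if (length(hit) == 0L) {
    tibble::tibble(bound_hr = NA_real_, fold_at_bound = NA_real_,
                   no_bound = TRUE)
  } else {
    tibble::tibble(bound_hr = times[hit[1]], fold_at_bound = folds[hit[1]],
                   no_bound = FALSE)
  }
}

#' Relative mRNA abundance by the delta-delta-Ct method
#'
#' `dCt = Ct(gene) - Ct(reference gene)` per condition (averaged over
#' replicates), `ddCt = dCt(condition) - dCt(reference condition)`, and the
#' relative abundance is `2^(-ddCt)`; every gene's level in the reference
#' condition is 1 by construction.
#'
#' @param ct Tibble with columns `gene`, `condition`, `replicate`, `ct`.
#' @param reference_gene Normalization gene measured in every
#'   condition/replicate (e.g. `"ama-1"`).
#' @param reference_condition Condition whose level defines 1.
#' @return Tibble: `gene`, `condition`, `ddct`, `rel_abundance`.
#' @export
delta_ct <- function(ct, reference_gene = "ama-1", reference_condition) {
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) abort("Ct values must be positive")
  ref <- dplyr::filter(ct, .data$gene == reference_gene)
  if (nrow(ref) == 0L) abort("reference gene not measured")
  have_ref <- dplyr::distinct(ct, .data$condition, .data$replicate) |>
    dplyr::anti_join(ref, by = c("condition", "replicate"))
  if (nrow(have_ref) > 0L) {
    abort("reference gene missing from some condition/replicate pairs")
  }
  dct <- ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::inner_join(
      dplyr::select(ref, "condition", "replicate", ref_ct = "ct"),
      by = c("condition", "replicate")) |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(dct = mean(.data$ct - .data$ref_ct), .groups = "drop")
  base <- dplyr::filter(dct, .data$condition == reference_condition)
  if (nrow(base) == 0L) abort("reference condition not measured")
  dct |>
    dplyr::inner_join(dplyr::select(base, "gene", base_dct = "dct"),
                      by = "gene") |>
    dplyr::mutate(ddct = .data$dct - .data$base_dct,
                  rel_abundance = 2^(-.data$ddct)) |>
    dplyr::select("gene", "condition", "ddct", "rel_abundance")
}
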