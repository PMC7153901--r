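#' Expected relative mRNA level during exponential decay after regulator loss
#'
#' After the regulator is degraded, a dependent transcript decays
#' exponentially from its steady-state level towards a residual floor:
#' `level(t) = floor + (1 - floor) * 2^(-(t - lag)/half_life)` for
#' `t > lag`, and 1 before the lag. Secondary targets inherit a lag equal to
#' the regulator-protein half-life because their decay cannot start until the
#' intermediate protein is gone.
#'
#' @param t Time in hours since regulator loss (vectorized).
#' @param half_life mRNA half-life in hours (> 0).
#' @param floor Residual fraction remaining after complete loss, in `[0, 1)`.
#' @param lag Delay in hours before decay starts.
#' @return Expected level relative to `t = 0`.
#' @export
#' @examples
#' decay_level(2, half_life = 1)          # 0.25
#' decay_level(2, half_life = 1, lag = 2) # 1
decay_level <- function(t, half_life, floor = 0, lag = 0) {
  stopifnot(all(half_life > 0), all(floor >= 0), all(floor < 1), all(lag >= 0))
  floor + (1 - floor) * 2^(-pmax(t - lag, 0) / half_life)
}

#' Configure a synthetic expression study with planted regulatory structure
#'
#' Builds the design for a two-condition (signaling ON vs OFF) contrast plus a
#' regulator-degradation time course, with planted primary targets (bound and
#' immediately decaying), secondary targets (unbound, decaying after a lag)
#' and additional dependent genes (responding only by the last time point).
#' `expression_config()` with no arguments reproduces the shipped
#' `paper_like` design.
#'
#' @param design Path to a design YAML or the name of a shipped design
#'   (`"paper_like"`). Individual fields can be overridden via `...`.
#' @param ... Named overrides of design fields (e.g. `n_genes`,
#'   `dispersion`, `reps`).
#' @return An `expression_config` list with a `planted` tibble
#'   (`gene_id`, `role`, `log2fc`, `half_life`, `lag`) and a
#'   `bound_genes` character vector.
#' @export
expression_config <- function(design = "paper_like", ...) {
  path <- if (file.exists(design)) design else
    system.file("extdata", "panels", paste0(design, ".yaml"),
                package = "gonadscan")
  if (!nzchar(path) || !file.exists(path)) {
    stop_config(sprintf("unknown expression design '%s'", design))
  }
  d <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots) > 0L) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop_config("design overrides must be named")
    }
    d[names(dots)] <- dots   # whole-field replacement, lists included
  }
  with(d, {
    stopifnot(n_primaries + n_secondaries <= n_dependent,
              n_primaries <= n_bound, reps >= 2, tc_reps >= 2,
              dispersion >= 0, floor_fraction >= 0, floor_fraction < 1)
  })
  n_other_dep <- d$n_dependent - d$n_primaries - d$n_secondaries
  n_bound_only <- d$n_bound - d$n_primaries
  n_null <- d$n_genes - d$n_dependent - n_bound_only
  if (n_null < 0) stop_config("n_genes too small for the planted sets")
  ids <- c(
    sprintf("primary_%02d", seq_len(d$n_primaries)),
    sprintf("secondary_%02d", seq_len(d$n_secondaries)),
    sprintf("dep_%03d", seq_len(n_other_dep)),
    sprintf("bound_%03d", seq_len(n_bound_only)),
    sprintf("gene_%04d", seq_len(n_null)))
  role <- rep(c("primary", "secondary", "other_dependent", "bound_only", "null"),
              c(d$n_primaries, d$n_secondaries, n_other_dep, n_bound_only, n_null))
  dep <- role %in% c("primary", "secondary", "other_dependent")
  lfc <- numeric(length(ids))
  lfc[dep] <- rep(unlist(d$log2fc_levels), length.out = sum(dep))
  hl <- lag <- rep(NA_real_, length(ids))
  hl[role == "primary"] <- d$primary_half_life
  hl[role == "secondary"] <- d$secondary_half_life
  hl[role == "other_dependent"] <- d$other_half_life
  lag[role == "primary"] <- 0
  lag[role == "secondary"] <- d$secondary_lag
  lag[role == "other_dependent"] <- d$other_lag
  planted <- tibble::tibble(gene_id = ids, role = role, log2fc = lfc,
                            half_life = hl, lag = lag)
  structure(
    c(d[setdiff(names(d), "name")],
      list(name = d$name %||% "custom",
           planted = planted,
           bound_genes = ids[role %in% c("primary", "bound_only")],
           dependent_genes = ids[dep],
           targets_dependent_genes = ids[role %in% c("primary", "secondary")])),
    class = "expression_config")
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
  else rpois(n, lambda = mu)
}

#' Generate synthetic count matrices with planted regulatory structure
#'
#' Draws negative-binomial counts for the ON/OFF contrast, the degradation
#' time course, and an ON vs targets-null contrast, under the planted design
#' of an [expression_config()]. Dependent genes are elevated in ON by their
#' planted log2 fold change; after regulator loss their expected level
#' follows [decay_level()]. Deterministic for fixed `(config, seed)`.
#'
#' @param cfg An [expression_config()].
#' @param seed Integer seed.
#' @return A list:
#' \describe{
#'   \item{on_off}{genes x samples count matrix, columns `ON_*` / `OFF_*`.}
#'   \item{timecourse}{named list of genes x `tc_reps` matrices, one per
#'     sequencing time point (hours, as names).}
#'   \item{targets_onoff}{count matrix for ON vs lst-1/sygl-1-null (`TOFF_*`).}
#'   \item{bound_genes}{character vector (the ChIP-positive analog list).}
#'   \item{truth}{the planted design, per-gene expected means included.}
#' }
#' @export
generate_expression <- function(cfg, seed) {
  stopifnot(inherits(cfg, "expression_config"))
  set.seed(as.integer(seed))
  n <- nrow(cfg$planted)
  ids <- cfg$planted$gene_id
  mu <- 2^runif(n, 8, 11)
  mu <- mu / sum(mu) * cfg$library_size

  dep <- !is.na(cfg$planted$half_life)
  off_mu <- mu
  off_mu[dep] <- mu[dep] / 2^cfg$planted$log2fc[dep]

  draw_mat <- function(means, reps, prefix) {
    m <- vapply(seq_len(reps), function(i) nb_draw(n, means, cfg$dispersion),
                numeric(n))
    dimnames(m) <- list(ids, sprintf("%s_%d", prefix, seq_len(reps)))
    storage.mode(m) <- "integer"
    m
  }

  on_off <- cbind(draw_mat(mu, cfg$reps, "ON"), draw_mat(off_mu, cfg$reps, "OFF"))

  tc_times <- unlist(cfg$rnaseq_timepoints)
  timecourse <- lapply(tc_times, function(t) {
    m_t <- rep(1, n)
    m_t[dep] <- decay_level(t, cfg$planted$half_life[dep],
                            floor = cfg$floor_fraction,
                            lag = cfg$planted$lag[dep])
    draw_mat(mu * m_t, cfg$tc_reps, sprintf("t%g", t))
  })
  names(timecourse) <- as.character(tc_times)

  toff_mu <- mu
  tdep <- ids %in% cfg$targets_dependent_genes
  toff_mu[tdep] <- mu[tdep] / 2^cfg$planted$log2fc[tdep]
  targets_onoff <- cbind(draw_mat(mu, cfg$reps, "ON"),
                         draw_mat(toff_mu, cfg$reps, "TOFF"))

  list(on_off = on_off, timecourse = timecourse,
       targets_onoff = targets_onoff,
       bound_genes = cfg$bound_genes,
       truth = list(config = cfg,
                    planted = dplyr::mutate(cfg$planted, mean_on = mu),
                    dependent_genes = cfg$dependent_genes,
                    primaries = ids[cfg$planted$role == "primary"],
                    secondaries = ids[cfg$planted$role == "secondary"]))
}

#' Write generated count matrices to TSV
#'
#' One TSV per matrix, gene ids in the first column, plus the bound-gene list
#' as a newline-delimited text file.
#'
#' @param sim Result of [generate_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump <- function(m, name) {
    readr::write_tsv(tibble::as_tibble(m, rownames = "gene_id"),
                     file.path(dir, paste0(name, ".tsv")))
  }
  dump(sim$on_off, "on_off")
  dump(sim$targets_onoff, "targets_onoff")
  purrr::iwalk(sim$timecourse, function(m, t) dump(m, paste0("timecourse_t", t)))
  writeLines(sim$bound_genes, file.path(dir, "bound_genes.txt"))
  invisible(dir)
}

#' Read a gene x sample count matrix written by [write_expression()]
#'
#' @param path TSV with `gene_id` first column.
#' @return Integer matrix with gene-id rownames.
#' @export
read_counts <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb[[1]]
  m
}

#' Read a bound-gene list (newline-delimited ids, or a BED-like table whose
#' gene-id column is taken verbatim)
#'
#' @param path Text file; if tab-delimited with >= 4 columns, the 4th (name)
#'   column is used, otherwise each line is one gene id.
#' @return Sorted character vector of unique gene ids.
#' @export
read_bound_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else f[[1L]], "")
  sort(unique(ids))
}
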