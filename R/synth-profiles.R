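#' Configure a synthetic intensity-profile genotype
#'
#' Describes the expected fluorescence of one genotype along the
#' distal-proximal axis as a piecewise-linear function of cell diameter (cd),
#' together with replicate noise and the untagged staining background. Levels
#' are in arbitrary fluorescence units; for panel fixtures they are usually
#' expressed on the normalized scale (control peak = 100) and scaled by a
#' common camera gain.
#'
#' @param genotype Genotype label, e.g. `"wt"` or `"gld2_gld1"`.
#' @param breakpoints Two-column data frame (`cd`, `level`): strictly
#'   increasing cds within `[1, max_cd]`, non-negative levels. Means at
#'   intermediate cds are linearly interpolated, ends extended flat.
#' @param tagged Does the strain carry the epitope tag? Untagged strains
#'   (`tagged = FALSE`) contribute only background and are used for
#'   background subtraction.
#' @param noise_sd Gaussian replicate noise SD per cd (fluorescence units).
#' @param background_level Untagged (non-specific) staining level added to
#'   every profile (fluorescence units).
#' @param n_germlines Number of replicate germlines to simulate.
#' @param max_cd Most proximal cd quantified (25 for LAG-1-like panels,
#'   35 for FBF-2-like panels).
#'
#' @return A `profile_config` list.
#' @export
#' @examples
#' cfg <- profile_config("wt",
#'   breakpoints = data.frame(cd = c(1, 4, 25), level = c(95, 100, 14)))
#' generate_profiles(cfg, seed = 1)
profile_config <- function(genotype, breakpoints, tagged = TRUE,
                           noise_sd = 0, background_level = 0,
                           n_germlines = 1L, max_cd = 25L) {
  check_number(max_cd, "max_cd", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(background_level, "background_level", min = 0)
  check_number(n_germlines, "n_germlines", min = 1)
  means <- eval_breakpoints(breakpoints, max_cd)  # validates breakpoints
  structure(
    list(genotype = genotype, tagged = isTRUE(tagged),
         breakpoints = as.data.frame(breakpoints),
         means = means, noise_sd = noise_sd,
         background_level = background_level,
         n_germlines = as.integer(n_germlines), max_cd = as.integer(max_cd)),
    class = "profile_config")
}

#' Generate replicate intensity profiles for one genotype
#'
#' Draws `n_germlines` raw per-cd profiles: the configured piecewise-linear
#' mean plus the untagged background, with independent Gaussian noise at each
#' cd. Deterministic for a fixed `(config, seed)` pair.
#'
#' @param cfg A [profile_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `genotype`, `tagged`, `replicate`, `cd`,
#'   `value`, `state` (`"raw"`). The generating truth (per-cd expected raw
#'   value) is attached as attribute `"truth"`.
#' @export
generate_profiles <- function(cfg, seed) {
  stopifnot(inherits(cfg, "profile_config"))
  set.seed(as.integer(seed))
  mu <- cfg$background_level + if (cfg$tagged) cfg$means else 0
  n <- cfg$n_germlines
  vals <- rep(mu, times = n) +
    rnorm(n * cfg$max_cd, mean = 0, sd = cfg$noise_sd)
  out <- tibble::tibble(
    genotype = cfg$genotype,
    tagged = cfg$tagged,
    replicate = rep(seq_len(n), each = cfg$max_cd),
    cd = rep(seq_len(cfg$max_cd), times = n),
    value = vals,
    state = "raw")
  attr(out, "truth") <- tibble::tibble(
    genotype = cfg$genotype, cd = seq_len(cfg$max_cd), mean_value = mu)
  out
}

#' Load a named figure-panel configuration
#'
#' Panel YAML files ship with the package under `extdata/panels` and encode
#' the genotype panels used throughout: per-genotype piecewise profiles on
#' the normalized scale (control peak = 100), the peak window and statistic,
#' the base cd, and generator noise settings. `panel` may also be a path to
#' a user YAML file with the same layout.
#'
#' @param panel Panel name (`"fig3"`, `"fig6"`, `"figS3"`, `"figS10"`) or a
#'   path to a YAML file.
#' @return A `gonad_panel` list: fields `name`, `protein`, `max_cd`,
#'   `peak_window`, `peak_stat`, `base_cd`, `control`, `untagged`, `gain`,
#'   `noise_sd`, `n_germlines` and `configs` (named list of
#'   [profile_config()]s with levels scaled to raw fluorescence units).
#' @export
load_panel <- function(panel) {
  path <- if (file.exists(panel)) panel else
    system.file("extdata", "panels", paste0(panel, ".yaml"),
                package = "gonadscan")
  if (!nzchar(path) || !file.exists(path)) {
    stop_config(sprintf("unknown panel '%s'", panel))
  }
  y <- yaml::read_yaml(path)
  gain <- y$gain %||% 1
  configs <- purrr::imap(y$genotypes, function(g, label) {
    bp <- matrix(unlist(g$breakpoints), ncol = 2, byrow = TRUE)
    profile_config(
      genotype = label,
      breakpoints = data.frame(cd = bp[, 1], level = gain * bp[, 2]),
      tagged = g$tagged %||% TRUE,
      noise_sd = g$noise_sd %||% y$noise_sd %||% 0,
      background_level = y$background_level %||% 0,
      n_germlines = g$n_germlines %||% y$n_germlines %||% 1L,
      max_cd = y$max_cd)
  })
  structure(
    list(name = y$name, protein = y$protein, max_cd = y$max_cd,
         peak_window = seq(y$peak_window[[1]], y$peak_window[[2]]),
         peak_stat = y$peak_stat %||% "mean",
         base_cd = y$base_cd, control = y$control, untagged = y$untagged,
         gain = gain, noise_sd = y$noise_sd %||% 0,
         n_germlines = y$n_germlines %||% 1L, configs = configs),
    class = "gonad_panel")
}

#' Generate raw profiles for every genotype of a panel
#'
#' @param panel A `gonad_panel` from [load_panel()].
#' @param seed Integer seed; genotypes get distinct deterministic sub-seeds.
#' @param noise_sd,n_germlines Optional overrides applied to every genotype.
#' @return A raw profile tibble covering all panel genotypes, truth attached
#'   as attribute `"truth"`.
#' @export
generate_panel_profiles <- function(panel, seed, noise_sd = NULL,
                                    n_germlines = NULL) {
  stopifnot(inherits(panel, "gonad_panel"))
  seed <- as.integer(seed)
  out <- purrr::imap(panel$configs, function(cfg, label) {
    if (!is.null(noise_sd)) cfg$noise_sd <- noise_sd
    if (!is.null(n_germlines)) cfg$n_germlines <- as.integer(n_germlines)
    generate_profiles(cfg, seed = seed + match(label, names(panel$configs)))
  })
  truth <- dplyr::bind_rows(purrr::map(out, attr, "truth"))
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- truth
  res
}

#' Write / read intensity profiles as TSV
#'
#' Long format: one row per (genotype, replicate, cd) with the value and
#' processing state, so profiles survive a round trip exactly.
#'
#' @param profiles Profile tibble.
#' @param path TSV path.
#' @return `path` (write) or a profile tibble (read).
#' @export
write_profiles <- function(profiles, path) {
  check_profiles(profiles)
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  check_profiles(tb)
  dplyr::mutate(tb, replicate = as.integer(.data$replicate),
                cd = as.integer(.data$cd))
}

#' Split a panel profile tibble into tagged, untagged and control sets
#'
#' Convenience used by the profile pipeline: the untagged strain drives
#' background subtraction and the tagged wild-type strain is the internal
#' normalization control.
#'
#' @param profiles Profile tibble from [generate_panel_profiles()].
#' @param panel The `gonad_panel` the profiles were generated from.
#' @return List with elements `tagged`, `untagged`, `control_label`.
#' @export
split_panel_profiles <- function(profiles, panel) {
  list(
    tagged = dplyr::filter(profiles, .data$tagged),
    untagged = dplyr::filter(profiles, .data$genotype == panel$untagged),
    control_label = panel$control)
}
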