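# internal helpers shared across modules

# stop with a classed condition so tests can assert on error class
stop_config <- function(msg) {
  abort(msg, class = "gonadscan_config_error")
}

check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(sprintf("`%s` must be a single number", name))
  }
  if (x < min || (!allow_zero && x == min)) {
    stop_config(sprintf("`%s` must be %s %s", name,
                        if (allow_zero) ">=" else ">", format(min)))
  }
  invisible(x)
}

# evaluate a piecewise-linear breakpoint spec (tibble/data.frame with columns
# cd, level) at integer cd positions 1..max_cd; constant extrapolation
eval_breakpoints <- function(breakpoints, max_cd) {
  bp <- as.data.frame(breakpoints)
  stopifnot(ncol(bp) >= 2L)
  names(bp)[1:2] <- c("cd", "level")
  if (is.unsorted(bp$cd, strictly = TRUE)) {
    stop_config("breakpoint cds must be strictly increasing")
  }
  if (any(bp$cd < 1) || any(bp$cd > max_cd)) {
    stop_config("breakpoint cds must lie within [1, max_cd]")
  }
  if (any(bp$level < 0)) stop_config("breakpoint levels must be >= 0")
  if (nrow(bp) == 1L) return(rep(bp$level, max_cd))
  approx(bp$cd, bp$level, xout = seq_len(max_cd), rule = 2)$y
}

# per-channel accessor with a friendly error
get_channel <- function(image, channel) {
  ch <- image$channels[[channel]]
  if (is.null(ch)) {
    abort(sprintf("channel '%s' not present in image (has: %s)",
                  channel, paste(names(image$channels), collapse = ", ")),
          class = "gonadscan_channel_error")
  }
  ch
}

is_profile_tbl <- function(x) {
  is.data.frame(x) && all(c("genotype", "replicate", "cd", "value", "state") %in% names(x))
}

check_profiles <- function(x, state = NULL, arg = "profiles") {
  if (!is_profile_tbl(x)) {
    abort(sprintf(
      "`%s` must be a profile tibble with columns genotype, replicate, cd, value, state",
      arg))
  }
  states <- unique(x$state)
  if (length(states) != 1L) {
    abort(sprintf("`%s` mixes processing states: %s", arg,
                  paste(states, collapse = ", ")))
  }
  if (!is.null(state) && states != state) {
    abort(sprintf("`%s` must be in state '%s' (got '%s')", arg, state, states))
  }
  invisible(x)
}
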