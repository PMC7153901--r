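make_profiles <- function(values_by_rep, genotype = "wt", tagged = TRUE,
                          state = "raw") {
  purrr::imap_dfr(values_by_rep, function(v, i) {
    tibble::tibble(genotype = genotype, tagged = tagged, replicate = i,
                   cd = seq_along(v), value = v, state = state)
  })
}

test_that("background subtraction removes the untagged mean and clips at 0", {
  tagged <- make_profiles(list(rep(120, 10)))
  untag <- make_profiles(list(rep(18, 10), rep(22, 10)),
                         genotype = "n2", tagged = FALSE)
  corr <- subtract_background(tagged, untag)
  expect_equal(corr$value, rep(100, 10))
  expect_equal(unique(corr$state), "corrected")
  # profile equal to the untagged mean corrects to all-zero
  same <- subtract_background(make_profiles(list(rep(20, 10))), untag)
  expect_equal(same$value, rep(0, 10))
  # clipping is recorded, raw difference kept for audit
  low <- subtract_background(make_profiles(list(rep(15, 10))), untag)
  expect_equal(low$value, rep(0, 10))
  expect_equal(low$value_unclipped, rep(-5, 10))
})

test_that("untagged self-subtraction leaves per-cd means near zero", {
  cfg <- profile_config("n2", data.frame(cd = c(1, 25), level = c(0, 0)),
                        tagged = FALSE, noise_sd = 5, background_level = 30,
                        n_germlines = 40)
  prof <- generate_profiles(cfg, 13)
  corr <- subtract_background(prof, prof)
  m <- tapply(corr$value_unclipped, corr$cd, mean)
  expect_true(all(abs(m) < 1e-10))  # subtracting its own mean is exact
})

test_that("normalization scales the batch so the control peak is 100", {
  ctrl <- make_profiles(list(rep(50, 10)), state = "corrected")
  other <- make_profiles(list(rep(30, 10)), genotype = "mut",
                         state = "corrected")
  norm <- normalize_to_control(other, ctrl, peak_window = 4)
  expect_equal(attr(norm, "scale_factor"), 2)
  expect_equal(norm$value, rep(60, 10))
  # control mean 100 -> identity
  ctrl100 <- make_profiles(list(rep(100, 10)), state = "corrected")
  expect_equal(normalize_to_control(other, ctrl100, 4)$value, other$value)
  # normalizing the control itself forces its peak to exactly 100
  nc <- normalize_to_control(ctrl, ctrl, 4)
  expect_equal(mean(summarize_profiles(nc)$mean[4]), 100)
  # ratios between cds are untouched by the rescaling
  set.seed(2)
  ragged <- make_profiles(list(runif(10, 10, 90)), state = "corrected")
  nr <- normalize_to_control(ragged, ctrl, 4)
  expect_equal(nr$value / nr$value[1], ragged$value / ragged$value[1])
})

test_that("normalization demands corrected inputs and a positive control", {
  raw <- make_profiles(list(rep(10, 5)))
  expect_error(normalize_to_control(raw, raw, 1), "corrected")
  zero <- make_profiles(list(rep(0, 5)), state = "corrected")
  ok <- make_profiles(list(rep(5, 5)), state = "corrected")
  expect_error(normalize_to_control(ok, zero, 2), "positive")
})

test_that("summaries report mean, sample SD and n per cd", {
  prof <- make_profiles(list(c(90, 5), c(110, 5)))
  s <- summarize_profiles(prof)
  expect_equal(s$mean[s$cd == 1], 100)
  expect_equal(s$sd[s$cd == 1], sd(c(90, 110)))
  expect_equal(s$sd[s$cd == 1], 14.14, tolerance = 1e-3)
  expect_equal(s$n, c(2L, 2L))
  # single profile: SD flagged as 0
  s1 <- summarize_profiles(make_profiles(list(c(4, 8))))
  expect_equal(s1$sd, c(0, 0))
  # mixed states refuse to summarize
  mixed <- dplyr::bind_rows(prof, make_profiles(list(rep(1, 2)),
                                                state = "corrected"))
  expect_error(summarize_profiles(mixed), "states")
})

test_that("zero-mean noise averages to zero within standard error", {
  cfg <- profile_config("x", data.frame(cd = c(1, 10), level = c(0, 0)),
                        noise_sd = 3, n_germlines = 500, max_cd = 10)
  s <- summarize_profiles(generate_profiles(cfg, 31))
  expect_true(all(abs(s$mean) <= 3 * 3 / sqrt(500)))
})

test_that("peak/base statistics cover both peak conventions", {
  s <- summarize_profiles(make_profiles(list(rep(5, 10))))
  expect_equal(peak_base(s, 4, 10)$fold_ratio, 1)
  vals <- c(10, 30, 60, 100, 80, 50, 30, 20, 15, 10)
  s2 <- summarize_profiles(make_profiles(list(vals)))
  pb_mean <- peak_base(s2, 3:5, 10, peak_stat = "mean")
  expect_equal(pb_mean$peak_mean, 80)
  pb_max <- peak_base(s2, 3:5, 10, peak_stat = "max")
  expect_equal(pb_max$peak_mean, 100)
  expect_equal(pb_max$fold_ratio, 10)
  # zero base flagged infinite
  s3 <- summarize_profiles(make_profiles(list(c(rep(10, 9), 0))))
  pb0 <- peak_base(s3, 1, 10)
  expect_true(is.infinite(pb0$fold_ratio) && pb0$infinite_ratio)
})

test_that("significance tiers match the legend mapping at the boundaries", {
  expect_equal(significance_tier(c(0.0001, 0.001, 0.01, 0.010001, 0.5)),
               c("***", "**", "*", "NS", "NS"))
  expect_equal(significance_tier(1e-7), "***")
  # monotone in p
  p <- sort(runif(50))
  tiers <- factor(significance_tier(p), levels = c("***", "**", "*", "NS"))
  expect_true(!is.unsorted(as.integer(tiers)))
})

test_that("test selection follows the sample-size rule", {
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(compare_levels(a, b)$test_used, "t")
  a40 <- rnorm(40); b40 <- rnorm(40)
  expect_equal(compare_levels(a40, b40)$test_used, "Z")
  # mixed sizes: the smaller sample decides
  expect_equal(compare_levels(rnorm(10), rnorm(40))$test_used, "t")
})

test_that("degenerate and identical samples compare as NS", {
  out <- compare_levels(c(5, 5, 5), c(5, 5, 5))
  expect_equal(out$p_value, 1)
  expect_equal(out$tier, "NS")
  same <- rnorm(12)
  expect_equal(compare_levels(same, same)$p_value, 1, tolerance = 1e-12)
})

test_that("Welch p-values agree with a permutation oracle", {
  # moderate overlap so the permutation p is resolvable at B = 20000
  set.seed(8)
  a <- c(4.1, 5.2, 3.8, 6.0, 4.9, 5.5, 4.4, 5.1)
  b <- c(5.0, 6.1, 5.9, 6.8, 5.2, 6.4, 5.7, 4.8)
  p_t <- compare_levels(a, b)$p_value
  p_perm <- perm_test_p(a, b, B = 20000, seed = 3)
  expect_lt(abs(p_t - p_perm), 0.02)
  # the spec's canonical separated samples are highly significant both ways
  expect_lt(compare_levels(1:10, 11:20)$p_value, 1e-5)
  expect_lte(perm_test_p(1:10, 11:20, B = 2000, seed = 1), 1 / 1000)
})

test_that("run_panel wires subtraction, normalization and summary together", {
  p <- load_panel("fig3")
  res <- run_panel(p, profiles = generate_panel_profiles(p, 1, noise_sd = 0,
                                                         n_germlines = 2))
  s <- res$summary
  expect_equal(unique(s$state), "normalized")
  wt <- dplyr::filter(s, genotype == "wt")
  expect_equal(wt$mean[wt$cd == 4], 100)
  # zero-noise shape is reproduced exactly up to the normalization scale
  expect_equal(wt$mean, p$configs$wt$means / p$gain)
})
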