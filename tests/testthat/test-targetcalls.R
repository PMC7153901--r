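test_that("CPM normalizes columns to one million", {
  m <- matrix(c(2, 999998, 10, 999990), ncol = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- cpm(m)
  expect_equal(cm["g1", "s1"], 2)
  expect_equal(colSums(cm), c(s1 = 1e6, s2 = 1e6))
  m0 <- rbind(m, g3 = c(0, 0))
  expect_equal(unname(cpm(m0)["g3", ]), c(0, 0))
  expect_error(cpm(matrix(0, 2, 2)), "zero column")
})

test_that("identical groups give zero log2 fold change for every gene", {
  set.seed(10)
  m <- matrix(rpois(50 * 4, 100), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  tab <- de_table(cbind(m, m), group_a = 1:4, group_b = 5:8)
  expect_equal(tab$log2fc, rep(0, 50))
  expect_equal(tab$p_value, rep(1, 50))
})

test_that("null simulations hold the type-I error near the nominal 0.05", {
  cfg <- expression_config(n_genes = 2000, n_bound = 0, n_dependent = 0,
                           n_primaries = 0, n_secondaries = 0)
  sim <- generate_expression(cfg, 55)
  tab <- de_table(sim$on_off, 1:5, 6:10)
  frac <- mean(tab$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), brute_bh(p))
  }
  # and de_table uses exactly that adjustment
  m <- matrix(rpois(40 * 6, 80), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  tab <- de_table(m, 1:3, 4:6)
  expect_equal(tab$fdr, brute_bh(tab$p_value))
})

test_that("regulation filtering applies the three printed thresholds", {
  tab <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    mean_cpm = c(3, 3, 1.9, 3, 2.0),
    log2fc = c(log2(2.5), log2(2.5), log2(2.5), log2(1.9), log2(4)),
    p_value = 0.001,
    fdr = c(0.01, 0.06, 0.01, 0.01, 0.01),
    contrast = "ON_vs_OFF")
  expect_equal(filter_regulated(tab, "up"), "a")      # b: fdr, c: cpm, d: fold
  # cpm must be strictly greater than the cutoff
  expect_false("e" %in% filter_regulated(tab, "up"))
  # direction is enforced on the sign
  tab_dn <- dplyr::mutate(tab, log2fc = -log2fc)
  expect_equal(filter_regulated(tab_dn, "down"), "a")
  expect_equal(filter_regulated(tab_dn, "up"), character(0))
})

test_that("relaxing any filter threshold never shrinks the gene set", {
  set.seed(14)
  tab <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:300),
    mean_cpm = runif(300, 0, 10),
    log2fc = rnorm(300, 0, 2),
    p_value = runif(300),
    fdr = runif(300),
    contrast = "c")
  base <- filter_regulated(tab, "up")
  expect_true(all(base %in% filter_regulated(tab, "up", fc_min = 1.5)))
  expect_true(all(base %in% filter_regulated(tab, "up", fdr_max = 0.2)))
  expect_true(all(base %in% filter_regulated(tab, "up", cpm_min = 1)))
})

test_that("bound/dependent intersection is a sorted set intersection", {
  expect_equal(intersect_targets(c("b", "a"), c("c", "d")), character(0))
  expect_equal(intersect_targets(c("b", "a"), c("a", "b")), c("a", "b"))
  expect_equal(intersect_targets(c("z", "m", "a"), c("m", "z")), c("m", "z"))
})

test_that("time-course classification separates primary from secondary", {
  mk_tab <- function(lfc) {
    tibble::tibble(gene_id = names(lfc), mean_cpm = 50, log2fc = unname(lfc),
                   p_value = 1e-6, fdr = 1e-5, contrast = "tc")
  }
  genes <- c(bound_early = -2, unbound_late = 0, never = 0, bound_late = 0)
  t2 <- mk_tab(genes)
  t4 <- mk_tab(c(bound_early = -2, unbound_late = -1.8, never = 0,
                 bound_late = -1.5))
  calls <- classify_timecourse(list(`2` = t2, `4` = t4),
                               bound_genes = c("bound_early", "bound_late"))
  cls <- setNames(calls$class, calls$gene_id)
  expect_equal(cls[["bound_early"]], "primary")
  expect_equal(cls[["unbound_late"]], "secondary")
  expect_equal(cls[["never"]], "unclassified")
  # a bound gene regulated only later is NOT secondary
  expect_equal(cls[["bound_late"]], "unclassified")
  expect_equal(calls$regulated_at[calls$gene_id == "unbound_late"], 4)
  expect_true(is.na(calls$regulated_at[calls$gene_id == "never"]))
  # missing earliest time point is an error
  expect_error(classify_timecourse(list(`4` = t4), "x", earliest = 2),
               "missing")
})

test_that("classification never crosses the bound/unbound constraint", {
  cfg <- expression_config(n_genes = 300, n_bound = 25, n_dependent = 20)
  for (seed in 1:20) {
    sim <- generate_expression(cfg, seed)
    tabs <- purrr::imap(sim$timecourse[c("2", "4", "48")], function(m, t) {
      de_table(cbind(sim$timecourse[["0"]], m), 1:4, 5:8,
               contrast = paste0("auxin_t", t))
    })
    calls <- classify_timecourse(tabs, sim$bound_genes)
    prim <- calls$gene_id[calls$class == "primary"]
    secd <- calls$gene_id[calls$class == "secondary"]
    expect_true(all(prim %in% sim$bound_genes))
    expect_equal(length(intersect(secd, sim$bound_genes)), 0)
    # planted primaries always recovered; planted secondaries never primary
    expect_setequal(prim, sim$truth$primaries)
    expect_equal(length(intersect(sim$truth$secondaries, prim)), 0)
  }
})

test_that("half-life bounds report the earliest 2-fold time", {
  expect_equal(half_life_bound(c(`1` = 3))$bound_hr, 1)
  expect_equal(half_life_bound(c(`2` = 5, `4` = 10))$bound_hr, 2)
  expect_equal(half_life_bound(c(`0.5` = 1.4, `1` = 3, `2` = 8))$bound_hr, 1)
  nb <- half_life_bound(c(`1` = 1.2, `2` = 1.8))
  expect_true(nb$no_bound && is.na(nb$bound_hr))
  # data-frame input
  df <- data.frame(time_hr = c(2, 4), fold_drop = c(5, 10))
  expect_equal(half_life_bound(df)$bound_hr, 2)
})

test_that("the bound is an upper bound for exponentially decaying species", {
  times <- c(0.5, 1, 2, 4)
  for (hl in c(0.3, 0.63, 1, 1.7, 3)) {
    folds <- setNames(1 / decay_level(times, hl), times)
    b <- half_life_bound(folds)
    if (!b$no_bound) expect_gte(b$bound_hr, hl)
  }
  # the documented case: true half-life 0.63 h sampled at 0.5/1/2/4 h
  folds <- setNames(1 / decay_level(times, 0.63), times)
  expect_equal(half_life_bound(folds)$bound_hr, 1)
})

test_that("delta-delta-Ct reproduces closed-form relative abundances", {
  ct <- tidyr::crossing(gene = c("ama-1", "lst-1"),
                        condition = c("OFF", "ON"),
                        replicate = 1:3) |>
    dplyr::mutate(ct = dplyr::case_when(
      gene == "ama-1" ~ 15,
      condition == "OFF" ~ 28,
      TRUE ~ 25))   # ddCt = -3 -> 8-fold up in ON
  out <- delta_ct(ct, reference_gene = "ama-1", reference_condition = "OFF")
  expect_equal(out$rel_abundance[out$condition == "OFF"], 1)
  expect_equal(out$rel_abundance[out$condition == "ON"], 8)
  # ddCt arithmetic: -1 -> 2, +2 -> 0.25
  ct2 <- tidyr::crossing(gene = c("ama-1", "g"), condition = c("ref", "a", "b"),
                         replicate = 1) |>
    dplyr::mutate(ct = dplyr::case_when(
      gene == "ama-1" ~ 15,
      condition == "ref" ~ 20,
      condition == "a" ~ 19,
      TRUE ~ 22))
  out2 <- delta_ct(ct2, reference_condition = "ref")
  expect_equal(out2$rel_abundance[out2$condition == "a"], 2)
  expect_equal(out2$rel_abundance[out2$condition == "b"], 0.25)
  # missing reference measurements error
  expect_error(delta_ct(dplyr::filter(ct, gene != "ama-1"),
                        reference_condition = "OFF"),
               "reference gene")
})
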