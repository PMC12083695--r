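test_that("corrected p closed forms are exact and ordered", {
  expect_equal(p_adjust_k(0.01, 5, "bonferroni"), 0.05)
  expect_equal(p_adjust_k(0.01, 5, "sidak"), 1 - 0.99^5)
  expect_equal(p_adjust_k(0.3, 1, "bonferroni"), 0.3)
  expect_equal(p_adjust_k(0.3, 1, "sidak"), 0.3)
  expect_equal(p_adjust_k(0.4, 10, "bonferroni"), 1)  # capped
  with_seed_local(1, p <- runif(50))
  for (k in c(1, 2, 5, 9)) {
    expect_true(all(p_adjust_k(p, k, "bonferroni") >=
                      p_adjust_k(p, k, "sidak") - 1e-15))
    expect_true(all(p_adjust_k(p, k, "sidak") >= p))
  }
  expect_error(p_adjust_k(0.5, 0), "k")
})

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  # small balanced 2-group x 2-time design, n = 3 per group
  tab <- make_stats_table(n_per_group = 3, groups = 1:2, seed = 4,
                          time_shift = 1, interaction_groups = 2)
  res <- rm_anova(tab, "area_mm2")
  d <- data.frame(animal = tab$animal, group = factor(tab$group),
                  time = factor(tab$timepoint), y = tab$area_mm2)
  oracle <- rm_anova_oracle(d)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "group"], oracle$F_group, tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "time"], oracle$F_time, tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "group:time"], oracle$F_gxt,
               tolerance = 1e-10)
  expect_equal(eff$df_num[eff$effect == "group"], oracle$df$group)
  expect_equal(eff$df_den[eff$effect == "group"], oracle$df$subj_err)
  expect_equal(eff$df_den[eff$effect == "time"], oracle$df$werr)
})

test_that("sums of squares partition into between- and within-subject parts", {
  for (seed in c(2, 8, 15)) {
    tab <- make_stats_table(n_per_group = 4, groups = 1:5, seed = seed,
                            group_shift = 0.5, time_shift = -1,
                            interaction_groups = c(3, 4))
    res <- rm_anova(tab, "area_mm2")
    eff <- res$effects
    ss <- function(e) eff$ss[eff$effect == e]
    d <- data.frame(animal = tab$animal, group = factor(tab$group),
                    time = factor(tab$timepoint), y = tab$area_mm2)
    oracle <- rm_anova_oracle(d)
    total <- ss("group") + ss("error:between") + ss("time") +
      ss("group:time") + ss("error:within")
    expect_equal(total, oracle$ss$total, tolerance = 1e-8)
    expect_equal(oracle$ss$between + oracle$ss$within, oracle$ss$total,
                 tolerance = 1e-8)
  }
})

test_that("rm_anova handles degenerate and incomplete input as specified", {
  tab <- make_stats_table(n_per_group = 3, groups = 1:2, seed = 1)
  tab$area_mm2 <- 1  # all identical
  expect_warning(res <- rm_anova(tab, "area_mm2"), "zero")
  expect_true(res$degenerate)
  expect_true(all(is.na(res$effects$F)))
  # listwise exclusion of animals missing a timepoint
  tab2 <- make_stats_table(n_per_group = 4, groups = 1:2, seed = 2)
  tab2 <- tab2[-1, ]  # drop one baseline row
  expect_warning(res2 <- rm_anova(tab2, "area_mm2"), "listwise")
  expect_equal(sum(res2$n_per_group), 7)
  # fewer than two complete animals in a group
  tab3 <- make_stats_table(n_per_group = 1, groups = 1:2, seed = 3)
  expect_error(rm_anova(tab3, "area_mm2"), ">= 2")
})

test_that("rm_anova detects a pure time effect without false group effects", {
  tab <- make_stats_table(n_per_group = 8, groups = 1:3, seed = 6,
                          time_shift = -2, sd = 1)
  res <- rm_anova(tab, "area_mm2")
  eff <- res$effects
  expect_lt(eff$p[eff$effect == "time"], 0.001)
  expect_gt(eff$p[eff$effect == "group"], 0.05)
  expect_gt(eff$p[eff$effect == "group:time"], 0.05)
})

test_that("RM-ANOVA interaction type-I error is calibrated at alpha = 0.05", {
  n_rep <- 400
  rejections <- 0
  with_seed_local(123, {
    for (r in seq_len(n_rep)) {
      y <- rnorm(5 * 4 * 2)
      tab <- data.frame(
        animal = rep(sprintf("a%02d", 1:20), each = 2),
        group = rep(1:5, each = 8),
        timepoint = rep(c("baseline", "h24"), 20),
        protocol = "sparse", phase = "initial_dip", area_mm2 = y
      )
      p <- rm_anova(tab, "area_mm2")$effects
      if (p$p[p$effect == "group:time"] < 0.05) rejections <- rejections + 1
    }
  })
  rate <- rejections / n_rep
  expect_gt(rate, 0.05 - 2.5 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("post hoc contrasts apply both corrections per group", {
  tab <- make_stats_table(n_per_group = 6, groups = 1:5, seed = 9,
                          interaction_groups = c(3, 4), sd = 0.5)
  ct <- posthoc_time_contrasts(tab, "area_mm2")
  expect_equal(nrow(ct), 5)
  expect_true(all(ct$p_bonferroni >= ct$p - 1e-15))
  expect_true(all(ct$p_bonferroni >= ct$p_sidak - 1e-15))
  expect_equal(ct$p_sidak, 1 - (1 - ct$p)^5, tolerance = 1e-12)
  expect_true(all(ct$significant[ct$group %in% c(3, 4)]))
  expect_false(any(ct$significant[ct$group %in% c(1, 2, 5)]))
  expect_error(posthoc_time_contrasts(tab, "area_mm2", correction = "holm"))
})

test_that("baseline equality check requires all five groups and is calibrated", {
  tab <- make_stats_table(n_per_group = 4, groups = 1:5, seed = 10)
  res <- baseline_equality_check(tab, "area_mm2")
  expect_s3_class(res, "baseline_check")
  expect_equal(res$n, 20)
  expect_error(baseline_equality_check(
    make_stats_table(n_per_group = 4, groups = 1:2, seed = 1), "area_mm2"),
    "all 5 groups")
  # null calibration (small Monte Carlo)
  n_rep <- 300
  with_seed_local(31, {
    rej <- 0
    for (r in seq_len(n_rep)) {
      tabr <- data.frame(
        animal = sprintf("a%02d", 1:20), group = rep(1:5, each = 4),
        timepoint = "baseline", protocol = "sparse", phase = "initial_dip",
        area_mm2 = rnorm(20)
      )
      if (baseline_equality_check(tabr, "area_mm2")$p < 0.05) rej <- rej + 1
    }
  })
  expect_lt(abs(rej / n_rep - 0.05), 2.5 * sqrt(0.05 * 0.95 / n_rep))
  # a 5-sd shifted group is detected essentially always: exact noncentral-F
  # power at alpha = 0.001 exceeds 99%, and the Monte-Carlo rate agrees
  ncp <- 4 * sum((c(5, 0, 0, 0, 0) - 1)^2)
  exact_power <- stats::pf(stats::qf(0.999, 4, 15), 4, 15, ncp = ncp,
                           lower.tail = FALSE)
  expect_gte(exact_power, 0.99)
  n_pow <- 100
  with_seed_local(32, {
    hits <- 0
    for (r in seq_len(n_pow)) {
      y <- rnorm(20)
      y[1:4] <- y[1:4] + 5
      tabr <- data.frame(
        animal = sprintf("a%02d", 1:20), group = rep(1:5, each = 4),
        timepoint = "baseline", protocol = "sparse", phase = "initial_dip",
        area_mm2 = y
      )
      if (baseline_equality_check(tabr, "area_mm2")$p < 0.001) hits <- hits + 1
    }
  })
  expect_gte(hits / n_pow, exact_power - 3 * sqrt(exact_power *
                                                    (1 - exact_power) / n_pow))
})

test_that("infarct group tests: null behaviour, power and effect sizes", {
  # identical groups: t ~ 0, p ~ 1
  tab0 <- data.frame(animal = 1:16, group = rep(c(1, 2), each = 8),
                     corrected_volume_mm3 = rep(c(1, 2, 3, 4), 4))
  r0 <- infarct_group_tests(tab0, pairs = list(c(1, 2)))
  expect_equal(r0$t_table$t, 0, tolerance = 1e-12)
  expect_equal(r0$t_table$p, 1, tolerance = 1e-12)
  # N(0,1) vs N(3,1), n = 8: the exact noncentral-t power at two-sided
  # alpha = 0.001 is ~0.93; the Monte-Carlo rejection rate must agree
  ncp <- 3 / sqrt(2 / 8)
  exact_power <- stats::pt(stats::qt(1 - 0.001 / 2, 14), 14, ncp = ncp,
                           lower.tail = FALSE)
  expect_gte(exact_power, 0.9)
  n_pow <- 200
  with_seed_local(41, {
    hits <- 0
    for (r in seq_len(n_pow)) {
      tabr <- data.frame(animal = 1:16, group = rep(c(1, 2), each = 8),
                         corrected_volume_mm3 = c(rnorm(8), rnorm(8, 3)))
      if (infarct_group_tests(tabr,
                              pairs = list(c(1, 2)))$t_table$p < 0.001)
        hits <- hits + 1
    }
  })
  expect_gte(hits / n_pow,
             exact_power - 3 * sqrt(exact_power * (1 - exact_power) / n_pow))
  # zero variance in both groups with equal means is a null result;
  # unequal means error
  tabz <- data.frame(animal = 1:8, group = rep(c(1, 2), each = 4),
                     corrected_volume_mm3 = rep(5, 8))
  expect_equal(infarct_group_tests(tabz,
                                   pairs = list(c(1, 2)))$t_table$p, 1)
  tabz2 <- tabz; tabz2$corrected_volume_mm3[5:8] <- 7
  expect_error(infarct_group_tests(tabz2, pairs = list(c(1, 2))),
               "zero variance")
  expect_error(infarct_group_tests(
    data.frame(animal = 1, group = 1, corrected_volume_mm3 = 1),
    pairs = list(c(1, 2))), ">= 2")
})
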