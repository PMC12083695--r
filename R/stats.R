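#' Multiple-contrast correction (Bonferroni and Sidak closed forms)
#'
#' `bonferroni`: `min(1, p * k)`. `sidak`: `1 - (1 - p)^k`. With `k = 1`
#' both return `p` unchanged; Bonferroni is always at least as
#' conservative as Sidak.
#'
#' @param p Numeric vector of raw p-values.
#' @param k Number of contrasts in the family.
#' @param method `"bonferroni"` or `"sidak"`.
#' @return Corrected p-values.
#' @export
p_adjust_k <- function(p, k, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  if (k < 1) stop("k must be >= 1")
  if (method == "bonferroni") pmin(1, p * k) else 1 - (1 - p)^k
}

# reshape a tidy WFR table to one row per animal x timepoint for one metric
metric_frame <- function(table, response, protocol, phase) {
  d <- table[table$protocol == protocol & table$phase == phase, , drop = FALSE]
  if (nrow(d) == 0)
    stop(sprintf("no rows for protocol '%s', phase '%s'", protocol, phase))
  if (!response %in% names(d)) stop("unknown response: ", response)
  data.frame(animal = d$animal, group = factor(d$group),
             time = factor(d$timepoint, levels = c("baseline", "h24")),
             y = d[[response]])
}

# drop animals missing a timepoint (listwise), with a warning
complete_animals <- function(d) {
  tab <- table(d$animal)
  keep <- names(tab)[tab == 2]
  if (length(keep) < length(tab))
    warning(sprintf("%d animal(s) missing a timepoint excluded (listwise)",
                    length(tab) - length(keep)))
  d[d$animal %in% keep, , drop = FALSE]
}

#' Mixed-design repeated-measures ANOVA (group x time)
#'
#' Fits the study's primary model: one between-subjects factor (group)
#' and one within-subjects factor (time: baseline vs 24 h), via
#' `stats::aov` with an `Error(animal)` stratum. With only two within
#' levels, sphericity holds automatically. Animals missing a timepoint
#' are excluded listwise with a warning; groups with fewer than two
#' complete animals are an error. A dataset with zero variance
#' everywhere is flagged (`degenerate = TRUE`) and F statistics are
#' reported as `NA`.
#'
#' @param table Tidy WFR table (from [quantify_study()]'s `wfr` element)
#'   or any data.frame with columns `animal`, `group`, `timepoint`,
#'   `protocol`, `phase` and the response.
#' @param response Metric column, e.g. `"area_mm2"` or
#'   `"peak_amplitude"`.
#' @param protocol,phase Which rows to analyse.
#' @return Object of class `rm_anova_result`: `effects` data.frame
#'   (effect, df_num, df_den, ss, F, p), `n_per_group`, `response`,
#'   `degenerate`, `sphericity_note`.
#' @export
rm_anova <- function(table, response = "area_mm2", protocol = "sparse",
                     phase = "initial_dip") {
  d <- complete_animals(metric_frame(table, response, protocol, phase))
  n_g <- table(unique(d[c("animal", "group")])$group)
  if (length(n_g) < 2) stop("need >= 2 groups")
  if (any(n_g < 2)) stop("every group needs >= 2 complete animals")
  degenerate <- stats::var(d$y) == 0
  if (degenerate) {
    eff <- data.frame(
      effect = c("group", "time", "group:time"),
      df_num = NA_real_, df_den = NA_real_, ss = 0,
      F = NA_real_, p = NA_real_
    )
    warning("zero between- and within-variance: F undefined")
  } else {
    fit <- stats::aov(y ~ group * time + Error(animal), data = d)
    s <- summary(fit)
    btw <- s[["Error: animal"]][[1]]
    wth <- s[["Error: Within"]][[1]]
    pick <- function(strat, name) {
      i <- match(name, trimws(rownames(strat)))
      err <- nrow(strat)  # residual row is last in each stratum
      data.frame(
        effect = name, df_num = strat$Df[i], df_den = strat$Df[err],
        ss = strat$`Sum Sq`[i], F = strat$`F value`[i], p = strat$`Pr(>F)`[i]
      )
    }
    eff <- rbind(pick(btw, "group"), pick(wth, "time"),
                 pick(wth, "group:time"))
    eff <- rbind(eff, data.frame(
      effect = c("error:between", "error:within"),
      df_num = c(btw$Df[nrow(btw)], wth$Df[nrow(wth)]),
      df_den = NA_real_,
      ss = c(btw$`Sum Sq`[nrow(btw)], wth$`Sum Sq`[nrow(wth)]),
      F = NA_real_, p = NA_real_
    ))
  }
  structure(list(
    effects = eff, n_per_group = as.vector(n_g),
    groups = names(n_g), response = response, protocol = protocol,
    phase = phase, degenerate = degenerate,
    sphericity_note = "two within-subject levels: sphericity holds automatically"
  ), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA (%s, %s, %s): group (between) x time (within)\n",
              x$response, x$protocol, x$phase))
  print(x$effects, row.names = FALSE, digits = 4)
  cat(" ", x$sphericity_note, "\n")
  invisible(x)
}

#' Per-group post hoc baseline vs 24 h contrasts
#'
#' Paired t-test of 24 h minus baseline within each group, with both
#' Bonferroni and Sidak family corrections (family size = number of
#' groups). The default decision column uses the Sidak correction, the
#' less conservative of the two.
#'
#' @inheritParams rm_anova
#' @param correction `"sidak"`, `"bonferroni"` or `"both"` (decision
#'   column then uses Sidak).
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with one row per group: `estimate`
#'   (mean 24 h - baseline), `t`, `df`, `p`, `p_bonferroni`, `p_sidak`,
#'   `significant`.
#' @export
posthoc_time_contrasts <- function(table, response = "area_mm2",
                                   protocol = "sparse",
                                   phase = "initial_dip",
                                   correction = c("sidak", "bonferroni",
                                                  "both"),
                                   alpha = 0.05) {
  correction <- match.arg(correction)
  d <- complete_animals(metric_frame(table, response, protocol, phase))
  groups <- sort(unique(d$group))
  k <- length(groups)
  rows <- lapply(groups, function(g) {
    dg <- d[d$group == g, ]
    wide <- merge(dg[dg$time == "baseline", c("animal", "y")],
                  dg[dg$time == "h24", c("animal", "y")], by = "animal")
    diffs <- wide$y.y - wide$y.x
    if (stats::sd(diffs) == 0) {
      data.frame(group = g, estimate = mean(diffs), t = NA_real_,
                 df = length(diffs) - 1, p = if (all(diffs == 0)) 1 else NA)
    } else {
      tt <- stats::t.test(diffs)
      data.frame(group = g, estimate = mean(diffs),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- p_adjust_k(out$p, k, "bonferroni")
  out$p_sidak <- p_adjust_k(out$p, k, "sidak")
  decision <- if (correction == "bonferroni") out$p_bonferroni else out$p_sidak
  out$significant <- !is.na(decision) & decision < alpha
  attr(out, "correction") <- correction
  attr(out, "alpha") <- alpha
  out
}

#' Baseline equality across the five groups
#'
#' One-way ANOVA of the baseline values across all five groups, with
#' pairwise Bonferroni-corrected contrasts — the design check that no
#' group differed before the intervention.
#'
#' @inheritParams rm_anova
#' @return List of class `baseline_check`: `F`, `df`, `p`, `pairwise`
#'   (Bonferroni-corrected pairwise p matrix), `n`.
#' @export
baseline_equality_check <- function(table, response = "area_mm2",
                                    protocol = "sparse",
                                    phase = "initial_dip") {
  d <- metric_frame(table, response, protocol, phase)
  d <- d[d$time == "baseline", , drop = FALSE]
  present <- sort(unique(as.integer(as.character(d$group))))
  if (!identical(present, 1:5))
    stop("baseline rows for all 5 groups are required (found: ",
         paste(present, collapse = ","), ")")
  fit <- stats::aov(y ~ group, data = d)
  s <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(d$y, d$group, p.adjust.method = "bonferroni")
  structure(list(
    F = s$`F value`[1], df = s$Df, p = s$`Pr(>F)`[1],
    pairwise = pw$p.value, n = nrow(d), response = response
  ), class = "baseline_check")
}

#' @export
print.baseline_check <- function(x, ...) {
  cat(sprintf(
    "baseline equality (%s): F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
    x$response, x$df[1], x$df[2], x$F, x$p, x$n
  ))
  invisible(x)
}

#' Infarct-volume group comparisons
#'
#' Welch two-sample t-tests for the requested group pairs plus a one-way
#' ANOVA across all groups present, with effect sizes (Cohen's d with
#' pooled s.d.; eta squared for the ANOVA). A pooled-variance t-test can
#' be requested instead of Welch.
#'
#' @param table Infarct table (from [quantify_study()]'s `infarct`
#'   element): columns `animal`, `group`, `corrected_volume_mm3`.
#' @param pairs List of length-2 group vectors; default all pairs of
#'   groups present.
#' @param var_equal Use the pooled-variance t-test (default `FALSE`,
#'   Welch).
#' @return List of class `infarct_tests`: `t_table` (pair, t, df, p,
#'   cohens_d), `anova` (F, df, p, eta_sq).
#' @export
infarct_group_tests <- function(table, pairs = NULL, var_equal = FALSE) {
  g <- sort(unique(table$group))
  if (is.null(pairs))
    pairs <- utils::combn(g, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- table$corrected_volume_mm3[table$group == pr[1]]
    y <- table$corrected_volume_mm3[table$group == pr[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 animals in each compared group")
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y))
        return(data.frame(group_a = pr[1], group_b = pr[2], t = 0,
                          df = length(x) + length(y) - 2, p = 1,
                          cohens_d = 0))
      stop("zero variance in both groups with unequal means: t undefined")
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(group_a = pr[1], group_b = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohens_d = if (sp > 0) (mean(x) - mean(y)) / sp else Inf)
  })
  t_table <- do.call(rbind, rows)
  an <- NULL
  if (length(g) >= 2) {
    d <- data.frame(y = table$corrected_volume_mm3, group = factor(table$group))
    s <- summary(stats::aov(y ~ group, data = d))[[1]]
    an <- data.frame(F = s$`F value`[1], df_num = s$Df[1], df_den = s$Df[2],
                     p = s$`Pr(>F)`[1],
                     eta_sq = s$`Sum Sq`[1] / sum(s$`Sum Sq`))
  }
  structure(list(t_table = t_table, anova = an,
                 test = if (var_equal) "pooled t" else "Welch t"),
            class = "infarct_tests")
}

#' @export
print.infarct_tests <- function(x, ...) {
  cat(sprintf("infarct group tests (%s):\n", x$test))
  print(x$t_table, row.names = FALSE, digits = 4)
  if (!is.null(x$anova)) {
    cat("one-way ANOVA:\n")
    print(x$anova, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
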