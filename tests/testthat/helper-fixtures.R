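# Small fixtures shared across test files; everything is generated in code.

# noise-free truth with integer-pixel blob centre, flat baseline and no
# vessels, so forward-model arithmetic is exact
flat_truth <- function(img_px = 33L, amplitudes = c(dip = -5e-4),
                       peak_times = c(dip = 2.5),
                       half_widths = c(dip = 2), noise_sd = 0, ...) {
  signal_truth(
    amplitudes = amplitudes, peak_times = peak_times,
    half_widths = half_widths, img_px = img_px,
    center = c((img_px + 1) %/% 2, (img_px + 1) %/% 2),
    noise_sd = noise_sd, n_vessels = 0L, ...
  )
}

# uniform-baseline variant of baseline_field: n_vessels = 0 keeps the
# smooth modulation; tests that need a strictly constant baseline build
# stacks by hand with this helper instead
constant_stack <- function(value, n, nt, onset, frame_ms = 500,
                           mm_per_pixel = 7 / n) {
  trial_stack(array(value, dim = c(n, n, nt)), frame_ms, onset, mm_per_pixel)
}

# expected dR/R of analysis frame k (1-based from onset) for a truth under
# a protocol: mean of the generating kernel over the five 100 ms mid-times
analysis_frame_kernel <- function(truth, protocol) {
  nt <- (protocol$pre_s + protocol$stim_s + protocol$post_s) * 10
  onset <- protocol$pre_s * 10 + 1
  raw_mids <- (seq_len(nt) - onset + 0.5) * 0.1
  km <- colMeans(matrix(signal_kernel(truth, raw_mids), 5))
  onset_an <- (onset - 1) %/% 5 + 1
  km[onset_an:length(km)]
}

# a Gaussian dR/R blob image (already "smoothed" shape for extent tests)
gaussian_blob <- function(n, amplitude, sigma, center = c((n + 1) / 2,
                                                          (n + 1) / 2)) {
  r <- matrix(seq_len(n), n, n)
  c_ <- t(r)
  amplitude * exp(-((r - center[1])^2 + (c_ - center[2])^2) / (2 * sigma^2))
}

# brute-force mixed-design (one between, one within factor) sums of
# squares: the independent oracle for rm_anova
rm_anova_oracle <- function(d) {
  # d: animal, group, time, y; balanced, complete
  gm <- mean(d$y)
  subj <- aggregate(y ~ animal + group, d, mean)
  grp <- aggregate(y ~ group, d, mean)
  tim <- aggregate(y ~ time, d, mean)
  cell <- aggregate(y ~ group + time, d, mean)
  n_per_g <- table(subj$group)
  stopifnot(length(unique(n_per_g)) == 1)
  n <- unname(n_per_g[1]); g <- length(n_per_g); t_ <- 2
  ss_between_subj <- t_ * sum((subj$y - gm)^2)
  ss_group <- t_ * n * sum((grp$y - gm)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_within <- sum((d$y - subj$y[match(paste(d$animal), paste(subj$animal))])^2)
  ss_time <- g * n * sum((tim$y - gm)^2)
  cell$gmean <- grp$y[match(cell$group, grp$group)]
  cell$tmean <- tim$y[match(cell$time, tim$time)]
  ss_gxt <- n * sum((cell$y - cell$gmean - cell$tmean + gm)^2)
  ss_werr <- ss_within - ss_time - ss_gxt
  df <- list(group = g - 1, subj_err = g * (n - 1), time = t_ - 1,
             gxt = (g - 1) * (t_ - 1), werr = g * (n - 1) * (t_ - 1))
  list(
    F_group = (ss_group / df$group) / (ss_subj_err / df$subj_err),
    F_time = (ss_time / df$time) / (ss_werr / df$werr),
    F_gxt = (ss_gxt / df$gxt) / (ss_werr / df$werr),
    ss = list(group = ss_group, subj_err = ss_subj_err, time = ss_time,
              gxt = ss_gxt, werr = ss_werr,
              between = ss_between_subj, within = ss_within,
              total = sum((d$y - gm)^2)),
    df = df
  )
}

# balanced synthetic long table for the stats module (no imaging involved)
make_stats_table <- function(n_per_group = 4, groups = 1:5, seed = 1,
                             group_shift = 0, time_shift = 0,
                             interaction_groups = integer(), sd = 1) {
  with_seed_local(seed, {
    rows <- list()
    for (g in groups) for (i in seq_len(n_per_group)) {
      a <- sprintf("g%d_a%02d", g, i)
      base <- rnorm(1, mean = g * group_shift, sd = sd)
      shift <- time_shift + if (g %in% interaction_groups) -3 * sd else 0
      for (tp in c("baseline", "h24")) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal = a, group = g, timepoint = tp, protocol = "sparse",
          phase = "initial_dip",
          area_mm2 = base + if (tp == "h24") shift + rnorm(1, sd = sd / 2)
          else rnorm(1, sd = sd / 2)
        )
      }
    }
    do.call(rbind, rows)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
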