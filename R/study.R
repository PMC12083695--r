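#' Five-group pMCAo/lidocaine study design
#'
#' Encodes the experimental design: five groups of `n_per_group` animals,
#' imaged at baseline and 24 h with both whisking protocols, with
#' group-dependent 24 h outcome rules.
#'
#' * group 1 — pMCAo + vehicle (PBS) + 0h stimulation: full recovery, no
#'   infarct;
#' * group 2 — sham + lidocaine + 0h stimulation: full recovery, no
#'   infarct;
#' * group 3 — pMCAo + lidocaine, no stimulation: WFR abolished in the
#'   drug diffusion area; infarct volume a linear function of slit size;
#' * group 4 — pMCAo + lidocaine + 0h stimulation: as group 3;
#' * group 5 — pMCAo + PBS, no stimulation: bimodal outcome, a
#'   `group5_p_protected` fraction of animals structurally protected
#'   (no infarct, partial functional recovery) and the rest sustaining a
#'   large infarct extending beyond the barrel field with an abolished
#'   representation.
#'
#' @param n_per_group Animals per group (default 8; 40 animals total).
#' @param slit_ranges Named list of `c(min, max)` uniform ranges (mm2) for
#'   the per-animal dura-slit size, one per group.
#' @param infarct_intercept,infarct_slope,infarct_noise_sd Linear rule
#'   `volume = intercept + slope * slit + N(0, sd)` (mm3) for groups 3-4.
#' @param group5_p_protected Mixture weight of the structurally protected
#'   group-5 outcome.
#' @param group5_protected_gain Residual 24 h signal gain inside the drug
#'   diffusion area for structurally protected group-5 animals: without
#'   stimulation their functional recovery is only partial even when no
#'   infarct forms (default 0.5).
#' @param group5_volume_mean,group5_volume_sd Large-infarct outcome
#'   distribution (mm3, truncated at 0) for unprotected group-5 animals.
#' @param edema_factor Ipsilateral swelling factor applied to infarcted
#'   brains.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_per_group = 8L,
                         slit_ranges = list(`1` = c(1, 3), `2` = c(1, 3),
                                            `3` = c(0.5, 2.5),
                                            `4` = c(1, 6), `5` = c(1, 3)),
                         infarct_intercept = 5, infarct_slope = 3,
                         infarct_noise_sd = 0.5,
                         group5_p_protected = 0.5,
                         group5_protected_gain = 0.5,
                         group5_volume_mean = 70, group5_volume_sd = 10,
                         edema_factor = 1.08) {
  groups <- data.frame(
    group = 1:5,
    occlusion = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    drug = c("PBS", "lidocaine", "lidocaine", "lidocaine", "PBS"),
    stimulation = c("plus0h", "plus0h", "none", "plus0h", "none"),
    label = c("pMCAo+veh+0h", "sham+lid+0h", "pMCAo+lid+ns",
              "pMCAo+lid+0h", "pMCAo+PBS+ns")
  )
  if (length(slit_ranges) != 5) stop("slit_ranges must cover the 5 groups")
  structure(list(
    groups = groups, n_per_group = as.integer(n_per_group),
    timepoints = c("baseline", "h24"), slit_ranges = slit_ranges,
    infarct_intercept = infarct_intercept, infarct_slope = infarct_slope,
    infarct_noise_sd = infarct_noise_sd,
    group5_p_protected = group5_p_protected,
    group5_protected_gain = group5_protected_gain,
    group5_volume_mean = group5_volume_mean,
    group5_volume_sd = group5_volume_sd,
    edema_factor = edema_factor
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: 5 groups x %d animals, baseline vs 24 h\n",
              x$n_per_group))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Sample the 24 h outcome rule for one group
#'
#' Draws per-animal slit sizes and structural/functional outcomes under
#' the design's group rules (without rasterizing any images). Exposed so
#' the outcome distributions — in particular the bimodal group-5 mixture —
#' can be examined at large n.
#'
#' @param design A [study_design()].
#' @param group Group id (1-5).
#' @param n Number of animals to draw.
#' @param seed Integer seed.
#' @return `data.frame` with `slit_size_mm2`, `protected` (no infarct at
#'   24 h), `infarct_volume_mm3` (intended edema-free volume),
#'   `signal_gain_24h` (24 h signal gain inside the drug diffusion area:
#'   1 full recovery, 0 abolished) and `edema_factor`.
#' @export
draw_group_outcomes <- function(design, group, n, seed = 1L) {
  stopifnot(inherits(design, "study_design"), group %in% 1:5)
  rng <- design$slit_ranges[[as.character(group)]]
  with_seed(seed, {
    slit <- stats::runif(n, rng[1], rng[2])
    if (group %in% c(1, 2)) {
      protected <- rep(TRUE, n)
      vol <- rep(0, n)
      atten <- rep(1, n)
    } else if (group %in% c(3, 4)) {
      protected <- rep(FALSE, n)
      vol <- pmax(0, design$infarct_intercept + design$infarct_slope * slit +
                    stats::rnorm(n, sd = design$infarct_noise_sd))
      atten <- rep(0, n)
    } else {
      protected <- stats::runif(n) < design$group5_p_protected
      vol <- ifelse(protected, 0,
                    pmax(0, stats::rnorm(n, design$group5_volume_mean,
                                         design$group5_volume_sd)))
      # structurally protected group-5 animals still show partial
      # functional impairment at 24 h (no stimulation was delivered)
      atten <- ifelse(protected, design$group5_protected_gain, 0)
    }
    data.frame(
      slit_size_mm2 = slit, protected = protected,
      infarct_volume_mm3 = vol, signal_gain_24h = atten,
      edema_factor = ifelse(vol > 0, design$edema_factor, 1)
    )
  })
}

#' Generate a synthetic study
#'
#' Draws every animal's ground truth (group assignment, slit size, 24 h
#' outcome, per-animal seeds) deterministically from the master seed.
#' Image blocks and TTC series are materialized per animal on demand via
#' [simulate_animal()], keeping the memory footprint of a full study
#' small; [quantify_study()] and [cmd_simulate()] drive that
#' materialization.
#'
#' @param design A [study_design()].
#' @param seed Master integer seed; identical `(design, seed)` yield
#'   identical studies.
#' @param groups Subset of group ids to generate (default all five).
#' @param img_px Imaging field size in pixels (7 mm field of view;
#'   `mm_per_pixel = 7 / img_px`).
#' @param n_trials Named vector: trials generated per block for each
#'   protocol (simulation size; the nominal acquisition block sizes of
#'   64/40 stay in the protocol metadata).
#' @param noise_sd Fractional frame noise s.d. (per pixel per 100 ms).
#' @return Object of class `isoi_study`: the design, parameters and an
#'   `animals` ground-truth table.
#' @export
make_study <- function(design, seed = 1L, groups = 1:5, img_px = 64L,
                       n_trials = c(sparse = 4L, condensed = 4L),
                       noise_sd = 3e-3) {
  stopifnot(inherits(design, "study_design"))
  if (!all(groups %in% 1:5)) stop("groups must be within 1:5")
  n <- design$n_per_group
  tabs <- list()
  seeds <- with_seed(seed, {
    outcome_seeds <- sample.int(.Machine$integer.max - 1L, 5)
    animal_seeds <- sample.int(.Machine$integer.max - 1L, 5 * n)
    list(outcome = outcome_seeds, animal = animal_seeds)
  })
  for (g in groups) {
    out <- draw_group_outcomes(design, g, n, seed = seeds$outcome[g])
    out$group <- g
    out$animal <- sprintf("g%d_a%02d", g, seq_len(n))
    out$seed <- seeds$animal[(g - 1L) * n + seq_len(n)]
    tabs[[length(tabs) + 1L]] <- out
  }
  animals <- do.call(rbind, tabs)
  rownames(animals) <- NULL
  structure(list(
    design = design, master_seed = as.integer(seed), groups = groups,
    img_px = as.integer(img_px), mm_per_pixel = 7 / img_px,
    n_trials = n_trials, noise_sd = noise_sd,
    animals = animals[, c("animal", "group", "slit_size_mm2", "protected",
                          "signal_gain_24h", "infarct_volume_mm3",
                          "edema_factor", "seed")]
  ), class = "isoi_study")
}

#' @export
print.isoi_study <- function(x, ...) {
  cat(sprintf(
    "isoi_study: %d animals (groups %s), %d px field (%.3f mm/px), seed %d\n",
    nrow(x$animals), paste(x$groups, collapse = ","), x$img_px,
    x$mm_per_pixel, x$master_seed
  ))
  cat(sprintf("  trials/block: sparse %d, condensed %d; frame noise sd %g\n",
              x$n_trials[["sparse"]], x$n_trials[["condensed"]], x$noise_sd))
  invisible(x)
}

#' @export
summary.isoi_study <- function(object, ...) {
  a <- object$animals
  agg <- do.call(rbind, lapply(split(a, a$group), function(d) data.frame(
    group = d$group[1], n = nrow(d),
    protected = sum(d$protected),
    mean_slit_mm2 = mean(d$slit_size_mm2),
    mean_infarct_mm3 = mean(d$infarct_volume_mm3)
  )))
  rownames(agg) <- NULL
  agg
}

# ROI geometry for a simulated animal: slit rectangle at the blob centre,
# drug-diffusion disc covering the suprathreshold blob, analysis ROI a
# margin beyond the diffusion disc.
study_geometry <- function(study, slit_mm2) {
  img_px <- study$img_px
  mpp <- study$mm_per_pixel
  center <- c((img_px + 1) / 2, (img_px + 1) / 2)
  sigma <- 0.55 / mpp
  slit_px <- slit_mm2 / mpp^2
  slit_h <- sqrt(slit_px / 3)
  slit_w <- 3 * slit_h
  slit <- rect_mask(img_px, center, slit_h, slit_w)
  half_diag <- sqrt(slit_h^2 + slit_w^2) / 2
  block_r <- max(2.2 * sigma, half_diag + 1)
  roi_r <- block_r + 3
  if (roi_r > (img_px - 1) / 2)
    stop("ROI exceeds image bounds; increase img_px or reduce slit size")
  block <- disc_mask(img_px, center, block_r)
  roi <- disc_mask(img_px, center, roi_r)
  list(center = center, sigma = sigma, slit = slit, block = block, roi = roi)
}

#' Materialize one animal's raw artifacts
#'
#' Generates the animal's four image blocks (sparse/condensed at
#' baseline/24 h), its TTC slice series and its ROI set from the study's
#' ground truth, deterministically from the animal's derived seed.
#' Attenuated 24 h representations carry a block mask over the drug
#' diffusion disc with the animal's `signal_gain_24h` (0 = abolished);
#' fully recovered animals reuse the baseline generative parameters
#' (fresh noise only).
#'
#' @param study An [make_study()] object.
#' @param animal Animal id (string from `study$animals$animal`) or row
#'   index.
#' @return List: `blocks` (nested `sparse`/`condensed` x
#'   `baseline`/`h24` lists of [trial_stack()]s), `ttc` (slice list with
#'   ground-truth attribute), `rois` ([roi_set()]), `info` (the animal's
#'   ground-truth row).
#' @export
simulate_animal <- function(study, animal) {
  stopifnot(inherits(study, "isoi_study"))
  if (is.character(animal)) {
    i <- match(animal, study$animals$animal)
    if (is.na(i)) stop("unknown animal id: ", animal)
  } else i <- animal
  info <- study$animals[i, ]
  geo <- study_geometry(study, info$slit_size_mm2)
  sub_seeds <- with_seed(info$seed, sample.int(.Machine$integer.max - 1L, 6))
  gain <- info$signal_gain_24h
  block_mask <- if (gain >= 1) NULL else geo$block
  truths <- list(
    sparse = list(
      baseline = signal_truth(img_px = study$img_px,
                              noise_sd = study$noise_sd,
                              field_seed = sub_seeds[6]),
      h24 = signal_truth(img_px = study$img_px, noise_sd = study$noise_sd,
                         field_seed = sub_seeds[6], block_mask = block_mask,
                         block_gain = gain)
    ),
    condensed = list(
      baseline = condensed_truth(img_px = study$img_px,
                                 noise_sd = study$noise_sd,
                                 field_seed = sub_seeds[6]),
      h24 = condensed_truth(img_px = study$img_px, noise_sd = study$noise_sd,
                            field_seed = sub_seeds[6],
                            block_mask = block_mask, block_gain = gain)
    )
  )
  blocks <- list()
  k <- 1L
  for (proto in c("sparse", "condensed")) {
    p <- isoi_protocol(proto)
    blocks[[proto]] <- list()
    for (tp in c("baseline", "h24")) {
      blocks[[proto]][[tp]] <- make_block(
        p, truths[[proto]][[tp]],
        n_trials = study$n_trials[[proto]], seed = sub_seeds[k]
      )
      k <- k + 1L
    }
  }
  tt <- ttc_truth(
    volume_mm3 = info$infarct_volume_mm3,
    edema_factor = info$edema_factor,
    surgical_site = study$design$groups$occlusion[info$group],
    spread = if (info$group == 5 && info$infarct_volume_mm3 > 0)
      "extended" else "focal"
  )
  list(
    blocks = blocks,
    ttc = make_ttc_series(tt, seed = sub_seeds[5]),
    rois = roi_set(geo$roi, geo$slit,
                   provenance = "synthetic: disc around slit footprint"),
    info = info
  )
}

#' Quantify a whole simulated study
#'
#' Materializes each animal in turn ([simulate_animal()]), runs the WFR
#' quantification ([quantify_animal()]) and the TTC volumetry
#' ([infarct_volume()]), and assembles the tidy study tables feeding the
#' statistics module.
#'
#' @param study An [make_study()] object.
#' @param what `"both"`, `"wfr"` or `"infarct"`.
#' @param half_width Smoothing kernel half-width (px).
#' @param verbose Print progress.
#' @return List of class `study_tables`: `wfr` (long per
#'   animal/timepoint/protocol/phase metric rows, with slit sizes) and
#'   `infarct` (one row per animal with volumes and slit size).
#' @export
quantify_study <- function(study, what = c("both", "wfr", "infarct"),
                           half_width = 5, verbose = FALSE) {
  what <- match.arg(what)
  wfr <- list()
  inf <- list()
  for (i in seq_len(nrow(study$animals))) {
    info <- study$animals[i, ]
    art <- simulate_animal(study, i)
    if (what != "infarct") {
      rows <- quantify_animal(art$blocks, art$rois, animal = info$animal,
                              group = info$group, half_width = half_width)
      rows$slit_size_mm2 <- info$slit_size_mm2
      wfr[[length(wfr) + 1L]] <- rows
    }
    if (what != "wfr") {
      res <- infarct_volume(art$ttc)
      inf[[length(inf) + 1L]] <- data.frame(
        animal = info$animal, group = info$group,
        slit_size_mm2 = info$slit_size_mm2,
        raw_volume_mm3 = res$raw_volume_mm3,
        ipsi_hemisphere_volume_mm3 = res$ipsi_hemisphere_volume_mm3,
        contra_hemisphere_volume_mm3 = res$contra_hemisphere_volume_mm3,
        corrected_volume_mm3 = res$corrected_volume_mm3,
        true_volume_mm3 = info$infarct_volume_mm3
      )
    }
    if (verbose) message("quantified ", info$animal)
  }
  structure(list(
    wfr = if (length(wfr)) do.call(rbind, wfr) else NULL,
    infarct = if (length(inf)) do.call(rbind, inf) else NULL
  ), class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("study_tables: %s WFR rows, %s infarct rows\n",
              if (is.null(x$wfr)) 0 else nrow(x$wfr),
              if (is.null(x$infarct)) 0 else nrow(x$infarct)))
  invisible(x)
}
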