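#' Simulate a study dataset on disk
#'
#' Writes, under `cfg$out_dir`: per-animal multi-page TIFF trial stacks
#' with JSON sidecars (`animals/<id>/<protocol>_<timepoint>/trialNNN.tif`),
#' TTC slice PNGs, ROI/slit mask PNGs, the ground-truth table
#' (`ground_truth.csv`) and a manifest (seeds, configuration, package
#' version, per-file MD5 hashes).
#'
#' @param cfg A `run_config` (see [default_config()]).
#' @return Invisibly, the manifest list.
#' @export
cmd_simulate <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  study <- config_study(cfg)
  root <- cfg$out_dir
  if (!dir.exists(root) && !dir.create(root, recursive = TRUE))
    stop("cannot create output dir: ", root)
  if (file.access(root, 2) != 0) stop("output dir not writable: ", root)
  files <- character()
  for (i in seq_len(nrow(study$animals))) {
    info <- study$animals[i, ]
    art <- simulate_animal(study, i)
    adir <- file.path(root, "animals", info$animal)
    for (proto in names(art$blocks)) {
      for (tp in names(art$blocks[[proto]])) {
        bdir <- file.path(adir, paste0(proto, "_", tp))
        dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
        blk <- art$blocks[[proto]][[tp]]
        for (j in seq_along(blk)) {
          f <- file.path(bdir, sprintf("trial%03d.tif", j))
          write_trial_stack(blk[[j]], f)
          files <- c(files, f)
        }
      }
    }
    tdir <- file.path(adir, "ttc")
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(art$ttc)) {
      f <- file.path(tdir, sprintf("slice%02d.png", j))
      write_ttc_slice(art$ttc[[j]], f)
      files <- c(files, f)
    }
    write_mask_png(art$rois$analysis_roi, file.path(adir, "roi.png"))
    write_mask_png(art$rois$slit_mask, file.path(adir, "slit.png"))
    files <- c(files, file.path(adir, "roi.png"), file.path(adir, "slit.png"))
    log_msg(cfg, "INFO", "simulated ", info$animal)
  }
  utils::write.csv(study$animals, file.path(root, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("isoistroke")),
    seed = cfg$seed, config = unclass(cfg),
    n_animals = nrow(study$animals),
    files = lapply(stats::setNames(files, nm = sub(paste0("^", root, "/?"),
                                                   "", files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Quantify a simulated dataset from disk
#'
#' Reads the trial stacks, TTC slices and masks written by
#' [cmd_simulate()], runs the WFR and infarct pipelines per animal and
#' writes `wfr_metrics.csv` / `infarct_volumes.csv` under `cfg$out_dir`.
#' Every row carries the thresholds, smoothing kernel and calibration
#' that produced it. Animals with missing masks are skipped with a
#' warning.
#'
#' @param cfg A `run_config`; `cfg$out_dir` must contain a simulated
#'   dataset.
#' @param protocols Protocols to quantify (default both).
#' @return Invisibly, a `study_tables` list (`wfr`, `infarct`).
#' @export
cmd_quantify <- function(cfg = default_config(),
                         protocols = c("sparse", "condensed")) {
  cfg <- validate_config(cfg)
  root <- cfg$out_dir
  gt <- utils::read.csv(file.path(root, "ground_truth.csv"))
  thresholds <- list(initial_dip = cfg$threshold_dip,
                     overshoot = cfg$threshold_overshoot,
                     condensed_dip = cfg$threshold_condensed)
  wfr <- list(); inf <- list()
  for (i in seq_len(nrow(gt))) {
    info <- gt[i, ]
    adir <- file.path(root, "animals", info$animal)
    roi_f <- file.path(adir, "roi.png")
    slit_f <- file.path(adir, "slit.png")
    if (!file.exists(roi_f) || !file.exists(slit_f)) {
      warning("missing mask(s) for ", info$animal, ": skipped")
      next
    }
    rois <- roi_set(read_mask_png(roi_f), read_mask_png(slit_f),
                    provenance = "mask PNGs from simulated dataset")
    blocks <- list()
    for (proto in protocols) {
      blocks[[proto]] <- list()
      for (tp in c("baseline", "h24")) {
        bdir <- file.path(adir, paste0(proto, "_", tp))
        tifs <- sort(list.files(bdir, pattern = "\\.tif$",
                                full.names = TRUE))
        blocks[[proto]][[tp]] <- lapply(tifs, read_trial_stack)
      }
    }
    rows <- quantify_animal(blocks, rois, animal = info$animal,
                            group = info$group,
                            half_width = cfg$half_width,
                            thresholds = thresholds)
    rows$slit_size_mm2 <- info$slit_size_mm2
    wfr[[length(wfr) + 1L]] <- rows
    slice_fs <- sort(list.files(file.path(adir, "ttc"),
                                pattern = "^slice[0-9]+\\.png$",
                                full.names = TRUE))
    slices <- lapply(slice_fs, read_ttc_slice)
    res <- infarct_volume(slices)
    inf[[length(inf) + 1L]] <- data.frame(
      animal = info$animal, group = info$group,
      slit_size_mm2 = info$slit_size_mm2,
      raw_volume_mm3 = res$raw_volume_mm3,
      ipsi_hemisphere_volume_mm3 = res$ipsi_hemisphere_volume_mm3,
      contra_hemisphere_volume_mm3 = res$contra_hemisphere_volume_mm3,
      corrected_volume_mm3 = res$corrected_volume_mm3
    )
    log_msg(cfg, "INFO", "quantified ", info$animal)
  }
  out <- structure(list(wfr = do.call(rbind, wfr),
                        infarct = do.call(rbind, inf)),
                   class = "study_tables")
  utils::write.csv(out$wfr, file.path(root, "wfr_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(out$infarct, file.path(root, "infarct_volumes.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Run the statistical battery on quantified tables
#'
#' Runs, for each protocol/phase/metric family: the group x time
#' RM-ANOVA and post hoc contrasts; plus the baseline-equality one-way
#' ANOVA, infarct t-tests/ANOVA and the groups 3 and 4 slit-size
#' regressions. Writes a machine-readable `stats_report.json` and a
#' human-readable `stats_report.txt` under `cfg$out_dir`.
#'
#' @param cfg A `run_config`; `cfg$out_dir` must contain
#'   `wfr_metrics.csv` and `infarct_volumes.csv` (from [cmd_quantify()])
#'   unless `tables` is supplied.
#' @param tables Optional in-memory `study_tables` list.
#' @return Invisibly, the report list.
#' @export
cmd_stats <- function(cfg = default_config(), tables = NULL) {
  cfg <- validate_config(cfg)
  root <- cfg$out_dir
  if (is.null(tables)) {
    wfr_f <- file.path(root, "wfr_metrics.csv")
    inf_f <- file.path(root, "infarct_volumes.csv")
    if (!file.exists(wfr_f) || !file.exists(inf_f))
      stop("quantification tables not found under ", root,
           "; run cmd_quantify() first")
    tables <- list(wfr = utils::read.csv(wfr_f),
                   infarct = utils::read.csv(inf_f))
  }
  families <- unique(tables$wfr[c("protocol", "phase")])
  report <- list(alpha = cfg$alpha, correction = cfg$correction,
                 families = list())
  for (i in seq_len(nrow(families))) {
    proto <- families$protocol[i]; ph <- families$phase[i]
    fam <- list()
    for (resp in c("area_mm2", "peak_amplitude")) {
      an <- tryCatch(
        rm_anova(tables$wfr, resp, proto, ph),
        error = function(e) e$message
      )
      ct <- if (is.character(an)) NULL else
        posthoc_time_contrasts(tables$wfr, resp, proto, ph,
                               correction = cfg$correction,
                               alpha = cfg$alpha)
      fam[[resp]] <- list(
        rm_anova = if (is.character(an)) an else an$effects,
        contrasts = ct
      )
    }
    bl <- tryCatch(
      baseline_equality_check(tables$wfr, "area_mm2", proto, ph),
      error = function(e) e$message
    )
    fam$baseline_equality <- if (is.character(bl)) bl else
      list(F = bl$F, p = bl$p)
    report$families[[paste(proto, ph, sep = ".")]] <- fam
  }
  report$infarct <- tryCatch(
    unclass(infarct_group_tests(tables$infarct)),
    error = function(e) e$message
  )
  for (g in c(3, 4)) {
    key <- paste0("slit_regression_g", g)
    report[[key]] <- tryCatch({
      r <- slit_regression(tables$infarct, groups = g)
      list(slope = r$slope, intercept = r$intercept,
           r_squared = r$r_squared, p_value = r$p_value,
           conf_int = r$conf_int, n = r$n)
    }, error = function(e) e$message)
  }
  if (!is.null(root) && dir.exists(root)) {
    jsonlite::write_json(report, file.path(root, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    txt <- file.path(root, "stats_report.txt")
    sink(txt); on.exit(sink(), add = TRUE)
    cat("isoistroke statistical report\n")
    cat("alpha =", cfg$alpha, "; correction =", cfg$correction, "\n\n")
    utils::str(report, max.level = 3, give.attr = FALSE)
  }
  invisible(report)
}
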