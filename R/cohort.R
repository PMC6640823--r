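#' Default cohort specification
#'
#' Study design and ground-truth parameter trajectories for the synthetic
#' cohort. Group sizes per week follow the study design (AMC 3/4/4/6 and
#' MI 3/3/3/6 animals at weeks 1/2/4/16). The channel-4 short-lifetime
#' trajectory in the infarct region rises in MI hearts from 303 +/- 89 ps at
#' week 1 to 566 +/- 57 ps at week 16 while staying near 410 ps in controls;
#' in remote regions the MI short lifetime sits consistently below control.
#' Mean-lifetime trajectories rise with time post-infarction in the infarct
#' scar (collagen deposition) and the reflectance chromophore mixture shifts
#' from the oxyhemoglobin/oxymyoglobin double peak towards reduced
#' cytochrome c in remote regions. Printed +/- SD values are treated as
#' between-animal SDs; within-measurement SD defaults to 30% of the
#' between-animal SD.
#'
#' @param within_frac within-measurement SD as a fraction of the
#'   between-animal SD.
#' @return a `cohort_spec` list with `group_sizes`, `params` (long table of
#'   trajectories), and `within_frac`.
#' @export
default_cohort_spec <- function(within_frac = 0.3) {
  group_sizes <- data.frame(week = c(1, 2, 4, 16),
                            AMC = c(3, 4, 4, 6), MI = c(3, 3, 3, 6))
  weeks <- c(1, 2, 4, 16)
  traj <- function(group, roi, parameter, mean, sd_between) {
    data.frame(group = group, roi = roi, week = weeks, parameter = parameter,
               mean = mean, sd_between = sd_between,
               stringsAsFactors = FALSE)
  }
  rois <- c("RV", "LVP", "LVA")
  rows <- list()
  for (roi in rois) {
    # channel 1: single-exponential lifetime (ns); rises steeply in the scar
    if (roi == "LVA") {
      rows <- c(rows,
                list(traj("AMC", roi, "tau_ch1", rep(2.6, 4), rep(0.4, 4)),
                     traj("MI", roi, "tau_ch1", c(1.8, 2.4, 3.3, 4.2),
                          c(0.8, 0.9, 1.0, 0.9))))
    } else {
      rows <- c(rows,
                list(traj("AMC", roi, "tau_ch1", rep(2.6, 4), rep(0.4, 4)),
                     traj("MI", roi, "tau_ch1", c(2.7, 2.8, 2.9, 2.9),
                          rep(0.5, 4))))
    }
    # channel 2 double-exponential (NAD(P)H band)
    rows <- c(rows, list(
      traj("AMC", roi, "tau1_ch2", rep(0.40, 4), rep(0.06, 4)),
      traj("AMC", roi, "tau2_ch2", rep(2.8, 4), rep(0.3, 4)),
      traj("AMC", roi, "afrac1_ch2", rep(0.70, 4), rep(0.05, 4))))
    if (roi == "LVA") {
      rows <- c(rows, list(
        traj("MI", roi, "tau1_ch2", c(0.42, 0.47, 0.55, 0.65),
             rep(0.08, 4)),
        traj("MI", roi, "tau2_ch2", c(2.9, 3.6, 4.3, 5.2), rep(0.5, 4)),
        traj("MI", roi, "afrac1_ch2", c(0.68, 0.64, 0.60, 0.55),
             rep(0.05, 4))))
    } else {
      rows <- c(rows, list(
        traj("MI", roi, "tau1_ch2", rep(0.42, 4), rep(0.07, 4)),
        traj("MI", roi, "tau2_ch2", c(2.9, 3.0, 3.1, 3.1), rep(0.4, 4)),
        traj("MI", roi, "afrac1_ch2", rep(0.68, 4), rep(0.05, 4))))
    }
    # channel 3 mirrors channel 2 (mixed collagen/NAD(P)H/FAD band; fitted
    # but excluded from default reports)
    rows <- c(rows, list(
      traj("AMC", roi, "tau1_ch3", rep(0.45, 4), rep(0.06, 4)),
      traj("AMC", roi, "tau2_ch3", rep(2.9, 4), rep(0.3, 4)),
      traj("AMC", roi, "afrac1_ch3", rep(0.68, 4), rep(0.05, 4)),
      traj("MI", roi, "tau1_ch3", rep(0.47, 4), rep(0.07, 4)),
      traj("MI", roi, "tau2_ch3", c(3.0, 3.1, 3.2, 3.3), rep(0.4, 4)),
      traj("MI", roi, "afrac1_ch3", rep(0.66, 4), rep(0.05, 4))))
    # channel 4 (FAD band): the headline short-lifetime trajectory
    rows <- c(rows, list(
      traj("AMC", roi, "tau1_ch4", rep(0.410, 4), rep(0.060, 4)),
      traj("AMC", roi, "tau2_ch4", rep(2.7, 4), rep(0.15, 4)),
      traj("AMC", roi, "afrac1_ch4", rep(0.75, 4), rep(0.04, 4))))
    if (roi == "LVA") {
      rows <- c(rows, list(
        traj("MI", roi, "tau1_ch4", c(0.303, 0.360, 0.430, 0.566),
             c(0.089, 0.080, 0.070, 0.057)),
        traj("MI", roi, "tau2_ch4", c(2.7, 2.75, 2.8, 2.9), rep(0.15, 4)),
        traj("MI", roi, "afrac1_ch4", rep(0.75, 4), rep(0.04, 4))))
    } else {
      rows <- c(rows, list(
        traj("MI", roi, "tau1_ch4", c(0.330, 0.340, 0.350, 0.390),
             rep(0.060, 4)),
        traj("MI", roi, "tau2_ch4", c(2.7, 2.75, 2.8, 2.8), rep(0.15, 4)),
        traj("MI", roi, "afrac1_ch4", rep(0.75, 4), rep(0.04, 4))))
    }
    # reflectance chromophore weights
    rows <- c(rows, list(
      traj("AMC", roi, "w_oxy", rep(1.0, 4), rep(0.10, 4)),
      traj("AMC", roi, "w_cytc", rep(0.10, 4), rep(0.03, 4)),
      traj("AMC", roi, "w_deoxy", rep(0.20, 4), rep(0.05, 4))))
    if (roi == "LVA") {
      rows <- c(rows, list(
        traj("MI", roi, "w_oxy", rep(0.60, 4), rep(0.08, 4)),
        traj("MI", roi, "w_cytc", rep(0.10, 4), rep(0.03, 4)),
        traj("MI", roi, "w_deoxy", rep(0.15, 4), rep(0.04, 4))))
    } else {
      rows <- c(rows, list(
        traj("MI", roi, "w_oxy", c(1.0, 0.85, 0.70, 0.50), rep(0.10, 4)),
        traj("MI", roi, "w_cytc", c(0.15, 0.35, 0.55, 0.90), rep(0.08, 4)),
        traj("MI", roi, "w_deoxy", rep(0.20, 4), rep(0.05, 4))))
    }
  }
  structure(list(group_sizes = group_sizes,
                 params = do.call(rbind, rows),
                 within_frac = within_frac),
            class = "cohort_spec")
}

# truncated-normal draw: resample until >= 10% of the mean (floor at 0);
# guards against non-physical negative lifetimes/intensities/weights
rtruncnorm_floor <- function(n, mean, sd) {
  lo <- pmax(0.1 * mean, 0)
  out <- stats::rnorm(n, mean, sd)
  for (tries in 1:100) {
    bad <- out < lo
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lo)
}

#' Generate a synthetic study cohort
#'
#' For each animal, draws per-region ground-truth parameter values from the
#' trajectory means (between-animal SD), then for each of the 9 measurements
#' (3 positions x 3 repeats) draws measurement-level values (within SD =
#' `within_frac` x between SD), and simulates the corresponding TCSPC
#' histograms and reflectance spectra. Every animal and measurement uses its
#' own random sub-stream, so outputs are reproducible and independent across
#' units.
#'
#' @param spec a `cohort_spec` (default [default_cohort_spec()]).
#' @param config a [sim_config()].
#' @param seed base integer seed.
#' @param channels detection channels to simulate histograms for.
#' @param rois regions of interest to simulate.
#' @return a `cohort` list: `manifest` (one row per measurement),
#'   `histograms` (named list keyed `measurement_id.chN`), `spectra` (named
#'   list of `sample` spectra keyed by measurement id), `reference` lamp
#'   spectrum, `irfs` (per channel), `ground_truth` (animal-level true
#'   values), `measurement_truth` (measurement-level true values), plus the
#'   `spec`, `config` and `seed` used.
#' @export
generate_cohort <- function(spec = default_cohort_spec(),
                            config = sim_config(), seed = 1L,
                            channels = 1:4,
                            rois = c("RV", "LVP", "LVA")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$group_sizes$AMC < 2) || any(spec$group_sizes$MI < 2))
    stop("group sizes must be >= 2", call. = FALSE)
  if (any(spec$params$sd_between < 0))
    stop("between-animal SDs must be >= 0", call. = FALSE)
  irfs <- lapply(channels, function(ch)
    simulate_irf(config, seed = substream(seed, 900, ch), channel = ch))
  if (length(irfs)) names(irfs) <- paste0("ch", channels)

  manifest <- list(); gt <- list(); mt <- list()
  histograms <- list(); spectra <- list()
  animal_counter <- 0L
  for (gi in seq_along(c("AMC", "MI"))) {
    group <- c("AMC", "MI")[gi]
    for (wi in seq_len(nrow(spec$group_sizes))) {
      week <- spec$group_sizes$week[wi]
      n_animals <- spec$group_sizes[[group]][wi]
      for (ai in seq_len(n_animals)) {
        animal_counter <- animal_counter + 1L
        animal_id <- sprintf("%s_w%02d_a%d", group, week, ai)
        for (roi in rois) {
          tr <- spec$params[spec$params$group == group &
                              spec$params$week == week &
                              spec$params$roi == roi, ]
          if (nrow(tr) == 0L)
            stop(sprintf("spec has no trajectories for %s/%s/week %s",
                         group, roi, week), call. = FALSE)
          roi_i <- match(roi, c("RV", "LVP", "LVA"))
          set.seed(substream(seed, gi, wi, ai, roi_i, 1))
          animal_true <- stats::setNames(
            rtruncnorm_floor(nrow(tr), tr$mean, tr$sd_between),
            tr$parameter)
          gt[[length(gt) + 1L]] <- data.frame(
            animal_id = animal_id, group = group, week = week, roi = roi,
            parameter = tr$parameter, true_value = unname(animal_true),
            stringsAsFactors = FALSE)
          meas_i <- 0L
          for (pos in 1:3) for (rep_i in 1:3) {
            meas_i <- meas_i + 1L
            mid <- sprintf("%s_%s_p%d_r%d", animal_id, roi, pos, rep_i)
            set.seed(substream(seed, gi, wi, ai, roi_i, 2, meas_i))
            sd_w <- spec$within_frac * tr$sd_between
            meas_true <- stats::setNames(
              rtruncnorm_floor(nrow(tr), animal_true, sd_w), tr$parameter)
            mt[[length(mt) + 1L]] <- data.frame(
              measurement_id = mid, animal_id = animal_id, group = group,
              week = week, roi = roi, position = pos, rep = rep_i,
              parameter = tr$parameter, true_value = unname(meas_true),
              stringsAsFactors = FALSE)
            manifest[[length(manifest) + 1L]] <- data.frame(
              measurement_id = mid, animal_id = animal_id, group = group,
              week = week, roi = roi, position = pos, rep = rep_i,
              stringsAsFactors = FALSE)
            for (ch in channels) {
              tp <- if (ch == 1L) {
                decay_params(alpha = 1, tau_ns = meas_true[["tau_ch1"]])
              } else {
                a1 <- meas_true[[sprintf("afrac1_ch%d", ch)]]
                a1 <- min(max(a1, 0.05), 0.95)
                t1 <- meas_true[[sprintf("tau1_ch%d", ch)]]
                t2 <- max(meas_true[[sprintf("tau2_ch%d", ch)]], t1 * 1.2)
                decay_params(alpha = c(a1, 1 - a1), tau_ns = c(t1, t2))
              }
              histograms[[paste0(mid, ".ch", ch)]] <- simulate_decay(
                tp, irfs[[paste0("ch", ch)]], config,
                seed = substream(seed, gi, wi, ai, roi_i, 3, meas_i, ch),
                channel = ch)
            }
            refl <- simulate_reflectance(
              c(oxy = meas_true[["w_oxy"]], cytc = meas_true[["w_cytc"]],
                deoxy = meas_true[["w_deoxy"]]),
              seed = substream(seed, gi, wi, ai, roi_i, 4, meas_i))
            refl$sample$meta <- c(refl$sample$meta,
                                  list(measurement_id = mid))
            spectra[[mid]] <- refl$sample
            reference <- refl$reference
          }
        }
      }
    }
  }
  structure(list(manifest = do.call(rbind, manifest),
                 histograms = histograms, spectra = spectra,
                 reference = reference, irfs = irfs,
                 ground_truth = do.call(rbind, gt),
                 measurement_truth = do.call(rbind, mt),
                 spec = spec, config = config, seed = seed,
                 channels = channels, rois = rois),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d animals, %d measurements, %d histograms, %d spectra (seed %d)\n",
    length(unique(x$manifest$animal_id)), nrow(x$manifest),
    length(x$histograms), length(x$spectra), x$seed))
  invisible(x)
}

#' Write a cohort to a directory of plain-text fixtures
#'
#' Layout: `histograms/*.csv`, `irf/*.csv`, `spectra/*.csv`,
#' `manifest.csv`, `ground_truth.csv`, `config.json`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (d in file.path(dir, c("histograms", "irf", "spectra")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$histograms))
    write_histogram(cohort$histograms[[nm]],
                    file.path(dir, "histograms", paste0(nm, ".csv")))
  for (nm in names(cohort$irfs))
    write_histogram(cohort$irfs[[nm]],
                    file.path(dir, "irf", paste0("irf_", nm, ".csv")))
  for (nm in names(cohort$spectra))
    write_spectrum(cohort$spectra[[nm]],
                   file.path(dir, "spectra", paste0(nm, ".csv")))
  write_spectrum(cohort$reference, file.path(dir, "spectra", "reference.csv"))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$seed <- cohort$seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
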