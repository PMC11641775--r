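# End-to-end study pipeline: simulate -> analyze -> compare -> report.

#' Default configuration of a full synthetic study
#'
#' Encodes the study design the pipeline emulates: four lighting conditions
#' with eight animals each recorded for twelve days, and — for the imaging
#' arm — four sacrifice time points (ZT/CT 0, 6, 12, 18) with eight fields per
#' condition/time-point cell for each of three presynaptic/postsynaptic
#' marker pairs. The per-condition simulation blocks (period, activity-phase
#' duration, activity rates, mid-activity break, arrhythmic fraction under
#' constant light) and the per-time-point puncta abundances and colocalized
#' fractions are the generator's definition of the study conditions; the
#' methods vignette documents the reasoning behind each value.
#'
#' @param master_seed Master seed; every stochastic stage derives its own
#'   seed from it via [derive_seed()].
#' @return A nested configuration list (class `study_config`), serializable
#'   with [write_study_config()].
#' @export
default_study_config <- function(master_seed = 1L) {
  tp <- c(0, 6, 12, 18)
  cfg <- list(
    master_seed = as.integer(master_seed),
    lights_on_clock = 8,
    activity = list(
      n_animals = 8, n_days = 12, sim_bin_minutes = 1, analysis_bin_minutes = 6,
      period_range_h = c(20, 28),
      conditions = list(
        LD12_12 = list(tau_h = 24, alpha_h = 11.8, rate_active = 10,
                       rate_rest = 0.25, masking = TRUE,
                       break_offset_h = 5, break_duration_h = 1.46,
                       arrhythmic_fraction = 0),
        DD = list(tau_h = 24 - 19 / 60, alpha_h = 12.7, rate_active = 9,
                  rate_rest = 0.6, masking = FALSE,
                  break_offset_h = 5, break_duration_h = 2.34,
                  arrhythmic_fraction = 0),
        LD16_8 = list(tau_h = 24, alpha_h = 8.2, rate_active = 14,
                      rate_rest = 0.25, masking = TRUE,
                      break_offset_h = 3, break_duration_h = 0.29,
                      arrhythmic_fraction = 0),
        LL = list(tau_h = 24 + 46.3 / 60, alpha_h = 9.1, rate_active = 4.1,
                  rate_rest = 0.3, masking = FALSE,
                  break_offset_h = NULL, break_duration_h = NULL,
                  arrhythmic_fraction = 0.5))),
    imaging = list(
      timepoints = tp, fields_per_cell = 8,
      field = list(width_px = 256, height_px = 256, pixel_size_um = 0.082,
                   optical_thickness_um = 0.46, spot_sigma_px = 2,
                   min_separation_px = 8, amp_range = c(0.5, 1),
                   background_level = 0.04, background_gradient = 0.04,
                   shot_noise = TRUE, photons = 200),
      pairs = list(
        Syp1_PSD95 = list(
          pre_protein = "Syp1", post_protein = "PSD95",
          n_pre = list(LD12_12 = c(140, 150, 85, 92), DD = c(130, 115, 95, 105),
                       LD16_8 = c(120, 120, 105, 120), LL = c(110, 110, 110, 110)),
          n_post = list(LD12_12 = c(100, 100, 100, 100), DD = c(115, 110, 85, 105),
                        LD16_8 = c(100, 100, 100, 100), LL = c(100, 100, 100, 100)),
          sigma_post = list(LD12_12 = c(1, 1, 1.25, 1.2), DD = c(1, 1, 1, 1),
                            LD16_8 = c(1, 1, 1, 1), LL = c(1, 1, 1, 1)),
          coloc = list(LD12_12 = c(0.75, 0.78, 0.60, 0.57), DD = c(0.78, 0.68, 0.57, 0.68),
                       LD16_8 = c(0.78, 0.70, 0.70, 0.73), LL = c(0.78, 0.78, 0.78, 0.78))),
        Pic_Hom1 = list(
          pre_protein = "Piccolo", post_protein = "Homer1",
          n_pre = list(LD12_12 = c(125, 125, 111, 122), DD = c(167, 152, 125, 131),
                       LD16_8 = c(131, 139, 125, 125), LL = c(116, 125, 127, 134)),
          n_post = list(LD12_12 = c(109, 100, 100, 100), DD = c(100, 114, 99, 116),
                        LD16_8 = c(111, 104, 100, 118), LL = c(100, 112, 100, 113)),
          sigma_post = NULL,
          coloc = list(LD12_12 = c(0.78, 0.78, 0.62, 0.68), DD = c(0.78, 0.75, 0.60, 0.78),
                       LD16_8 = c(0.75, 0.70, 0.68, 0.73), LL = c(0.78, 0.78, 0.78, 0.78))),
        NRXN_PICK1 = list(
          pre_protein = "NRXN", post_protein = "PICK1",
          n_pre = list(LD12_12 = c(145, 145, 145, 145), DD = c(145, 145, 145, 145),
                       LD16_8 = c(145, 122, 145, 145), LL = c(145, 145, 145, 145)),
          n_post = list(LD12_12 = c(100, 100, 100, 100), DD = c(122, 100, 97, 130),
                        LD16_8 = c(100, 100, 100, 100), LL = c(100, 100, 100, 100)),
          sigma_pre = list(LD12_12 = c(1, 0.95, 1.1, 1), DD = c(1, 1.15, 1, 1),
                           LD16_8 = c(1.15, 1, 1.15, 1.15), LL = c(1, 1, 1, 1)),
          coloc = list(LD12_12 = c(0.70, 0.70, 0.70, 0.60), DD = c(0.70, 0.57, 0.55, 0.70),
                       LD16_8 = c(0.70, 0.70, 0.70, 0.70), LL = c(0.70, 0.70, 0.70, 0.70))))))
  class(cfg) <- "study_config"
  cfg
}

#' Write / read a study configuration as YAML
#' @param config A `study_config` list.
#' @param path YAML file path.
#' @return `write_study_config` returns `path` invisibly; `read_study_config`
#'   a `study_config`.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "study_config"
  cfg
}

activity_schema <- c("condition", "animal_id", "arrhythmic_planted", "tau_h",
                     "delta_h", "alpha_h", "rho_h", "overall_activity", "qp",
                     "percent_qp", "rhythmic", "day_activity", "night_activity",
                     "percent_day", "activity_phase_total", "rest_phase_total",
                     "break_mean_h")
imaging_schema <- c("pair", "condition", "timepoint", "field_id", "count_pre",
                    "count_post", "area_fraction_pre_pct", "area_fraction_post_pct",
                    "co_labeled_count", "density_per_um3", "participation_pre_pct",
                    "participation_post_pct", "saturated")
comparison_schema <- c("variable", "test_used", "p_omnibus", "group1", "group2",
                       "estimate", "p_adj", "verdict")

comparison_to_df <- function(cmp, variable) {
  if (is.null(cmp)) return(NULL)
  cbind(data.frame(variable = variable, test_used = cmp$test_used,
                   p_omnibus = cmp$p_omnibus, stringsAsFactors = FALSE),
        cmp$pairwise[c("group1", "group2", "estimate", "p_adj", "verdict")])
}

compare_safe <- function(values, group, ...) {
  keep <- !is.na(values)
  values <- values[keep]
  group <- droplevels(as.factor(group[keep]))
  sizes <- table(group)
  group <- factor(group, levels = names(sizes)[sizes >= 3])
  keep <- !is.na(group)
  if (nlevels(group) < 2) return(NULL)
  compare_groups(values[keep], group[keep], ...)
}

#' Run the locomotor-activity arm of a study
#'
#' Simulates every configured animal under its condition, analyzes each
#' record with [analyze_rhythm()] and compares the rhythm parameters across
#' conditions. Deterministic given the master seed. Under constant light the
#' configured arrhythmic fraction of animals (the first
#' `round(fraction * n)` of the cell) is simulated rate-homogeneous; their
#' alpha/delta stay `NA` in the table.
#'
#' @param config A `study_config` (see [default_study_config()]).
#' @return List with `params` (one row per animal, schema-stable) and
#'   `comparisons` (one flattened comparison table over all rhythm
#'   variables).
#' @export
run_activity_study <- function(config) {
  act <- config$activity
  rows <- list()
  for (cond in names(act$conditions)) {
    cc <- act$conditions[[cond]]
    schedule <- light_schedule(cond, lights_on_clock = config$lights_on_clock)
    n_arr <- round((cc$arrhythmic_fraction %||% 0) * act$n_animals)
    for (i in seq_len(act$n_animals)) {
      seed <- derive_seed(config$master_seed, "activity", cond, i)
      params <- sim_activity_params(
        tau_h = cc$tau_h, alpha_h = cc$alpha_h,
        rate_active = cc$rate_active, rate_rest = cc$rate_rest,
        break_offset_h = cc$break_offset_h,
        break_duration_h = cc$break_duration_h,
        masking = isTRUE(cc$masking), arrhythmic = i <= n_arr,
        seed = seed)
      sim <- simulate_activity(params, schedule, n_days = act$n_days,
                               bin_minutes = act$sim_bin_minutes)
      rec <- bin_activity(sim$record, act$analysis_bin_minutes)
      rec$animal_id <- sprintf("%s_%02d", cond, i)
      rp <- tryCatch(
        analyze_rhythm(rec, period_range_h = act$period_range_h),
        error = function(e)
          stop(sprintf("activity analysis failed for %s: %s",
                       rec$animal_id, conditionMessage(e)), call. = FALSE))
      rows[[rec$animal_id]] <- cbind(
        data.frame(condition = cond, stringsAsFactors = FALSE),
        as.data.frame(rp),
        data.frame(arrhythmic_planted = i <= n_arr))
    }
  }
  params_table <- do.call(rbind, rows)
  rownames(params_table) <- NULL
  params_table <- params_table[activity_schema]

  vars <- c("tau_h", "delta_h", "alpha_h", "rho_h", "overall_activity",
            "percent_qp", "day_activity", "night_activity", "percent_day")
  cmp <- lapply(vars, function(v)
    comparison_to_df(compare_safe(params_table[[v]], params_table$condition), v))
  comparisons <- do.call(rbind, cmp)
  rownames(comparisons) <- NULL
  list(params = params_table, comparisons = comparisons)
}

#' Run the imaging arm of a study
#'
#' Simulates and quantifies every configured field (pair x condition x time
#' point x field), then per pair and condition compares puncta counts,
#' covered areas and synapse density across the four time points, classifies
#' the expression change of each protein for every time-point contrast, and
#' summarizes percent participation per protein.
#'
#' @param config A `study_config`.
#' @return List with `fields` (per-field quantification table),
#'   `density_comparisons`, `expression_labels` (pair, condition, protein,
#'   contrast, verdicts, label) and `participation` (per pair/protein mean
#'   percent participation).
#' @export
run_imaging_study <- function(config) {
  img <- config$imaging
  fld <- img$field
  tp_names <- paste0("T", img$timepoints)
  rows <- list()
  for (pair in names(img$pairs)) {
    pc <- img$pairs[[pair]]
    for (cond in names(pc$coloc)) {
      for (ti in seq_along(img$timepoints)) {
        for (f in seq_len(img$fields_per_cell)) {
          seed <- derive_seed(config$master_seed, "imaging", pair, cond,
                              img$timepoints[ti], f)
          sp <- sim_image_params(
            width_px = fld$width_px, height_px = fld$height_px,
            pixel_size_um = fld$pixel_size_um,
            optical_thickness_um = fld$optical_thickness_um,
            n_puncta_a = pc$n_pre[[cond]][ti],
            n_puncta_b = pc$n_post[[cond]][ti],
            coloc_fraction = pc$coloc[[cond]][ti],
            spot_sigma_px = fld$spot_sigma_px *
              c((pc$sigma_pre[[cond]] %||% rep(1, 4))[ti],
                (pc$sigma_post[[cond]] %||% rep(1, 4))[ti]),
            amp_range = fld$amp_range,
            background_level = fld$background_level,
            background_gradient = fld$background_gradient,
            min_separation_px = fld$min_separation_px,
            shot_noise = fld$shot_noise, photons = fld$photons, seed = seed)
          field_id <- sprintf("%s_%s_T%02d_f%02d", pair, cond,
                              img$timepoints[ti], f)
          field <- simulate_puncta_field(sp, field_id = field_id)
          q <- quantify_field(field)
          rows[[field_id]] <- cbind(
            data.frame(pair = pair, condition = cond,
                       timepoint = tp_names[ti], stringsAsFactors = FALSE), q)
        }
      }
    }
  }
  fields <- do.call(rbind, rows)
  rownames(fields) <- NULL
  fields <- fields[imaging_schema]

  density_cmp <- list()
  labels <- list()
  participation <- list()
  for (pair in names(img$pairs)) {
    pc <- img$pairs[[pair]]
    fp <- fields[fields$pair == pair, ]
    participation[[pair]] <- data.frame(
      pair = pair,
      protein = c(pc$pre_protein, pc$post_protein),
      mean_participation_pct = c(mean(fp$participation_pre_pct, na.rm = TRUE),
                                 mean(fp$participation_post_pct, na.rm = TRUE)),
      stringsAsFactors = FALSE)
    for (cond in names(pc$coloc)) {
      d <- fp[fp$condition == cond, ]
      tpf <- factor(d$timepoint, levels = tp_names)
      dens <- comparison_to_df(compare_safe(d$density_per_um3, tpf), "density_per_um3")
      if (!is.null(dens))
        density_cmp[[paste(pair, cond)]] <-
          cbind(data.frame(pair = pair, condition = cond,
                           stringsAsFactors = FALSE), dens)
      for (side in c("pre", "post")) {
        protein <- if (side == "pre") pc$pre_protein else pc$post_protein
        cnt <- compare_safe(d[[paste0("count_", side)]], tpf)
        area <- compare_safe(d[[paste0("area_fraction_", side, "_pct")]], tpf)
        if (is.null(cnt) || is.null(area)) next
        prs <- cnt$pairwise
        for (j in seq_len(nrow(prs))) {
          cv <- prs$verdict[j]
          av <- pair_verdict(area, prs$group1[j], prs$group2[j])
          labels[[length(labels) + 1L]] <- data.frame(
            pair = pair, condition = cond, protein = protein,
            contrast = paste(prs$group2[j], "vs", prs$group1[j]),
            count_verdict = cv, area_verdict = av,
            label = classify_expression_change(cv, av),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(fields = fields,
       density_comparisons = do.call(rbind, c(density_cmp, list(make.row.names = FALSE))),
       expression_labels = do.call(rbind, c(labels, list(make.row.names = FALSE))),
       participation = do.call(rbind, c(participation, list(make.row.names = FALSE))))
}

#' Run the full synthetic study
#'
#' Both arms of the pipeline under one master seed. The result is fully
#' deterministic: re-running with the same configuration gives identical
#' tables.
#'
#' @param config A `study_config`; default [default_study_config()].
#' @param out_dir Optional output directory; when given, all tables are
#'   written as CSV (see [write_study_report()]).
#' @return An object of class `study_report` with elements `activity`,
#'   `imaging` and `config`.
#' @export
run_full_study <- function(config = default_study_config(), out_dir = NULL) {
  report <- structure(
    list(activity = run_activity_study(config),
         imaging = run_imaging_study(config),
         config = config),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic study report\n")
  cat(sprintf("  activity: %d animals, %d condition comparisons\n",
              nrow(x$activity$params),
              length(unique(x$activity$comparisons$variable))))
  cat(sprintf("  imaging: %d fields, %d expression-change labels\n",
              nrow(x$imaging$fields), nrow(x$imaging$expression_labels)))
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV tables under `activity/`, `imaging/` and `stats/`; optionally a few
#' representative figures (actogram and periodogram of the first animal per
#' condition) under `figures/`. Output is byte-stable across reruns with the
#' same configuration.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @param figures Also render PNG figures (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir, figures = FALSE) {
  for (d in c("activity", "imaging", "stats", if (figures) "figures"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  stopifnot(identical(names(report$activity$params), activity_schema),
            identical(names(report$imaging$fields), imaging_schema))
  w <- function(x, ...) utils::write.csv(x, file.path(dir, ...), row.names = FALSE)
  w(report$activity$params, "activity", "rhythm_params.csv")
  w(report$activity$comparisons, "stats", "activity_comparisons.csv")
  w(report$imaging$fields, "imaging", "field_quantification.csv")
  w(report$imaging$density_comparisons, "stats", "density_comparisons.csv")
  w(report$imaging$expression_labels, "stats", "expression_change_labels.csv")
  w(report$imaging$participation, "imaging", "participation_summary.csv")
  if (figures) {
    act <- report$config$activity
    for (cond in names(act$conditions)) {
      cc <- act$conditions[[cond]]
      seed <- derive_seed(report$config$master_seed, "activity", cond, 1L)
      params <- sim_activity_params(
        tau_h = cc$tau_h, alpha_h = cc$alpha_h, rate_active = cc$rate_active,
        rate_rest = cc$rate_rest, break_offset_h = cc$break_offset_h,
        break_duration_h = cc$break_duration_h, masking = isTRUE(cc$masking),
        seed = seed)
      sim <- simulate_activity(params,
                               light_schedule(cond, report$config$lights_on_clock),
                               n_days = act$n_days,
                               bin_minutes = act$sim_bin_minutes)
      rec <- bin_activity(sim$record, 30)
      grDevices::png(file.path(dir, "figures", paste0("actogram_", cond, ".png")),
                     width = 800, height = 600)
      plot(build_actogram(rec))
      grDevices::dev.off()
      rec6 <- bin_activity(sim$record, act$analysis_bin_minutes)
      grDevices::png(file.path(dir, "figures", paste0("periodogram_", cond, ".png")),
                     width = 800, height = 600)
      plot(chi_square_periodogram(window_record(rec6, 24),
                                  act$period_range_h[1], act$period_range_h[2]))
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
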