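# End-to-end pipeline: simulate -> audiometry -> behavior -> imaging stats
# -> report, driven by one configuration and one master seed.

PIPELINE_STAGES <- c("simulate", "audiometry", "behavior", "stats", "report")

#' Default pipeline configuration
#'
#' Cohort structure mirrors the standard two-strain design: 14 well-hearing
#' Black hooded rats (paired and noise-floor analyses), of which the first
#' 9 also undergo the startle-control condition (repeated-measures
#' analysis), plus 5 hearing-impaired Lister hooded rats included in the
#' correlative analysis (n = 19). Phantom volumes live on a 32 x 32 x 16
#' grid with 5% multiplicative voxel noise and 10% global subject scaling;
#' ground-truth effects follow [default_phantom_effects]. The noise-floor
#' criterion t defaults to the two-tailed critical value of the split-half
#' null test (df = n - 2 = 12 at n = 14); set `stats$criterion_df` to 13
#' to use the paired-test convention instead.
#'
#' @return A nested configuration list understood by [run_pipeline].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_black = 14L, n_lister = 5L, n_rm = 9L),
    session = list(background_level = 65, startle_level = 110,
                   prepulse_levels = PPI_PREPULSE_LEVELS),
    baep = list(start_level = 100, step = 10, n_sweeps = 1000, noise_sd = 1),
    phantom = list(grid_shape = c(32L, 32L, 16L), noise_sd = 0.05,
                   global_scale_sd = 0.1, baseline = 100),
    stats = list(alpha = 0.05, criterion_df = 12L,
                 noise_floor = "split_half"),
    io = list(write_volumes = TRUE, write_baep = FALSE)
  )
}

stage_error <- function(stage, e) {
  stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", stage,
                              conditionMessage(e)),
                      class = c("ppipet_stage_error", "ppipet_error"),
                      stage = stage, parent = e))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, deterministically for a given `config$seed`: (1) `simulate` --
#' subject profiles, startle sessions and per-trial amplitudes, BAEP sweep
#' series, the VOI atlas and the phantom PET cohort whose per-subject
#' covariate is the relative event difference measured in that subject's
#' simulated PPI session; (2) `audiometry` -- hearing-threshold estimation
#' per subject and strain comparison; (3) `behavior` -- per-level PPI,
#' event counts, session-half comparisons and cohort behavioral statistics;
#' (4) `stats` -- reference-region normalization, paired t-map (PPI vs
#' background, Black hooded subjects), repeated-measures ANOVA with Tukey
#' q-maps (three conditions, RM subset), Pearson correlation map (all
#' subjects), split-half and hemisphere-flip noise floors, significance
#' masks, VOI symmetry check and whole-VOI detections; (5) `report` -- TSV
#' tables, NIfTI maps and a JSON run report with seed, version and file
#' checksums.
#'
#' @param config Configuration list, see [default_pipeline_config]; a path
#'   to a YAML file is also accepted.
#' @param out_dir Output directory (created).
#' @param through Last stage to execute; earlier stages always run (they
#'   are cheap and deterministic).
#' @return A `run_report` list (invisibly the same object written to
#'   `report.json` plus in-memory stage results under `$objects`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         through = "report") {
  if (is.character(config)) config <- read_pipeline_config(config)
  through <- match.arg(through, PIPELINE_STAGES)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$out_dir <- out_dir
  st$files <- character()

  n_through <- match(through, PIPELINE_STAGES)
  runners <- list(simulate = stage_simulate, audiometry = stage_audiometry,
                  behavior = stage_behavior, stats = stage_stats,
                  report = stage_report)
  for (stage in PIPELINE_STAGES[seq_len(n_through)]) {
    tryCatch(runners[[stage]](st), error = function(e) {
      manifest <- list(failed_stage = stage, error = conditionMessage(e),
                       files = st$files)
      jsonlite::write_json(manifest, file.path(out_dir, "partial_report.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_error(stage, e)
    })
  }
  invisible(st$report %||% list(objects = as.list(st)))
}

record_file <- function(st, path) {
  st$files <- unique(c(st$files, path))
  invisible(path)
}

stage_simulate <- function(st) {
  cfg <- st$config
  seed <- cfg$seed
  nb <- cfg$cohort$n_black; nl <- cfg$cohort$n_lister
  subjects <- c(sprintf("b%02d", seq_len(nb)), sprintf("l%02d", seq_len(nl)))
  strains <- c(rep("black_hooded", nb), rep("lister_hooded", nl))

  profiles <- lapply(seq_along(subjects), function(i)
    strain_profile(strains[i], seed = child_seed(seed, i)))
  names(profiles) <- subjects

  plans <- list(); measures <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    plans[[s]] <- build_session_plan(
      seed = child_seed(seed, 200 + i), condition = "ppi",
      background_level = cfg$session$background_level,
      startle_level = cfg$session$startle_level,
      prepulse_levels = cfg$session$prepulse_levels)
    measures[[s]] <- simulate_session_amplitudes(
      plans[[s]], profiles[[s]], seed = child_seed(seed, 300 + i))
  }

  counts <- lapply(measures, classify_events)
  rel_diff <- vapply(counts, relative_event_difference, numeric(1))

  # Startle-control sessions for the repeated-measures subset, with the
  # startle count matched to the subject's startle reactions in its PPI
  # session (clipped into the constructible range).
  rm_subjects <- subjects[seq_len(cfg$cohort$n_rm)]
  sc_measures <- list()
  for (i in seq_along(rm_subjects)) {
    s <- rm_subjects[i]
    override <- clip(counts[[s]]$n_startle, 30, 150)
    sc_plan <- build_session_plan(
      seed = child_seed(seed, 600 + i), condition = "startle_control",
      n_startle_override = override,
      background_level = cfg$session$background_level,
      startle_level = cfg$session$startle_level,
      prepulse_levels = cfg$session$prepulse_levels)
    sc_measures[[s]] <- simulate_session_amplitudes(
      sc_plan, profiles[[s]], seed = child_seed(seed, 700 + i))
  }

  baep <- lapply(seq_along(subjects), function(i)
    simulate_baep_series(
      true_threshold = profiles[[i]]$hearing_threshold / 0.8509,
      start_level = cfg$baep$start_level, step = cfg$baep$step,
      n_sweeps = cfg$baep$n_sweeps, noise_sd = cfg$baep$noise_sd,
      stop_level = 0, seed = child_seed(seed, 400 + i)))
  names(baep) <- subjects

  atlas <- default_phantom_atlas(cfg$phantom$grid_shape)
  cohort <- simulate_pet_cohort(
    atlas, default_phantom_effects(), n_subjects = length(subjects),
    covariates = unname(rel_diff), noise_sd = cfg$phantom$noise_sd,
    global_scale_sd = cfg$phantom$global_scale_sd,
    baseline = cfg$phantom$baseline, seed = child_seed(seed, 500),
    subjects = subjects)

  ses_dir <- file.path(st$out_dir, "sessions")
  dir.create(ses_dir, showWarnings = FALSE)
  for (s in subjects)
    record_file(st, write_startle_tsv(
      measures[[s]], file.path(ses_dir, paste0(s, "_ppi.tsv")),
      plan = plans[[s]], profile = profiles[[s]]))
  for (s in names(sc_measures))
    record_file(st, write_startle_tsv(
      sc_measures[[s]], file.path(ses_dir, paste0(s, "_startle_control.tsv"))))
  write_atlas(atlas, file.path(st$out_dir, "atlas"))
  record_file(st, file.path(st$out_dir, "atlas", "atlas_labels.nii.gz"))
  record_file(st, file.path(st$out_dir, "atlas", "atlas_names.tsv"))
  if (isTRUE(cfg$io$write_volumes)) {
    write_cohort_nifti(cohort, file.path(st$out_dir, "volumes"))
    record_file(st, file.path(st$out_dir, "volumes", "cohort.json"))
  }
  if (isTRUE(cfg$io$write_baep))
    for (s in subjects)
      write_baep_series(baep[[s]], file.path(st$out_dir, "baep", s))

  st$subjects <- subjects; st$strains <- strains; st$profiles <- profiles
  st$plans <- plans; st$measures <- measures; st$sc_measures <- sc_measures
  st$counts <- counts; st$rel_diff <- rel_diff
  st$baep <- baep; st$atlas <- atlas; st$cohort <- cohort
  invisible(st)
}

stage_audiometry <- function(st) {
  est <- lapply(st$baep, estimate_hearing_threshold)
  tab <- data.frame(
    subject = st$subjects, strain = st$strains,
    true_threshold_spl = vapply(st$profiles, function(p) p$hearing_threshold,
                                numeric(1)),
    est_threshold_pspl = vapply(est, function(e) e$value_pspl, numeric(1)),
    est_threshold_spl = vapply(est, function(e) e$value_spl, numeric(1)),
    stringsAsFactors = FALSE)
  tt <- stats::t.test(est_threshold_spl ~ strain, data = tab)
  st$thresholds <- tab
  st$threshold_test <- list(t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value,
                            means = tapply(tab$est_threshold_spl, tab$strain, mean))
  record_file(st, write_tsv(tab, file.path(st$out_dir, "hearing_thresholds.tsv")))
  invisible(st)
}

stage_behavior <- function(st) {
  ppi_rows <- lapply(st$subjects, function(s) {
    tab <- session_ppi(st$measures[[s]])
    data.frame(subject = s, strain = st$strains[match(s, st$subjects)],
               prepulse_level = tab$prepulse_level,
               ppi_percent = tab$ppi_percent,
               mean_startle_alone = attr(tab, "mean_startle_alone"),
               stringsAsFactors = FALSE)
  })
  ppi_table <- do.call(rbind, ppi_rows)

  subject_table <- data.frame(
    subject = st$subjects, strain = st$strains,
    hearing_threshold = st$thresholds$est_threshold_spl,
    n_ppi = vapply(st$counts, function(cn) cn$n_ppi, numeric(1)),
    n_startle = vapply(st$counts, function(cn) cn$n_startle, numeric(1)),
    rel_diff = unname(st$rel_diff),
    startle_amplitude = vapply(st$subjects, function(s)
      mean(st$measures[[s]]$amplitude[st$measures[[s]]$block == "paradigm" &
                                        st$measures[[s]]$kind == "startle_alone"]),
      numeric(1)),
    stringsAsFactors = FALSE)

  group <- behavioral_group_stats(ppi_table, subject_table)

  black <- st$subjects[st$strains == "black_hooded"]
  halves <- list(
    ppi_amplitude = session_half_comparison(st$measures[black], "startle_amplitude"),
    ppi_percent = session_half_comparison(st$measures[black], "ppi_percent"),
    startle_control_amplitude =
      session_half_comparison(st$sc_measures, "startle_amplitude"))

  record_file(st, write_tsv(ppi_table, file.path(st$out_dir, "ppi_by_level.tsv")))
  record_file(st, write_tsv(subject_table, file.path(st$out_dir, "subjects.tsv")))
  st$ppi_table <- ppi_table; st$subject_table <- subject_table
  st$group_stats <- group; st$halves <- halves
  invisible(st)
}

stage_stats <- function(st) {
  cfg <- st$config
  alpha <- cfg$stats$alpha
  norm <- reference_region_normalize(st$cohort)
  black <- st$subjects[st$strains == "black_hooded"]
  rm_subjects <- st$subjects[seq_len(cfg$cohort$n_rm)]

  paired_cohort <- subset_cohort(norm, black, c("ppi", "background"))
  t_map <- paired_t_map(paired_cohort, "ppi", "background")

  criterion <- critical_t(cfg$stats$criterion_df, alpha)
  floor_sh <- split_half_noise_floor(paired_cohort, "background",
                                     seed = child_seed(cfg$seed, 800),
                                     criterion_t = criterion)
  floor_flip <- hemisphere_flip_noise_floor(paired_cohort, "background",
                                            criterion_t = criterion)
  floor <- switch(cfg$stats$noise_floor, split_half = floor_sh,
                  flip = floor_flip, none = NULL)

  t_mask <- threshold_and_mask(t_map, alpha, floor)
  diff <- condition_difference(paired_cohort, "ppi", "background")
  symmetry <- if (any(t_mask)) voi_direction_check(diff, st$atlas, t_mask) else NULL
  detections <- voi_detections(t_mask, st$atlas)

  rm_cohort <- subset_cohort(norm, rm_subjects,
                             c("ppi", "startle_control", "background"))
  rm_maps <- rm_anova_tukey_maps(rm_cohort)

  all_diff <- condition_difference(norm, "ppi", "background")
  r_map <- pearson_r_map(all_diff, unname(norm$covariate))
  r_mask <- threshold_and_mask(r_map, alpha)

  map_dir <- file.path(st$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  vx <- st$cohort$voxel_size
  record_file(st, paste0(write_stat_map(t_map, file.path(map_dir, "paired_t_ppi_vs_background"), vx), ".nii.gz"))
  for (nm in names(rm_maps$q_maps))
    record_file(st, paste0(write_stat_map(rm_maps$q_maps[[nm]],
                                          file.path(map_dir, paste0("tukey_q_", nm)), vx), ".nii.gz"))
  record_file(st, paste0(write_stat_map(r_map, file.path(map_dir, "pearson_r_ppi_minus_background"), vx), ".nii.gz"))
  record_file(st, write_volume_nifti(t_mask * 1,
                                     file.path(map_dir, "mask_paired_t.nii.gz"), vx))
  if (!is.null(symmetry))
    record_file(st, write_tsv(symmetry, file.path(st$out_dir, "voi_symmetry.tsv")))
  record_file(st, write_tsv(detections, file.path(st$out_dir, "voi_detections.tsv")))

  st$norm <- norm; st$t_map <- t_map; st$t_mask <- t_mask
  st$floor_split_half <- floor_sh; st$floor_flip <- floor_flip
  st$rm_maps <- rm_maps; st$r_map <- r_map; st$r_mask <- r_mask
  st$symmetry <- symmetry; st$detections <- detections
  st$criterion_t <- criterion
  invisible(st)
}

stage_report <- function(st) {
  cfg <- st$config
  truth <- st$cohort$truth
  truth_vois <- unique(truth$voi[truth$effect != 0 | truth$covariate_beta != 0])
  det <- st$detections
  report <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("ppipet")),
    config = cfg,
    behavior = list(
      anova = st$group_stats$anova,
      sidak = st$group_stats$sidak,
      mann_whitney = cbind(outcome = rownames(st$group_stats$mann_whitney),
                           st$group_stats$mann_whitney),
      pearson_threshold_vs_rel_diff = st$group_stats$pearson,
      halves = lapply(st$halves, function(h)
        h[c("metric", "early_mean", "late_mean", "difference",
            "percent_change", "t", "df", "p")])),
    audiometry = st$threshold_test,
    imaging = list(
      criterion_t = st$criterion_t,
      split_half = unclass(st$floor_split_half)[c("mean_t", "sd_t",
                                                  "criterion_t", "above_noise_cut", "separation_sd", "df")],
      hemisphere_flip = unclass(st$floor_flip)[c("mean_t", "sd_t",
                                                 "criterion_t", "above_noise_cut", "separation_sd", "df")],
      paired_t_df = st$t_map$df,
      masked_voxels = sum(st$t_mask),
      detected_vois = det$voi[det$detected],
      true_effect_vois = truth_vois,
      all_true_vois_detected = all(truth_vois %in% det$voi[det$detected]),
      false_voi_detections = setdiff(det$voi[det$detected], truth_vois),
      symmetry = st$symmetry),
    files = lapply(stats::setNames(st$files, basename(st$files)), function(f)
      unname(tools::md5sum(f)))
  )
  path <- file.path(st$out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  st$report <- structure(c(report, list(path = path)), class = "run_report")
  invisible(st)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed=%d, %d files under %s\n", x$seed,
              length(x$files), dirname(x$path)))
  cat(sprintf("  paired-t mask: %d voxels; detected VOIs: %s\n",
              x$imaging$masked_voxels,
              paste(x$imaging$detected_vois, collapse = ", ")))
  invisible(x)
}
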