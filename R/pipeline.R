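# End-to-end orchestration: simulate -> classify -> quantify -> score
# -> threshold -> stats, with a machine-readable run manifest and
# stage-tagged logging to stderr.

#' Pipeline configuration
#'
#' Reads a YAML or JSON configuration file (or takes a list) and fills
#' defaults. Fields: `seed`; `out_dir`; `simulate` (logical; when
#' FALSE, `image_dir`/`mask_dir`/`cohort_csv` must point at inputs);
#' `n_patients`; `image_size`; `stain` (stain_params overrides);
#' `cohort` (cohort_sim_config overrides); `classifier`
#' (window/n_per_class/n_train_images); `positivity`
#' (positivity_config overrides); `thresholds` (threshold_config
#' overrides); `tree` (k/max_depth/min_node_size); `log_level`.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param out_dir output directory (overrides the file's value).
#' @param seed seed (overrides the file's value).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_config_file(config) else config
  if (!is.list(cfg)) stop("`config` must be a list or a file path",
                          call. = FALSE)
  defaults <- list(
    seed = 1L, out_dir = "pipeline-out", simulate = TRUE,
    n_patients = 30L, image_size = 128L,
    image_dir = NULL, mask_dir = NULL, cohort_csv = NULL,
    stain = list(), cohort = list(),
    classifier = list(window = 9L, n_per_class = 1500L,
                      n_train_images = 4L),
    positivity = list(), thresholds = list(),
    tree = list(k = 10L, max_depth = 3L, min_node_size = 10L),
    log_level = "info"
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  for (fld in c("seed", "n_patients", "image_size")) {
    cfg[[fld]] <- as.integer(cfg[[fld]])
  }
  if (!isTRUE(cfg$simulate)) {
    for (fld in c("image_dir", "cohort_csv")) {
      if (is.null(cfg[[fld]]) || !file.exists(cfg[[fld]])) {
        stop(sprintf("input path `%s` missing or does not exist", fld),
             call. = FALSE)
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file `%s` does not exist", path), call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full quantification and prognosis pipeline
#'
#' Simulates (or loads) core images and a cohort, trains the tissue
#' classifier on annotated training cores, classifies and quantifies
#' every analysis core, scores and aggregates duplicates, discovers
#' thresholds by cross-validated survival trees (skipped with a note
#' when the evaluable cohort is too small), and writes association and
#' survival statistics. All artifacts land under `out_dir`, described
#' by `manifest.json`.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list(), outputs = character(0))

  # --- stage: simulate / load ------------------------------------------
  if (isTRUE(cfg$simulate)) {
    log_stage("simulate", "generating cohort of ", cfg$n_patients,
              " patients")
    ccfg <- do.call(cohort_sim_config,
                    utils::modifyList(list(n_patients = cfg$n_patients,
                                           seed = cfg$seed),
                                      cfg$cohort))
    sim <- generate_cohort(ccfg)
    cohort <- sim$patients
    sp <- do.call(stain_params, cfg$stain)
    sz <- cfg$image_size
    n_cores <- 2L * cfg$n_patients
    log_stage("simulate", "rendering ", n_cores, " core images at ",
              sz, "x", sz)
    # per-core positivity follows the patient's simulated scores so the
    # imaging route and the cohort route agree in expectation
    cores_meta <- sim$cores
    images <- vector("list", n_cores)
    truths <- vector("list", n_cores)
    for (i in seq_len(n_cores)) {
      pfrac <- min(cores_meta$nuclear_autoscore[i] / 50, 1)
      cfrac <- min(cores_meta$cyt_autoscore[i] / 50, 1)
      spi <- stain_params(
        fraction_positive_nuclei = pfrac,
        fraction_positive_cytoplasm = cfrac,
        nuclear_dab_od = sp$nuclear_dab_od,
        cytoplasmic_dab_od = sp$cytoplasmic_dab_od,
        hematoxylin_od = sp$hematoxylin_od,
        tumour_area_fraction = sp$tumour_area_fraction,
        lymphocyte_area_fraction = sp$lymphocyte_area_fraction,
        nuclei_per_1000px2 = sp$nuclei_per_1000px2,
        noise_sd = sp$noise_sd)
      g <- generate_core_image(spi, sz, sz,
                               seed = (cfg$seed %% 20000L) * 100000L + i)
      images[[i]] <- g$image
      truths[[i]] <- g$truth
    }
    manifest$stages$simulate <- list(n_patients = nrow(cohort),
                                     n_cores = n_cores)
  } else {
    log_stage("load", "reading images from ", cfg$image_dir)
    img_files <- sort(list.files(cfg$image_dir, "\\.png$",
                                 full.names = TRUE))
    images <- lapply(img_files, read_image)
    truths <- NULL
    if (!is.null(cfg$mask_dir)) {
      mask_files <- sort(list.files(cfg$mask_dir, "\\.png$",
                                    full.names = TRUE))
      truths <- lapply(mask_files, function(p) list(class_mask = read_mask(p)))
    }
    cohort <- read.csv(cfg$cohort_csv)
    cores_meta <- data.frame(
      patient_id = rep(cohort$patient_id,
                       length.out = length(images)),
      replicate = rep(1:2, length.out = length(images)))
    manifest$stages$simulate <- list(loaded = length(images))
  }

  # --- stage: train + classify -----------------------------------------
  n_train <- min(cfg$classifier$n_train_images, length(images))
  if (is.null(truths)) stop("classification requires annotation masks",
                            call. = FALSE)
  log_stage("classify", "training on ", n_train, " annotated cores")
  model <- train_classifier(images[seq_len(n_train)],
                            truths[seq_len(n_train)],
                            window = cfg$classifier$window,
                            n_per_class = cfg$classifier$n_per_class,
                            seed = cfg$seed)
  save_classifier(model, file.path(cfg$out_dir, "classifier.rds"))
  tissue <- lapply(images, classify_tissue, model = model)
  manifest$stages$classify <- list(n_images = length(images),
                                   n_train = n_train)

  # --- stage: quantify + score -----------------------------------------
  log_stage("quantify", "quantifying ", length(images), " cores")
  pos_cfg <- do.call(positivity_config, cfg$positivity)
  core_rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    q <- quantify_compartments(images[[i]], tissue[[i]],
                               thresholds = pos_cfg)
    core_rows[[i]] <- autoscore_record(
      q, patient_id = cores_meta$patient_id[i],
      replicate = cores_meta$replicate[i], thresholds = pos_cfg)
  }
  core_scores <- do.call(rbind, core_rows)
  write_table_csv(core_scores, file.path(cfg$out_dir, "core_scores.csv"))
  patient_scores <- aggregate_cohort(core_scores)
  thr_cfg <- do.call(threshold_config, cfg$thresholds)
  patient_scores$snas_group <-
    dichotomize(patient_scores$nuclear_autoscore, thr_cfg$snas_threshold)
  patient_scores$cnr_group <-
    dichotomize(patient_scores$cnr, thr_cfg$cnr_threshold)
  write_table_csv(patient_scores,
                  file.path(cfg$out_dir, "patient_scores.csv"))
  n_eval <- sum(patient_scores$evaluable)
  manifest$stages$score <- list(
    patients_in = nrow(patient_scores), evaluable = n_eval,
    non_evaluable = nrow(patient_scores) - n_eval)

  # survival columns come from the cohort table; measured scores from
  # the imaging route
  merged <- merge(cohort[, intersect(
    c("patient_id", "age", "age_group", "size_group", "nodal", "grade",
      "er", "pr", "ki67", "her2", "treatment", "os_time", "os_event",
      "bcss_time", "bcss_event"), names(cohort))],
    patient_scores, by = "patient_id")
  merged <- merged[order(merged$patient_id), ]
  analysis <- merged[isTRUE_vec(merged$evaluable) & !is.na(merged$cnr), ]
  write_table_csv(merged, file.path(cfg$out_dir, "cohort_scored.csv"))

  # --- stage: threshold discovery --------------------------------------
  tree_file <- file.path(cfg$out_dir, "tree.json")
  tree_input <- data.frame(
    snas = analysis$nuclear_autoscore,
    cytoplasmic = analysis$cyt_autoscore,
    cnr = analysis$cnr,
    bcss_time = analysis$bcss_time,
    bcss_event = analysis$bcss_event)
  if (nrow(tree_input) >= 50L && sum(tree_input$bcss_event) >= 10L) {
    log_stage("threshold", "cross-validated tree on n = ",
              nrow(tree_input))
    cv <- select_model_cv(tree_input, k = cfg$tree$k, seed = cfg$seed,
                          max_depth = cfg$tree$max_depth,
                          min_node_size = cfg$tree$min_node_size)
    tree_json <- list(
      selected_fold = cv$selected,
      root_predictor = cv$root_predictor,
      root_threshold = cv$root_threshold,
      fold_accuracy = cv$accuracy,
      importance = as.list(variable_importance(cv$selected_model)))
    manifest$stages$threshold <- list(
      n = nrow(tree_input), root_predictor = cv$root_predictor,
      root_threshold = cv$root_threshold)
    write_table_csv(
      data.frame(fold = seq_along(cv$accuracy), accuracy = cv$accuracy),
      file.path(cfg$out_dir, "cv_accuracy.csv"))
  } else {
    log_stage("threshold", "skipped: evaluable cohort too small")
    tree_json <- list(skipped = "evaluable cohort below n = 50 or < 10 events")
    manifest$stages$threshold <- list(skipped = TRUE,
                                      n = nrow(tree_input))
  }
  jsonlite::write_json(tree_json, tree_file, auto_unbox = TRUE,
                       digits = NA)

  # --- stage: statistics ------------------------------------------------
  log_stage("stats", "association and survival statistics on n = ",
            nrow(analysis))
  stats_out <- list()
  if (nrow(analysis) >= 20L) {
    for (strat in c("snas_group", "cnr_group")) {
      if (nlevels(droplevels(analysis[[strat]])) == 2L) {
        t1 <- build_table1(analysis, stratifier = strat)
        write_table_csv(t1, file.path(
          cfg$out_dir, sprintf("table1_%s.csv", strat)))
        stats_out[[strat]] <- "written"
      }
    }
    km <- km_estimate(analysis$bcss_time, analysis$bcss_event,
                      analysis$cnr_group)
    write_table_csv(km, file.path(cfg$out_dir, "km_bcss_cnr.csv"))
    lr <- tryCatch(
      logrank_test(analysis$bcss_time, analysis$bcss_event,
                   analysis$cnr_group),
      error = function(e) list(chi_square = NA, df = 1L, p = NA))
    cox <- tryCatch(
      cox_fit(analysis, "cnr_group", outcome = "BCSS"),
      error = function(e) {
        data.frame(term = "cnr_group", hazard_ratio = NA, ci_low = NA,
                   ci_high = NA, p = NA, n = nrow(analysis),
                   n_events = sum(analysis$bcss_event), loglik = NA,
                   converged = FALSE)
      })
    write_table_csv(cox, file.path(cfg$out_dir, "cox_bcss.csv"))
    stats_out$logrank_bcss_cnr <- lr
  } else {
    log_stage("stats", "cohort too small for survival statistics")
    write_table_csv(data.frame(), file.path(cfg$out_dir, "cox_bcss.csv"))
    stats_out$skipped <- "fewer than 20 evaluable patients"
  }
  manifest$stages$stats <- list(n = nrow(analysis))

  manifest$outputs <- sort(union(list.files(cfg$out_dir),
                                 "manifest.json"))
  manifest$config <- cfg[setdiff(names(cfg), "out_dir")]
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_stage("done", "outputs in ", cfg$out_dir)
  invisible(manifest)
}
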