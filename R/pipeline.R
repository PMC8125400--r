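# Pipeline orchestration: a YAML-configurable front end over the package's
# modules (simulate / extract / table / viz / train / evaluate / compare).
# Every command resolves the config against the defaults (unknown keys are
# rejected), writes its artifacts under the output directory together with
# the resolved config snapshot, and draws all randomness from the single
# global seed -- so a re-run with the same snapshot reproduces every output
# file byte-identically.

#' Default pipeline configuration
#'
#' @return nested list mirroring each module's parameters; every value can
#'   be overridden from a YAML file or by code.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    io = list(input_dir = NULL, output_dir = "picboost_out",
              labels_file = NULL),
    simdata = list(n_classes = 2L, n_per_class = 6L, n_features = 50L,
                   n_discriminant = 5L, fold_change = 4,
                   mz_jitter_ppm = 5, rt_jitter_s = 3,
                   noise_points_per_scan = 10, intensity_cv = 0.3,
                   rt_length_s = 600, scan_interval_s = 0.5,
                   mz_min = 100, mz_max = 1000),
    pics = list(mz_tol_ppm = 15, coarse_width = 0.1, min_length = 5L,
                max_gap = 2L, min_apex = NULL),
    peaks = list(snr_min = 3, scale_min = 2, scale_max = 30,
                 n_scales = 8L),
    features = list(mz_tol_ppm = 10, rt_tol_s = 10, min_frac = 0.5,
                    fill_rt_tol_s = 15, normalize_at = "train"),
    embed = list(n_neighbors = 15L, min_dist = 0.1, perplexity = NULL,
                 write_plots = FALSE),
    boost = list(n_estimators = 100L, learning_rate = 0.1, max_depth = 3L,
                 gamma = 0, reg_lambda = 1, min_child_weight = 1,
                 subsample = 1, colsample_bytree = 1,
                 test_fraction = 0.33, grid = NULL, k_folds = 5L),
    compare = list(table_a = NULL, table_b = NULL))
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_user("unknown config key(s): ",
              paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Load and resolve a pipeline configuration
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged on top (e.g. from CLI flags).
#' @return resolved config list; unknown keys raise an error.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_user("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

out_dir <- function(config, ...) {
  d <- file.path(config$io$output_dir, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_snapshot <- function(config) {
  yaml::write_yaml(config, file.path(out_dir(config),
                                     "config_resolved.yaml"))
}

config_cohort_spec <- function(config) {
  s <- config$simdata
  cohort_spec(n_classes = s$n_classes, n_per_class = s$n_per_class,
              n_features = s$n_features,
              n_discriminant = s$n_discriminant,
              fold_change = s$fold_change,
              mz_jitter_ppm = s$mz_jitter_ppm,
              rt_jitter_s = s$rt_jitter_s,
              noise_points_per_scan = s$noise_points_per_scan,
              intensity_cv = s$intensity_cv,
              rt_grid = seq(0, s$rt_length_s, by = s$scan_interval_s),
              mz_range = c(s$mz_min, s$mz_max), seed = config$seed)
}

config_pic_params <- function(config) {
  p <- config$pics
  pic_params(mz_tol_ppm = p$mz_tol_ppm, coarse_width = p$coarse_width,
             min_length = p$min_length, max_gap = p$max_gap,
             min_apex = p$min_apex)
}

config_scales <- function(config) {
  p <- config$peaks
  exp(seq(log(p$scale_min), log(p$scale_max), length.out = p$n_scales))
}

#' Pipeline: simulate a synthetic cohort
#'
#' Writes one mzML per sample under `<out>/raw/`, a `labels.csv` manifest
#' and the ground-truth tables.
#'
#' @param config resolved configuration ([load_config]).
#' @return invisibly, the list of written run paths.
#' @export
pipeline_simulate <- function(config = default_config()) {
  write_snapshot(config)
  raw_dir <- out_dir(config, "raw")
  sim <- simulate_cohort(config_cohort_spec(config))
  paths <- character(0)
  for (sid in names(sim$runs)) {
    p <- file.path(raw_dir, paste0(sid, ".mzML"))
    write_run(sim$runs[[sid]], p)
    paths[sid] <- p
  }
  write.csv(data.frame(sample_id = names(sim$labels),
                       label = unname(sim$labels)),
            file.path(out_dir(config), "labels.csv"), row.names = FALSE)
  write.csv(sim$truth$features,
            file.path(out_dir(config), "truth_features.csv"),
            row.names = FALSE)
  write.csv(sim$truth$samples,
            file.path(out_dir(config), "truth_samples.csv"),
            row.names = FALSE)
  message("simulate: ", length(paths), " runs written to ", raw_dir)
  invisible(paths)
}

pipeline_input_files <- function(config) {
  dir <- config$io$input_dir %||% file.path(config$io$output_dir, "raw")
  if (!dir.exists(dir)) stop_user("input directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.(mzML|mzXML|mzml|mzxml)$",
                      full.names = TRUE)
  if (!length(files))
    stop_user("no mzML/mzXML files in ", dir)
  sort(files)
}

#' Pipeline: extract PICs and peaks from every run
#'
#' @param config resolved configuration.
#' @return invisibly, named list of per-sample peak data.frames.
#' @export
pipeline_extract <- function(config = default_config()) {
  write_snapshot(config)
  files <- pipeline_input_files(config)
  params <- config_pic_params(config)
  scales <- config_scales(config)
  pic_dir <- out_dir(config, "pics")
  peak_dir <- out_dir(config, "peaks")
  peaks_by_sample <- list()
  for (f in files) {
    run <- read_run(f)
    pics <- extract_pics(run, params)
    pk <- detect_peaks_all(pics, scales = scales,
                           snr_min = config$peaks$snr_min)
    write.csv(as.data.frame(pics),
              file.path(pic_dir, paste0(run$sample_id, "_pics.csv")),
              row.names = FALSE)
    write.csv(pk, file.path(peak_dir,
                            paste0(run$sample_id, "_peaks.csv")),
              row.names = FALSE)
    peaks_by_sample[[run$sample_id]] <- pk
    message("extract: ", run$sample_id, ": ", length(pics), " PICs, ",
            nrow(pk), " peaks")
  }
  invisible(peaks_by_sample)
}

read_labels <- function(config) {
  lf <- config$io$labels_file %||%
    file.path(config$io$output_dir, "labels.csv")
  if (!file.exists(lf)) return(NULL)
  lab <- read.csv(lf)
  setNames(as.character(lab$label), lab$sample_id)
}

#' Pipeline: build the cross-sample peak table
#'
#' RT-shift correction against the first sample, grouping, isotope and
#' adduct annotation, missing-value filling from the raw runs, and
#' (configurably) normalization. Writes `table.csv` (+ labels companion).
#'
#' @param config resolved configuration.
#' @return invisibly, the [peak_table].
#' @export
pipeline_table <- function(config = default_config()) {
  write_snapshot(config)
  peak_dir <- file.path(config$io$output_dir, "peaks")
  pk_files <- sort(list.files(peak_dir, pattern = "_peaks\\.csv$",
                              full.names = TRUE))
  if (!length(pk_files))
    stop_user("no extracted peaks found under ", peak_dir,
              "; run pipeline_extract first")
  peaks_by_sample <- lapply(pk_files, read.csv)
  names(peaks_by_sample) <- sub("_peaks\\.csv$", "", basename(pk_files))
  labels <- read_labels(config)
  if (!is.null(labels) &&
      !all(names(peaks_by_sample) %in% names(labels)))
    stop_user("labels file does not cover all extracted samples")
  fcfg <- config$features
  shifted <- rt_shift_correct(peaks_by_sample,
                              reference = names(peaks_by_sample)[1L],
                              mz_tol_ppm = fcfg$mz_tol_ppm,
                              rt_tol_s = fcfg$rt_tol_s)
  groups <- group_across_samples(shifted$peaks,
                                 mz_tol_ppm = fcfg$mz_tol_ppm,
                                 rt_tol_s = fcfg$rt_tol_s,
                                 min_frac = fcfg$min_frac,
                                 labels = labels)
  groups <- annotate_isotopes(groups, mz_tol_ppm = fcfg$mz_tol_ppm,
                              rt_tol_s = fcfg$rt_tol_s)
  groups <- annotate_adducts(groups, mz_tol_ppm = fcfg$mz_tol_ppm,
                             rt_tol_s = fcfg$rt_tol_s)
  files <- pipeline_input_files(config)
  runs <- lapply(files, read_run)
  names(runs) <- vapply(runs, `[[`, "", "sample_id")
  tbl <- fill_missing(groups, runs, config_pic_params(config),
                      rt_tol_s = fcfg$fill_rt_tol_s, labels = labels)
  if (identical(fcfg$normalize_at, "table"))
    tbl <- normalize_table(tbl)
  write_peak_table(tbl, file.path(out_dir(config), "table.csv"))
  message("table: ", nrow(tbl$matrix), " samples x ", ncol(tbl$matrix),
          " features")
  invisible(tbl)
}

read_pipeline_table <- function(config) {
  tf <- file.path(config$io$output_dir, "table.csv")
  if (!file.exists(tf))
    stop_user("no peak table at ", tf, "; run pipeline_table first")
  read_peak_table(tf,
                  normalized = identical(config$features$normalize_at,
                                         "table"))
}

#' Pipeline: embed and visualize the peak table
#'
#' Writes PCA, t-SNE and UMAP coordinates as CSV (and optional PNG
#' scatter plots). Embeddings are fit on the autoscaled full table.
#'
#' @param config resolved configuration.
#' @return invisibly, named list of `ms_embedding`s.
#' @export
pipeline_viz <- function(config = default_config()) {
  write_snapshot(config)
  tbl <- read_pipeline_table(config)
  if (!tbl$normalized) tbl <- normalize_table(tbl)
  ecfg <- config$embed
  n <- nrow(tbl$matrix)
  out <- list(
    pca = pca_embed(tbl),
    tsne = tsne_embed(tbl, perplexity = ecfg$perplexity,
                      seed = config$seed),
    umap = umap_embed(tbl,
                      n_neighbors = min(ecfg$n_neighbors, n - 1L),
                      min_dist = ecfg$min_dist, seed = config$seed))
  viz_dir <- out_dir(config, "viz")
  for (m in names(out)) {
    write_embedding(out[[m]], file.path(viz_dir, paste0(m, ".csv")))
    if (isTRUE(ecfg$write_plots)) {
      grDevices::png(file.path(viz_dir, paste0(m, ".png")),
                     width = 600, height = 500)
      plot(out[[m]], labels = tbl$labels, main = toupper(m))
      grDevices::dev.off()
    }
  }
  message("viz: embeddings written to ", viz_dir)
  invisible(out)
}

#' Pipeline: train the boosted discriminant model
#'
#' Stratified 67/33 split, optional grid-search CV on the training set,
#' normalization statistics fit on the training split and applied to all
#' samples, and a [gbtree] fit. Writes `model.json`, `split.csv`,
#' `table_normalized.csv` and (with a grid) `cv_table.csv`.
#'
#' @param config resolved configuration.
#' @return invisibly, the fitted [gbtree].
#' @export
pipeline_train <- function(config = default_config()) {
  write_snapshot(config)
  tbl <- read_pipeline_table(config)
  if (is.null(tbl$labels))
    stop_user("peak table carries no labels; training needs classes")
  bcfg <- config$boost
  split <- train_test_split(tbl, test_fraction = bcfg$test_fraction,
                            stratify = TRUE, seed = config$seed)
  if (!tbl$normalized) {
    ntab <- normalize_table(tbl, fit_on = split$train$sample_ids)
  } else ntab <- tbl
  xtr <- ntab$matrix[split$train$sample_ids, , drop = FALSE]
  ytr <- ntab$labels[split$train$sample_ids]
  pars <- list(n_estimators = bcfg$n_estimators,
               learning_rate = bcfg$learning_rate,
               max_depth = bcfg$max_depth, gamma = bcfg$gamma,
               reg_lambda = bcfg$reg_lambda,
               min_child_weight = bcfg$min_child_weight,
               subsample = bcfg$subsample,
               colsample_bytree = bcfg$colsample_bytree)
  if (!is.null(bcfg$grid)) {
    grid <- expand.grid(bcfg$grid, stringsAsFactors = FALSE)
    cv <- grid_search_cv(xtr, ytr, grid, k_folds = bcfg$k_folds,
                         seed = config$seed)
    pars[names(cv$best_params)] <- as.list(cv$best_params)
    write.csv(cv$cv_table, file.path(out_dir(config), "cv_table.csv"),
              row.names = FALSE)
    message("train: grid search best CV accuracy ",
            round(cv$best_accuracy, 3))
  }
  model <- do.call(gbtree, c(list(x = xtr, y = ytr, seed = config$seed),
                             pars))
  write_gbtree(model, file.path(out_dir(config), "model.json"))
  write_peak_table(ntab, file.path(out_dir(config),
                                   "table_normalized.csv"))
  split_df <- data.frame(
    sample_id = c(split$train$sample_ids, split$test$sample_ids),
    role = rep(c("train", "test"),
               c(length(split$train$sample_ids),
                 length(split$test$sample_ids))))
  write.csv(split_df[order(split_df$sample_id), ],
            file.path(out_dir(config), "split.csv"), row.names = FALSE)
  message("train: model fitted on ", nrow(xtr), " samples")
  invisible(model)
}

#' Pipeline: evaluate the trained model on the held-out test set
#'
#' Writes `metrics.json` (accuracy, per-class and macro metrics, AUCs),
#' `roc.csv` and `confusion.csv`.
#'
#' @param config resolved configuration.
#' @return invisibly, the evaluation list ([evaluate_classifier]).
#' @export
pipeline_evaluate <- function(config = default_config()) {
  write_snapshot(config)
  od <- config$io$output_dir
  mf <- file.path(od, "model.json")
  if (!file.exists(mf))
    stop_user("no model at ", mf, "; run pipeline_train first")
  model <- read_gbtree(mf)
  ntab <- read_peak_table(file.path(od, "table_normalized.csv"),
                          normalized = TRUE)
  split_df <- read.csv(file.path(od, "split.csv"))
  test_ids <- split_df$sample_id[split_df$role == "test"]
  xte <- ntab$matrix[test_ids, , drop = FALSE]
  yte <- ntab$labels[test_ids]
  pred <- predict(model, xte)
  proba <- predict(model, xte, type = "prob")
  ev <- evaluate_classifier(yte, pred, proba, classes = model$classes)
  metrics <- list(
    accuracy = ev$metrics$accuracy,
    macro = as.list(ev$metrics$macro),
    per_class = ev$metrics$per_class,
    macro_auc = ev$roc$macro_auc,
    auc_per_class = lapply(ev$roc$per_class, `[[`, "auc"))
  jsonlite::write_json(metrics, file.path(od, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  roc_df <- do.call(rbind, lapply(names(ev$roc$per_class), function(cl) {
    rc <- ev$roc$per_class[[cl]]
    data.frame(class = cl, threshold = rc$thresholds, fpr = rc$fpr,
               tpr = rc$tpr)
  }))
  write.csv(roc_df, file.path(od, "roc.csv"), row.names = FALSE)
  write.csv(as.data.frame(unclass(ev$confusion)),
            file.path(od, "confusion.csv"))
  message("evaluate: test accuracy ", round(ev$metrics$accuracy, 3),
          ", macro AUC ", round(ev$roc$macro_auc, 3))
  invisible(ev)
}

#' Pipeline: compare two feature tables (Venn counts)
#'
#' @param config resolved configuration with `compare$table_a` and
#'   `compare$table_b` pointing at peak-table CSVs.
#' @return invisibly, the [match_feature_sets] result.
#' @export
pipeline_compare <- function(config = default_config()) {
  write_snapshot(config)
  cc <- config$compare
  if (is.null(cc$table_a) || is.null(cc$table_b))
    stop_user("compare needs 'table_a' and 'table_b' paths")
  ta <- read_peak_table(cc$table_a)
  tb <- read_peak_table(cc$table_b)
  res <- match_feature_sets(ta, tb,
                            mz_tol_ppm = config$features$mz_tol_ppm,
                            rt_tol_s = config$features$rt_tol_s)
  jsonlite::write_json(res[c("n_only_a", "n_common", "n_only_b")],
                       file.path(out_dir(config), "venn.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Run the whole pipeline end to end
#'
#' simulate (unless `io$input_dir` points at existing runs) -> extract ->
#' table -> viz -> train -> evaluate.
#'
#' @param config resolved configuration.
#' @return invisibly, the evaluation result.
#' @export
pipeline_run <- function(config = default_config()) {
  if (is.null(config$io$input_dir)) pipeline_simulate(config)
  pipeline_extract(config)
  pipeline_table(config)
  pipeline_viz(config)
  pipeline_train(config)
  pipeline_evaluate(config)
}
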