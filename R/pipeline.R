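# Pipeline orchestration: simulate/load -> filter+extract -> impute ->
# interpatient split -> feature selection -> train -> evaluate.
# Stage outputs are cached in out_dir/cache keyed by a content hash of the
# stage inputs, so reruns with an unchanged config reuse artifacts.

#' Build a pipeline configuration
#'
#' All randomness in a run flows from the single `seed`. The configuration
#' round-trips through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]) and is copied as a provenance block into every
#' output the run writes.
#'
#' @param source `"synthetic"` (simulate a cohort) or `"files"` (read
#'   records from disk in the chosen dialect).
#' @param synthetic Options for the synthetic source: `n_train`, `n_test`
#'   (patients per side), `n_beats`, and any [sim_spec()] override such as
#'   `noise_sd`.
#' @param files Options for the file source: `dialect`, named lists
#'   `records` (id -> path), `train_records`, `test_records`.
#' @param filter Filter parameters (`per_ref_B3` defaults, see
#'   [filter_spec()]).
#' @param weight_mode `"inverse_prior"` or `"explicit"` (then give
#'   `weights`).
#' @param weights Named class weights when `weight_mode = "explicit"`.
#' @param selector `"mi-topk"` (filter ranking, keep the top `k`) or
#'   `"wrapper"` (forward-backward with the wLDA learner).
#' @param k Number of features kept by the mi-topk selector.
#' @param max_features Wrapper cap.
#' @param model `"wsvm"` or `"wlda"`.
#' @param grid `degrees` and `costs` searched by leave-one-patient-out CV
#'   when the model is wsvm; a 1x1 grid skips the search.
#' @param standardize Standardize features inside the SVM.
#' @param bcr_kind `"arithmetic"` or `"geometric"`.
#' @param seed Master seed.
#' @param out_dir Artifact directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = "synthetic",
                            synthetic = list(n_train = 8L, n_test = 4L,
                                             n_beats = 300L),
                            files = list(),
                            filter = list(baseline_window_1 = 0.2,
                                          baseline_window_2 = 0.6,
                                          lowpass_cutoff = 35,
                                          provenance = "per_ref_B3"),
                            weight_mode = "inverse_prior", weights = NULL,
                            selector = "mi-topk", k = 6L, max_features = 10L,
                            model = "wsvm",
                            grid = list(degrees = c(2), costs = c(1)),
                            standardize = TRUE,
                            bcr_kind = "arithmetic",
                            seed = 1L, out_dir = tempfile("ecgbeats_run_"),
                            log_level = "info") {
  cfg <- list(source = source, synthetic = synthetic, files = files,
              filter = filter, weight_mode = weight_mode, weights = weights,
              selector = selector, k = as.integer(k),
              max_features = as.integer(max_features), model = model,
              grid = grid, standardize = standardize, bcr_kind = bcr_kind,
              seed = as.integer(seed), out_dir = out_dir,
              log_level = log_level)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$source %in% c("synthetic", "files"))
    stop("config error: unknown source '", cfg$source, "'")
  if (!cfg$model %in% c("wsvm", "wlda"))
    stop("config error: unknown model '", cfg$model, "'")
  if (!cfg$selector %in% c("mi-topk", "wrapper", "none"))
    stop("config error: unknown selector '", cfg$selector, "'")
  if (!cfg$weight_mode %in% c("inverse_prior", "explicit"))
    stop("config error: unknown weight_mode '", cfg$weight_mode, "'")
  if (cfg$weight_mode == "explicit" && is.null(cfg$weights))
    stop("config error: explicit weight_mode needs weights")
  if (!cfg$bcr_kind %in% c("arithmetic", "geometric"))
    stop("config error: unknown bcr_kind '", cfg$bcr_kind, "'")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[intersect(names(cfg), names(formals(pipeline_config)))])
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[ecgbeats] ", ...)
  invisible(NULL)
}

# cache wrapper: compute value or reuse the cached artifact with this key
stage_cached <- function(cfg, name, key, compute) {
  dir.create(file.path(cfg$out_dir, "cache"), showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cfg$out_dir, "cache", paste0(name, "-", hash_obj(key), ".rds"))
  if (file.exists(f)) {
    pipe_log(cfg, "stage ", name, ": cached (", basename(f), ")")
    return(readRDS(f))
  }
  val <- compute()
  saveRDS(val, f)
  pipe_log(cfg, "stage ", name, ": computed")
  val
}

load_pipeline_records <- function(cfg) {
  if (cfg$source == "synthetic") {
    syn <- cfg$synthetic
    extra <- syn[setdiff(names(syn), c("n_train", "n_test", "n_beats"))]
    sims <- do.call(simulate_patients,
                    c(list(n_patients = syn$n_train + syn$n_test,
                           n_beats = syn$n_beats, seed = cfg$seed), extra))
    list(sims = sims,
         train_ids = names(sims)[seq_len(syn$n_train)],
         test_ids = names(sims)[syn$n_train + seq_len(syn$n_test)])
  } else {
    fl <- cfg$files
    sims <- lapply(fl$records, function(p) {
      rec <- read_record(p, fl$dialect)
      ref <- read_beats(p, fl$dialect, "reference")
      det <- tryCatch(read_beats(p, fl$dialect, "detected"), error = function(e) ref)
      fid <- read_fiducials(p, fl$dialect, beats = ref)
      list(record = rec, beats_ref = ref, beats_det = det, fiducials = fid)
    })
    list(sims = sims, train_ids = unlist(fl$train_records),
         test_ids = unlist(fl$test_records))
  }
}

#' Run the full interpatient classification pipeline
#'
#' Executes the stages in order -- data, filtering + feature extraction,
#' patient-mean imputation, interpatient split, feature selection, model
#' training, evaluation -- with content-hash caching of the heavy stages,
#' and writes the feature matrix, ranking or selection trace, model and
#' report under `cfg$out_dir`. Model selection (feature subsets,
#' hyperparameters, imputation statistics, histogram ranges) only ever sees
#' training-side patients.
#'
#' @param cfg A [pipeline_config()] (or path to its YAML file).
#' @return A list of class `pipeline_result`: `report`
#'   (`evaluation_report`), `features` (selected names), `model`, `cv`
#'   (grid log or NULL), `paths` of written artifacts.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fspec <- filter_spec(cfg$filter$baseline_window_1, cfg$filter$baseline_window_2,
                       cfg$filter$lowpass_cutoff)

  data <- stage_cached(cfg, "data", cfg[c("source", "synthetic", "files", "seed")],
                       function() load_pipeline_records(cfg))
  fm <- stage_cached(cfg, "features",
                     list(cfg[c("source", "synthetic", "files", "seed", "filter")]),
                     function() {
    fms <- lapply(names(data$sims), function(id) {
      s <- data$sims[[id]]
      s$record$record_id <- id
      extract_sim_features(s, fspec)
    })
    impute_patient_mean(rbind_features(fms))
  })
  stem <- file.path(cfg$out_dir, "features")
  write_features(fm, stem)
  paths <- list(features_csv = paste0(stem, ".csv"),
                features_json = paste0(stem, ".json"))

  sp <- split_interpatient(fm, data$train_ids, data$test_ids)
  y_tr <- sp$train$beats$label; y_te <- sp$test$beats$label
  classes <- AAMI_CLASSES[AAMI_CLASSES %in% unique(y_tr)]
  weights <- if (cfg$weight_mode == "inverse_prior")
    inverse_prior_weights(y_tr, classes) else unlist(cfg$weights)[classes]

  if (cfg$selector == "mi-topk") {
    ranking <- rank_by_mi(sp$train, y_tr)
    paths$ranking <- file.path(cfg$out_dir, "ranking.tsv")
    write_mi_ranking(ranking, paths$ranking)
    feats <- ranking$name[seq_len(min(cfg$k, nrow(ranking)))]
    pipe_log(cfg, "mi-topk selected: ", paste(feats, collapse = ", "))
  } else if (cfg$selector == "wrapper") {
    trace <- forward_backward(sp$train, y_tr,
                              max_features = cfg$max_features,
                              seed = cfg$seed)
    paths$trace <- file.path(cfg$out_dir, "trace.json")
    write_trace_json(trace, paths$trace)
    feats <- trace$final_set
    pipe_log(cfg, "wrapper selected: ", paste(feats, collapse = ", "))
  } else feats <- colnames(fm$x)

  x_tr <- sp$train$x[, feats, drop = FALSE]
  x_te <- sp$test$x[, feats, drop = FALSE]
  cv <- NULL
  if (cfg$model == "wsvm") {
    degrees <- cfg$grid$degrees; costs <- cfg$grid$costs
    if (length(degrees) * length(costs) > 1L) {
      cv <- loo_patient_cv(sp$train, y_tr, degrees = degrees, costs = costs,
                           weights = weights, features = feats,
                           standardize = cfg$standardize)
      degree <- cv$best$degree; cost <- cv$best$cost
    } else { degree <- degrees[1]; cost <- costs[1] }
    model <- wsvm(x_tr, y_tr, degree = degree, cost = cost, weights = weights,
                  standardize = cfg$standardize)
    paths$model <- file.path(cfg$out_dir, "model.rds")
    saveRDS(list(format = "ecgbeats-wsvm-v1", model = model), paths$model)
  } else {
    model <- wlda(x_tr, y_tr, weights)
    paths$model <- file.path(cfg$out_dir, "model.json")
    write_wlda_json(model, paths$model)
  }

  pred <- predict(model, x_te)
  classes_eval <- classes[classes %in% unique(y_te)]
  if (length(classes_eval) < length(classes))
    pipe_log(cfg, "classes absent from the test side: ",
             paste(setdiff(classes, classes_eval), collapse = ", "))
  report <- evaluation_report(y_te, pred, classes = classes_eval,
                              kind = cfg$bcr_kind)
  paths$report <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(
    list(bcr = report$bcr,
         per_class_accuracy = as.list(report$per_class_accuracy),
         n_beats = as.list(stats::setNames(report$n_beats, classes_eval)),
         confusion = as.data.frame.matrix(unclass(report$confusion)),
         features = feats, model = cfg$model,
         class_ratios = as.data.frame.matrix(sp$ratios),
         provenance = unclass(cfg)),
    paths$report, auto_unbox = TRUE, digits = NA)
  pipe_log(cfg, sprintf("test BCR %.2f%%", 100 * report$bcr))
  structure(list(report = report, features = feats, model = model, cv = cv,
                 split = sp["ratios"], paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result -- features:", paste(x$features, collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}
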