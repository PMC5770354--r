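#' Pipeline configuration
#'
#' Assembles and validates the configuration for a full automated QSAR
#' modeling run. Three input modes are supported: \code{fully_automated}
#' (a target accession plus activity type, resolved against a ChEMBL-style
#' activity endpoint or a saved response), \code{customized_structures}
#' (a CSV/SMILES/SDF file of compound records), and
#' \code{customized_features} (a precomputed feature table: column
#' \code{compound_id}, column \code{activity_value}, numeric features).
#'
#' @param mode One of \code{"fully_automated"},
#'   \code{"customized_structures"}, \code{"customized_features"}.
#' @param workdir Working directory for all run artifacts.
#' @param input_path Input file (customized modes).
#' @param uniprot_id,activity_type Target accession and activity label
#'   (\code{fully_automated} requires both; \code{activity_type} is also
#'   required for \code{customized_structures} curation).
#' @param endpoint Activity endpoint URL or saved-response path
#'   (\code{fully_automated}).
#' @param target_name Free-text label recorded in the manifest.
#' @param include_descriptors Compute the descriptor block (default TRUE).
#' @param fingerprints List of \code{\link{fingerprint_spec}}s (default a
#'   single Morgan radius-2 / 1024-bit block).
#' @param nfold Importance-ranking folds (default 10).
#' @param ntree Trees per forest (default 500).
#' @param learner Stepwise/final learner, \code{"svm"} or \code{"rf"}.
#' @param ranking_methods Which importance aggregations to carry through
#'   selection (default both \code{"scaled"} and \code{"unscaled"}).
#' @param train_fraction Outer training fraction (default 0.75).
#' @param step_size Stepwise increment (default 1).
#' @param tolerance Parsimony tolerance for subset selection (default 0).
#' @param modi_threshold Modelability gate threshold (default 0.45).
#' @param modi_mode \code{"warn"} or \code{"halt"}.
#' @param ad_Z Applicability-domain multiplier (default 0.5).
#' @param activity_prescaled Skip the activity log scaling when inputs are
#'   already normalized to \[0, 1\] (default FALSE).
#' @param seed Base seed; every stochastic stage derives its own seed from
#'   it by a fixed offset.
#' @return An object of class \code{qsar_config}.
#' @export
qsar_config <- function(mode = c("customized_features",
                                 "customized_structures",
                                 "fully_automated"),
                        workdir,
                        input_path = NULL,
                        uniprot_id = NULL, activity_type = NULL,
                        endpoint = NULL, target_name = NULL,
                        include_descriptors = TRUE,
                        fingerprints = list(fingerprint_spec()),
                        nfold = 10L, ntree = 500L,
                        learner = c("svm", "rf"),
                        ranking_methods = c("scaled", "unscaled"),
                        train_fraction = 0.75, step_size = 1L,
                        tolerance = 0,
                        modi_threshold = 0.45,
                        modi_mode = c("warn", "halt"),
                        ad_Z = 0.5,
                        activity_prescaled = FALSE,
                        seed = 1L) {
  mode <- match.arg(mode)
  learner <- match.arg(learner)
  modi_mode <- match.arg(modi_mode)
  ranking_methods <- match.arg(ranking_methods, several.ok = TRUE)
  if (missing(workdir) || !nzchar(workdir))
    config_error("workdir is required")
  if (mode == "fully_automated") {
    if (is.null(uniprot_id) || is.null(activity_type) || is.null(endpoint))
      config_error("fully_automated mode requires uniprot_id, activity_type and endpoint")
  } else {
    if (is.null(input_path))
      config_error(paste0(mode, " mode requires input_path"))
  }
  if (mode == "customized_structures" && is.null(activity_type))
    config_error("customized_structures mode requires activity_type")
  structure(list(
    mode = mode, workdir = workdir, input_path = input_path,
    uniprot_id = uniprot_id, activity_type = activity_type,
    endpoint = endpoint, target_name = target_name,
    include_descriptors = include_descriptors, fingerprints = fingerprints,
    nfold = as.integer(nfold), ntree = as.integer(ntree),
    learner = learner, ranking_methods = ranking_methods,
    train_fraction = train_fraction, step_size = as.integer(step_size),
    tolerance = tolerance, modi_threshold = modi_threshold,
    modi_mode = modi_mode, ad_Z = ad_Z,
    activity_prescaled = activity_prescaled, seed = as.integer(seed)),
    class = "qsar_config")
}

# fixed per-stage seed offsets: the whole run reproduces from one integer
stage_seed <- function(config, stage) {
  config$seed + switch(stage, partition = 1L, ranking = 2L,
                       stepwise = 3L, model = 4L)
}

#' Run the automated QSAR modeling pipeline
#'
#' Executes, in order: input ingestion (per mode), curation, featurization,
#' activity scaling, 75/25 partition into training set and Independent
#' Validation Set, train-set min-max feature scaling, the modelability
#' gate, random-forest importance ranking (per configured method),
#' stepwise feature selection, full-model and selected-feature-model
#' fitting, external validation and the applicability-domain report. Every
#' stage writes its artifact into the working directory before the next
#' stage starts, so a failed run keeps its partial outputs.
#'
#' @param config A \code{\link{qsar_config}}.
#' @return An object of class \code{qsar_run}: paths of all artifacts plus
#'   the in-memory reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qsar_config"))
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(wd, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  artifacts <- list(run_log = logfile)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (inherits(e, "autoqsar_error")) {
        e$message <- paste0("[stage ", name, "] ", conditionMessage(e))
        stop(e)
      }
      abort_aq(paste0("[stage ", name, "] ", conditionMessage(e)),
               "autoqsar_stage_error")
    })
  }

  # ---- ingest + curate + featurize ------------------------------------
  if (config$mode == "customized_features") {
    stage("ingest", {
      df <- utils::read.csv(config$input_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
      if (!all(c("compound_id", "activity_value") %in% names(df)))
        config_error("feature-table input needs compound_id and activity_value columns")
      raw_activity <- stats::setNames(as.numeric(df$activity_value),
                                      df$compound_id)
      feat_cols <- setdiff(names(df), c("compound_id", "activity_value"))
      v <- as.matrix(df[, feat_cols, drop = FALSE])
      storage.mode(v) <- "double"
      rownames(v) <- df$compound_id
      keep <- apply(v, 2L, function(col) max(col) > min(col))
      kinds <- ifelse(apply(v, 2L, function(col) all(col %in% c(0, 1))),
                      "fingerprint", "descriptor")
      features <- feature_matrix(v[, keep, drop = FALSE], kinds[keep])
      aq_log("ingest", nrow(v), " feature rows, ", sum(keep), " usable columns",
             file = logfile)
    })
  } else {
    records <- stage("ingest", {
      if (config$mode == "fully_automated") {
        q <- target_query(config$uniprot_id, config$activity_type)
        payload <- fetch_bioactivities(q, config$endpoint)
        r <- parse_chembl_payload(payload)
        aq_log("ingest", length(payload), " activity entries, ",
               nrow(r), " records (", nrow(attr(r, "skips")), " skipped)",
               file = logfile)
        r
      } else {
        r <- parse_input(config$input_path)
        aq_log("ingest", nrow(r), " records from ", config$input_path,
               file = logfile)
        r
      }
    })
    curated <- stage("curate", {
      cd <- curate(records, config$activity_type)
      write_curation_log(cd, file.path(wd, "curation_log.csv"))
      utils::write.csv(cd$records, file.path(wd, "curated_records.csv"),
                       row.names = FALSE)
      aq_log("curate", nrow(cd$records), " records kept", file = logfile)
      cd
    })
    artifacts$curation_log <- file.path(wd, "curation_log.csv")
    stage("featurize", {
      smis <- stats::setNames(curated$records$canonical_smiles,
                              curated$records$compound_id)
      blocks <- list()
      if (config$include_descriptors)
        blocks <- c(blocks, list(compute_descriptors(smis)))
      for (s in config$fingerprints)
        blocks <- c(blocks, list(compute_fingerprints(smis, s)))
      # drop compounds rejected by any block before merging
      keep_ids <- Reduce(intersect, lapply(blocks, function(b)
        rownames(fm_values(b))))
      blocks <- lapply(blocks, function(b) fm_subset(b, keep_ids))
      features <- merge_feature_blocks(blocks)
      raw_activity <- stats::setNames(
        curated$records$activity_value,
        curated$records$compound_id)[rownames(fm_values(features))]
      manifest <- list(
        toolkit = chem_toolkit_version(),
        include_descriptors = config$include_descriptors,
        fingerprints = lapply(config$fingerprints, unclass),
        removed_constant = attr(features, "removed_constant"))
      jsonlite::write_json(manifest, file.path(wd, "features_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_feature_matrix(features, file.path(wd, "features.csv"))
      aq_log("featurize", nrow(fm_values(features)), " x ",
             ncol(fm_values(features)), " feature matrix", file = logfile)
    })
    artifacts$features <- file.path(wd, "features.csv")
  }

  # ---- scale activities + partition + scale features ------------------
  y_scaled <- stage("scale_activity", {
    if (config$activity_prescaled) {
      if (any(raw_activity < 0 | raw_activity > 1))
        domain_error("activity_prescaled is set but values fall outside [0, 1]")
      raw_activity
    } else scale_activity(raw_activity)
  })
  split <- stage("partition", {
    s <- partition_data(rownames(fm_values(features)),
                        config$train_fraction,
                        stage_seed(config, "partition"))
    aq_log("partition", length(s$train_ids), " training / ",
           length(s$ivs_ids), " IVS compounds", file = logfile)
    s
  })
  stage("scale_features", {
    X_train <- fm_subset(features, split$train_ids)
    # columns constant within the training partition cannot be min-max
    # scaled; drop them from the run (logged), as at merge time
    vtr <- fm_values(X_train)
    keep <- colnames(vtr)[apply(vtr, 2L, function(col) max(col) > min(col))]
    if (length(keep) < ncol(vtr))
      aq_log("scale_features", ncol(vtr) - length(keep),
             " columns constant in the training partition removed",
             file = logfile)
    X_train <- fm_subset(X_train, cols = keep)
    scaler <- fit_minmax(X_train)
    X_train_s <- apply_minmax(X_train, scaler)
    X_ivs_s <- apply_minmax(fm_subset(features, split$ivs_ids, keep), scaler)
  })
  y_train <- y_scaled[split$train_ids]
  y_ivs <- y_scaled[split$ivs_ids]

  # ---- modelability gate ----------------------------------------------
  modi_res <- stage("modelability", {
    m <- modi(X_train_s, y_train, threshold = config$modi_threshold)
    jsonlite::write_json(
      list(scores = m$scores, gate_k = m$gate_k, score = m$score,
           threshold = m$gate_threshold, passed = m$passed),
      file.path(wd, "modi.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    aq_log("modelability",
           paste(sprintf("MODI(k=%d)=%.3f", m$scores$k, m$scores$score),
                 collapse = " "),
           " gate=", if (m$passed) "pass" else "fail", file = logfile)
    modelability_gate(m, config$modi_mode)
    m
  })
  artifacts$modi <- file.path(wd, "modi.json")

  # ---- ranking + stepwise selection per method ------------------------
  ranking <- stage("ranking", {
    rk <- rank_features_cv(X_train_s, y_train, nfold = config$nfold,
                           ntree = config$ntree,
                           seed = stage_seed(config, "ranking"))
    tab <- rk$scaled
    full_tab <- data.frame(
      feature = tab$feature, mean_importance = tab$mean_importance,
      z_score = tab$z_score,
      rank_scaled = match(tab$feature, rank_features(rk$scaled)),
      rank_unscaled = match(tab$feature, rank_features(rk$unscaled)),
      stringsAsFactors = FALSE)
    utils::write.csv(full_tab[order(full_tab$rank_scaled), ],
                     file.path(wd, "importance.csv"), row.names = FALSE)
    aq_log("ranking", "importance over ", config$nfold, " folds",
           file = logfile)
    rk
  })
  artifacts$importance <- file.path(wd, "importance.csv")

  selections <- list()
  for (method in config$ranking_methods) {
    selections[[method]] <- stage(paste0("stepwise_", method), {
      ranked <- rank_features(ranking[[method]])
      tr <- stepwise_trace(X_train_s, y_train, ranked,
                           learner = config$learner,
                           step_size = config$step_size,
                           seed = stage_seed(config, "stepwise"))
      utils::write.csv(as.data.frame(tr),
                       file.path(wd, paste0("stepwise_", method, ".csv")),
                       row.names = FALSE)
      grDevices::png(file.path(wd, paste0("stepwise_", method, ".png")),
                     width = 720, height = 480)
      plot(tr, main = paste("stepwise selection -", method, "ranking"))
      grDevices::dev.off()
      sel <- select_features(tr, ranked, config$tolerance)
      aq_log(paste0("stepwise_", method), "selected ", sel$size,
             " features (internal RMSE ", sprintf("%.4f", sel$rmse), ")",
             file = logfile)
      list(trace = tr, selected = sel)
    })
  }

  # ---- model building + external validation + AD ----------------------
  internal_split <- attr(selections[[1L]]$trace, "internal_split")
  reports <- list()
  ad_rows <- list()
  fz <- if (config$mode == "customized_features") NULL else
    list(include_descriptors = config$include_descriptors,
         fingerprints = config$fingerprints)

  build <- function(label, feats) {
    vm <- fit_and_validate(X_train_s, y_train, X_ivs_s, y_ivs,
                           features = feats, learner = config$learner,
                           internal_split = internal_split,
                           model_label = label,
                           seed = stage_seed(config, "model"))
    bundle_dir <- file.path(wd, paste0("model_", label))
    save_model_bundle(vm, bundle_dir, scaler, X_train_s,
                      activity_scaled = !config$activity_prescaled,
                      ad_Z = config$ad_Z, featurization = fz)
    utils::write.csv(
      data.frame(compound_id = split$ivs_ids, observed = unname(y_ivs),
                 predicted = vm$predictions_ivs, stringsAsFactors = FALSE),
      file.path(wd, paste0("ivs_predictions_", label, ".csv")),
      row.names = FALSE)
    ad <- applicability_domain(
      fm_values(X_train_s)[, vm$features, drop = FALSE],
      fm_values(X_ivs_s)[, vm$features, drop = FALSE], Z = config$ad_Z)
    list(vm = vm, ad = ad, bundle = bundle_dir)
  }

  full <- stage("model_full", build("full", NULL))
  reports$full <- full$vm$report
  ad_rows$full <- cbind(model = "full", full$ad$compounds)
  artifacts$model_full <- full$bundle
  for (method in config$ranking_methods) {
    label <- paste0("sf_", method)
    built <- stage(paste0("model_", label),
                   build(label, selections[[method]]$selected$features))
    reports[[label]] <- built$vm$report
    ad_rows[[label]] <- cbind(model = label, built$ad$compounds)
    artifacts[[paste0("model_", label)]] <- built$bundle
  }

  validation_report <- do.call(rbind, unname(reports))
  rownames(validation_report) <- NULL
  utils::write.csv(validation_report, file.path(wd, "validation_report.csv"),
                   row.names = FALSE)
  ad_report <- do.call(rbind, unname(ad_rows))
  rownames(ad_report) <- NULL
  utils::write.csv(ad_report, file.path(wd, "ad_report.csv"),
                   row.names = FALSE)
  artifacts$validation_report <- file.path(wd, "validation_report.csv")
  artifacts$ad_report <- file.path(wd, "ad_report.csv")
  aq_log("validate", "IVS scores written", file = logfile)

  manifest <- list(
    config = unclass_config(config),
    seeds = list(base = config$seed,
                 partition = stage_seed(config, "partition"),
                 ranking = stage_seed(config, "ranking"),
                 stepwise = stage_seed(config, "stepwise"),
                 model = stage_seed(config, "model")),
    n_train = length(split$train_ids), n_ivs = length(split$ivs_ids),
    n_features = ncol(fm_values(X_train_s)),
    modi = list(score = modi_res$score, passed = modi_res$passed),
    selected = lapply(selections, function(s)
      list(size = s$selected$size, rmse = s$selected$rmse)),
    artifacts = artifacts,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(wd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts$manifest <- file.path(wd, "manifest.json")

  structure(list(
    artifacts = artifacts, config = config, split = split,
    modi = modi_res, selections = selections,
    validation_report = validation_report, ad_report = ad_report),
    class = "qsar_run")
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$fingerprints <- lapply(out$fingerprints, unclass)
  out
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("qsar_run in", x$config$workdir, "\n")
  cat(sprintf("MODI(k=%d) = %.3f (%s)\n", x$modi$gate_k, x$modi$score,
              if (x$modi$passed) "passed" else "failed"))
  print(x$validation_report, row.names = FALSE)
  invisible(x)
}
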