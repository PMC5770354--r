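#' Persist a validated model as a reusable bundle
#'
#' Writes a versioned directory holding everything needed to reproduce the
#' model's predictions on new compounds: the fitted learner, the selected
#' feature subset, the training-set min-max scaler restricted to that
#' subset, the activity-scaling flag, the applicability-domain reference
#' (scaled training rows and Z), and, for structure inputs, the
#' featurization recipe.
#'
#' @param vm A \code{validated_model} from \code{\link{fit_and_validate}}.
#' @param path Bundle directory (created if needed).
#' @param scaler The \code{minmax_params} fitted on the training partition.
#' @param X_train_scaled Scaled training matrix (any superset of the
#'   model's features); stored restricted to them for the AD check.
#' @param activity_scaled Whether activities passed through the log
#'   scaling, so external predictions are reported on the same scale.
#' @param ad_Z AD threshold multiplier.
#' @param featurization Optional list describing how to featurize raw
#'   structures: \code{include_descriptors} flag and a list of
#'   \code{fingerprint_spec}s.
#' @return \code{path}, invisibly.
#' @export
save_model_bundle <- function(vm, path, scaler, X_train_scaled,
                              activity_scaled = TRUE, ad_Z = 0.5,
                              featurization = NULL) {
  stopifnot(inherits(vm, "validated_model"),
            inherits(scaler, "minmax_params"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  feats <- vm$features
  Xt <- fm_values(X_train_scaled)[, feats, drop = FALSE]
  meta <- list(
    bundle_version = 1L,
    learner = vm$learner,
    features = feats,
    activity_scaled = activity_scaled,
    ad_Z = ad_Z,
    scaler = list(min = as.list(scaler$min[feats]),
                  max = as.list(scaler$max[feats])),
    seed = vm$seed)
  if (!is.null(featurization)) {
    meta$featurization <- list(
      include_descriptors = isTRUE(featurization$include_descriptors),
      fingerprints = lapply(featurization$fingerprints, function(s)
        list(kind = s$kind, n_bits = s$n_bits, radius = s$radius)),
      toolkit = tryCatch(chem_toolkit_version(), error = function(e) NULL))
  }
  jsonlite::write_json(meta, file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(vm$model, file.path(path, "model.rds"))
  utils::write.csv(
    data.frame(compound_id = rownames(Xt), Xt, check.names = FALSE),
    file.path(path, "train_scaled.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a persisted model bundle
#'
#' @param path Bundle directory written by \code{\link{save_model_bundle}}.
#' @return An object of class \code{model_bundle}.
#' @export
load_model_bundle <- function(path) {
  meta_path <- file.path(path, "bundle.json")
  if (!file.exists(meta_path))
    io_error(paste0("not a model bundle (no bundle.json): ", path))
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  model <- readRDS(file.path(path, "model.rds"))
  train <- utils::read.csv(file.path(path, "train_scaled.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  Xt <- as.matrix(train[, -1L, drop = FALSE])
  rownames(Xt) <- train[[1L]]
  scaler <- structure(list(min = unlist(meta$scaler$min),
                           max = unlist(meta$scaler$max)),
                      class = "minmax_params")
  structure(list(meta = meta, model = model, scaler = scaler,
                 X_train_scaled = Xt, path = path),
            class = "model_bundle")
}

#' Predict new compounds from a persisted model bundle
#'
#' Accepts either raw structures (SMILES, canonicalized and featurized
#' with the bundle's stored recipe) or precomputed feature rows (a
#' data.frame or matrix containing at least the bundle's feature columns,
#' on the unscaled feature scale). Inputs are scaled with the bundle's
#' stored training-set parameters, restricted to the selected features and
#' predicted; every prediction carries an applicability-domain flag from
#' the bundle's training reference.
#'
#' @param bundle A \code{model_bundle} or a bundle directory path.
#' @param newdata Character vector of SMILES, or a data.frame/matrix of
#'   feature rows.
#' @return A data.frame with columns \code{compound_id},
#'   \code{prediction}, \code{nn_distance}, \code{in_domain}; structure
#'   inputs that fail featurization appear with \code{NA} predictions and
#'   the rejection reason.
#' @export
predict_external <- function(bundle, newdata) {
  if (is.character(bundle) && length(bundle) == 1L)
    bundle <- load_model_bundle(bundle)
  stopifnot(inherits(bundle, "model_bundle"))
  feats <- bundle$meta$features
  rejections <- NULL

  if (is.character(newdata)) {
    fz <- bundle$meta$featurization
    if (is.null(fz))
      config_error("bundle was built from feature rows; supply feature rows, not structures")
    can <- canonicalize_and_desalt(
      newdata, names(newdata) %||% paste0("NEW_", seq_along(newdata)))
    ok <- can$status == "ok"
    rejections <- can[!ok, c("compound_id", "reason"), drop = FALSE]
    if (!any(ok)) empty_dataset_error("no input structure could be parsed")
    smis <- stats::setNames(can$canonical_smiles[ok], can$compound_id[ok])
    blocks <- list()
    if (isTRUE(fz$include_descriptors))
      blocks <- c(blocks, list(compute_descriptors(smis)))
    fps <- fz$fingerprints
    if (is.data.frame(fps)) fps <- split(fps, seq_len(nrow(fps)))
    for (s in fps)
      blocks <- c(blocks, list(compute_fingerprints(
        smis, fingerprint_spec(s$kind, s$n_bits, s$radius))))
    X <- do.call(cbind, lapply(blocks, fm_values))
  } else {
    X <- as.matrix(as.data.frame(newdata)[,
      setdiff(colnames(as.data.frame(newdata)), "compound_id"), drop = FALSE])
    if (is.null(rownames(X)) && "compound_id" %in% colnames(as.data.frame(newdata)))
      rownames(X) <- as.data.frame(newdata)$compound_id
    storage.mode(X) <- "double"
  }

  missing_cols <- setdiff(feats, colnames(X))
  if (length(missing_cols) > 0L)
    alignment_error(paste0("input lacks model feature(s): ",
                           paste(utils::head(missing_cols, 5L), collapse = ", ")))
  X <- X[, feats, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, bundle$scaler$min, "-"), 2L,
              bundle$scaler$max - bundle$scaler$min, "/")
  preds <- predict_learner(bundle$model, Xs)
  ad <- applicability_domain(bundle$X_train_scaled, Xs,
                             Z = bundle$meta$ad_Z)
  out <- data.frame(
    compound_id = rownames(Xs) %||% as.character(seq_len(nrow(Xs))),
    prediction = preds,
    nn_distance = ad$compounds$nn_distance,
    in_domain = ad$compounds$in_domain,
    reason = "", stringsAsFactors = FALSE)
  if (!is.null(rejections) && nrow(rejections) > 0L) {
    out <- rbind(out, data.frame(
      compound_id = rejections$compound_id, prediction = NA_real_,
      nn_distance = NA_real_, in_domain = NA, reason = rejections$reason,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
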