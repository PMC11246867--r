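#' Persist a fitted model as JSON
#'
#' KNN-type models are memory-based: the (scaled) training data is part of
#' the model, so the document contains the configuration, scaler, member
#' definitions and training matrix. Numbers are written with 17 significant
#' digits, enough to round-trip IEEE doubles exactly, so a reloaded model
#' reproduces predictions bit-for-bit.
#'
#' @param model A fitted [rkknn_fit()] or [fit_plain_knn()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "rkknn")) {
    doc <- list(
      type = "rkknn",
      control = unclass(model$control),
      d = model$d,
      scaler = list(min = model$scaler$min, max = model$scaler$max),
      feature_names = model$feature_names,
      X = model$X,
      y = model$y,
      members = lapply(model$members, function(m) {
        list(bootstrap_indices = m$bootstrap_indices,
             feature_subset = m$feature_subset,
             k_opt = m$k_opt, h_opt = m$h_opt)
      })
    )
  } else if (inherits(model, "plain_knn")) {
    doc <- list(
      type = "plain_knn",
      scaler = list(min = model$scaler$min, max = model$scaler$max),
      X = model$X,
      y = model$y,
      k_opt = model$k_opt
    )
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Load a model persisted by [save_model()]
#'
#' @param path JSON path.
#' @return The reconstructed `rkknn` or `plain_knn` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(list(min = as.numeric(doc$scaler$min),
                           max = as.numeric(doc$scaler$max)),
                      class = "rk_scaler")
  if (identical(doc$type, "plain_knn")) {
    X <- as.matrix(doc$X)
    return(structure(
      list(scaler = scaler, X = X, y = as.numeric(doc$y),
           k_opt = as.integer(doc$k_opt)),
      class = "plain_knn"
    ))
  }
  if (!identical(doc$type, "rkknn")) {
    stop("unrecognized model document type: ", doc$type)
  }
  ctl <- doc$control
  control <- rkknn_control(
    B = ctl$B, d = if (is.null(ctl$d)) NULL else ctl$d,
    kernel = ctl$kernel, folds = ctl$folds,
    k_candidates = if (is.null(ctl$k_candidates)) NULL else
      as.integer(ctl$k_candidates),
    kappas = as.numeric(ctl$kappas), master_seed = ctl$master_seed,
    tune_scope = ctl$tune_scope, aggregate = ctl$aggregate,
    resample = ctl$resample, tune_metric = ctl$tune_metric
  )
  # members arrive as a data frame when homogeneous; normalize to a list
  members <- doc$members
  if (is.data.frame(members)) {
    members <- lapply(seq_len(nrow(members)), function(i) {
      list(bootstrap_indices = as.integer(members$bootstrap_indices[[i]]),
           feature_subset = as.integer(members$feature_subset[[i]]),
           k_opt = as.integer(members$k_opt[[i]]),
           h_opt = as.numeric(members$h_opt[[i]]))
    })
  } else {
    members <- lapply(members, function(m) {
      list(bootstrap_indices = as.integer(unlist(m$bootstrap_indices)),
           feature_subset = as.integer(unlist(m$feature_subset)),
           k_opt = as.integer(m$k_opt),
           h_opt = if (is.null(m$h_opt)) NA_real_ else as.numeric(m$h_opt))
    })
  }
  X <- as.matrix(doc$X)
  colnames(X) <- doc$feature_names
  structure(
    list(control = control, d = as.integer(doc$d), scaler = scaler,
         X = X, y = as.numeric(doc$y),
         feature_names = as.character(doc$feature_names),
         members = members),
    class = "rkknn"
  )
}

#' Write predictions with provenance
#'
#' Writes a CSV of predictions; a comment-style header row is avoided, so
#' the seed and configuration travel in a sibling JSON sidecar
#' (`<path>.meta.json`) sufficient to rerun the prediction bit-identically.
#'
#' @param pred Numeric prediction vector.
#' @param path Output CSV path.
#' @param meta Named list of run metadata (seed, config, versions).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path, meta = list()) {
  utils::write.csv(data.frame(prediction = pred), path, row.names = FALSE)
  meta$package_version <- as.character(utils::packageVersion("rkknn"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}
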