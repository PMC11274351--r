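#' Write / read a feature schema file
#'
#' Schemas are stored as YAML (or JSON, by file extension): an ordered list of
#' features with `name`, `kind`, `min`, `max` and `colorIndex`.
#'
#' @param schema A [FeatureSchema-class].
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `writeSchema` returns `path` invisibly; `readSchema` the schema.
#' @export
writeSchema <- function(schema, path) {
  f <- schema@features
  lst <- lapply(seq_len(nrow(f)), function(i) {
    list(name = f$name[i], kind = f$kind[i], min = f$domainMin[i],
         max = f$domainMax[i], colorIndex = f$colorIndex[i])
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(list(features = lst), path)
  }
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)$features
  }
  specs <- lapply(lst, function(x) {
    featureSpec(x$name, x$kind, x$min, x$max, x$colorIndex)
  })
  do.call(featureSchema, specs)
}

#' Read a tabular dataset from CSV
#'
#' The CSV must have a header with exactly the schema's feature names plus a
#' `label` column (0/1, 1 = positive). Validation failures name the offending
#' row and column: missing values, non-binary labels and ordinal values
#' outside their declared domain are all rejected.
#'
#' @param csvPath Path to the comma-separated, `.`-decimal, UTF-8 data file.
#' @param schema A [FeatureSchema-class] or the path to a schema file.
#' @return A [TabularDataset-class]; row order is preserved.
#' @export
readTabularDataset <- function(csvPath, schema) {
  if (is.character(schema)) schema <- readSchema(schema)
  df <- utils::read.csv(csvPath, check.names = FALSE)
  nms <- featureNames(schema)
  missing <- setdiff(c(nms, "label"), names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  for (cn in c(nms, "label")) {
    bad <- which(is.na(df[[cn]]))
    if (length(bad)) {
      stop("missing value at row ", bad[1], ", column '", cn, "'")
    }
  }
  if (!all(df$label %in% c(0, 1))) {
    bad <- which(!df$label %in% c(0, 1))[1]
    stop("label must be 0/1; row ", bad, " has label ", df$label[bad])
  }
  f <- schema@features
  for (j in which(f$kind == "ordinal")) {
    x <- df[[f$name[j]]]
    bad <- which(x != round(x) | x < f$domainMin[j] | x > f$domainMax[j])
    if (length(bad)) {
      stop("ordinal feature '", f$name[j], "' out of domain [",
           f$domainMin[j], ", ", f$domainMax[j], "] at row ", bad[1],
           " (value ", x[bad[1]], ")")
    }
  }
  tabularDataset(schema, as.matrix(df[, nms, drop = FALSE]),
                 as.integer(df$label))
}

#' Write a tabular dataset to CSV
#'
#' @param dataset A [TabularDataset-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTabularDataset <- function(dataset, path) {
  df <- as.data.frame(featureValues(dataset))
  df$label <- classLabels(dataset)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore an evaluation report as JSON
#'
#' @param report An [EvaluationReport-class].
#' @param path JSON file path.
#' @return `writeEvaluationReport` returns `path` invisibly;
#'   `readEvaluationReport` the report.
#' @export
writeEvaluationReport <- function(report, path) {
  payload <- list(
    probs = report@probs, labels = report@labels,
    threshold = report@threshold, confusion = as.list(report@confusion),
    metrics = report@metrics, rocPoints = report@rocPoints,
    calibration = report@calibration, folds = report@folds,
    details = report@details[setdiff(names(report@details), "audit")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEvaluationReport
#' @export
readEvaluationReport <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EvaluationReport", probs = as.numeric(p$probs),
      labels = as.integer(p$labels), threshold = p$threshold,
      confusion = confusionCounts(p$confusion$TP, p$confusion$FP,
                                  p$confusion$TN, p$confusion$FN),
      metrics = as.list(p$metrics),
      rocPoints = as.data.frame(p$rocPoints),
      calibration = as.data.frame(p$calibration),
      folds = as.data.frame(p$folds),
      details = if (is.null(p$details)) list() else as.list(p$details))
}

#' Run the end-to-end pipeline
#'
#' Drives normalize, encode, optional augmentation and model evaluation from a
#' single configuration, writing the artifacts to disk. Modes:
#' \describe{
#'   \item{`"encode"`}{write one PNG per record to `outDir`.}
#'   \item{`"evaluate"`}{leave-one-out evaluation of one classifier
#'     ([runLoocv()]); writes `report.json`.}
#'   \item{`"stack"`}{stacking-ensemble evaluation ([stackLoocv()]); writes
#'     `report.json`.}
#' }
#' A single global seed fans out to per-stage and per-fold seeds through
#' [deriveSeed()], so two runs with identical configuration and seed produce
#' byte-identical reports.
#'
#' @param dataset A [TabularDataset-class] (or CSV path; then `schema` must be
#'   given).
#' @param mode One of `"encode"`, `"evaluate"`, `"stack"`.
#' @param outDir Output directory, created if needed.
#' @param schema Optional schema (object or path) when `dataset` is a path.
#' @param classifier Classifier for `"evaluate"` (default [cnnClassifier()]).
#' @param members Member list for `"stack"`.
#' @param meta Meta-factory for `"stack"`.
#' @param kAugment Augmentations per training image.
#' @param encoding An [encodingConfig()].
#' @param augmentation An [augmentationConfig()].
#' @param seed Global seed.
#' @param writeImages In `"evaluate"`/`"stack"` modes, also write the encoded
#'   PNGs.
#' @param ... Passed through to [runLoocv()] / [stackLoocv()].
#' @return The mode's result: a list of PNG paths, or an
#'   [EvaluationReport-class].
#' @export
runPipeline <- function(dataset, mode = c("encode", "evaluate", "stack"),
                        outDir = tempfile("tab2img_"), schema = NULL,
                        classifier = cnnClassifier(), members = NULL,
                        meta = rfMetaFactory(), kAugment = 0L,
                        encoding = encodingConfig(),
                        augmentation = augmentationConfig(),
                        seed = 1L, writeImages = FALSE, ...) {
  mode <- match.arg(mode)
  if (is.character(dataset)) {
    if (is.null(schema)) stop("a schema is required to read a CSV dataset")
    dataset <- readTabularDataset(dataset, schema)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t2iLog("pipeline", sprintf("mode=%s n=%d seed=%d", mode, nSamples(dataset),
                             seed))
  encodeAll <- function() {
    imgs <- encodeDataset(dataset, encoding)
    paths <- file.path(outDir, sprintf("record_%03d.png", seq_along(imgs)))
    for (i in seq_along(imgs)) writeImagePNG(imgs[[i]], paths[i])
    t2iLog("encode", sprintf("wrote %d PNG files to %s", length(paths), outDir))
    paths
  }
  if (mode == "encode") return(encodeAll())
  if (writeImages) encodeAll()
  report <- if (mode == "evaluate") {
    runLoocv(dataset, classifier, kAugment = kAugment, encoding = encoding,
             augmentation = augmentation, seed = deriveSeed(seed, 1), ...)
  } else {
    if (is.null(members)) stop("stack mode requires a member list")
    stackLoocv(dataset, members, meta = meta, encoding = encoding,
               augmentation = augmentation, seed = deriveSeed(seed, 2), ...)
  }
  writeEvaluationReport(report, file.path(outDir, "report.json"))
  t2iLog("report", sprintf("F1 %.3f AUC %.3f Brier %.4f",
                           report@metrics$f1, report@metrics$auc,
                           report@metrics$brier))
  report
}
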