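#' Simulate a synthetic cohort on disk
#'
#' Convenience wrapper around [generateCohort()] with study-like defaults:
#' paretic-limb functional fractions drawn in 0.2–0.5 (the non-paretic limb
#' higher), gait oscillation, and low sensor noise.
#'
#' @param outDir cohort directory to create.
#' @param nSubjects number of subjects.
#' @param seed cohort RNG seed.
#' @param sessionMinutes minutes of recording per subject.
#' @param ratesHz sampling rates to draw from.
#' @param annotators number of annotators.
#' @param transitionJitterS annotator disagreement half-width (s).
#' @param noiseSdG sensor noise (g).
#' @param profiles optional explicit paretic-limb profiles.
#' @return Invisibly, the manifest path.
#' @export
simulateCohort <- function(outDir, nSubjects = 8, seed = 1,
                           sessionMinutes = 10, ratesHz = c(30, 50),
                           annotators = 3, transitionJitterS = 0.5,
                           noiseSdG = 0.02, profiles = NULL) {
  cfg <- cohortConfig(nSubjects, ratesHz, sessionMinutes, annotators,
                      transitionJitterS, seed)
  if (is.null(profiles))
    profiles <- defaultProfiles(nSubjects, seed = .childSeed(seed, 999),
                                noiseSdG = noiseSdG)
  generateCohort(cfg, profiles, outDir)
}

#' Load a cohort manifest
#'
#' @param cohortDir directory written by [generateCohort()].
#' @return The parsed manifest list.
#' @export
readManifest <- function(cohortDir) {
  path <- file.path(cohortDir, "manifest.yaml")
  if (!file.exists(path)) .stopf("no manifest.yaml in %s", cohortDir)
  yaml::read_yaml(path)
}

# Preprocess one subject end to end: sync detection, clock alignment,
# down-sampling, axis harmonization, consensus labels, label transfer.
.preprocessSubject <- function(cohortDir, entry, frameRate, mirrorAxis = "x") {
  sides <- c("left", "right")
  roles <- ifelse(sides == entry$paretic_side, "paretic", "nonparetic")
  ann <- readAnnotationCsv(file.path(cohortDir, entry$files$annotations),
                           frameRateHz = frameRate)
  out <- list()
  for (i in seq_along(sides)) {
    side <- sides[i]
    tr <- readAccelCsv(file.path(cohortDir, entry$files[[side]]), side,
                       roles[i], rateHz = entry$rate_hz)
    peaks <- detectSyncPeaks(tr)
    map <- alignClocks(peaks, unlist(entry$video_peaks_s))
    tr30 <- resampleTo30Hz(tr)
    tr30 <- harmonizeAxes(tr30, mirrorAxis)
    cons <- consensusLabels(ann, side)
    lab30 <- transferLabels(cons, map, nSamples(tr30),
                            t0 = timeStamps(tr30)[1])
    out[[roles[i]]] <- list(trace = tr30, labels = lab30, map = map)
  }
  out
}

#' Build a windowed dataset variant from a cohort on disk
#'
#' Runs the full preprocessing chain for every subject — sync-peak
#' detection, video/sensor clock alignment, down-sampling to 30 Hz, axis
#' harmonization, majority-vote consensus labels, label transfer, unknown
#' removal and 2-s windowing — and concatenates the per-subject windows.
#'
#' @param cohortDir cohort directory.
#' @param variant `"paretic"`, `"nonparetic"` or `"combined"`.
#' @param windowS window length in seconds.
#' @param mirrorAxis axis negated on left-side traces.
#' @return A [WindowedDataset-class] spanning all subjects.
#' @export
buildVariantDataset <- function(cohortDir, variant = "paretic", windowS = 2,
                                mirrorAxis = "x") {
  man <- readManifest(cohortDir)
  parts <- lapply(man$subjects, function(entry) {
    pre <- .preprocessSubject(cohortDir, entry, man$video_frame_rate_hz,
                              mirrorAxis)
    assembleVariant(pre$paretic, pre$nonparetic, variant, windowS,
                    subjectId = entry$id)
  })
  .rbindDatasets(parts)
}

.rbindDatasets <- function(parts) {
  parts <- parts[vapply(parts, nSamples, 1L) > 0]
  if (!length(parts)) .stopf("no windows produced")
  n <- sum(vapply(parts, nSamples, 1L))
  d <- dim(windowArray(parts[[1]]))
  X <- array(0, c(n, d[2], d[3]))
  y <- integer(0)
  sid <- character(0)
  at <- 0L
  for (p in parts) {
    k <- nSamples(p)
    X[at + seq_len(k), , ] <- windowArray(p)
    y <- c(y, windowLabels(p))
    sid <- c(sid, subjectIds(p))
    at <- at + k
  }
  windowedDataset(X, y, sid, datasetVariant(parts[[1]]))
}

#' Evaluate a classifier over a split plan
#'
#' For every fold: fit the robust scaler on the training windows only and
#' apply it to both sides; optionally rebalance the training split with
#' SMOTE (never the test split); train the classifier (the conv/dense
#' network, or the random-forest baseline on handcrafted features) with the
#' held-out fold as the monitored validation set; and compute accuracy and
#' per-class F1 on both splits. Leave-one-subject-out plans are checked for
#' subject leakage on every fold.
#'
#' @param dataset a [WindowedDataset-class].
#' @param plan a `SplitPlan` from [makeIntrasubjectFolds()] or
#'   [makeLosoFolds()].
#' @param trainCfg a [trainConfig()].
#' @param smoteCfg optional [smoteConfig()]; applied to training data only.
#' @param classifier `"cnn"` or `"rf"`.
#' @param rfCfg an [rfSettings()] for the baseline.
#' @param seed base seed; per-fold training seeds derive from it.
#' @param verbose print per-fold progress.
#' @return An `EvaluationResult` list: `metrics` (one row per fold and
#'   split), `folds` (per-fold provenance: indices, scaler fit indices,
#'   SMOTE counts), `histories` (CNN training histories), `plan`,
#'   `classifier`.
#' @export
evaluateWithPlan <- function(dataset, plan, trainCfg = trainConfig(),
                             smoteCfg = NULL, classifier = c("cnn", "rf"),
                             rfCfg = rfSettings(), seed = 1,
                             verbose = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(is(dataset, "WindowedDataset"), inherits(plan, "SplitPlan"))
  X <- windowArray(dataset)
  y <- windowLabels(dataset)
  sids <- subjectIds(dataset)

  rows <- list()
  prov <- list()
  hists <- list()
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train
    te <- plan$folds[[f]]$test
    if (length(intersect(tr, te)))
      .stopf("fold %d: train and test indices overlap", f)
    if (plan$scheme == "loso" &&
        length(intersect(unique(sids[tr]), unique(sids[te]))))
      .stopf("fold %d: subject leakage between train and test", f)

    scaler <- fitScaler(X[tr, , , drop = FALSE])
    xTr <- applyScaler(scaler, X[tr, , , drop = FALSE])
    xTe <- applyScaler(scaler, X[te, , , drop = FALSE])
    yTr <- y[tr]; yTe <- y[te]
    nSynth <- 0L
    if (!is.null(smoteCfg)) {
      cfgF <- smoteCfg
      if (is.null(cfgF$seed)) cfgF$seed <- .childSeed(seed, 100L + f)
      reb <- rebalanceTrainingSet(xTr, yTr, sids[tr], cfgF)
      xTr <- reb$x; yTr <- reb$y
      nSynth <- reb$nSynthetic
    }

    subject <- if (plan$scheme == "loso") unique(sids[te])[1]
               else paste(unique(sids[te]), collapse = "+")
    if (verbose)
      message(sprintf("[fold %d/%d] train %d (+%d synthetic), test %d",
                      f, length(plan$folds), length(te) * 0 + length(yTr) -
                        nSynth, nSynth, length(yTe)))

    if (classifier == "cnn") {
      cfgT <- trainCfg
      if (is.null(cfgT$seed)) cfgT$seed <- .childSeed(seed, f)
      model <- trainModel(xTr, yTr, xTe, yTe, cfgT)
      hists[[f]] <- trainingHistory(model)
      mTr <- computeMetrics(yTr, classifyProb(predictProba(model, xTr)))
      mTe <- computeMetrics(yTe, classifyProb(predictProba(model, xTe)))
    } else {
      if (length(unique(yTr)) < 2)
        .stopf("single-class training data; rebalance first")
      fTr <- extractFeatureMatrix(xTr)
      fTe <- extractFeatureMatrix(xTe)
      rfCfgF <- rfCfg
      rfCfgF$seed <- .childSeed(seed, 200L + f)
      rf <- .rfFold(fTr, yTr, fTe, yTe, rfCfgF)
      mTr <- rf$train; mTe <- rf$val
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, subject = subject, split = "train",
      accuracy = mTr$accuracy, f1Functional = mTr$f1Functional,
      f1Nonfunctional = mTr$f1Nonfunctional, n = mTr$n)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, subject = subject, split = "val",
      accuracy = mTe$accuracy, f1Functional = mTe$f1Functional,
      f1Nonfunctional = mTe$f1Nonfunctional, n = mTe$n)
    prov[[f]] <- list(trainIdx = tr, testIdx = te, scalerFitIdx = tr,
                      smoteApplied = !is.null(smoteCfg), nSynthetic = nSynth,
                      trainSubjects = unique(sids[tr]),
                      testSubjects = unique(sids[te]))
  }
  structure(list(metrics = do.call(rbind, rows), folds = prov,
                 histories = hists, plan = plan, classifier = classifier),
            class = "EvaluationResult")
}

#' Intrasubject (within-subject) evaluation
#'
#' Runs stratified k-fold cross-validation separately within each subject
#' and pools the per-fold metrics; subjects whose windows cannot support
#' `k` folds are skipped with a message.
#'
#' @inheritParams evaluateWithPlan
#' @param k folds per subject (default 5).
#' @return An `EvaluationResult`; `metrics$subject` carries the subject id.
#' @export
evaluateIntrasubject <- function(dataset, k = 5, trainCfg = trainConfig(),
                                 smoteCfg = NULL, classifier = "cnn",
                                 rfCfg = rfSettings(), seed = 1,
                                 verbose = FALSE) {
  sids <- subjectIds(dataset)
  subs <- unique(sids)
  allRows <- list()
  folds <- list()
  hists <- list()
  for (si in seq_along(subs)) {
    idx <- which(sids == subs[si])
    sub <- windowedDataset(windowArray(dataset)[idx, , , drop = FALSE],
                           windowLabels(dataset)[idx], sids[idx],
                           datasetVariant(dataset))
    if (nSamples(sub) < k || length(unique(windowLabels(sub))) < 2) {
      message("skipping subject ", subs[si],
              ": too few windows or single class")
      next
    }
    plan <- makeIntrasubjectFolds(windowLabels(sub), k,
                                  seed = .childSeed(seed, si))
    res <- evaluateWithPlan(sub, plan, trainCfg, smoteCfg, classifier,
                            rfCfg, seed = .childSeed(seed, 1000L + si),
                            verbose = verbose)
    res$metrics$subject <- subs[si]
    allRows[[si]] <- res$metrics
    folds[[subs[si]]] <- res$folds
    hists[[subs[si]]] <- res$histories
  }
  if (!length(allRows)) .stopf("no subject supported %d-fold evaluation", k)
  structure(list(metrics = do.call(rbind, allRows), folds = folds,
                 histories = hists, scheme = "kfold",
                 classifier = classifier),
            class = "EvaluationResult")
}

#' Intersubject (leave-one-subject-out) evaluation
#'
#' @inheritParams evaluateWithPlan
#' @return An `EvaluationResult` with one fold per held-out subject.
#' @export
evaluateIntersubject <- function(dataset, trainCfg = trainConfig(),
                                 smoteCfg = NULL, classifier = "cnn",
                                 rfCfg = rfSettings(), seed = 1,
                                 verbose = FALSE) {
  plan <- makeLosoFolds(subjectIds(dataset))
  evaluateWithPlan(dataset, plan, trainCfg, smoteCfg, classifier, rfCfg,
                   seed = seed, verbose = verbose)
}

#' Random-forest baseline over an existing split plan
#'
#' Runs the handcrafted-feature random-forest baseline on exactly the folds
#' of `plan`, so the network and the baseline are compared on matching
#' splits.
#'
#' @param dataset a [WindowedDataset-class].
#' @param plan the `SplitPlan` already used for the network.
#' @param settings an [rfSettings()].
#' @param seed base seed.
#' @return An `EvaluationResult` with `classifier = "rf"`.
#' @export
runBaseline <- function(dataset, plan, settings = rfSettings(), seed = 1) {
  evaluateWithPlan(dataset, plan, classifier = "rf", rfCfg = settings,
                   seed = seed)
}

#' Run the full pipeline and write reports
#'
#' Preprocesses a cohort into the requested dataset variants, evaluates the
#' classifier under the requested scheme, and writes one CSV (per-fold
#' metrics) and one JSON (aggregate summary) report per variant, plus the
#' effective configuration and a line-delimited JSON log. Every report
#' embeds the seed and the MD5 hash of the configuration, so runs with equal
#' hashes are comparable.
#'
#' @param cohortDir cohort directory (see [simulateCohort()]).
#' @param outDir output directory for reports.
#' @param variants subset of `paretic`, `nonparetic`, `combined`.
#' @param scheme `"kfold"` (intrasubject) or `"loso"` (intersubject).
#' @param k folds for the intrasubject scheme.
#' @param smoteRatio optional SMOTE target ratio (e.g. 0.5); `NULL` disables
#'   rebalancing.
#' @param classifier `"cnn"` or `"rf"`.
#' @param trainCfg a [trainConfig()].
#' @param windowS window length (s).
#' @param mirrorAxis left-arm mirror axis.
#' @param seed base seed recorded in every output.
#' @return Invisibly, a list of per-variant report paths.
#' @export
runPipeline <- function(cohortDir, outDir, variants = "paretic",
                        scheme = c("kfold", "loso"), k = 5,
                        smoteRatio = NULL, classifier = "cnn",
                        trainCfg = trainConfig(), windowS = 2,
                        mirrorAxis = "x", seed = 1) {
  scheme <- match.arg(scheme)
  variants <- match.arg(variants, c("paretic", "nonparetic", "combined"),
                        several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- list(cohort = normalizePath(cohortDir), variants = variants,
                 scheme = scheme, k = k, smote_ratio = smoteRatio,
                 classifier = classifier, window_s = windowS,
                 mirror_axis = mirrorAxis, seed = seed,
                 max_epochs = trainCfg$maxEpochs,
                 batch_size = trainCfg$batchSize)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  logPath <- file.path(outDir, "run.log.jsonl")
  logLine <- function(...) {
    rec <- list(...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logPath,
        append = TRUE)
  }
  logLine(event = "start", config_hash = cfgHash, seed = seed,
          settings = config)

  smoteCfg <- if (!is.null(smoteRatio)) smoteConfig(targetRatio = smoteRatio)
  paths <- list()
  for (v in variants) {
    logLine(event = "preprocess", variant = v)
    ds <- buildVariantDataset(cohortDir, v, windowS, mirrorAxis)
    logLine(event = "dataset", variant = v, n_windows = nSamples(ds),
            n_functional = sum(windowLabels(ds) == 1L))
    res <- if (scheme == "kfold")
      evaluateIntrasubject(ds, k, trainCfg, smoteCfg, classifier,
                           seed = seed)
    else
      evaluateIntersubject(ds, trainCfg, smoteCfg, classifier, seed = seed)
    val <- res$metrics[res$metrics$split == "val", ]
    agg <- aggregateMetrics(val, level = if (scheme == "kfold") "subject"
                                         else "fold")
    csvPath <- file.path(outDir, sprintf("report_%s_%s.csv", v, scheme))
    utils::write.csv(res$metrics, csvPath, row.names = FALSE)
    report <- list(config_hash = cfgHash, seed = seed, variant = v,
                   scheme = scheme, classifier = classifier,
                   n_windows = nSamples(ds),
                   aggregate = agg)
    jsonPath <- file.path(outDir, sprintf("report_%s_%s.json", v, scheme))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA)
    logLine(event = "report", variant = v, csv = csvPath, json = jsonPath)
    paths[[v]] <- list(csv = csvPath, json = jsonPath)
  }
  logLine(event = "done")
  invisible(paths)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks that a JSON report produced by [runPipeline()] contains every
#' field required by the schema shipped with the package.
#'
#' @param path report JSON path.
#' @return `TRUE` invisibly; missing fields raise an error.
#' @export
validateReport <- function(path) {
  schema <- yaml::read_yaml(system.file("schema", "report-schema.yaml",
                                        package = "armetry"))
  rep <- jsonlite::read_json(path)
  missing <- setdiff(unlist(schema$required), names(rep))
  if (length(missing))
    .stopf("report %s missing field(s): %s", path,
           paste(missing, collapse = ", "))
  for (fld in unlist(schema$aggregate_required))
    if (!fld %in% names(rep$aggregate[[1]]))
      .stopf("report aggregate entries missing '%s'", fld)
  invisible(TRUE)
}

#' Persist / load a WindowedDataset as plain text
#'
#' Windows are stored flattened (one row per window) in a CSV next to a
#' YAML sidecar holding labels, subject ids, variant and dimensions.
#'
#' @param ds a [WindowedDataset-class].
#' @param prefix file prefix; writes `<prefix>.csv` and `<prefix>.yaml`.
#' @return [writeWindowedDataset()] invisibly returns `prefix`;
#'   [readWindowedDataset()] returns the dataset.
#' @export
writeWindowedDataset <- function(ds, prefix) {
  stopifnot(is(ds, "WindowedDataset"))
  d <- dim(windowArray(ds))
  flat <- matrix(windowArray(ds), d[1], d[2] * d[3])
  data.table::fwrite(data.table::as.data.table(flat),
                     paste0(prefix, ".csv"), col.names = FALSE)
  yaml::write_yaml(list(n = d[1], t = d[2], c = d[3],
                        y = windowLabels(ds),
                        subject_ids = subjectIds(ds),
                        variant = datasetVariant(ds)),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname writeWindowedDataset
#' @export
readWindowedDataset <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  flat <- as.matrix(data.table::fread(paste0(prefix, ".csv"),
                                      header = FALSE))
  windowedDataset(array(flat, c(meta$n, meta$t, meta$c)),
                  meta$y, meta$subject_ids, meta$variant)
}
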