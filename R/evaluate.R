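#' Intrasubject k-fold split plan
#'
#' Partitions window indices into `k` folds of near-equal size for
#' within-subject cross-validation. When labels are supplied and both
#' classes have at least `k` members, folds are stratified by class so that
#' low-functional-use subjects do not produce folds with an empty class.
#'
#' @param y binary label vector (stratified folds), or a single count of
#'   windows (unstratified).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return A `SplitPlan` list with `scheme = "kfold"` and `folds`, each
#'   holding disjoint `train`/`test` index vectors whose test sets partition
#'   the index set.
#' @export
makeIntrasubjectFolds <- function(y, k = 5, seed = 1) {
  if (length(y) == 1L && is.numeric(y)) {
    n <- as.integer(y)
    y <- NULL
  } else {
    y <- as.integer(y)
    n <- length(y)
  }
  if (n < k) .stopf("cannot make %d folds from %d windows", k, n)
  foldId <- integer(n)
  .withSeed(seed, {
    if (!is.null(y) && min(table(factor(y, levels = c(0L, 1L)))) >= k) {
      offset <- 0L
      for (cls in c(0L, 1L)) {
        idx <- sample(which(y == cls))
        foldId[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- (offset + length(idx)) %% k
      }
    } else {
      foldId <- (seq_len(n) - 1L) %% k + 1L
      foldId <- foldId[sample.int(n)]
    }
  })
  folds <- lapply(seq_len(k), function(f)
    list(train = which(foldId != f), test = which(foldId == f)))
  structure(list(scheme = "kfold", folds = folds, k = k, seed = seed),
            class = "SplitPlan")
}

#' Leave-one-subject-out split plan
#'
#' One fold per subject: fold `i` tests exactly subject `i`'s windows and
#' trains on every other subject's. The train/test subject sets are disjoint
#' by construction (re-checked on every use by the evaluation runner).
#'
#' @param subjectIds character vector of per-window subject tags
#'   (>= 2 distinct subjects).
#' @return A `SplitPlan` list with `scheme = "loso"`, `folds` and
#'   `testSubjects`.
#' @export
makeLosoFolds <- function(subjectIds) {
  subs <- unique(subjectIds)
  if (length(subs) < 2)
    .stopf("leave-one-subject-out needs >= 2 subjects, got %d", length(subs))
  folds <- lapply(subs, function(s)
    list(train = which(subjectIds != s), test = which(subjectIds == s)))
  structure(list(scheme = "loso", folds = folds, testSubjects = subs,
                 subjectIds = subjectIds), class = "SplitPlan")
}

#' Classification metrics for one evaluation split
#'
#' Accuracy and per-class F1 with functional (1) as the positive class for
#' `f1Functional` and non-functional (0) as the positive class for
#' `f1Nonfunctional`, plus the confusion counts they derive from. An F1
#' whose class never occurs (zero denominator) is defined as 0 with a
#' warning.
#'
#' @param yTrue,yPred equal-length binary vectors.
#' @return A `MetricSet` list: `accuracy`, `f1Functional`,
#'   `f1Nonfunctional`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    .stopf("length mismatch: %d true vs %d predicted", length(yTrue),
           length(yPred))
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  stopifnot(all(yTrue %in% 0:1), all(yPred %in% 0:1))
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  tn <- sum(yTrue == 0 & yPred == 0)
  fn <- sum(yTrue == 1 & yPred == 0)
  f1 <- function(tp2, fp2, fn2, cls) {
    den <- 2 * tp2 + fp2 + fn2
    if (den == 0) {
      warning("F1 for class ", cls, " undefined (class absent); reporting 0")
      return(0)
    }
    2 * tp2 / den
  }
  structure(list(
    accuracy = (tp + tn) / length(yTrue),
    f1Functional = f1(tp, fp, fn, "functional"),
    f1Nonfunctional = f1(tn, fn, fp, "non-functional"),
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(yTrue)),
    class = "MetricSet")
}

#' Aggregate metrics to mean +/- standard deviation
#'
#' Fold-level aggregation averages directly over entries; subject-level
#' aggregation (the intrasubject convention) first averages folds within
#' each subject, then takes mean and standard deviation across subjects.
#' Standard deviations use the n-1 denominator; a single entry yields 0 with
#' a warning.
#'
#' @param df data.frame with columns `subject`, `fold`, and metric columns
#'   (`accuracy`, `f1Functional`, `f1Nonfunctional`).
#' @param level `"fold"` or `"subject"`.
#' @param metrics metric column names to aggregate.
#' @return data.frame with one row per metric: `metric`, `mean`, `sd`, `n`.
#' @export
aggregateMetrics <- function(df, level = c("subject", "fold"),
                             metrics = c("accuracy", "f1Functional",
                                         "f1Nonfunctional")) {
  level <- match.arg(level)
  if (nrow(df) == 0) .stopf("nothing to aggregate")
  vals <- lapply(metrics, function(mcol) {
    v <- df[[mcol]]
    if (level == "subject") {
      v <- tapply(v, df$subject, mean)
    }
    v
  })
  n <- length(vals[[1]])
  if (n == 1) warning("single entry: standard deviation reported as 0")
  data.frame(
    metric = metrics,
    mean = vapply(vals, mean, 1),
    sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else 0, 1),
    n = n)
}

#' Paired train-versus-validation comparison
#'
#' Two-sided paired t-test on per-subject (or per-fold) paired scores, with
#' the paired Cohen's d using the pooled-SD denominator
#' `d = mean(train - val) / sqrt((sd_train^2 + sd_val^2) / 2)` and a 95% CI
#' `d +/- 1.96 * se(d)`, where `se(d) = sqrt(1/n + d^2/(2n))` corrected for
#' the pairing correlation `r` by the factor `sqrt(2 (1 - r))`. The
#' alternative convention `d_z = mean(diff) / sd(diff)` is reported as well.
#'
#' @param train,val equal-length paired score vectors, `n >= 2`.
#' @return A `ComparisonStats` list: `meanDiff`, `pValue`, `cohensD`,
#'   `ci95`, `dz`, `r`, `n`. Zero-variance differences give `pValue = NA`.
#' @export
pairedComparison <- function(train, val) {
  if (length(train) != length(val))
    .stopf("paired vectors differ in length")
  n <- length(train)
  if (n < 2) .stopf("need n >= 2 pairs")
  d <- train - val
  sdTr <- stats::sd(train); sdVal <- stats::sd(val)
  pooled <- sqrt((sdTr^2 + sdVal^2) / 2)
  cohensD <- if (pooled > 0) mean(d) / pooled else NA_real_
  dz <- if (stats::sd(d) > 0) mean(d) / stats::sd(d) else NA_real_
  r <- if (sdTr > 0 && sdVal > 0) stats::cor(train, val) else NA_real_
  p <- if (stats::sd(d) > 0)
    stats::t.test(train, val, paired = TRUE)$p.value else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.na(cohensD)) {
    se <- sqrt(1 / n + cohensD^2 / (2 * n))
    if (!is.na(r)) se <- se * sqrt(2 * (1 - r))
    ci <- cohensD + c(-1.96, 1.96) * se
  }
  structure(list(meanDiff = mean(d), pValue = p, cohensD = cohensD,
                 ci95 = ci, dz = dz, r = r, n = n),
            class = "ComparisonStats")
}
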