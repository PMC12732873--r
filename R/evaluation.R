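#' Confusion-matrix metrics
#'
#' Computes TP/TN/FP/FN counts and the four standard promoter-benchmark
#' metrics: sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, accuracy `Acc = (TP + TN) / total` and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any marginal of the MCC denominator is zero (e.g. a degenerate
#' all-positive predictor) the coefficient is reported as 0.
#'
#' @param truth,pred binary vectors of equal length: 0/1, logicals, or
#'   labels matched against `positive`.
#' @param positive the label counted as the positive class when `truth` /
#'   `pred` are not already 0/1.
#' @return a `metrics_report` list with fields `TP`, `TN`, `FP`, `FN`, `Sn`,
#'   `Sp`, `Acc`, `MCC`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
classification_metrics <- function(truth, pred, positive = 1) {
  if (length(truth) != length(pred)) stop("truth and pred length mismatch")
  if (length(truth) == 0L) stop("empty input")
  t <- as.numeric(as.vector(truth) == positive)
  p <- as.numeric(as.vector(pred) == positive)
  if (anyNA(t) || anyNA(p)) stop("NA labels are not allowed")
  TP <- sum(t == 1 & p == 1); TN <- sum(t == 0 & p == 0)
  FP <- sum(t == 0 & p == 1); FN <- sum(t == 1 & p == 0)
  den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  rep_ <- list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    Acc = (TP + TN) / (TP + TN + FP + FN),
    MCC = if (den > 0) (TP * TN - FP * FN) / den else 0
  )
  class(rep_) <- "metrics_report"
  rep_
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("Sn=%.4f  Sp=%.4f  Acc=%.4f  MCC=%.4f\n",
              x$Sn, x$Sp, x$Acc, x$MCC))
  invisible(x)
}

#' Seeded stratified k-fold split
#'
#' Partitions record indices into k folds, stratified so every fold's class
#' proportions match the global ones to within one sample: within each class
#' the (seeded) shuffled indices are dealt round-robin across folds.
#'
#' @param labels class label per record (any atomic vector).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return a `fold_split`: list of `k` integer index vectors (disjoint,
#'   union = all indices).
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class '", names(tab)[which(tab < k)[1]],
         "' has fewer than k = ", k, " members")
  }
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in names(tab)) {
    idx <- sample(which(as.character(labels) == cl))
    assign_to <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  folds <- lapply(folds, sort)
  structure(folds, class = "fold_split", seed = seed, k = k)
}

#' Repeated stratified cross-validation
#'
#' Runs `runs` independent rounds of stratified k-fold cross-validation
#' (default 10 x 5-fold): per fold a fresh model is trained on the remaining
#' folds and evaluated on the held-out one; metrics are aggregated across
#' folds and runs.
#'
#' @param ds a labeled [promoter_dataset()].
#' @param stage 1 (promoter vs non-promoter) or 2 (strong vs weak among
#'   promoters).
#' @param config a [promkan_config()].
#' @param runs number of repeats (default 10).
#' @param k folds per repeat (default 5).
#' @param seed base seed; run r uses `seed + r - 1` for its split and
#'   training.
#' @param verbose print per-fold progress.
#' @return list with `folds` (data frame: run, fold, n_test, TP..MCC) and
#'   `summary` (mean and sd of Sn/Sp/Acc/MCC over all folds).
#' @export
repeated_cv <- function(ds, stage = 1L, config = promkan_config(),
                        runs = 10L, k = 5L, seed = 1L, verbose = FALSE) {
  y <- stage_labels(ds, stage)
  keep <- which(!is.na(y))
  rows <- list()
  for (r in seq_len(runs)) {
    run_seed <- seed + r - 1L
    folds <- stratified_kfold(y[keep], k = k, seed = run_seed)
    for (f in seq_len(k)) {
      test_idx <- keep[folds[[f]]]
      train_idx <- setdiff(keep, test_idx)
      fit <- promkan(ds[train_idx, ], stage = stage, config = config,
                     seed = run_seed * 1000L + f, verbose = FALSE)
      pr <- predict(fit, ds[test_idx, ], type = "prob")
      m <- classification_metrics(y[test_idx], as.numeric(pr >= config$threshold))
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, fold = f, n_test = length(test_idx),
        TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
        Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC)
      if (verbose) {
        message(sprintf("run %d fold %d: Acc %.3f MCC %.3f", r, f, m$Acc, m$MCC))
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  metr <- c("Sn", "Sp", "Acc", "MCC")
  summ <- data.frame(
    metric = metr,
    mean = vapply(metr, function(m) mean(folds_df[[m]]), 0),
    sd = vapply(metr, function(m) stats::sd(folds_df[[m]]), 0)
  )
  list(folds = folds_df, summary = summ)
}

#' Export repeated-fold assignments as a table
#'
#' Materializes the stratified splits used by [repeated_cv()] as a data
#' frame (`id`, `run`, `fold`), optionally written as TSV, so fold
#' membership can be audited or reused outside the package.
#'
#' @param ds a labeled [promoter_dataset()].
#' @param stage stage whose labels drive the stratification (1 or 2).
#' @param runs,k repeats and folds, as in [repeated_cv()].
#' @param seed base seed; run r uses `seed + r - 1`, matching
#'   [repeated_cv()] exactly.
#' @param path optional TSV output path.
#' @return the assignment data frame, invisibly if `path` is given.
#' @export
fold_assignments <- function(ds, stage = 1L, runs = 10L, k = 5L, seed = 1L,
                             path = NULL) {
  y <- stage_labels(ds, stage)
  keep <- which(!is.na(y))
  rows <- list()
  for (r in seq_len(runs)) {
    folds <- stratified_kfold(y[keep], k = k, seed = seed + r - 1L)
    for (f in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = ds$id[keep[folds[[f]]]], run = r, fold = f)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# binary 0/1 target for a stage; NA where the record does not participate
stage_labels <- function(ds, stage) {
  if (stage == 1L) {
    ifelse(is.na(ds$stage1), NA_real_,
           as.numeric(ds$stage1 == "promoter"))
  } else {
    ifelse(is.na(ds$stage2), NA_real_, as.numeric(ds$stage2 == "strong"))
  }
}
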