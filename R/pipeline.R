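# End-to-end orchestration: extract the 14 parameters from a window, compare
# groups, train the three perceptrons (HRV / RRV / combined) on one shared
# stratified split, and report.

#' Feature-set column definitions
#'
#' @return named list: `hrv` (11 columns), `rrv` (3), `all` (14), each with
#'   the default hidden-layer width used in the pipeline (5 / 5 / 13).
#' @export
feature_sets <- function() {
  fn <- feature_names()
  list(hrv = list(columns = fn[1:11], n_hidden = 5),
       rrv = list(columns = fn[12:14], n_hidden = 5),
       all = list(columns = fn, n_hidden = 13))
}

#' Extract the 14 parameters from one window
#'
#' Runs R-peak detection, ectopic flagging + IPFM correction and the HRV
#' parameters on the ECG; band-pass, breath-peak detection and the RRV
#' parameters on the respiration trace.  Any stage error marks the window
#' excluded (with the reason) instead of propagating.
#'
#' @param window a [labeled_window()].
#' @param ectopic_tol relative deviation threshold for ectopic flagging.
#' @return list with `ok`; on success `features` (named numeric, 14 fields)
#'   and `qc` (beat/breath/ectopic counts), on failure `reason`.
#' @export
extract_features <- function(window, ectopic_tol = 0.2) {
  stopifnot(inherits(window, "labeled_window"))
  notes <- character(0)
  out <- try(withCallingHandlers({
    beats <- detect_r_peaks(window$ecg)
    mask <- flag_ectopic(beats, ectopic_tol)
    nn <- correct_ectopic_ipfm(beats, mask)
    hrv <- hrv_vector(nn)
    rrv <- rrv_vector(window$resp)
    qc <- list(n_beats = length(beats$peak_times),
               n_ectopic = sum(mask),
               n_corrected = nn$n_corrected,
               notes = notes)
    list(ok = TRUE, features = unlist(c(hrv, rrv))[feature_names()],
         qc = qc)
  }, warning = function(w) {   # QC notes, not errors (e.g. period range)
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  }), silent = TRUE)
  if (inherits(out, "try-error"))
    return(list(ok = FALSE, reason = trimws(conditionMessage(attr(out, "condition")))))
  out
}

#' Extract a feature table from a cohort of windows
#'
#' @param windows list of [labeled_window()] objects.
#' @param verbose log per-window QC and exclusions (default FALSE).
#' @return data.frame (`source_id`, 14 features, `label`); excluded windows
#'   are dropped and reported in the `"exclusions"` attribute.
#' @export
extract_cohort <- function(windows, verbose = FALSE) {
  rows <- list()
  excl <- list()
  for (w in windows) {
    r <- extract_features(w)
    if (r$ok) {
      rows[[length(rows) + 1]] <-
        cbind(data.frame(source_id = w$source_id),
              as.data.frame(as.list(r$features)),
              data.frame(label = w$label))
      if (verbose)
        message(sprintf("%s: %d beats (%d ectopic), ok", w$source_id,
                        r$qc$n_beats, r$qc$n_ectopic))
    } else {
      excl[[w$source_id]] <- r$reason
      if (verbose) message(sprintf("%s: EXCLUDED (%s)", w$source_id, r$reason))
    }
  }
  if (length(rows) == 0) stop("all windows excluded")
  out <- do.call(rbind, rows)
  attr(out, "exclusions") <- excl
  out
}

#' Group comparison of the 14 parameters
#'
#' Per-parameter group means, SDs and a two-sample p-value (two-sided
#' Mann-Whitney by default, Welch t as an option).
#'
#' @param features feature data.frame with a `label` column (+1 VT /
#'   -1 control).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return data.frame: `parameter`, `control_mean`, `control_sd`, `vt_mean`,
#'   `vt_sd`, `p_value`, `test`.
#' @export
compare_groups <- function(features, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (sum(features$label == 1) < 3 || sum(features$label == -1) < 3)
    stop("each group needs at least 3 records")
  rows <- lapply(feature_names(), function(p) {
    vt <- features[[p]][features$label == 1]
    ct <- features[[p]][features$label == -1]
    pv <- if (test == "wilcoxon")
      suppressWarnings(wilcox.test(vt, ct, exact = FALSE)$p.value)
    else t.test(vt, ct)$p.value
    data.frame(parameter = p, control_mean = mean(ct), control_sd = sd(ct),
               vt_mean = mean(vt), vt_sd = sd(vt), p_value = pv, test = test)
  })
  do.call(rbind, rows)
}

#' Run the full three-classifier experiment
#'
#' One stratified split shared by the HRV-only, RRV-only and combined feature
#' sets; one perceptron trained per set; evaluation on the held-out test set.
#'
#' @param features feature data.frame (`source_id`, 14 features, `label`).
#' @param sets feature-set definitions, see [feature_sets()].
#' @param train_fraction per-class training fraction (default 2/3).
#' @param cfg an [mlp_config()]; its seed drives both the split and the
#'   weight initialization.
#' @param out_dir optional directory: writes the feature table, one model
#'   JSON and one report JSON per set.
#' @return named list per set: `model`, `report`, plus `split` and
#'   `comparison` at the top level.
#' @export
run_experiment <- function(features, sets = feature_sets(),
                           train_fraction = 2 / 3, cfg = mlp_config(),
                           out_dir = NULL) {
  counts <- table(features$label)
  if (length(counts) < 2 || any(counts < 6))
    stop("need at least 6 windows per class")
  sp <- split_stratified(features$label, train_fraction, cfg$seed)
  results <- list()
  for (nm in names(sets)) {
    cols <- sets[[nm]]$columns
    xtr <- as.matrix(features[sp$train, cols, drop = FALSE])
    xte <- as.matrix(features[sp$test, cols, drop = FALSE])
    model <- train_mlp(xtr, features$label[sp$train],
                       sets[[nm]]$n_hidden, cfg)
    rep_ <- evaluate(predict(model, xte), features$label[sp$test])
    results[[nm]] <- list(model = model, report = rep_)
  }
  out <- list(sets = results, split = sp,
              comparison = compare_groups(features))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    for (nm in names(results)) {
      write_mlp_json(results[[nm]]$model,
                     file.path(out_dir, paste0("model_", nm, ".json")))
      write_report_json(results[[nm]]$report,
                        file.path(out_dir, paste0("report_", nm, ".json")))
    }
  }
  out
}

#' Serialize an evaluation report to JSON (and back)
#'
#' @param report an `eval_report`.
#' @param path file path.
#' @return `path` invisibly / the restored `eval_report`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- unclass(report)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$roc)) obj$roc <- as.data.frame(obj$roc)
  if (is.null(obj$auc)) obj$auc <- NA_real_
  structure(obj, class = "eval_report")
}

fraction_str <- function(num, den) {
  if (den == 0) return("NA")
  sprintf("%.1f (%d/%d)", 100 * num / den, num, den)
}

#' Human-readable experiment summary
#'
#' Prints a performance table (metrics as percentages with their underlying
#' fractions, plus AUC) and the group comparison.
#'
#' @param results output of [run_experiment()].
#' @return the summary lines, invisibly.
#' @export
report_summary <- function(results) {
  if (length(results$sets) == 0) stop("empty results")
  lines <- c(sprintf("%-10s %5s %14s %14s %14s %14s %14s %6s",
                     "ANN with", "Input", "Sensitivity", "Specificity",
                     "Accuracy", "PPV", "NPV", "AUC"))
  for (nm in names(results$sets)) {
    r <- results$sets[[nm]]$report
    m <- results$sets[[nm]]$model
    lines <- c(lines, sprintf(
      "%-10s %5d %14s %14s %14s %14s %14s %6s", nm, nrow(m$w1),
      fraction_str(r$tp, r$tp + r$fn),
      fraction_str(r$tn, r$tn + r$fp),
      fraction_str(r$tp + r$tn, r$tp + r$tn + r$fp + r$fn),
      fraction_str(r$tp, r$tp + r$fp),
      fraction_str(r$tn, r$tn + r$fn),
      if (is.na(r$auc)) "NA" else sprintf("%.2f", r$auc)))
  }
  cat(lines, sep = "\n")
  if (!is.null(results$comparison)) {
    cat("\nGroup comparison (control vs pre-VT):\n")
    cmp <- results$comparison
    for (i in seq_len(nrow(cmp)))
      cat(sprintf("  %-8s %10.4g +/- %-10.4g %10.4g +/- %-10.4g p=%.3g\n",
                  cmp$parameter[i], cmp$control_mean[i], cmp$control_sd[i],
                  cmp$vt_mean[i], cmp$vt_sd[i], cmp$p_value[i]))
  }
  invisible(lines)
}
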