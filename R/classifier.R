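# One-hidden-layer backpropagation perceptron for pre-VT vs control
# classification, with stratified splitting, evaluation metrics and ROC/AUC.
#
# Architecture: z-scored inputs (training statistics), tanh hidden layer,
# linear scalar output, targets +1 (VT) / -1 (control), full-batch gradient
# descent on the mean squared error, stopping at MSE < 1e-5 or the epoch cap.

#' Stratified train/test split
#'
#' Splits each class with `round(train_fraction * n_class)` records to the
#' training set (a 52+52 cohort at 2/3 gives 35+35 train / 17+17 test), the
#' remainder to test, with seed-reproducible random assignment.
#'
#' @param labels vector of +1/-1 class labels.
#' @param train_fraction fraction of each class used for training
#'   (default 2/3).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_stratified <- function(labels, train_fraction = 2 / 3, seed) {
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present")
  counts <- table(labels)
  if (any(counts < 3)) stop("each class needs at least 3 records")
  idx <- with_seed(seed, {
    lapply(classes, function(cl) {
      members <- which(labels == cl)
      ntr <- round(train_fraction * length(members))
      if (ntr >= length(members) || ntr < 1)
        stop("train_fraction leaves an empty train or test set")
      sample(members, ntr)
    })
  })
  train <- sort(unlist(idx))
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Training configuration for the perceptron
#'
#' @param lr learning rate for full-batch gradient descent (default 0.01).
#' @param momentum classic momentum coefficient (default 0, plain descent).
#' @param max_epochs epoch cap (default 50000); the stopping rule
#'   MSE < `mse_target` is rarely reachable on noisy data.
#' @param mse_target stop training once the MSE falls below this
#'   (default 1e-5).
#' @param seed RNG seed for weight initialization.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(lr = 0.01, momentum = 0, max_epochs = 50000,
                       mse_target = 1e-5, seed = 1) {
  structure(list(lr = lr, momentum = momentum, max_epochs = max_epochs,
                 mse_target = mse_target, seed = seed),
            class = "mlp_config")
}

#' Train the one-hidden-layer perceptron
#'
#' @param x numeric matrix (rows = records, columns = features) or data.frame
#'   of feature columns.
#' @param labels vector of +1/-1 targets.
#' @param n_hidden hidden-layer width (defaults used in the pipeline: 5 for
#'   HRV-only, 5 for RRV-only, 13 for all 14 features).
#' @param cfg an [mlp_config()].
#' @param trace record the per-epoch MSE trajectory (default FALSE).
#' @return object of class `mlp_model` with weight matrices (`w1`, `b1`,
#'   `w2`, `b2`), normalization statistics and training metadata.
#' @export
train_mlp <- function(x, labels, n_hidden = 5, cfg = mlp_config(),
                      trace = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite features")
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1")
  if (min(table(labels)) < 1 || length(unique(labels)) < 2)
    stop("need examples from both classes")
  y <- as.numeric(labels)
  n <- nrow(x); d <- ncol(x)
  mu <- colMeans(x)
  sigma <- apply(x, 2, pop_sd)
  sigma[sigma == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sigma, "/")

  init <- with_seed(cfg$seed, list(
    w1 = matrix(runif(d * n_hidden, -1, 1) / sqrt(d), d, n_hidden),
    b1 = runif(n_hidden, -0.5, 0.5),
    w2 = matrix(runif(n_hidden, -1, 1) / sqrt(n_hidden), n_hidden, 1),
    b2 = runif(1, -0.5, 0.5)))
  w1 <- init$w1; b1 <- init$b1; w2 <- init$w2; b2 <- init$b2
  vw1 <- 0 * w1; vb1 <- 0 * b1; vw2 <- 0 * w2; vb2 <- 0

  mse <- Inf
  history <- if (trace) numeric(cfg$max_epochs) else NULL
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    h <- tanh(sweep(z %*% w1, 2, b1, "+"))
    out <- drop(h %*% w2) + b2
    err <- out - y
    mse <- mean(err^2)
    if (trace) history[epoch] <- mse
    if (mse < cfg$mse_target) break
    # backprop (gradients of mean squared error)
    go <- 2 * err / n
    gw2 <- crossprod(h, go)
    gb2 <- sum(go)
    gh <- (go %o% drop(w2)) * (1 - h^2)
    gw1 <- crossprod(z, gh)
    gb1 <- colSums(gh)
    vw1 <- cfg$momentum * vw1 - cfg$lr * gw1
    vb1 <- cfg$momentum * vb1 - cfg$lr * gb1
    vw2 <- cfg$momentum * vw2 - cfg$lr * gw2
    vb2 <- cfg$momentum * vb2 - cfg$lr * gb2
    w1 <- w1 + vw1; b1 <- b1 + vb1; w2 <- w2 + vw2; b2 <- b2 + vb2
  }
  structure(list(
    w1 = w1, b1 = b1, w2 = w2, b2 = b2,
    norm_stats = list(mean = mu, sd = sigma),
    feature_names = colnames(x),
    n_hidden = n_hidden,
    train_meta = list(epochs = epoch, final_mse = mse,
                      converged = mse < cfg$mse_target,
                      seed = cfg$seed, lr = cfg$lr,
                      momentum = cfg$momentum),
    mse_history = if (trace) history[seq_len(epoch)] else NULL),
    class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> %d-%d-1 perceptron; %d epoch(s), final MSE %.3g (%s)\n",
    nrow(x$w1), x$n_hidden, x$train_meta$epochs, x$train_meta$final_mse,
    if (x$train_meta$converged) "converged" else "epoch cap"))
  invisible(x)
}

#' Continuous score of the perceptron
#'
#' @param object an `mlp_model`.
#' @param x matrix or data.frame of feature rows (columns matching training).
#' @param ... unused.
#' @return numeric score per row; the class decision is `sign(score)` with 0
#'   mapped to control.
#' @export
predict.mlp_model <- function(object, x, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != nrow(object$w1))
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 nrow(object$w1), ncol(x)))
  z <- sweep(sweep(x, 2, object$norm_stats$mean), 2, object$norm_stats$sd, "/")
  h <- tanh(sweep(z %*% object$w1, 2, object$b1, "+"))
  drop(h %*% object$w2) + object$b2
}

#' Classify scores into +1/-1
#'
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0, the midpoint of the +/-1
#'   targets); a score exactly at the threshold is assigned to control.
#' @return vector of +1/-1 labels.
#' @export
classify <- function(scores, threshold = 0) {
  ifelse(scores > threshold, 1, -1)
}

#' Evaluate scores against labels
#'
#' Confusion counts at the decision threshold, the five scalar metrics, and
#' the ROC curve (all score thresholds, ties grouped) with trapezoidal AUC.
#'
#' @param scores numeric scores (higher = more VT-like).
#' @param labels +1/-1 truth.
#' @param threshold decision threshold (default 0).
#' @return object of class `eval_report`: `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`, `roc`
#'   (data.frame of `fpr`, `tpr`), `auc`.
#' @export
evaluate <- function(scores, labels, threshold = 0) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == 1
  neg <- labels == -1
  if (!any(pos) || !any(neg)) {
    warning("one-class input: ROC/AUC undefined")
    roc <- NULL; auc <- NA_real_
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- pos[ord]
    grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tie group
    tpr <- c(0, cumsum(p)[grp_end] / sum(pos))
    fpr <- c(0, cumsum(!p)[grp_end] / sum(neg))
    roc <- data.frame(fpr = fpr, tpr = tpr)
    auc <- trapz(fpr, tpr)
  }
  pred <- classify(scores, threshold)
  tp <- sum(pred == 1 & pos); fn <- sum(pred == -1 & pos)
  tn <- sum(pred == -1 & neg); fp <- sum(pred == 1 & neg)
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(scores),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    roc = roc, auc = auc), class = "eval_report")
}

#' Build an evaluation report directly from confusion counts
#'
#' @param tp,fn,tn,fp confusion counts.
#' @param auc optional externally computed AUC.
#' @return an `eval_report` (without ROC points).
#' @export
eval_from_counts <- function(tp, fn, tn, fp, auc = NA_real_) {
  scores <- c(rep(1, tp), rep(-1, fn), rep(-1, tn), rep(1, fp))
  labels <- c(rep(1, tp + fn), rep(-1, tn + fp))
  rep_ <- suppressWarnings(evaluate(scores, labels))
  rep_$roc <- NULL
  rep_$auc <- auc
  rep_
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  confusion: TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf(
    "  sensitivity %s  specificity %s  accuracy %s  PPV %s  NPV %s  AUC %s\n",
    pct(x$sensitivity), pct(x$specificity), pct(x$accuracy),
    pct(x$ppv), pct(x$npv),
    if (is.na(x$auc)) "NA" else sprintf("%.2f", x$auc)))
  invisible(x)
}

pct <- function(p) if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)

#' Pairwise (Mann-Whitney) AUC
#'
#' Fraction of (positive, negative) score pairs with the positive scoring
#' higher; ties count one half.  Serves as an exact oracle for the
#' trapezoidal ROC AUC.
#'
#' @param scores numeric scores.
#' @param labels +1/-1 truth.
#' @return AUC in `[0, 1]`.
#' @export
auc_brute <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  if (length(sp) == 0 || length(sn) == 0) stop("both classes must be present")
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Plot an ROC curve
#'
#' @param x an `eval_report` with ROC points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eval_report <- function(x, ...) {
  if (is.null(x$roc)) stop("report carries no ROC points")
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Hidden-layer width selection by validation accuracy
#'
#' Re-splits the training data, trains one model per candidate width and
#' returns the width with the best validation accuracy (ties go to the
#' smaller network).
#'
#' @param x feature matrix, `labels` +1/-1.
#' @param labels class labels.
#' @param widths candidate hidden sizes (default 1:20).
#' @param cfg an [mlp_config()]; its seed also drives the validation split.
#' @param val_fraction fraction of `x` held out for validation (default 1/4).
#' @return list with `best` width and `accuracy` per candidate.
#' @export
select_hidden <- function(x, labels, widths = 1:20, cfg = mlp_config(),
                          val_fraction = 0.25) {
  sp <- split_stratified(labels, 1 - val_fraction, cfg$seed)
  x <- as.matrix(x)
  acc <- vapply(widths, function(h) {
    m <- train_mlp(x[sp$train, , drop = FALSE], labels[sp$train], h, cfg)
    mean(classify(predict(m, x[sp$test, , drop = FALSE])) == labels[sp$test])
  }, 0)
  list(best = widths[which.max(acc)], accuracy = setNames(acc, widths))
}

#' Serialize a model to JSON
#'
#' Weights, normalization statistics and training metadata are written in
#' full precision; [read_mlp_json()] restores them exactly.
#'
#' @param model an `mlp_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(w1 = model$w1, b1 = model$b1, w2 = as.numeric(model$w2),
              b2 = model$b2, norm_mean = model$norm_stats$mean,
              norm_sd = model$norm_stats$sd,
              feature_names = model$feature_names,
              n_hidden = model$n_hidden, train_meta = model$train_meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w1 <- matrix(unlist(obj$w1), ncol = obj$n_hidden)
  if (!is.null(obj$feature_names)) rownames(w1) <- obj$feature_names
  structure(list(
    w1 = w1,
    b1 = as.numeric(obj$b1),
    w2 = matrix(as.numeric(obj$w2), ncol = 1),
    b2 = as.numeric(obj$b2),
    norm_stats = list(mean = as.numeric(obj$norm_mean),
                      sd = as.numeric(obj$norm_sd)),
    feature_names = obj$feature_names,
    n_hidden = as.integer(obj$n_hidden),
    train_meta = obj$train_meta), class = "mlp_model")
}
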