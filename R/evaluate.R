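#' Confusion matrix constructor and accessors
#'
#' @param tp,fp,fn,tn tile counts.
#' @return a [ConfusionMatrix-class].
#' @examples
#' cm <- confusionMatrix(37267, 7815, 2283, 105787)
#' matrixMetrics(cm)
#' @export
confusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

#' @rdname confusionMatrix
#' @param cm a [ConfusionMatrix-class].
#' @export
totalCount <- function(cm) cm@tp + cm@fp + cm@fn + cm@tn

#' Tally tile-level outcomes into a confusion matrix
#'
#' Applies the positive/negative convention: a tile is predicted positive
#' iff it is nonblank and its score reaches \code{cutoff}; nonblank tiles
#' below the cutoff and ALL blank tiles are predicted negative. Every tile
#' (blank included) is tallied against its truth label, so the matrix total
#' is 64 x images.
#'
#' @param manifest data.frame with columns \code{truth_label}
#'   (\code{"cancer"}/\code{"no_cancer"}), \code{is_blank} (logical) and
#'   \code{score} (NA for blank tiles).
#' @param cutoff tile-positive probability cutoff (default 0.5).
#' @return a [ConfusionMatrix-class].
#' @export
tileOutcomes <- function(manifest, cutoff = 0.5) {
  need <- c("truth_label", "is_blank", "score")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(manifest$truth_label)))
    stop("data error: every tile needs a truth label")
  pos <- !manifest$is_blank & !is.na(manifest$score) &
    manifest$score >= cutoff
  truthPos <- manifest$truth_label == "cancer"
  confusionMatrix(tp = sum(pos & truthPos), fp = sum(pos & !truthPos),
                  fn = sum(!pos & truthPos), tn = sum(!pos & !truthPos))
}

#' Accuracy, precision, recall and F-measure of a confusion matrix
#'
#' \code{accuracy = (tp + tn) / total}; \code{precision = tp / (tp + fp)};
#' \code{recall = tp / (tp + fn)} (sensitivity);
#' \code{f_measure = 2 * precision * recall / (precision + recall)}.
#' Zero denominators yield \code{NaN} markers rather than errors.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric vector \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f_measure}.
#' @examples
#' round(matrixMetrics(confusionMatrix(37267, 7815, 2283, 105787)), 3)
#' #  accuracy precision    recall f_measure
#' #     0.934     0.827     0.942     0.881
#' @export
matrixMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  sdiv <- function(a, b) if (b == 0) NaN else a / b
  acc <- sdiv(cm@tp + cm@tn, totalCount(cm))
  prec <- sdiv(cm@tp, cm@tp + cm@fp)
  rec <- sdiv(cm@tp, cm@tp + cm@fn)
  f <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) NaN else
    2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f_measure = f)
}

#' Malignant probability of one image
#'
#' The ratio of positive tiles in an original captured image: predicted
#' positives / 64. Blank tiles count toward the denominator (they are
#' predicted negatives).
#'
#' @param positives number of predicted-positive tiles, or a logical
#'   vector of per-tile positivity of length \code{nTilesPerImage}.
#' @param nTilesPerImage tiles per image (64).
#' @return a proportion on the grid \code{{0, 1/64, ..., 1}}.
#' @examples
#' malignantProbability(4)   # 0.0625, the clinical operating point
#' @export
malignantProbability <- function(positives, nTilesPerImage = 64L) {
  if (is.logical(positives)) {
    if (length(positives) != nTilesPerImage)
      stop("geometry error: expected ", nTilesPerImage, " tiles, got ",
           length(positives))
    positives <- sum(positives)
  }
  if (positives < 0 || positives > nTilesPerImage)
    stop("geometry error: positive count outside [0, ", nTilesPerImage, "]")
  positives / nTilesPerImage
}

#' Verdict configuration constructor
#'
#' @param threshold malignant-probability threshold; default 0.0625
#'   (4 of 64 tiles).
#' @param strict use strict \code{>} instead of \code{>=}.
#' @return a [VerdictConfig-class].
#' @export
verdictConfig <- function(threshold = 0.0625, strict = FALSE) {
  new("VerdictConfig", threshold = as.numeric(threshold),
      strict = isTRUE(strict))
}

#' Per-image verdicts from a tile manifest
#'
#' Aggregates tile decisions per image into the malignant probability and
#' applies the verdict threshold (malignant iff probability >= threshold,
#' or > with \code{strict}). Image truth is \code{"cancerous"} iff the
#' image contains at least one cancer-truth tile, so cancer-tissue images
#' without malignant findings count as normal files.
#'
#' @param manifest tile manifest data.frame with \code{image_id},
#'   \code{truth_label}, \code{is_blank}, \code{score}.
#' @param config a [VerdictConfig-class].
#' @param cutoff tile-positive probability cutoff.
#' @param nTilesPerImage tiles per image (64).
#' @return data.frame: \code{image_id}, \code{malignant_probability},
#'   \code{predicted_class}, \code{truth_class}.
#' @export
imageVerdicts <- function(manifest, config = verdictConfig(), cutoff = 0.5,
                          nTilesPerImage = 64L) {
  pos <- !manifest$is_blank & !is.na(manifest$score) &
    manifest$score >= cutoff
  ids <- unique(manifest$image_id)
  res <- lapply(ids, function(id) {
    sel <- manifest$image_id == id
    if (sum(sel) != nTilesPerImage)
      stop("geometry error: image ", id, " has ", sum(sel), " tiles")
    mp <- malignantProbability(sum(pos[sel]), nTilesPerImage)
    dec <- if (config@strict) mp > config@threshold else mp >= config@threshold
    data.frame(image_id = id, malignant_probability = mp,
               predicted_class = if (dec) "malignant" else "nonmalignant",
               truth_class = if (any(manifest$truth_label[sel] == "cancer"))
                 "cancerous" else "normal",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Image-level sensitivity and specificity
#'
#' Sensitivity: malignant-called cancerous files / cancerous files.
#' Specificity: nonmalignant-called normal files / normal files. An empty
#' class yields \code{NaN}.
#'
#' @param verdicts data.frame as from [imageVerdicts()].
#' @return named numeric vector \code{sensitivity}, \code{specificity}.
#' @examples
#' v <- data.frame(predicted_class = c(rep("malignant", 1314),
#'                                     rep("nonmalignant", 42)),
#'                 truth_class = "cancerous")
#' imageLevelRates(v)["sensitivity"]   # 1314/1356 = 0.969
#' @export
imageLevelRates <- function(verdicts) {
  canc <- verdicts$truth_class == "cancerous"
  norm <- verdicts$truth_class == "normal"
  sens <- if (!any(canc)) NaN else
    sum(canc & verdicts$predicted_class == "malignant") / sum(canc)
  spec <- if (!any(norm)) NaN else
    sum(norm & verdicts$predicted_class == "nonmalignant") / sum(norm)
  c(sensitivity = sens, specificity = spec)
}

#' ROC curve and AUC of the malignant probability
#'
#' Sweeps the decision threshold over the malignant-probability grid
#' \code{{0, 1/64, ..., 1}} plus a sentinel above 1 (decision rule: score
#' >= threshold), and integrates the (FPR, TPR) points by the trapezoid
#' rule. Single-class input yields \code{NA} AUC.
#'
#' @param verdicts data.frame with \code{malignant_probability} and
#'   \code{truth_class}.
#' @param nTilesPerImage grid denominator (64).
#' @return list: \code{points} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
rocCurve <- function(verdicts, nTilesPerImage = 64L) {
  y <- verdicts$truth_class == "cancerous"
  s <- verdicts$malignant_probability
  thr <- c(0:nTilesPerImage / nTilesPerImage, 1 + 1 / nTilesPerImage)
  pts <- do.call(rbind, lapply(thr, function(t) {
    called <- s >= t
    data.frame(threshold = t,
               fpr = if (any(!y)) mean(called[!y]) else NaN,
               tpr = if (any(y)) mean(called[y]) else NaN)
  }))
  if (!any(y) || !all(c(TRUE, FALSE) %in% y))
    return(list(points = pts, auc = NA_real_))
  o <- order(pts$fpr, pts$tpr)
  fpr <- pts$fpr[o]; tpr <- pts$tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Plot an ROC curve
#'
#' Draws the (FPR, TPR) staircase of a [rocCurve()] result with the AUC in
#' the legend; writes an SVG when \code{file} is given.
#'
#' @param roc a list as returned by [rocCurve()].
#' @param file optional SVG output path.
#' @param ... passed to [plot()].
#' @return the input, invisibly.
#' @export
plotROC <- function(roc, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::svg(file)
    on.exit(grDevices::dev.off())
  }
  o <- order(roc$points$fpr, roc$points$tpr)
  plot(roc$points$fpr[o], roc$points$tpr[o], type = "l", lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", roc$auc))
  invisible(roc)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The U statistic is computed from
#' ranks (with midranks for ties). For combined n <= 20 the two-sided p
#' comes from exact enumeration of all group assignments (valid under
#' ties); otherwise from the normal approximation with tie correction.
#'
#' @param x,y numeric score vectors for the two groups.
#' @return list: \code{U} (statistic of group \code{x}), \code{p.value}.
#' @examples
#' mannWhitneyU(c(5, 6, 7), c(1, 2, 3))$U   # 9 = n1 * n2, full separation
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 20L) {
    ## exact: enumerate all assignments of ranks to group 1
    comb <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[comb], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p.value = 1))
    z <- (U - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p.value = p)
}

#' Cohen's kappa for a 2 x 2 agreement table
#'
#' Chance-corrected agreement between two raters:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o} and chance agreement \eqn{p_e} from the marginals. If
#' \eqn{p_e = 1}, kappa is 1 when \eqn{p_o = 1} and \code{NaN} otherwise.
#'
#' @param table 2 x 2 (or k x k) numeric matrix of rater-1 by rater-2
#'   counts.
#' @return kappa in [-1, 1].
#' @examples
#' cohensKappa(matrix(c(25, 0, 0, 30), 2, byrow = TRUE))   # 1
#' @export
cohensKappa <- function(table) {
  table <- as.matrix(table)
  n <- sum(table)
  if (n <= 0) stop("agreement table must have a positive total")
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (abs(po - 1) < .Machine$double.eps^0.5) return(1)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}
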