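#' Pixel confusion counts between a predicted and a reference mask
#'
#' TP are polyp pixels predicted as polyp, FP background pixels predicted
#' as polyp, TN background predicted as background, FN polyp predicted as
#' background.
#'
#' @param predicted,truth Binary masks (values 0/1 or logical) of the same
#'   resolution.
#' @return A `confusion_counts` object (fields TP, FP, TN, FN).
#' @export
confusion_from_masks <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop("predicted and truth masks differ in resolution", call. = FALSE)
  p <- as.vector(predicted); t <- as.vector(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("masks must be strictly binary", call. = FALSE)
  confusion_counts(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
                   TN = sum(p == 0 & t == 0), FN = sum(p == 0 & t == 1))
}

#' @rdname confusion_from_masks
#' @param TP,FP,TN,FN Non-negative pixel tallies.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d (total %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

# Zero-denominator rule: a ratio whose denominator vanishes is 1 when the
# complementary error count is also zero (the condition holds vacuously)
# and 0 otherwise, so per-image averages stay total.
safe_ratio <- function(num, den, vacuous_ok) {
  if (den > 0) num / den else if (vacuous_ok) 1 else 0
}

#' Evaluation metrics from confusion counts
#'
#' Computes the full pixel-wise evaluation suite: accuracy, sensitivity
#' (recall), specificity, precision, per-class IoU, mean IoU, Dice
#' coefficient and the F2 score (the F-beta measure at beta = 2, which
#' weights recall above precision).
#'
#' @param counts A `confusion_counts` object.
#' @param aggregation_mode Label recorded in the report: counts from one
#'   image give `"per_image_mean"` semantics once averaged; counts pooled
#'   over a dataset give `"dataset_aggregate"`.
#' @return A one-row tibble (class `metric_report`) with all metrics in
#'   `[0, 1]` and a `degenerate` flag marking any zero-denominator
#'   fallback.
#' @examples
#' compute_metrics(confusion_counts(TP = 3, FP = 1, TN = 5, FN = 1))
#' @export
compute_metrics <- function(counts,
                            aggregation_mode = c("per_image_mean",
                                                 "dataset_aggregate")) {
  stopifnot(inherits(counts, "confusion_counts"))
  aggregation_mode <- match.arg(aggregation_mode)
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  sens <- safe_ratio(TP, TP + FN, FP == 0)
  spec <- safe_ratio(TN, TN + FP, FN == 0)
  prec <- safe_ratio(TP, TP + FP, FN == 0)
  iou_p <- safe_ratio(TP, TP + FP + FN, TRUE)
  iou_b <- safe_ratio(TN, TN + FP + FN, TRUE)
  dice <- safe_ratio(2 * TP, 2 * TP + FP + FN, TRUE)
  f2 <- if (4 * prec + sens > 0) 5 * prec * sens / (4 * prec + sens) else 0
  degenerate <- (TP + FN == 0) || (TN + FP == 0) || (TP + FP == 0)
  report <- tibble::tibble(
    accuracy = (TP + TN) / total, sensitivity = sens, specificity = spec,
    precision = prec, iou_polyp = iou_p, iou_background = iou_b,
    mean_iou = (iou_p + iou_b) / 2, dice = dice, f2 = f2,
    aggregation_mode = aggregation_mode, degenerate = degenerate)
  class(report) <- c("metric_report", class(report))
  report
}

#' Average per-image metric reports
#'
#' The arithmetic mean of every metric over images (the `per_image_mean`
#' aggregation).  Pooling confusion counts first and computing metrics once
#' (`dataset_aggregate`) generally gives different values; both modes are
#' available.
#'
#' @param per_image_reports A list of `metric_report`s, or a tibble of
#'   stacked reports.
#' @return A one-row `metric_report` with `aggregation_mode
#'   = "per_image_mean"`.
#' @export
aggregate_per_image <- function(per_image_reports) {
  if (inherits(per_image_reports, "data.frame"))
    per_image_reports <- list(per_image_reports)
  if (length(per_image_reports) == 0)
    stop("cannot aggregate an empty report list", call. = FALSE)
  all <- dplyr::bind_rows(per_image_reports)
  num <- all[vapply(all, is.numeric, logical(1))]
  out <- tibble::as_tibble(as.list(colMeans(num)))
  out$aggregation_mode <- "per_image_mean"
  out$degenerate <- any(all$degenerate)
  class(out) <- c("metric_report", class(out))
  out
}

#' Histogram of per-image accuracies over the six reporting ranges
#'
#' Bins per-image accuracies into the six ranges used for test-set
#' reporting: 90-100%, 80-89.99%, 70-79.99%, 60-69.99%, 50-59.99% and
#' 0-49.99%.
#'
#' @param per_image_accuracies Numeric vector of fractions in `[0, 1]`.
#' @return A tibble with the range labels (highest first) and counts; the
#'   counts sum to the input length.
#' @examples
#' bin_accuracies(c(0.95, 0.85, 0.30))
#' @export
bin_accuracies <- function(per_image_accuracies) {
  a <- per_image_accuracies
  if (length(a) && (any(a < 0) || any(a > 1)))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  breaks <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  labels <- c("90-100%", "80-89.99%", "70-79.99%", "60-69.99%", "50-59.99%",
              "0-49.99%")
  counts <- integer(6)
  for (i in seq_along(breaks))
    counts[i] <- if (i == 1) sum(a >= 0.9) else
      sum(a >= breaks[i] & a < breaks[i - 1])
  counts[6] <- sum(a < 0.5)
  tibble::tibble(range = factor(labels, levels = labels), n = counts)
}

#' Evaluate predicted masks against reference masks
#'
#' Pairs predicted and reference mask files by filename stem (or takes two
#' lists of in-memory masks), computes per-image metrics, and returns the
#' per-image table, both aggregations and the accuracy histogram.
#'
#' @param predicted Directory of predicted mask PNGs, or a list of binary
#'   masks.
#' @param truth Directory of reference mask PNGs, or a list of binary
#'   masks in the same order.
#' @return A list with `per_image` (tibble), `per_image_mean`,
#'   `dataset_aggregate` (both `metric_report`s) and `histogram`.
#' @export
evaluate_masks <- function(predicted, truth) {
  if (is.character(predicted)) {
    pf <- sort(list.files(predicted, pattern = "\\.png$", full.names = TRUE))
    tf <- sort(list.files(truth, pattern = "\\.png$", full.names = TRUE))
    ps <- tools::file_path_sans_ext(basename(pf))
    ts <- tools::file_path_sans_ext(basename(tf))
    if (!identical(ps, ts))
      stop("predicted and truth mask sets differ: ",
           paste(symdiff_stems(ps, ts), collapse = ", "), call. = FALSE)
    predicted <- lapply(pf, read_mask)
    truth <- lapply(tf, read_mask)
    names(predicted) <- ps
  }
  if (length(predicted) != length(truth))
    stop("mask lists differ in length", call. = FALSE)
  counts <- Map(confusion_from_masks, predicted, truth)
  reports <- lapply(counts, compute_metrics)
  per_image <- dplyr::bind_rows(reports, .id = "image")
  pooled <- confusion_counts(
    TP = sum(vapply(counts, `[[`, numeric(1), "TP")),
    FP = sum(vapply(counts, `[[`, numeric(1), "FP")),
    TN = sum(vapply(counts, `[[`, numeric(1), "TN")),
    FN = sum(vapply(counts, `[[`, numeric(1), "FN")))
  list(per_image = per_image,
       per_image_mean = aggregate_per_image(reports),
       dataset_aggregate = compute_metrics(pooled, "dataset_aggregate"),
       histogram = bin_accuracies(per_image$accuracy))
}

symdiff_stems <- function(a, b) union(setdiff(a, b), setdiff(b, a))
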