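#' Competition-style evaluation
#'
#' Predictions are scored with the clipped multiclass log loss
#' \deqn{-\frac{1}{N}\sum_{i=1}^{N}\sum_{j=1}^{M} y_{ij} \log p_{ij},}
#' where `y_ij` indicates the true whale of image `i`, `p_ij` is the
#' predicted probability, the logarithm is natural, and every probability is
#' first replaced by `max(min(p, 1 - 1e-15), 1e-15)` to avoid the extremes
#' of the log. Top-1 and top-5 accuracy and the submission CSV format are
#' also provided.
#'
#' @name evaluation
NULL

#' Construct a prediction set
#'
#' @param names Character image names (length N).
#' @param roster Character identity labels (length M).
#' @param p `N x M` matrix of probabilities; rows must be nonnegative and
#'   sum to 1 within 1e-6.
#' @return An object of class `"prediction_set"`.
#' @export
prediction_set <- function(names, roster, p) {
  p <- as.matrix(p)
  names <- as.character(names); roster <- as.character(roster)
  if (nrow(p) != length(names) || ncol(p) != length(roster)) {
    stop("probability matrix must be length(names) x length(roster)", call. = FALSE)
  }
  if (anyDuplicated(names)) stop("duplicate image names", call. = FALSE)
  if (anyDuplicated(roster)) stop("duplicate roster identities", call. = FALSE)
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("prediction rows must sum to 1 within 1e-6", call. = FALSE)
  }
  dimnames(p) <- list(names, roster)
  structure(list(names = names, roster = roster, p = p),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set: %d images x %d identities>\n",
              length(x$names), length(x$roster)))
  invisible(x)
}

#' Construct a truth set
#'
#' @param names Character image names.
#' @param identity True identity per image.
#' @return An object of class `"truth_set"`.
#' @export
truth_set <- function(names, identity) {
  names <- as.character(names); identity <- as.character(identity)
  if (length(names) != length(identity)) {
    stop("`names` and `identity` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(names)) stop("duplicate image names", call. = FALSE)
  structure(list(names = names, identity = identity), class = "truth_set")
}

# Align a truth set to a prediction set; errors on mismatches.
align_truth <- function(preds, truth) {
  stopifnot(inherits(preds, "prediction_set"), inherits(truth, "truth_set"))
  m <- match(preds$names, truth$names)
  if (anyNA(m)) {
    stop("truth is missing images: ",
         paste(head(preds$names[is.na(m)], 5), collapse = ", "), call. = FALSE)
  }
  ident <- truth$identity[m]
  j <- match(ident, preds$roster)
  if (anyNA(j)) {
    stop("true identities outside the roster: ",
         paste(head(unique(ident[is.na(j)]), 5), collapse = ", "), call. = FALSE)
  }
  j
}

#' Clip probabilities away from 0 and 1
#'
#' Replaces every entry `p` by `max(min(p, 1 - 1e-15), 1e-15)`. No
#' renormalization is applied afterwards, so clipped rows need not sum
#' to 1 — this matches the scoring convention the log loss formula implies.
#'
#' @param p Matrix (or vector) of probabilities in `[0, 1]`.
#' @return The clipped matrix.
#' @export
clip_probabilities <- function(p) {
  if (any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1] before clipping", call. = FALSE)
  }
  pmin(pmax(p, 1e-15), 1 - 1e-15)
}

#' Clipped multiclass log loss
#'
#' @param preds A [prediction_set()].
#' @param truth A [truth_set()] covering the same images.
#' @return The mean negative natural log of the clipped probability assigned
#'   to each true identity (nonnegative).
#' @export
logloss <- function(preds, truth) {
  j <- align_truth(preds, truth)
  pc <- clip_probabilities(preds$p)
  -mean(log(pc[cbind(seq_along(j), j)]))
}

#' Top-k accuracy
#'
#' Fraction of images whose true identity ranks among the `k` most probable
#' predictions. Ties are broken by ascending roster order, so the result is
#' deterministic.
#'
#' @param preds A [prediction_set()].
#' @param truth A [truth_set()].
#' @param k Number of candidate predictions allowed, `1 <= k <= M`.
#' @return A fraction in `[0, 1]`.
#' @export
top_k_accuracy <- function(preds, truth, k = 5L) {
  if (k < 1 || k > length(preds$roster)) {
    stop(sprintf("`k` must be in [1, %d]", length(preds$roster)), call. = FALSE)
  }
  j <- align_truth(preds, truth)
  hits <- vapply(seq_along(j), function(i) {
    ord <- order(-preds$p[i, ], seq_along(preds$roster))
    j[i] %in% ord[seq_len(k)]
  }, logical(1))
  mean(hits)
}

#' Full evaluation report
#'
#' @param preds A [prediction_set()].
#' @param truth A [truth_set()].
#' @return An `"eval_report"`: list with `logloss`, `top1`, `top5`
#'   (`top5 = top_k` with `k = min(5, M)`), `N` and `M`.
#' @export
eval_report <- function(preds, truth) {
  structure(list(logloss = logloss(preds, truth),
                 top1 = top_k_accuracy(preds, truth, 1L),
                 top5 = top_k_accuracy(preds, truth, min(5L, length(preds$roster))),
                 N = length(preds$names), M = length(preds$roster)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("logloss %.4f | top-1 %.2f%% | top-5 %.2f%% (N = %d, M = %d)\n",
              x$logloss, 100 * x$top1, 100 * x$top5, x$N, x$M))
  invisible(x)
}

#' Write predictions as a competition submission CSV
#'
#' Header `Image,<id_1>,...,<id_M>`, one row per image, probabilities at
#' full precision.
#'
#' @param preds A [prediction_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_submission <- function(preds, path) {
  stopifnot(inherits(preds, "prediction_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Image", preds$roster), collapse = ","), con)
  for (i in seq_along(preds$names)) {
    writeLines(paste(c(preds$names[i],
                       format(preds$p[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a submission CSV back into a prediction set
#'
#' Columns may appear in any order; they are aligned to `roster`. The
#' reader validates that every roster identity has a column, that all cells
#' are numeric, and that each row sums to 1 within 1e-3 (slack for files
#' written with rounded probabilities).
#'
#' @param path Submission file path.
#' @param roster Expected identity labels.
#' @return A [prediction_set()].
#' @export
read_submission <- function(path, roster) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Image" %in% names(df)) {
    stop("submission lacks the 'Image' column", call. = FALSE)
  }
  missing <- setdiff(roster, names(df))
  if (length(missing)) {
    stop("submission is missing identity columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c("Image", roster))
  if (length(extra)) {
    stop("submission has unknown identity columns: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  p <- as.matrix(df[, roster, drop = FALSE])
  if (!is.numeric(p) || anyNA(p)) {
    bad <- which(is.na(p) | !is.finite(p), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (row %d, column '%s')", bad[1, 1], roster[bad[1, 2]]) else ""
    stop("non-numeric probability cell", loc, call. = FALSE)
  }
  sums <- rowSums(p)
  if (any(abs(sums - 1) > 1e-3)) {
    stop(sprintf("row %d probabilities sum to %.4f, not 1",
                 which.max(abs(sums - 1)), sums[which.max(abs(sums - 1))]),
         call. = FALSE)
  }
  prediction_set(df$Image, roster, p / sums)
}
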