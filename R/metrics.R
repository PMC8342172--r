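# Overlap metrics between a predicted and a reference mask.  The confusion
# fractions are all normalized by the reference area, so TP + FN = 1 for a
# nonempty reference; precision, recall, F1 and IoU follow from them.

check_masks <- function(pred, ref) {
  if (!is.matrix(pred) || !is.matrix(ref))
    stop("masks must be matrices", call. = FALSE)
  if (!all(dim(pred) == dim(ref)))
    stop("masks must share a shape", call. = FALSE)
  list(pred = pred > 0, ref = ref > 0)
}

#' Confusion fractions of two masks
#'
#' `TP = |pred & ref| / |ref|`, `FN = (|ref| - |pred & ref|) / |ref|`,
#' `FP = (|pred| - |pred & ref|) / |ref|` — all normalized by the reference
#' area.
#'
#' @param pred Predicted mask (logical or 0/1 matrix).
#' @param ref Reference mask, same shape; must be nonempty.
#' @return Named numeric vector `c(TP, FN, FP)`.
#' @export
confusion_fractions <- function(pred, ref) {
  m <- check_masks(pred, ref)
  nb <- sum(m$ref)
  if (nb == 0) stop("reference mask is empty", call. = FALSE)
  inter <- sum(m$pred & m$ref)
  c(TP = inter / nb, FN = (nb - inter) / nb, FP = (sum(m$pred) - inter) / nb)
}

#' Segmentation metrics report
#'
#' Precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`, their harmonic mean
#' `F1`, and `IoU = |pred & ref| / |pred | ref|`, computed from the
#' reference-normalized confusion fractions (so `P` equals the standard
#' `|pred & ref| / |pred|`).  An empty prediction against a nonempty
#' reference yields all-zero metrics with `degenerate = TRUE`.
#'
#' @inheritParams confusion_fractions
#' @return One-row tibble with columns `TP`, `FN`, `FP`, `prec`, `reca`,
#'   `F1`, `IoU`, `degenerate`.
#' @export
segmentation_metrics <- function(pred, ref) {
  m <- check_masks(pred, ref)
  if (sum(m$pred) == 0 && sum(m$ref) == 0)
    stop("both masks are empty; metrics undefined", call. = FALSE)
  cf <- confusion_fractions(m$pred, m$ref)
  inter <- sum(m$pred & m$ref)
  uni <- sum(m$pred | m$ref)
  degenerate <- sum(m$pred) == 0
  if (degenerate || inter == 0) {
    p <- 0; r <- 0; f1 <- 0
  } else {
    p <- cf[["TP"]] / (cf[["TP"]] + cf[["FP"]])
    r <- cf[["TP"]] / (cf[["TP"]] + cf[["FN"]])
    f1 <- 2 * p * r / (p + r)
  }
  tibble::tibble(TP = cf[["TP"]], FN = cf[["FN"]], FP = cf[["FP"]],
                 prec = p, reca = r, F1 = f1, IoU = inter / uni,
                 degenerate = degenerate)
}

#' Intersection over union
#'
#' @inheritParams confusion_fractions
#' @return Scalar IoU in `[0, 1]`.
#' @export
mask_iou <- function(pred, ref) {
  m <- check_masks(pred, ref)
  uni <- sum(m$pred | m$ref)
  if (uni == 0) stop("both masks are empty; IoU undefined", call. = FALSE)
  sum(m$pred & m$ref) / uni
}
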