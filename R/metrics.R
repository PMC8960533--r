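# ---------------------------------------------------------------------------
# Voxelwise confusion counts and the four segmentation scores, with
# lesion-size stratification from the truth mask's equivalent-sphere
# diameter.
# ---------------------------------------------------------------------------

#' Voxelwise confusion counts
#'
#' Counts true/false positives/negatives between a binary predicted mask
#' and a binary truth mask. Voxels whose *truth* value equals
#' `ignore_label` (typically 2, treated aneurysms) are excluded from all
#' four counts.
#'
#' @param pred predicted mask ([new_label_mask()] or array), values in
#'   \{0, 1\}.
#' @param truth reference mask; values in \{0, 1\} apart from
#'   `ignore_label`.
#' @param ignore_label optional truth label excluded from evaluation.
#' @return object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN` and `n` (voxels evaluated).
#' @export
confusion_counts <- function(pred, truth, ignore_label = NULL) {
  p <- .vol_data(pred)
  t <- .vol_data(truth)
  if (!identical(dim(p), dim(t)))
    stop("prediction and truth shapes differ: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t), collapse = "x"))
  p <- as.vector(p); t <- as.vector(t)
  if (!is.null(ignore_label)) {
    keep <- t != ignore_label
    p <- p[keep]; t <- t[keep]
  }
  badp <- setdiff(unique(p), c(0, 1))
  badt <- setdiff(unique(t), c(0, 1))
  if (length(badp) > 0)
    stop("prediction is not binary; offending values: {",
         paste(sort(badp), collapse = ", "), "}")
  if (length(badt) > 0)
    stop("truth is not binary after exclusion; offending values: {",
         paste(sort(badt), collapse = ", "), "}")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn, n = length(p)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP =", x$TP, " FP =", x$FP, " FN =", x$FN,
      " TN =", x$TN, " (", x$n, "voxels )\n")
  invisible(x)
}

# Degenerate-denominator policy: a 0/0 score is 1.0 when the complementary
# error count is also zero (nothing to find and nothing wrongly called),
# otherwise 0.0.
.safe_ratio <- function(num, den, other_errors) {
  if (den == 0) return(if (other_errors == 0) 1 else 0)
  num / den
}

#' Segmentation scores from confusion counts
#'
#' Dice `2TP / (FP + 2TP + FN)`, sensitivity (recall) `TP / (TP + FN)`,
#' specificity `TN / (FP + TN)` and precision `TP / (TP + FP)`, each in
#' \[0, 1\]. Degenerate zero denominators never raise: an empty prediction
#' against an empty truth scores 1.0 on all four (flagged by
#' [evaluate_masks()]), while an empty prediction against a non-empty
#' truth scores 0.0.
#'
#' @param counts a [confusion_counts()] object.
#' @return scalar score.
#' @export
dice_score <- function(counts) {
  with(counts, if (FP + 2 * TP + FN == 0) 1 else 2 * TP / (FP + 2 * TP + FN))
}

#' @rdname dice_score
#' @export
sensitivity <- function(counts) with(counts, .safe_ratio(TP, TP + FN, FP))

#' @rdname dice_score
#' @export
specificity <- function(counts) with(counts, .safe_ratio(TN, FP + TN, FN))

#' @rdname dice_score
#' @export
precision <- function(counts) with(counts, .safe_ratio(TP, TP + FP, FN))

#' Aneurysm size class from an equivalent-sphere diameter
#'
#' The clinical size strata are `< 3 mm`, `3-7 mm` and `> 7 mm`. The
#' diameter of a mask is taken as the diameter of the sphere with the same
#' volume: `d = 2 * (3 V / (4 pi))^(1/3)` with `V` the foreground volume in
#' mm^3 from the voxel spacing.
#'
#' @param diameter_mm numeric vector of diameters in mm.
#' @return factor with levels `"<3mm"`, `"3-7mm"`, `">7mm"`.
#' @export
lesion_size_class <- function(diameter_mm) {
  out <- ifelse(diameter_mm < 3, "<3mm",
                ifelse(diameter_mm <= 7, "3-7mm", ">7mm"))
  factor(out, levels = c("<3mm", "3-7mm", ">7mm"))
}

.equiv_diameter <- function(mask_data, spacing) {
  v <- sum(mask_data == 1) * prod(spacing)
  if (v == 0) return(NA_real_)
  2 * (3 * v / (4 * pi))^(1 / 3)
}

#' Evaluate predicted masks against reference masks
#'
#' Computes per-case confusion counts and the four scores, plus the
#' unweighted mean across cases; optionally stratifies by the truth mask's
#' equivalent-sphere diameter class. Cases where both masks are empty are
#' scored 1.0 and flagged in the `degenerate` column.
#'
#' @param preds a predicted mask or list of them.
#' @param truths matching reference mask(s).
#' @param ignore_label optional truth label (e.g. 2) excluded from the
#'   counts.
#' @param case_ids optional case identifiers.
#' @return object of class `daunet_metrics`: list with `cases` (per-case
#'   tibble), `summary` (mean scores, one row, plus per-size-class rows
#'   when diameters are available).
#' @export
evaluate_masks <- function(preds, truths, ignore_label = NULL,
                           case_ids = NULL) {
  if (!is.list(preds) || inherits(preds, "label_mask")) preds <- list(preds)
  if (!is.list(truths) || inherits(truths, "label_mask")) truths <- list(truths)
  if (length(preds) != length(truths))
    stop("unpaired cases: ", length(preds), " predictions vs ",
         length(truths), " truths")
  n <- length(preds)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    cc <- confusion_counts(preds[[i]], truths[[i]], ignore_label)
    sp <- .vol_spacing(truths[[i]])
    td <- .vol_data(truths[[i]])
    if (!is.null(ignore_label)) td <- td * (td != ignore_label)
    dia <- .equiv_diameter(td, sp)
    tibble::tibble(
      case = case_ids[i], TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
      dice = dice_score(cc), sensitivity = sensitivity(cc),
      specificity = specificity(cc), precision = precision(cc),
      diameter_mm = dia,
      size_class = as.character(lesion_size_class(dia)),
      degenerate = cc$TP + cc$FP + cc$FN == 0)
  })
  cases <- do.call(rbind, rows)
  agg <- function(df, label) tibble::tibble(
    group = label, n = nrow(df), dice = mean(df$dice),
    sensitivity = mean(df$sensitivity), specificity = mean(df$specificity),
    precision = mean(df$precision))
  summary <- agg(cases, "all")
  strata <- unique(cases$size_class[!is.na(cases$size_class)])
  for (s in sort(strata))
    summary <- rbind(summary, agg(cases[!is.na(cases$size_class) &
                                          cases$size_class == s, ], s))
  structure(list(cases = cases, summary = summary,
                 ignore_label = ignore_label),
            class = "daunet_metrics")
}

#' @export
print.daunet_metrics <- function(x, ...) {
  cat("<daunet_metrics> ", nrow(x$cases), " case(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a metrics report to CSV and/or JSON
#'
#' @param report a [evaluate_masks()] object.
#' @param csv_path,json_path optional output paths; the CSV holds the
#'   per-case table, the JSON both the per-case table and the aggregate.
#' @return the report, invisibly.
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "daunet_metrics"))
  if (!is.null(csv_path)) readr::write_csv(report$cases, csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(list(cases = report$cases, summary = report$summary),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(report)
}
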