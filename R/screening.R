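#' Screening thresholds
#'
#' Activity-class boundaries used in screening validation: actives at
#' IC50 <= 400 nM, inactives at IC50 > 3000 nM (the band in between is
#' "intermediate" and excluded from confusion tallies), hit retention at
#' predicted IC50 <= 0.5 uM, and a primary-assay cut of 75% inhibition
#' at 10 uM. All concentrations in molar.
#'
#' @param active_ic50_max,inactive_ic50_min,hit_predicted_ic50_max molar
#'   concentrations.
#' @param primary_inhibition_min percent inhibition.
#' @export
screening_thresholds <- function(active_ic50_max = 400e-9,
                                 inactive_ic50_min = 3000e-9,
                                 hit_predicted_ic50_max = 0.5e-6,
                                 primary_inhibition_min = 75) {
  stopifnot(active_ic50_max < inactive_ic50_min)
  list(active_ic50_max = active_ic50_max,
       inactive_ic50_min = inactive_ic50_min,
       hit_predicted_ic50_max = hit_predicted_ic50_max,
       primary_inhibition_min = primary_inhibition_min)
}

#' Classify compounds by IC50 thresholds
#'
#' @param ic50 positive IC50 values in molar.
#' @param thresholds a [screening_thresholds()].
#' @return Character vector in {"active", "inactive", "intermediate"}:
#'   active iff ic50 <= the active bound (inclusive), inactive iff
#'   strictly above the inactive bound.
#' @export
classify_by_thresholds <- function(ic50, thresholds = screening_thresholds()) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 values must be positive and finite")
  ifelse(ic50 <= thresholds$active_ic50_max, "active",
         ifelse(ic50 > thresholds$inactive_ic50_min, "inactive",
                "intermediate"))
}

#' Confusion counts and derived screening statistics
#'
#' Standard 2x2 tally of predicted hit flags against true labels, with
#' sensitivity SEN = TP/(TP+FN), specificity SPC = TN/(TN+FP), accuracy
#' and yield of actives Ya = TP/(TP+FP). Ratios with zero denominators
#' are reported as `NA` (absent), never coerced to 0.
#'
#' @param predicted logical vector of predicted-hit flags.
#' @param actual logical vector (TRUE = truly active) or character labels
#'   "active"/"inactive".
#' @return A `ConfusionCounts` list: `TP`, `FP`, `TN`, `FN`, `SEN`,
#'   `SPC`, `ACC`, `Ya`.
#' @export
confusion <- function(predicted, actual) {
  if (is.character(actual)) actual <- actual == "active"
  stopifnot(is.logical(predicted), is.logical(actual))
  if (length(predicted) != length(actual))
    stop("predicted and actual differ in length")
  TP <- sum(predicted & actual); FP <- sum(predicted & !actual)
  TN <- sum(!predicted & !actual); FN <- sum(!predicted & actual)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 SEN = ratio(TP, TP + FN), SPC = ratio(TN, TN + FP),
                 ACC = ratio(TP + TN, TP + FP + TN + FN),
                 Ya = ratio(TP, TP + FP)),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("<ConfusionCounts TP %d FP %d TN %d FN %d | SEN %.3f SPC %.3f ACC %.3f Ya %.3f>\n",
              x$TP, x$FP, x$TN, x$FN, x$SEN, x$SPC, x$ACC, x$Ya))
  invisible(x)
}

#' Guner-Henry (GH) score
#'
#' \deqn{GH = (0.75\,Ya + 0.25\,SEN)\,SPC} with all three components as
#' fractions in [0, 1]. A perfect classifier scores 1.
#'
#' @param counts a [confusion()] result.
#' @export
gh_score <- function(counts) {
  for (comp in c("Ya", "SEN", "SPC"))
    if (is.na(counts[[comp]]))
      stop("GH component ", comp, " is undefined (zero denominator)")
  (0.75 * counts$Ya + 0.25 * counts$SEN) * counts$SPC
}

#' ROC AUC by the Mann-Whitney pairwise statistic
#'
#' Fraction of (active, inactive) pairs where the active scores higher,
#' ties counted 1/2 — exact and invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores numeric screening scores (higher = more active-looking;
#'   `-Inf` is a valid "not captured" sentinel).
#' @param labels logical (TRUE = active) or "active"/"inactive" strings.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "active"
  stopifnot(length(scores) == length(labels))
  a <- scores[labels]; b <- scores[!labels]
  if (!length(a) || !length(b))
    stop("roc_auc needs at least one active and one inactive")
  cmp <- outer(a, b, function(x, y)
    ifelse(x > y, 1, ifelse(x == y, 0.5, 0)))
  mean(cmp)
}

#' Rank predictions and retain hits above a potency cut
#'
#' Retains compounds whose predicted log(1/IC50) meets the hit threshold
#' (predicted IC50 <= `hit_predicted_ic50_max`, boundary inclusive) and
#' orders them by descending prediction, ties by compound id.
#'
#' @param predictions named numeric vector of predicted log(1/IC50).
#' @param thresholds a [screening_thresholds()].
#' @return data.frame with `compound_id` and `predicted_log_inv_ic50`.
#' @export
rank_and_filter_hits <- function(predictions,
                                 thresholds = screening_thresholds()) {
  cut <- log_inverse_ic50(thresholds$hit_predicted_ic50_max)
  keep <- predictions >= cut
  ids <- names(predictions)
  if (is.null(ids)) ids <- as.character(seq_along(predictions))
  ids <- ids[keep]; vals <- unname(predictions[keep])
  ord <- order(-vals, ids)
  data.frame(compound_id = ids[ord], predicted_log_inv_ic50 = vals[ord],
             stringsAsFactors = FALSE)
}

#' Union of per-model hit lists
#'
#' Removes duplicates across hit lists, preserving first-seen order.
#'
#' @param hit_lists list of character vectors.
#' @export
dedupe_hits <- function(hit_lists) {
  unique(unlist(hit_lists, use.names = FALSE))
}

#' TSV metric report for a screening run
#'
#' One row per query with the canonical column names `AUC`, `ACC`,
#' `TNR`, `TPR`, `GH`.
#'
#' @param results named list of lists with elements `auc` and `counts`.
#' @param path optional output TSV path.
#' @export
screening_report <- function(results, path = NULL) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(query = nm, AUC = r$auc, ACC = r$counts$ACC,
               TNR = r$counts$SPC, TPR = r$counts$SEN,
               GH = gh_score(r$counts))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
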