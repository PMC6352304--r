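# Validation against known species labels: confusion counts over all
# unordered genome pairs, and sensitivity/specificity swept over a grid of
# similarity thresholds (an ROC analysis with sensitivity plotted against
# 100 - specificity).

.check_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    if (!all(c("genome_id", "species") %in% names(labels)))
      stop("labels need columns 'genome_id' and 'species'", call. = FALSE)
    labels <- setNames(as.character(labels$species),
                       as.character(labels$genome_id))
  }
  stopifnot(is.character(labels), !is.null(names(labels)))
  miss <- setdiff(ids, names(labels))
  if (length(miss))
    stop("no species label for genome(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  labels[ids]
}

#' Confusion counts of a delineation at one threshold
#'
#' Classifies every unordered genome pair (diagonal excluded) into
#' true/false positives/negatives: a positive call is a similarity above the
#' threshold, and the truth is whether the pair shares a species label.
#' Sensitivity is `100 * tp / (tp + fn)` and specificity
#' `100 * tn / (tn + fp)`; when a denominator is zero (no intra- or no
#' inter-species pairs in the dataset) the rate is reported as `NA` rather
#' than silently coerced to 0 or 100.
#'
#' @param sim A `wgp_similarity` matrix.
#' @param labels Named character vector (genome_id -> species) or data.frame
#'   with columns `genome_id`, `species`; must cover every genome.
#' @param threshold Percentage threshold.
#' @param strict Logical; same-species call uses `>` (default) or `>=`.
#' @return A `wgp_confusion` list: `tp`, `fn`, `tn`, `fp`, `threshold`,
#'   `sensitivity`, `specificity` (percent, possibly `NA`).
#' @export
confusion_counts <- function(sim, labels, threshold = 96, strict = TRUE) {
  stopifnot(inherits(sim, "wgp_similarity"))
  ids <- rownames(sim)
  if (length(ids) < 2L) stop("at least one genome pair required",
                             call. = FALSE)
  lab <- .check_labels(labels, ids)
  ut <- upper.tri(sim)
  s <- sim[ut]
  same <- outer(lab, lab, "==")[ut]
  pos <- if (strict) s > threshold else s >= threshold
  tp <- sum(pos & same); fn <- sum(!pos & same)
  fp <- sum(pos & !same); tn <- sum(!pos & !same)
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp, threshold = threshold,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
    class = "wgp_confusion")
}

#' @export
print.wgp_confusion <- function(x, ...) {
  cat("<wgp_confusion> threshold ", x$threshold,
      ": TP ", x$tp, ", FN ", x$fn, ", TN ", x$tn, ", FP ", x$fp,
      "; sensitivity ", format(x$sensitivity, digits = 4),
      "%, specificity ", format(x$specificity, digits = 4), "%\n", sep = "")
  invisible(x)
}

# Threshold grid built by integer stepping to avoid floating accumulation.
.threshold_grid <- function(t_min, t_max, step) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(step),
            step > 0)
  if (t_min >= t_max) stop("t_min must be < t_max", call. = FALSE)
  n <- floor((t_max - t_min) / step + 1e-9)
  t_min + (0:n) * step
}

#' Sensitivity/specificity sweep over a threshold grid
#'
#' Evaluates [confusion_counts()] at every threshold from `t_min` to `t_max`
#' in steps of `step` (inclusive; the default 90/98/0.5 grid has 17 points).
#' As the threshold rises, sensitivity is non-increasing and specificity
#' non-decreasing by construction.
#'
#' @inheritParams confusion_counts
#' @param t_min,t_max,step Threshold grid in percent.
#' @return A `wgp_roc` data.frame: `threshold`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`.
#' @export
roc_sweep <- function(sim, labels, t_min = 90, t_max = 98, step = 0.5,
                      strict = TRUE) {
  grid <- .threshold_grid(t_min, t_max, step)
  rows <- lapply(grid, function(t) {
    cc <- confusion_counts(sim, labels, threshold = t, strict = strict)
    data.frame(threshold = t, tp = cc$tp, fn = cc$fn, tn = cc$tn,
               fp = cc$fp, sensitivity = cc$sensitivity,
               specificity = cc$specificity)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wgp_roc", class(out))
  out
}

#' Per-subset ROC comparison report
#'
#' Runs the threshold sweep for several parameter subsets on the same
#' parameter table and stacks the results, the tabular analogue of
#' comparing ROC curves of single parameters against their averages. The
#' default subsets are the four single parameters plus the nested presets
#' s2, s3 and s4.
#'
#' @param params Parameter table.
#' @param labels Species labels (see [confusion_counts()]).
#' @param subsets Named list of parameter subsets; names label the report
#'   rows.
#' @inheritParams roc_sweep
#' @return data.frame with a leading `subset` column followed by the
#'   [roc_sweep()] columns.
#' @export
subset_comparison_report <- function(params, labels,
                                     subsets = NULL,
                                     t_min = 90, t_max = 98, step = 0.5,
                                     strict = TRUE) {
  if (is.null(subsets))
    subsets <- list(diff_p = "diff_p", tr_0 = "tr_0", tr_cg = "tr_cg",
                    a_cp = "a_cp", s2 = "s2", s3 = "s3", s4 = "s4")
  stopifnot(is.list(subsets), length(subsets) >= 1L,
            !is.null(names(subsets)))
  rows <- lapply(names(subsets), function(nm) {
    sim <- similarity_matrix(params, subset = subsets[[nm]])
    sw <- roc_sweep(sim, labels, t_min = t_min, t_max = t_max,
                    step = step, strict = strict)
    cbind(subset = nm, as.data.frame(sw))
  })
  do.call(rbind, rows)
}
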