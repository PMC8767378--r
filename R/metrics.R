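# Evaluation metrics (MAE, R^2, mean average precision over landmark
# categories) and the group statistics used in the morphometric summaries
# (pooled means, percentage tables, Welch t, Kruskal-Wallis).

#' Mean absolute error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Mean of absolute differences (0 iff identical).
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    stop_nf("nf_shape_error", "y_true and y_pred must have equal positive length")
  mean(abs(y_true - y_pred))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`; 1 for perfect
#' prediction, 0 for the mean predictor, possibly negative for worse.
#'
#' @param y_true,y_pred Equal-length numeric vectors, `length >= 2`.
#' @return R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    stop_nf("nf_shape_error", "need equal lengths >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop_nf("nf_undefined_error", "R^2 undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Keypoint evaluation configuration
#'
#' @param radius Correctness radius: a detection is correct when within
#'   this distance of the true point (default 5, in the same units as the
#'   coordinates — px unless mm are supplied).
#' @param categories Landmark codes treated as detection categories.
#' @return `keypoint_eval_config` object.
#' @export
keypoint_eval_config <- function(radius = 5, categories = NULL) {
  if (radius <= 0) stop_nf("nf_parameter_error", "radius must be > 0")
  structure(list(radius = radius, categories = categories),
            class = "keypoint_eval_config")
}

#' Mean average precision over landmark categories
#'
#' Each landmark code is a detection category. Detections (with
#' confidences) are matched greedily, highest confidence first, to unmatched
#' ground-truth points of the same category and instance; a match within
#' the correctness radius is a true positive. AP per category is the
#' 101-point interpolated area under the precision-recall curve; mAP is the
#' mean over categories that have at least one ground truth (categories
#' without truths are skipped with a warning).
#'
#' @param detections Data frame: `instance`, `code`, `x`, `y`,
#'   `confidence`.
#' @param truths Data frame: `instance`, `code`, `x`, `y`.
#' @param cfg A [keypoint_eval_config()].
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(detections, truths,
                                   cfg = keypoint_eval_config()) {
  cats <- cfg$categories %||% unique(truths$code)
  aps <- numeric(0)
  for (cat_ in cats) {
    tr <- truths[truths$code == cat_, , drop = FALSE]
    if (!nrow(tr)) {
      warning("category '", cat_, "' has no ground truth; skipped")
      next
    }
    de <- detections[detections$code == cat_, , drop = FALSE]
    n_pos <- nrow(tr)
    if (!nrow(de)) { aps <- c(aps, 0); next }
    de <- de[order(-de$confidence), , drop = FALSE]
    matched <- rep(FALSE, n_pos)
    tp <- fp <- numeric(nrow(de))
    for (i in seq_len(nrow(de))) {
      cand <- which(!matched & tr$instance == de$instance[i])
      if (length(cand)) {
        d2 <- (tr$x[cand] - de$x[i])^2 + (tr$y[cand] - de$y[i])^2
        j <- cand[which.min(d2)]
        if (min(d2) <= cfg$radius^2) {
          matched[j] <- TRUE; tp[i] <- 1
        } else fp[i] <- 1
      } else fp[i] <- 1
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    recall <- ctp / n_pos
    precision <- ctp / (ctp + cfp)
    # 101-point interpolation: mean over r of max precision at recall >= r
    ap <- mean(vapply(seq(0, 1, by = 0.01), function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1)))
    aps <- c(aps, ap)
  }
  if (!length(aps)) stop_nf("nf_data_error", "no category had ground truth")
  mean(aps)
}

#' Pooled (weighted) mean of group summaries
#'
#' `sum(n_i * mean_i) / sum(n_i)` — the "average value" column of a
#' per-group summary table.
#'
#' @param groups Data frame with columns `n` and `mean` (one row per
#'   group), or a list of `list(n=, mean=)`.
#' @return Pooled mean.
#' @export
pooled_mean <- function(groups) {
  if (is.list(groups) && !is.data.frame(groups))
    groups <- do.call(rbind, lapply(groups, as.data.frame))
  if (!nrow(groups)) stop_nf("nf_parameter_error", "empty group list")
  if (any(groups$n < 1)) stop_nf("nf_parameter_error", "group n must be >= 1")
  sum(groups$n * groups$mean) / sum(groups$n)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value (wraps `stats::t.test`).
#'
#' @param a,b Numeric samples, each of size >= 2 with positive variance.
#' @return List `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || sd(a) == 0 || sd(b) == 0)
    stop_nf("nf_stat_error", "each sample needs >= 2 values and positive variance")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on `g - 1` degrees
#' of freedom (wraps `stats::kruskal.test`).
#'
#' @param groups List of >= 2 numeric samples, each of size >= 2.
#' @return List `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop_nf("nf_stat_error", "need >= 2 groups with >= 2 values each")
  if (length(unique(unlist(groups))) == 1)
    stop_nf("nf_stat_error", "all values identical; H undefined")
  ht <- kruskal.test(groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Frequency and percentage summary of class labels
#'
#' Counts and percentages of the total per label; percentages are reported
#' half-up rounded to one decimal for report parity, with the exact
#' fractions retained.
#'
#' @param labels Character/factor vector of hard labels (or a data frame
#'   plus `column`).
#' @param column Column name when `labels` is a data frame.
#' @return Data frame: `label`, `count`, `fraction`, `percent` (1 dp).
#' @export
summarize_classification <- function(labels, column = NULL) {
  if (is.data.frame(labels)) labels <- labels[[column]]
  tab <- table(labels)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$fraction, 1)
  out
}
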