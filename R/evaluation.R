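# Grouped cross-validation, undersampling, and confusion metrics.
#
# The cross table follows the convention rows = prediction, columns =
# PCR result: tn = predicted-negative/PCR-negative, fn =
# predicted-negative/PCR-positive, fp = predicted-positive/PCR-negative,
# tp = predicted-positive/PCR-positive.

.sample_labels <- function(samples) {
  vapply(samples, function(s) s$label, integer(1))
}
.sample_templates <- function(samples) {
  vapply(samples, function(s) s$template_id, character(1))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Stratified grouped k-fold assignment
#'
#' Within each (template, label) stratum, samples are shuffled with the
#' given seed and dealt round-robin (from a random starting group) into
#' `k` groups, so per-stratum group sizes differ by at most one.
#'
#' @param samples List of labeled `pseudo_sentence` objects.
#' @param k Number of groups (default 5).
#' @param seed Integer seed.
#' @return Integer vector of group ids (1..k), one per sample.
#' @export
stratified_group_split <- function(samples, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- .sample_labels(samples)
  tpl <- .sample_templates(samples)
  groups <- integer(length(samples))
  .with_seed(seed, {
    strata <- split(seq_along(samples), paste(tpl, labels, sep = "\r"))
    for (idx in strata) {
      idx <- if (length(idx) > 1L) sample(idx) else idx
      offset <- sample.int(k, 1L) - 1L
      groups[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    }
  })
  groups
}

#' Per-template undersampling to label parity
#'
#' For every template, majority-label samples are randomly subsampled
#' without replacement down to the minority count; templates where one
#' class is absent contribute no samples.  The retained samples keep
#' their original order.
#'
#' @param samples List of labeled `pseudo_sentence` objects.
#' @param seed Integer seed.
#' @return The retained sublist of `samples`.
#' @export
undersample <- function(samples, seed = 1L) {
  labels <- .sample_labels(samples)
  tpl <- .sample_templates(samples)
  keep <- logical(length(samples))
  .with_seed(seed, {
    for (t in unique(tpl)) {
      i0 <- which(tpl == t & labels == 0L)
      i1 <- which(tpl == t & labels == 1L)
      m <- min(length(i0), length(i1))
      if (m == 0L) next
      pick <- function(ix) if (length(ix) > m) sample(ix, m) else ix
      keep[pick(i0)] <- TRUE
      keep[pick(i1)] <- TRUE
    }
  })
  samples[keep]
}

#' Build a prediction-vs-result cross table
#'
#' @param truth Integer vector of PCR results (0/1).
#' @param pred Integer vector of predictions (0/1).
#' @return A `cross_table` list with counts `tn`, `fn`, `fp`, `tp`.
#' @export
cross_table <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(tn = sum(pred == 0L & truth == 0L),
                 fn = sum(pred == 0L & truth == 1L),
                 fp = sum(pred == 1L & truth == 0L),
                 tp = sum(pred == 1L & truth == 1L)),
            class = "cross_table")
}

#' Sensitivity, specificity and accuracy from a cross table
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), accuracy =
#' (tp+tn)/total.  A zero denominator yields NA for that metric and
#' sets the `undefined` flag.
#'
#' @param t A `cross_table` (or list with fields tn, fn, fp, tp).
#' @return A list with `sensitivity`, `specificity`, `accuracy` and
#'   `undefined` (logical).
#' @examples
#' confusion_metrics(list(tn = 1481, fn = 242, fp = 197, tp = 312))
#' @export
confusion_metrics <- function(t) {
  tp <- t$tp; tn <- t$tn; fp <- t$fp; fn <- t$fn
  total <- tp + tn + fp + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       undefined = anyNA(c(sens, spec, acc)))
}

#' Grouped cross-validation of the classifier
#'
#' Splits the samples with [stratified_group_split()], trains one model
#' per fold on the other k-1 groups, and validates on the held-out
#' group.  The pooled cross table sums the k validation tables, so all
#' the data contributes to one table.
#'
#' @param samples List of labeled `pseudo_sentence` objects.
#' @param k Number of folds (default 5).
#' @param model_cfg A [model_config()]; the fold index is added to its
#'   seed so folds train independently but reproducibly.
#' @param seed Seed for the fold assignment.
#' @param trainer Function `(samples, cfg, validation)` returning a
#'   list with `model` and `history`; defaults to [train_classifier()].
#' @param predictor Function `(model, samples)` returning a data.frame
#'   with columns `probability` and `label`; defaults to
#'   [predict_samples()].
#' @return A list with `fold_metrics` (data.frame), `pooled`
#'   (`cross_table`), `pooled_metrics`, `histories` (per-fold list),
#'   `predictions` (data.frame with one row per sample) and `groups`.
#' @export
cross_validate <- function(samples, k = 5L, model_cfg = model_config(),
                           seed = 1L,
                           trainer = function(s, cfg, validation) {
                             train_classifier(s, cfg, validation)
                           },
                           predictor = predict_samples) {
  groups <- stratified_group_split(samples, k = k, seed = seed)
  labels <- .sample_labels(samples)
  pooled <- list(tn = 0L, fn = 0L, fp = 0L, tp = 0L)
  fold_rows <- list()
  histories <- vector("list", k)
  pred_rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(groups == f)
    train_idx <- which(groups != f)
    if (!length(test_idx)) next
    single_class <- length(unique(labels[test_idx])) < 2L
    if (single_class) {
      warning("fold ", f, " validation group has a single class")
    }
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f
    fit <- trainer(samples[train_idx], cfg_f, samples[test_idx])
    histories[[f]] <- fit$history
    pr <- predictor(fit$model, samples[test_idx])
    ct <- cross_table(labels[test_idx], pr$label)
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + ct[[nm]]
    m <- confusion_metrics(ct)
    fold_rows[[f]] <- data.frame(fold = f, tn = ct$tn, fn = ct$fn,
                                 fp = ct$fp, tp = ct$tp,
                                 sensitivity = m$sensitivity,
                                 specificity = m$specificity,
                                 accuracy = m$accuracy,
                                 single_class = single_class)
    pred_rows[[f]] <- data.frame(
      index = test_idx, fold = f,
      pair_id = vapply(samples[test_idx], function(s) s$pair_id,
                       character(1)),
      template_id = vapply(samples[test_idx], function(s) s$template_id,
                           character(1)),
      label = labels[test_idx],
      probability = pr$probability, prediction = pr$label,
      dG_fwd = vapply(samples[test_idx], function(s) s$dG_fwd, numeric(1)),
      dG_rev = vapply(samples[test_idx], function(s) s$dG_rev, numeric(1)),
      stringsAsFactors = FALSE)
  }
  pooled <- structure(pooled, class = "cross_table")
  preds <- do.call(rbind, pred_rows)
  preds <- preds[order(preds$index), , drop = FALSE]
  rownames(preds) <- NULL
  list(fold_metrics = do.call(rbind, fold_rows), pooled = pooled,
       pooled_metrics = confusion_metrics(pooled),
       histories = histories, predictions = preds, groups = groups)
}

#' Compare per-fold metric values between two conditions
#'
#' Two-sided Student's (equal-variance) and Welch's (unequal-variance)
#' t-tests on fold-level replicates.
#'
#' @param a,b Numeric vectors of per-fold metric values (length >= 2).
#' @return A list with `student_p` and `welch_p`.
#' @export
compare_conditions <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(student_p = 1, welch_p = 1))
    }
    return(list(student_p = 0, welch_p = 0))
  }
  list(student_p = stats::t.test(a, b, var.equal = TRUE)$p.value,
       welch_p = stats::t.test(a, b, var.equal = FALSE)$p.value)
}

#' Gibbs-energy scatter table of predictions
#'
#' One row per retained sample: the forward and reverse priming-site
#' Gibbs energies, the PCR result, the prediction, and the confusion
#' category (TP/FN/TN/FP).  Samples removed by undersampling are not in
#' the prediction set and therefore have no row.
#'
#' @param predictions Prediction data.frame as returned in
#'   `cross_validate()$predictions`.
#' @return A data.frame with columns `pair_id`, `template_id`, `dG_fwd`,
#'   `dG_rev`, `pcr_result`, `prediction`, `category`.
#' @export
gibbs_scatter_table <- function(predictions) {
  cat_of <- function(res, pred) {
    ifelse(res == 1L & pred == 1L, "TP",
           ifelse(res == 1L & pred == 0L, "FN",
                  ifelse(res == 0L & pred == 0L, "TN", "FP")))
  }
  data.frame(pair_id = predictions$pair_id,
             template_id = predictions$template_id,
             dG_fwd = predictions$dG_fwd, dG_rev = predictions$dG_rev,
             pcr_result = predictions$label,
             prediction = predictions$prediction,
             category = cat_of(predictions$label, predictions$prediction),
             stringsAsFactors = FALSE)
}
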