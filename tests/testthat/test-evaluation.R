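mk_sample <- function(i, template, label, dGf = NA_real_, dGr = NA_real_) {
  new_pseudo_sentence(paste0("p", i), template, tokens = character(0),
                      label = label, dG_fwd = dGf, dG_rev = dGr)
}

test_that("stratified split deals (template, label) strata evenly", {
  samples <- c(lapply(1:6, mk_sample, template = "t1", label = 0L),
               lapply(7:10, mk_sample, template = "t1", label = 1L))
  g <- stratified_group_split(samples, k = 5L, seed = 4L)
  expect_length(g, 10L)
  labels <- vapply(samples, function(s) s$label, integer(1))
  for (lb in 0:1) {
    counts <- tabulate(g[labels == lb], nbins = 5L)
    expect_lte(diff(range(counts)), 1L)
  }
  expect_true(all(tabulate(g, nbins = 5L) >= 1L))
  # five identical-stratum samples spread one per group
  five <- lapply(1:5, mk_sample, template = "tx", label = 1L)
  expect_setequal(stratified_group_split(five, k = 5L, seed = 1L), 1:5)
  # deterministic per seed
  expect_identical(g, stratified_group_split(samples, k = 5L, seed = 4L))
})

test_that("undersampling equalizes labels per template", {
  samples <- c(lapply(1:10, mk_sample, template = "t1", label = 0L),
               lapply(11:12, mk_sample, template = "t1", label = 1L),
               lapply(13:14, mk_sample, template = "t2", label = 0L),
               lapply(15:16, mk_sample, template = "t2", label = 1L),
               lapply(17:20, mk_sample, template = "t3", label = 0L))
  kept <- undersample(samples, seed = 5L)
  tpl <- vapply(kept, function(s) s$template_id, character(1))
  lab <- vapply(kept, function(s) s$label, integer(1))
  expect_equal(sum(tpl == "t1" & lab == 0L), 2L)
  expect_equal(sum(tpl == "t1" & lab == 1L), 2L)
  expect_equal(sum(tpl == "t2"), 4L)          # already balanced: unchanged
  expect_equal(sum(tpl == "t3"), 0L)          # single-class template dropped
  # parity property on randomized tables
  set.seed(6)
  for (rep in 1:5) {
    rnd <- lapply(1:40, function(i) {
      mk_sample(i, sample(c("a", "b", "c"), 1), sample(0:1, 1))
    })
    kt <- undersample(rnd, seed = rep)
    if (!length(kt)) next
    tp <- vapply(kt, function(s) s$template_id, character(1))
    lb <- vapply(kt, function(s) s$label, integer(1))
    for (t in unique(tp)) {
      expect_equal(sum(tp == t & lb == 0L), sum(tp == t & lb == 1L))
    }
  }
})

test_that("confusion metrics reproduce the published worked examples", {
  a <- confusion_metrics(list(tn = 1481, fn = 242, fp = 197, tp = 312))
  expect_equal(round(a$sensitivity, 2), 0.56)
  expect_equal(round(a$specificity, 2), 0.88)
  expect_equal(round(a$accuracy, 2), 0.80)
  b <- confusion_metrics(list(tn = 380, fn = 174, fp = 138, tp = 416))
  expect_equal(round(b$sensitivity, 3), 0.705)
  expect_equal(round(b$specificity, 3), 0.734)
  expect_equal(round(b$accuracy, 3), 0.718)
  perfect <- confusion_metrics(list(tn = 10, fn = 0, fp = 0, tp = 10))
  expect_equal(unlist(perfect[1:3]), c(sensitivity = 1, specificity = 1,
                                       accuracy = 1))
  z <- confusion_metrics(list(tn = 5, fn = 0, fp = 1, tp = 0))
  expect_true(is.na(z$sensitivity) && z$undefined)
})

test_that("accuracy is the class-weighted mean of sensitivity and specificity", {
  set.seed(7)
  for (rep in 1:10) {
    t <- list(tn = sample(1:50, 1), fn = sample(1:50, 1),
              fp = sample(1:50, 1), tp = sample(1:50, 1))
    m <- confusion_metrics(t)
    P <- t$tp + t$fn; N <- t$tn + t$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("condition comparison runs Student and Welch t-tests", {
  same <- compare_conditions(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$student_p, 1)
  expect_equal(same$welch_p, 1)
  apart <- compare_conditions(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9))
  expect_lt(apart$student_p, 0.01)
  expect_lt(apart$welch_p, 0.01)
  # equal sample variances: the two statistics coincide
  a <- c(0.2, 0.4, 0.6); b <- c(0.5, 0.7, 0.9)
  both <- compare_conditions(a, b)
  expect_equal(both$student_p, both$welch_p, tolerance = 1e-12)
})

test_that("cross-validation with a constant-prediction stub recovers base rates", {
  samples <- c(lapply(1:30, mk_sample, template = "t1", label = 0L),
               lapply(31:45, mk_sample, template = "t1", label = 1L),
               lapply(46:65, mk_sample, template = "t2", label = 0L),
               lapply(66:75, mk_sample, template = "t2", label = 1L))
  stub_trainer <- function(s, cfg, validation) {
    list(model = "always-negative", history = NULL)
  }
  stub_predictor <- function(model, s) {
    data.frame(probability = rep(0, length(s)),
               label = rep(0L, length(s)))
  }
  res <- cross_validate(samples, k = 5L, seed = 8L,
                        trainer = stub_trainer,
                        predictor = stub_predictor)
  expect_equal(res$pooled$tn + res$pooled$fn + res$pooled$fp +
                 res$pooled$tp, 75)
  expect_equal(res$pooled$tn, 50)
  expect_equal(res$pooled$fn, 25)
  m <- res$pooled_metrics
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 50 / 75)
  # every sample validates exactly once
  expect_equal(sort(res$predictions$index), 1:75)
})

test_that("cross-validation pools fold tables and learns separable data", {
  set.seed(9)
  samples <- separable_sentences(25L, 25L)
  res <- cross_validate(samples, k = 5L,
                        model_cfg = model_config(embedding_dim = 16L,
                                                 hidden_dim = 16L,
                                                 batch_size = 8L,
                                                 epochs = 15L, seed = 2L),
                        seed = 9L)
  total <- res$pooled$tn + res$pooled$fn + res$pooled$fp + res$pooled$tp
  expect_equal(total, 50)
  expect_gte(res$pooled_metrics$accuracy, 0.9)
  expect_equal(nrow(res$fold_metrics), 5L)
})

test_that("the Gibbs scatter table categorizes retained samples only", {
  preds <- data.frame(pair_id = c("a", "b", "c", "d"),
                      template_id = "t",
                      label = c(1L, 1L, 0L, 0L),
                      prediction = c(1L, 0L, 0L, 1L),
                      dG_fwd = c(-20, -15, -4, -6),
                      dG_rev = c(-18, -12, -5, -7))
  tab <- gibbs_scatter_table(preds)
  expect_equal(tab$category, c("TP", "FN", "TN", "FP"))
  expect_equal(nrow(tab), 4L)
})
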