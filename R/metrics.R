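#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return a list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from binary label vectors
#'
#' @param y_true,y_pred 0/1 (or logical) vectors of equal length.
#' @return a `confusion_counts` object.
#' @export
confusion_from_labels <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  confusion_counts(tp = sum(y_true == 1 & y_pred == 1),
                   fp = sum(y_true == 0 & y_pred == 1),
                   fn = sum(y_true == 1 & y_pred == 0),
                   tn = sum(y_true == 0 & y_pred == 0))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any
#' zero-denominator case returns 0 by convention.  Values are returned at
#' full precision; round only at the presentation layer.
#'
#' @param c a `confusion_counts` object.
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(c) {
  P <- if (c$tp + c$fp == 0) 0 else c$tp / (c$tp + c$fp)
  R <- if (c$tp + c$fn == 0) 0 else c$tp / (c$tp + c$fn)
  F1 <- f1_from_pr(P, R)
  c(precision = P, recall = R, f1 = F1)
}

#' F1 as the harmonic mean of precision and recall
#'
#' @param P,R precision and recall in `[0, 1]`.
#' @return `2PR/(P+R)`, or 0 when `P + R = 0`.
#' @export
f1_from_pr <- function(P, R) {
  ifelse(P + R == 0, 0, 2 * P * R / (P + R))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' any factor under the root is 0.
#'
#' @param c a `confusion_counts` object.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  f <- c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)
  if (any(f == 0)) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(prod(f))
}

metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(metric,
    precision = function(yt, yp) {
      if (sum(yp == 1) == 0) return(NA_real_)
      sum(yt == 1 & yp == 1) / sum(yp == 1)
    },
    recall = function(yt, yp) {
      if (sum(yt == 1) == 0) return(NA_real_)
      sum(yt == 1 & yp == 1) / sum(yt == 1)
    },
    f1 = function(yt, yp) {
      if (sum(yt == 1) == 0 && sum(yp == 1) == 0) return(NA_real_)
      p <- if (sum(yp == 1) == 0) 0 else sum(yt == 1 & yp == 1) / sum(yp == 1)
      r <- if (sum(yt == 1) == 0) 0 else sum(yt == 1 & yp == 1) / sum(yt == 1)
      f1_from_pr(p, r)
    },
    accuracy = function(yt, yp) mean(yt == yp),
    mcc = function(yt, yp) mcc(confusion_from_labels(yt, yp)),
    stop("unknown metric: ", metric))
}

#' Bootstrap confidence interval for a classification metric
#'
#' Resamples example indices with replacement `n` times and reports the
#' resample mean with a percentile 2.5/97.5% interval.  Inputs are
#' canonicalized by sorting on `(y_true, y_pred)` before seeding, so the
#' result is invariant to input reordering.  Resamples on which the metric
#' is undefined (e.g. no positives drawn) are skipped and counted.
#'
#' @param y_true,y_pred 0/1 vectors of length >= 2.
#' @param metric `"precision"`, `"recall"`, `"f1"`, `"accuracy"`, `"mcc"`
#'   or a `function(y_true, y_pred)`.
#' @param n number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return a list with `mean`, `lo`, `hi`, `n_bootstrap`, `n_skipped`.
#' @export
bootstrap_ci <- function(y_true, y_pred, metric = "f1", n = 1000L,
                         seed = 42L) {
  if (length(y_true) < 2L || length(y_true) != length(y_pred)) {
    stop("need equal-length vectors of size >= 2")
  }
  f <- metric_fun(metric)
  ord <- order(y_true, y_pred, method = "radix")
  yt <- as.integer(y_true)[ord]; yp <- as.integer(y_pred)[ord]
  m <- length(yt)
  set.seed(seed)
  idx <- matrix(sample.int(m, m * n, replace = TRUE), nrow = n)
  vals <- vapply(seq_len(n), function(b) f(yt[idx[b, ]], yp[idx[b, ]]),
                 numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stop("metric undefined in every bootstrap resample")
  v <- vals[ok]
  list(mean = mean(v),
       lo = unname(stats::quantile(v, 0.025)),
       hi = unname(stats::quantile(v, 0.975)),
       n_bootstrap = n, n_skipped = sum(!ok))
}

#' Paired t-test between two metric vectors
#'
#' @param a,b equal-length numeric vectors (>= 2) of paired metric values.
#' @return a list with `t` and two-sided `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("need equal-length vectors of size >= 2")
  }
  if (stats::var(a - b) == 0) {
    stop("zero variance of paired differences")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (>= 2) with nonzero variance.
#' @return the correlation coefficient `r`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need equal-length vectors of size >= 2")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

PLASTIZYME_KOS <- list(PET = "K21104", PHB = c("K05973", "K03932"))

#' KO- or score-based benchmarking confusion counts
#'
#' Under the `ko` scheme a truth-set protein annotated with a correct KO
#' for its polymer (PET: K21104; PHB: K05973 or K03932) is a true
#' positive, any other or missing annotation a false negative; a
#' negative-set protein carrying any plastizyme KO is a false positive,
#' otherwise a true negative.  Under the `score` scheme a protein is
#' called positive iff its score for the polymer strictly exceeds
#' `threshold` (default 0.5), with the same TP/FN/FP/TN mapping.
#'
#' @param predictions `ko` scheme: named character vector protein id ->
#'   KO (`NA` = no annotation).  `score` scheme: numeric matrix with
#'   protein ids as row names and polymer columns.
#' @param truth list with elements named after the polymers (character
#'   vectors of protein ids) plus `negative`; sets must be disjoint.
#' @param scheme `"ko"` or `"score"`.
#' @param threshold score threshold for the `score` scheme.
#' @param ko_map correct-KO lookup (polymer -> KO ids).
#' @return named list of `confusion_counts`, one per polymer.
#' @export
benchmark_confusion <- function(predictions, truth,
                                scheme = c("ko", "score"), threshold = 0.5,
                                ko_map = PLASTIZYME_KOS) {
  scheme <- match.arg(scheme)
  polymers <- setdiff(names(truth), "negative")
  all_ids <- unlist(truth[polymers], use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("protein present in two truth sets: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  neg <- truth$negative
  out <- list()
  for (p in polymers) {
    pos <- truth[[p]]
    if (scheme == "ko") {
      correct <- ko_map[[p]]
      any_ko <- unlist(ko_map, use.names = FALSE)
      pos_hit <- !is.na(predictions[pos]) & predictions[pos] %in% correct
      neg_hit <- !is.na(predictions[neg]) & predictions[neg] %in% any_ko
    } else {
      sc <- predictions[, p]
      pos_hit <- !is.na(sc[pos]) & sc[pos] > threshold
      neg_hit <- !is.na(sc[neg]) & sc[neg] > threshold
    }
    out[[p]] <- confusion_counts(tp = sum(pos_hit), fn = sum(!pos_hit),
                                 fp = sum(neg_hit), tn = sum(!neg_hit))
  }
  out
}

#' Hits per million proteins
#'
#' @param n_hits number of hits.
#' @param n_proteins total predicted proteins in the sample (>= 1).
#' @return `n_hits / n_proteins * 1e6`.
#' @export
hits_per_million <- function(n_hits, n_proteins) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  n_hits / n_proteins * 1e6
}

#' Build an evaluation report row (mirrors published metric tables)
#'
#' @param polymer,model_name labels for the row.
#' @param y_true,y_pred 0/1 vectors.
#' @param n_bootstrap bootstrap resamples per metric (0 disables CIs).
#' @param seed RNG seed for the bootstrap.
#' @return a one-row `data.frame` with precision/recall/F1/MCC and
#'   optional 95% CI bounds per metric.
#' @export
evaluation_report <- function(polymer, model_name, y_true, y_pred,
                              n_bootstrap = 1000L, seed = 42L) {
  cc <- confusion_from_labels(y_true, y_pred)
  prf <- precision_recall_f1(cc)
  row <- data.frame(model = model_name, polymer = polymer,
                    precision = prf["precision"], recall = prf["recall"],
                    f1 = prf["f1"], mcc = mcc(cc),
                    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (n_bootstrap > 0) {
    for (m in c("precision", "recall", "f1")) {
      ci <- bootstrap_ci(y_true, y_pred, m, n = n_bootstrap, seed = seed)
      row[[paste0(m, "_lo")]] <- ci$lo
      row[[paste0(m, "_hi")]] <- ci$hi
    }
  }
  row
}
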