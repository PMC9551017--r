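## Ranking evaluation against a gold standard (AUROC via the midrank
## Mann-Whitney statistic, AUPRC as stepwise average precision) and the
## paired Wilcoxon comparison used by the ablation harness.

## expand a ranking over the gold universe; unranked pairs get -Inf
## (lowest confidence) unless dropped
ranking_over_universe <- function(ranked, gold, unranked = c("append", "exclude")) {
  unranked <- match.arg(unranked)
  ids <- gold$gene_ids
  reg <- rep(ids, times = length(ids))
  tgt <- rep(ids, each = length(ids))
  keep <- reg != tgt
  uni <- data.frame(regulator = reg[keep], target = tgt[keep], stringsAsFactors = FALSE)
  key <- function(df) paste(df$regulator, df$target, sep = "\r")
  ranked <- as.data.frame(ranked, stringsAsFactors = FALSE)
  extra <- setdiff(key(ranked), key(uni))
  if (length(extra) > 0L) stop("ranking contains pairs outside the gold universe")
  sc <- stats::setNames(ranked$score, key(ranked))
  uni$score <- unname(sc[key(uni)])
  if (unranked == "exclude") {
    uni <- uni[!is.na(uni$score), , drop = FALSE]
  } else {
    uni$score[is.na(uni$score)] <- -Inf
  }
  uni$label <- key(uni) %in% key(gold$edges)
  ## deterministic order: descending score, lexicographic tie-break
  uni <- uni[order(-uni$score, uni$regulator, uni$target, method = "radix"), , drop = FALSE]
  rownames(uni) <- NULL
  uni
}

#' Evaluate a ranked edge list against a gold standard
#'
#' AUROC is computed by the rank-statistic (Mann-Whitney) formulation with
#' midranks for ties; AUPRC is stepwise average precision (mean of the
#' precision at each positive hit down the ranking). Gold pairs absent from
#' the ranking are appended below every ranked pair (DREAM convention) by
#' default.
#'
#' @param ranked data.frame `regulator`, `target`, `score` (e.g. from
#'   [infer_network()] or [read_edge_ranking()]).
#' @param gold a [gold_standard()].
#' @param unranked `"append"` (default) or `"exclude"`.
#' @return list with `auroc`, `auprc`, `roc_points` (FPR, TPR), `pr_points`
#'   (recall, precision), `n_positives`, `n_negatives`.
#' @export
evaluate_ranking <- function(ranked, gold, unranked = "append") {
  uni <- ranking_over_universe(ranked, gold, unranked)
  np <- sum(uni$label); nn <- sum(!uni$label)
  if (np == 0L || nn == 0L) {
    stop("metrics undefined: ", np, " positives and ", nn, " negatives")
  }
  r <- rank(uni$score, ties.method = "average")
  auroc <- (sum(r[uni$label]) - np * (np + 1) / 2) / (np * nn)
  tp <- cumsum(uni$label)
  fp <- cumsum(!uni$label)
  prec <- tp / (tp + fp)
  auprc <- mean(prec[uni$label])
  roc <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  pr <- data.frame(recall = tp / np, precision = prec)
  list(auroc = auroc, auprc = auprc,
       roc_points = roc, pr_points = pr,
       n_positives = np, n_negatives = nn)
}

#' Precision among the top-k ranked edges
#' @param ranked ranked edge data.frame.
#' @param gold a [gold_standard()].
#' @param k cutoff, `1 <= k <=` number of universe pairs.
#' @return fraction of the top k that are gold positives.
#' @export
precision_at_k <- function(ranked, gold, k) {
  uni <- ranking_over_universe(ranked, gold)
  if (k < 1L || k > nrow(uni)) stop("k out of range")
  mean(uni$label[seq_len(k)])
}

#' Confusion-based metrics at a top-k cutoff
#'
#' Threshold-dependent companions to the ranking metrics: predictions are
#' the top-k pairs, everything else negative.
#'
#' @inheritParams precision_at_k
#' @return list `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `accuracy`,
#'   `mcc`.
#' @export
confusion_at_k <- function(ranked, gold, k) {
  uni <- ranking_over_universe(ranked, gold)
  if (k < 1L || k > nrow(uni)) stop("k out of range")
  pred <- seq_len(nrow(uni)) <= k
  tp <- sum(pred & uni$label); fp <- sum(pred & !uni$label)
  fn <- sum(!pred & uni$label); tn <- sum(!pred & !uni$label)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = tp / max(tp + fp, 1L),
       recall = tp / max(tp + fn, 1L),
       accuracy = (tp + tn) / length(pred),
       mcc = mcc)
}

#' Paired Wilcoxon comparison of per-trial metrics
#'
#' Signed-rank test on the paired differences of two equal-length trial
#' samples (e.g. per-seed AUROC with and without the grey stage). Uses the
#' exact null distribution for n <= 25 when no zero differences or tied
#' absolute differences are present, otherwise the normal approximation
#' with continuity correction. If every difference is zero the comparison
#' is degenerate and p = 1 is returned.
#'
#' @param sample_a,sample_b numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"greater"` (a tends above b), or
#'   `"less"`.
#' @return list with `statistic` (V), `p_value`, `alternative`,
#'   `degenerate`, and the two samples.
#' @export
compare_trials <- function(sample_a, sample_b,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(sample_a) != length(sample_b)) stop("samples must be paired (equal length)")
  if (length(sample_a) < 1L) stop("empty samples")
  d <- sample_a - sample_b
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, alternative = alternative,
                degenerate = TRUE, sample_a = sample_a, sample_b = sample_b))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz))) && all(d != 0)
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, paired = TRUE,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       alternative = alternative, degenerate = FALSE,
       sample_a = sample_a, sample_b = sample_b)
}
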