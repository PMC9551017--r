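## Granger-style causal stage: lagged designs per target, one of four
## regressors (lasso, ridge, random forest, gradient boosting), per-regulator
## importances, combination with the dynamic grey association, and direction
## resolution from the weight matrix supports.

#' Regressor configuration
#'
#' @param kind one of `"lasso"`, `"ridge"`, `"rf"`, `"xgboost"`.
#' @param lambda regularization coefficient for lasso/ridge; `NULL` (default)
#'   selects it by 5-fold cross-validation over glmnet's path (deterministic
#'   fold assignment). For xgboost this is the L2 complexity parameter
#'   (default 1).
#' @param gamma xgboost minimum split gain (default 0).
#' @param n_trees trees per ensemble fit (rf) / boosting rounds (xgboost).
#' @param max_depth tree depth cap; `NULL` means the library default
#'   (unlimited for rf, 6 for xgboost).
#' @param seed integer base seed for stochastic fits.
#' @param n_repeats number of reseeded fits averaged for stochastic
#'   regressors (rf, xgboost); ignored for lasso/ridge.
#' @return a `regressor_config` list.
#' @export
regressor_config <- function(kind = c("lasso", "ridge", "rf", "xgboost"),
                             lambda = NULL, gamma = 0,
                             n_trees = 100L, max_depth = NULL,
                             seed = 1L, n_repeats = 10L) {
  kind <- match.arg(kind)
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(list(kind = kind, lambda = lambda, gamma = gamma,
                 n_trees = as.integer(n_trees), max_depth = max_depth,
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats)),
            class = "regressor_config")
}

#' Build a lagged regression design for one target gene
#'
#' For each replicate block and each timepoint `t > d`, the response is the
#' target at `t` and the predictor row concatenates every regulator at lags
#' `1..d`. Rows never span block boundaries.
#'
#' @param table an [expression_table()].
#' @param target_id the target gene.
#' @param d lag order >= 1.
#' @param regulator_ids candidate regulators; default all genes (the
#'   target's own lags act as autoregressive controls and are dropped from
#'   edge scores downstream).
#' @return list with `response`, `predictors` (rows x (regulators*d)),
#'   `column_index` (data.frame `gene`, `lag`), and `d`.
#' @export
build_lagged_design <- function(table, target_id, d = 2L, regulator_ids = NULL) {
  d <- as.integer(d)
  if (d < 1L) stop("lag order d must be >= 1")
  if (!target_id %in% table$gene_ids) stop("unknown target: ", target_id)
  if (is.null(regulator_ids)) regulator_ids <- table$gene_ids
  if (!all(regulator_ids %in% table$gene_ids)) stop("unknown regulator id(s)")
  resp <- numeric(0); rows <- list()
  for (block in table$series) {
    n <- ncol(block)
    if (n <= d) stop("replicate block of length ", n, " cannot support lag order ", d)
    for (t in (d + 1L):n) {
      resp <- c(resp, block[target_id, t])
      rows[[length(rows) + 1L]] <-
        as.vector(vapply(regulator_ids,
                         function(g) block[g, t - seq_len(d)],
                         numeric(d)))
    }
  }
  resp <- unname(resp)
  X <- do.call(rbind, rows)
  ci <- data.frame(gene = rep(regulator_ids, each = d),
                   lag = rep(seq_len(d), times = length(regulator_ids)),
                   stringsAsFactors = FALSE)
  colnames(X) <- paste0(ci$gene, "_lag", ci$lag)
  list(response = resp, predictors = X, column_index = ci, d = d)
}

## column standardization shared by the penalized fits; zero-variance
## columns are flagged and excluded from the fit (importance 0)
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  Xs <- sweep(X[, keep, drop = FALSE], 2, mu[keep], "-")
  Xs <- sweep(Xs, 2, sdv[keep], "/")
  list(X = Xs, keep = keep)
}

fit_glmnet_importance <- function(X, y, alpha, lambda) {
  p <- ncol(X)
  padded <- FALSE
  if (p == 1L) {               # glmnet needs >= 2 columns; pad with a dead one
    X <- cbind(X, 0)
    padded <- TRUE
  }
  if (is.null(lambda)) {
    n <- nrow(X)
    nfolds <- max(3L, min(5L, n %/% 3L))
    if (n < 3L * nfolds) {
      ## too few rows for honest CV: light fixed penalty
      fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = 1e-3,
                            standardize = FALSE, intercept = TRUE)
      co <- as.numeric(stats::coef(fit))[-1]
      if (padded) co <- co[1L]
      return(abs(co))
    }
    foldid <- rep_len(seq_len(nfolds), n)     # deterministic folds
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                            standardize = FALSE, intercept = TRUE)
    lambda <- cv$lambda.min
    fitobj <- cv$glmnet.fit
    co <- as.numeric(stats::coef(fitobj, s = lambda, exact = FALSE))[-1]
  } else {
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                          standardize = FALSE, intercept = TRUE)
    co <- as.numeric(stats::coef(fit))[-1]
  }
  if (padded) co <- co[1L]
  abs(co)
}

fit_rf_importance <- function(X, y, config) {
  imp <- numeric(ncol(X))
  dat <- data.frame(y = y, X, check.names = FALSE)
  for (r in seq_len(config$n_repeats)) {
    fit <- ranger::ranger(
      dependent.variable.name = "y", data = dat,
      num.trees = config$n_trees,
      ## regression-forest convention p/3, floored at 2 so split candidates
      ## compete and impurity importance reflects predictive value
      mtry = min(ncol(X), max(2L, floor(ncol(X) / 3))),
      max.depth = if (is.null(config$max_depth)) 0 else config$max_depth,
      importance = "impurity",
      seed = config$seed + r - 1L,
      num.threads = 1L, verbose = FALSE)
    imp <- imp + fit$variable.importance[colnames(X)]
  }
  pmax(imp / config$n_repeats, 0)
}

fit_xgb_importance <- function(X, y, config) {
  imp <- numeric(ncol(X))
  names(imp) <- colnames(X)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  for (r in seq_len(config$n_repeats)) {
    params <- list(objective = "reg:squarederror",
                   max_depth = if (is.null(config$max_depth)) 3L else config$max_depth,
                   eta = 0.1,
                   lambda = if (is.null(config$lambda)) 1 else config$lambda,
                   gamma = config$gamma,
                   subsample = 0.8,
                   nthread = 1L,
                   seed = config$seed + r - 1L)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = config$n_trees, verbose = 0)
    tab <- xgboost::xgb.importance(model = fit)
    if (!is.null(tab) && nrow(tab) > 0L) {
      gain <- stats::setNames(tab$Gain, tab$Feature)
      hit <- intersect(names(gain), names(imp))
      imp[hit] <- imp[hit] + gain[hit]
    }
  }
  imp / config$n_repeats
}

#' Per-(gene, lag) importances from one regressor fit
#'
#' lasso/ridge: absolute coefficients of a penalized fit on standardized
#' predictors. rf: impurity (variance-reduction) importances averaged over
#' reseeded forests. xgboost: per-feature gain averaged over reseeded
#' boosters. Constant predictor columns always get importance 0.
#'
#' @param design output of [build_lagged_design()].
#' @param config a [regressor_config()].
#' @return named non-negative numeric vector, one entry per design column.
#' @export
fit_importances <- function(design, config) {
  X <- design$predictors; y <- design$response
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty design")
  std <- standardize_columns(X)
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (!any(std$keep) || stats::sd(y) == 0) return(imp)
  kind <- config$kind
  if (kind %in% c("lasso", "ridge")) {
    alpha <- if (kind == "lasso") 1 else 0
    imp[std$keep] <- fit_glmnet_importance(std$X, y, alpha, config$lambda)
  } else if (kind == "rf") {
    imp[std$keep] <- fit_rf_importance(X[, std$keep, drop = FALSE], y, config)
  } else {
    imp[std$keep] <- fit_xgb_importance(X[, std$keep, drop = FALSE], y, config)
  }
  imp
}

#' Sum lag-specific importances into per-gene weights
#'
#' @param importances vector from [fit_importances()].
#' @param column_index the design's `column_index`.
#' @param drop_gene gene whose weight is removed (the target itself).
#' @return named per-gene weight vector.
#' @export
aggregate_lags <- function(importances, column_index, drop_gene = NULL) {
  w <- tapply(importances, column_index$gene, sum)
  w <- w[unique(column_index$gene)]     # preserve regulator order
  if (!is.null(drop_gene)) w <- w[setdiff(names(w), drop_gene)]
  w
}

#' Assemble the regulator x target weight matrix
#'
#' Fits one lagged regression per target and stacks the per-gene
#' importances; each nonzero column is rescaled to sum to 1 so targets are
#' comparable in the global ranking.
#'
#' @param table an [expression_table()].
#' @param config a [regressor_config()].
#' @param d lag order.
#' @param regulator_ids candidate regulators (e.g. a TF list); default all
#'   genes.
#' @param dga optional association matrix; with `dga_topk` it restricts each
#'   target's candidates to its `dga_topk` highest-association regulators.
#' @param dga_topk integer or `NULL`.
#' @param self_lags include the target's own lags in the design (dropped
#'   from scores either way); default TRUE.
#' @param normalize rescale nonzero columns to sum 1; default TRUE.
#' @return weight matrix, regulators x targets, non-negative, diagonal 0.
#' @export
assemble_weight_matrix <- function(table, config, d = 2L, regulator_ids = NULL,
                                   dga = NULL, dga_topk = NULL,
                                   self_lags = TRUE, normalize = TRUE) {
  ids <- table$gene_ids
  if (is.null(regulator_ids)) regulator_ids <- ids
  W <- matrix(0, length(regulator_ids), length(ids),
              dimnames = list(regulator_ids, ids))
  for (j in ids) {
    cand <- setdiff(regulator_ids, j)
    if (!is.null(dga) && !is.null(dga_topk) && length(cand) > dga_topk) {
      cand <- cand[order(-dga[cand, j], cand)][seq_len(dga_topk)]
    }
    if (length(cand) == 0L) next
    ## canonical (sorted) regulator order so results do not depend on the
    ## input ordering of the gene set
    fit_regs <- sort(if (self_lags) unique(c(cand, j)) else cand)
    design <- build_lagged_design(table, j, d = d, regulator_ids = fit_regs)
    cfg <- config
    cfg$seed <- (config$seed + sum(utf8ToInt(j))) %% .Machine$integer.max
    imp <- fit_importances(design, cfg)
    w <- aggregate_lags(imp, design$column_index, drop_gene = j)
    W[names(w), j] <- w
  }
  W[!is.finite(W)] <- 0
  W <- pmax(W, 0)
  if (normalize) {
    cs <- colSums(W)
    nz <- cs > 0
    W[, nz] <- sweep(W[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  if (identical(rownames(W), colnames(W))) diag(W) <- 0
  W
}

#' Combine association and regression scores
#'
#' @param dga association matrix (regulators x targets or full genes x
#'   genes).
#' @param w weight matrix from [assemble_weight_matrix()].
#' @param mode `"product"` (elementwise, default), `"regression_only"`
#'   (ablation arm), or `"dga_only"`.
#' @return score matrix shaped like `w`.
#' @export
combine_scores <- function(dga, w, mode = c("product", "regression_only", "dga_only")) {
  mode <- match.arg(mode)
  if (mode == "regression_only") return(w)
  if (is.null(dga)) stop("mode '", mode, "' needs the association matrix")
  dsub <- dga[rownames(w), colnames(w), drop = FALSE]
  if (mode == "dga_only") {
    if (identical(rownames(dsub), colnames(dsub))) diag(dsub) <- 0
    return(dsub)
  }
  out <- dsub * w
  if (identical(rownames(out), colnames(out))) diag(out) <- 0
  out
}

#' Resolve edge directions from weight-matrix support
#'
#' `x -> y` is emitted when x carries weight for predicting y but y carries
#' none for x; when both weights exceed the threshold the genes are reported
#' as regulating each other (both directions emitted).
#'
#' @param w square weight matrix (regulators == targets).
#' @param threshold support threshold (weight strictly greater counts as
#'   membership); default 0, matching the sparsity-based reading for lasso.
#' @return data.frame `regulator`, `target`, `reciprocal` (logical).
#' @export
resolve_direction <- function(w, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  ids <- rownames(w)
  if (!identical(ids, colnames(w))) stop("resolve_direction needs a square matrix over one gene set")
  reg <- character(0); tgt <- character(0); rec <- logical(0)
  for (x in ids) for (y in ids) {
    if (x == y) next
    if (w[x, y] > threshold) {
      reg <- c(reg, x); tgt <- c(tgt, y); rec <- c(rec, w[y, x] > threshold)
    }
  }
  data.frame(regulator = reg, target = tgt, reciprocal = rec, stringsAsFactors = FALSE)
}

## flatten a score matrix to the deterministic ranked edge list
rank_edges <- function(scores) {
  reg <- rep(rownames(scores), times = ncol(scores))
  tgt <- rep(colnames(scores), each = nrow(scores))
  keep <- reg != tgt
  sort_ranking(data.frame(regulator = reg[keep], target = tgt[keep],
                          score = as.vector(scores)[keep],
                          stringsAsFactors = FALSE))
}

#' Infer a ranked regulatory network
#'
#' End-to-end inference: dynamic grey association, lagged-regression weight
#' matrix, score combination, and flattening into a deterministically ranked
#' edge list.
#'
#' @param table an [expression_table()].
#' @param regressor regressor kind (see [regressor_config()]).
#' @param d lag order (default 2).
#' @param rho distinguished coefficient of the grey stage.
#' @param combine `"product"`, `"regression_only"`, or `"dga_only"`.
#' @param regulator_ids optional TF list restricting regulators.
#' @param dga_topk optional candidate pre-filter: only the top-k association
#'   partners of each target enter its regression.
#' @param seed integer seed.
#' @param lambda,n_trees,max_depth,n_repeats,gamma passed to
#'   [regressor_config()].
#' @param L_init,L_min,L_max,normalization,pool_extrema passed to
#'   [dynamic_grey_association()].
#' @param self_lags include autoregressive lags in each design.
#' @return a `ranked_edges` data.frame (`regulator`, `target`, `score`) with
#'   attributes `scores`, `weights`, `dga`, and `params`.
#' @export
infer_network <- function(table,
                          regressor = c("lasso", "ridge", "rf", "xgboost"),
                          d = 2L, rho = 0.5,
                          combine = c("product", "regression_only", "dga_only"),
                          regulator_ids = NULL, dga_topk = NULL,
                          seed = 1L, lambda = NULL, n_trees = 100L,
                          max_depth = NULL, n_repeats = 10L, gamma = 0,
                          L_init = NULL, L_min = 2L, L_max = NULL,
                          normalization = "zscore", pool_extrema = "window",
                          self_lags = TRUE) {
  regressor <- match.arg(regressor)
  combine <- match.arg(combine)
  config <- regressor_config(regressor, lambda = lambda, gamma = gamma,
                             n_trees = n_trees, max_depth = max_depth,
                             seed = seed, n_repeats = n_repeats)
  need_dga <- combine != "regression_only" || !is.null(dga_topk)
  dga <- NULL
  if (need_dga) {
    dga <- dynamic_grey_association(table, rho = rho, L_init = L_init,
                                    L_min = L_min, L_max = L_max,
                                    normalization = normalization,
                                    pool_extrema = pool_extrema)
  }
  w <- NULL; scores <- NULL
  if (combine == "dga_only") {
    ridx <- if (is.null(regulator_ids)) table$gene_ids else regulator_ids
    scores <- dga[ridx, , drop = FALSE]
  } else {
    w <- assemble_weight_matrix(table, config, d = d, regulator_ids = regulator_ids,
                                dga = dga, dga_topk = dga_topk, self_lags = self_lags)
    scores <- combine_scores(dga, w, mode = combine)
  }
  ranked <- rank_edges(scores)
  attr(ranked, "scores") <- scores
  attr(ranked, "weights") <- w
  attr(ranked, "dga") <- dga
  attr(ranked, "params") <- list(regressor = regressor, d = d, rho = rho,
                                 combine = combine, seed = seed,
                                 dga_topk = dga_topk,
                                 normalization = normalization,
                                 pool_extrema = pool_extrema)
  class(ranked) <- c("ranked_edges", class(ranked))
  ranked
}

#' @export
print.ranked_edges <- function(x, n = 10L, ...) {
  p <- attr(x, "params")
  cat("ranked_edges:", nrow(x), "edges")
  if (!is.null(p)) cat(" (", p$regressor, ", combine=", p$combine, ")", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}
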