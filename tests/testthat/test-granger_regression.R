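test_that("lagged designs have the right shape and indexing", {
  tab <- random_table(3, 5, seed = 1)
  des <- build_lagged_design(tab, "g1", d = 2)
  expect_equal(dim(des$predictors), c(3L, 6L))          # (5-2) rows, 3 genes x 2 lags
  expect_equal(des$column_index$gene, rep(c("g1", "g2", "g3"), each = 2))
  expect_equal(des$column_index$lag, rep(1:2, 3))

  tab2 <- random_table(2, 4, blocks = 2, seed = 2)
  des2 <- build_lagged_design(tab2, "g2", d = 1)
  expect_equal(nrow(des2$predictors), 6L)               # 3 per block, no boundary rows
  b1 <- tab2$series[[1]]; b2 <- tab2$series[[2]]
  expect_equal(des2$response, c(b1["g2", 2:4], b2["g2", 2:4]))
  expect_equal(unname(des2$predictors[, "g1_lag1"]), c(b1["g1", 1:3], b2["g1", 1:3]))

  tgt <- rbind(y = c(1, 2, 3, 4), x = c(10, 20, 30, 40))
  tt <- expression_table(tgt)
  d3 <- build_lagged_design(tt, "y", d = 1, regulator_ids = "x")
  expect_equal(d3$response, c(2, 3, 4))
  expect_equal(unname(d3$predictors[, 1]), c(10, 20, 30))

  expect_error(build_lagged_design(tab, "g1", d = 5), "lag order")
  expect_error(build_lagged_design(tab, "nope", d = 1), "unknown target")
})

test_that("a large enough lasso penalty shrinks every importance to zero", {
  tab <- random_table(4, 30, seed = 10)
  des <- build_lagged_design(tab, "g1", d = 2)
  imp <- fit_importances(des, regressor_config("lasso", lambda = 1e6))
  expect_true(all(imp == 0))
})

test_that("every regressor puts >10x importance on the true lagged driver", {
  set.seed(7)
  n <- 201
  x <- rnorm(n); z <- rnorm(n)
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.9 * x[t - 1] + rnorm(1, sd = 0.01)
  tab <- expression_table(rbind(x = x, z = z, y = y))
  des <- build_lagged_design(tab, "y", d = 1, regulator_ids = c("x", "z"))
  for (kind in c("lasso", "ridge", "rf", "xgboost")) {
    imp <- fit_importances(des, regressor_config(kind, seed = 1, n_repeats = 3, n_trees = 50))
    expect_gt(imp["x_lag1"], 10 * max(imp["z_lag1"], 1e-12))
  }
})

test_that("constant columns and constant responses are tolerated, never fatal", {
  tab <- random_table(3, 20, seed = 3)
  flat <- tab$series[[1]]
  flat["g2", ] <- 4.2
  tabf <- expression_table(flat, gene_ids = tab$gene_ids)
  des <- build_lagged_design(tabf, "g1", d = 1)
  imp <- fit_importances(des, regressor_config("ridge", lambda = 0.1))
  expect_equal(unname(imp["g2_lag1"]), 0)
  expect_true(all(imp >= 0))

  ## constant target: all importances zero
  des2 <- build_lagged_design(tabf, "g2", d = 1)
  expect_true(all(fit_importances(des2, regressor_config("lasso")) == 0))
})

test_that("ridge on a single proportional predictor concentrates the weight", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  tab <- expression_table(rbind(x = x, y = c(0, 2 * x[-10])))
  des <- build_lagged_design(tab, "y", d = 1, regulator_ids = "x")
  imp <- fit_importances(des, regressor_config("ridge", lambda = 0.01))
  expect_gt(imp["x_lag1"], 0)
})

test_that("lag importances aggregate by gene and drop the target", {
  ci <- data.frame(gene = c("a", "a", "b", "b"), lag = c(1, 2, 1, 2))
  w <- aggregate_lags(c(0.2, 0.3, 0.1, 0), ci, drop_gene = NULL)
  expect_equal(unname(w["a"]), 0.5)
  expect_equal(unname(w["b"]), 0.1)
  w2 <- aggregate_lags(c(0.2, 0.3, 0.1, 0), ci, drop_gene = "a")
  expect_equal(names(w2), "b")
  expect_true(all(aggregate_lags(rep(0, 4), ci) == 0))
})

test_that("the weight matrix finds a single planted edge and respects TF lists", {
  set.seed(11)
  n <- 100
  g1 <- rnorm(n)
  g2 <- numeric(n); g3 <- rnorm(n)
  for (t in 2:n) g2[t] <- 0.8 * g1[t - 1] + rnorm(1, sd = 0.05)
  tab <- expression_table(rbind(g1 = g1, g2 = g2, g3 = g3))
  W <- assemble_weight_matrix(tab, regressor_config("lasso"), d = 1)
  expect_equal(rownames(W)[which.max(W[, "g2"])], "g1")
  expect_true(all(W >= 0))
  expect_true(all(diag(W) == 0))
  ## nonzero columns sum to one
  cs <- colSums(W)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))

  ## constant table -> all-zero matrix
  flat <- expression_table(matrix(3, 3, 10, dimnames = list(c("a", "b", "c"), NULL)))
  expect_true(all(assemble_weight_matrix(flat, regressor_config("lasso"), d = 1) == 0))

  ## TF restriction: rows only for TFs
  Wtf <- assemble_weight_matrix(tab, regressor_config("lasso"), d = 1,
                                regulator_ids = c("g1", "g3"))
  expect_equal(rownames(Wtf), c("g1", "g3"))
  expect_equal(ncol(Wtf), 3)
})

test_that("score combination modes follow the elementwise contract", {
  ids <- c("a", "b")
  dga <- matrix(c(0, 0.5, 0.7, 0), 2, 2, dimnames = list(ids, ids))
  w <- matrix(c(0, 0.4, 0, 0), 2, 2, dimnames = list(ids, ids))
  expect_equal(combine_scores(dga, w, "regression_only"), w)
  prod <- combine_scores(dga, w, "product")
  expect_equal(prod["b", "a"], 0.5 * 0.4)
  expect_equal(prod["a", "b"], 0)                 # zero factor annihilates
  expect_equal(combine_scores(dga, w, "dga_only"), dga)
  expect_error(combine_scores(NULL, w, "product"), "association")
})

test_that("direction resolution emits one-way and reciprocal edges correctly", {
  ids <- c("x", "y")
  w <- matrix(c(0, 0, 0.3, 0), 2, 2, dimnames = list(ids, ids))  # w[x,y]=0.3
  ed <- resolve_direction(w, 0)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$regulator, "x"); expect_equal(ed$target, "y")
  expect_false(ed$reciprocal)

  w["y", "x"] <- 0.2
  ed2 <- resolve_direction(w, 0)
  expect_equal(nrow(ed2), 2)
  expect_true(all(ed2$reciprocal))

  expect_equal(nrow(resolve_direction(matrix(0, 2, 2, dimnames = list(ids, ids)), 0)), 0)
  expect_error(resolve_direction(w, -1), "threshold")
})

test_that("a one-step delayed noisy copy is recovered as the top edge", {
  set.seed(19)
  n <- 60
  g1 <- cumsum(rnorm(n))
  g2 <- c(0, g1[-n]) + rnorm(n, sd = 0.05)
  g3 <- rnorm(n)
  tab <- expression_table(rbind(g1 = g1, g2 = g2, g3 = g3))
  ranked <- infer_network(tab, regressor = "lasso", d = 1, seed = 4)
  expect_equal(ranked$regulator[1], "g1")
  expect_equal(ranked$target[1], "g2")
})

test_that("inference is deterministic given the seed, stochastic regressors included", {
  net <- sample_network(6, 0.2, seed = 14)
  tab <- simulate_timeseries(net, n_timepoints = 12, n_blocks = 2, seed = 15)
  for (kind in c("lasso", "rf", "xgboost")) {
    r1 <- infer_network(tab, regressor = kind, seed = 7, n_repeats = 2, n_trees = 30)
    r2 <- infer_network(tab, regressor = kind, seed = 7, n_repeats = 2, n_trees = 30)
    expect_identical(as.data.frame(r1), as.data.frame(r2))
    f1 <- tempfile(); f2 <- tempfile()
    write_edge_ranking(r1, f1); write_edge_ranking(r2, f2)
    expect_identical(readLines(f1), readLines(f2))     # byte-identical output
  }
})

test_that("edge scores are invariant to gene input order up to relabelling", {
  tab <- random_table(4, 14, seed = 31)
  perm <- c(2, 4, 1, 3)
  tab_p <- expression_table(tab$series[[1]][perm, ], gene_ids = tab$gene_ids[perm])
  r1 <- infer_network(tab, regressor = "lasso", seed = 3)
  r2 <- infer_network(tab_p, regressor = "lasso", seed = 3)
  s1 <- attr(r1, "scores"); s2 <- attr(r2, "scores")
  expect_equal(s2[rownames(s1), colnames(s1)], s1, tolerance = 1e-10)
})

test_that("dga-topk pre-filtering keeps only top-association candidates per target", {
  tab <- random_table(5, 15, seed = 41)
  r <- infer_network(tab, regressor = "lasso", seed = 2, dga_topk = 2)
  W <- attr(r, "weights")
  expect_true(all(colSums(W > 0) <= 2))
})
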