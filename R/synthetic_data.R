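## Synthetic benchmark generator: random directed networks with signed edge
## strengths, simulated either as a stable VAR(1) process or as Hill-kinetics
## ODEs, written out in the DREAM4 dialect so the whole tool is testable
## end to end without external data.

#' Sample a random directed regulatory network
#'
#' @param m gene count.
#' @param density expected edge probability per ordered pair, in (0, 1).
#' @param topology `"erdos_renyi"` (iid pairs, default) or
#'   `"scale_free_out"` (Zipf-weighted source hubs, same expected density).
#' @param coef_range magnitude range for the signed edge strengths; each
#'   edge gets a strength uniform in `[-hi, -lo] U [lo, hi]`.
#' @param seed integer seed.
#' @return list with `adjacency` (regulator x target signed weight matrix),
#'   `edges` (data.frame `regulator`, `target`, `weight`), `gold` (a
#'   [gold_standard()]), and `gene_ids`.
#' @export
sample_network <- function(m, density = 0.15, topology = c("erdos_renyi", "scale_free_out"),
                           coef_range = c(0.5, 1), seed = 1L) {
  topology <- match.arg(topology)
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (m < 2L) stop("need at least 2 genes")
  set.seed(seed)
  ids <- sprintf("G%d", seq_len(m))
  A <- matrix(0, m, m, dimnames = list(ids, ids))
  if (topology == "erdos_renyi") {
    p <- matrix(density, m, m)
  } else {
    z <- 1 / seq_len(m)                 # Zipf out-hub weights
    rowp <- density * m * z / sum(z)
    p <- matrix(pmin(rowp, 1), m, m)
  }
  draw <- matrix(stats::runif(m * m), m, m) < p
  diag(draw) <- FALSE
  nedges <- sum(draw)
  if (nedges > 0L) {
    mag <- stats::runif(nedges, coef_range[1], coef_range[2])
    sgn <- sample(c(-1, 1), nedges, replace = TRUE)
    A[draw] <- mag * sgn
  }
  idx <- which(draw, arr.ind = TRUE)
  edges <- data.frame(regulator = ids[idx[, 1]], target = ids[idx[, 2]],
                      weight = A[draw], stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(adjacency = A, edges = edges,
       gold = gold_standard(edges[, c("regulator", "target")], ids),
       gene_ids = ids)
}

## spectral-radius rescale keeping the VAR(1) stable but the signal strong;
## nilpotent (DAG) systems have radius 0 and are left untouched
stabilize_var <- function(A, target_radius = 0.9) {
  ev <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (ev > 1e-8) A * (target_radius / ev) else A
}

hill_act <- function(x, K = 1, h = 2) x^h / (K^h + x^h)

#' Simulate replicate expression time series from a network
#'
#' `var1`: x_t = A x_{t-1} + noise with A the transposed signed adjacency
#' rescaled to spectral radius 0.9 (when nonzero), initial state standard
#' normal. `hill_ode`: dx_i/dt = sum over parents of |b| * hill(x_parent)
#' (activating form for b > 0, repressing for b < 0) - decay * x_i + basal,
#' integrated with fixed-step RK4 and observation noise added afterwards.
#' Values are shifted to be positive, expression-like. Blocks are
#' independent replicates.
#'
#' @param network output of [sample_network()].
#' @param model `"var1"` (default) or `"hill_ode"`.
#' @param noise_sd noise standard deviation (process noise for var1,
#'   observation noise for hill_ode); default 0.1.
#' @param n_timepoints timepoints per block (default 21, the DREAM4 size-10
#'   series length).
#' @param n_blocks replicate series (default 5, the DREAM4 size-10 sample
#'   count).
#' @param dt integration step for hill_ode.
#' @param seed integer seed.
#' @param spectral_radius stability target for var1.
#' @return an [expression_table()].
#' @export
simulate_timeseries <- function(network, model = c("var1", "hill_ode"),
                                noise_sd = 0.1, n_timepoints = 21L,
                                n_blocks = 5L, dt = 0.5, seed = 1L,
                                spectral_radius = 0.9) {
  model <- match.arg(model)
  if (n_timepoints < 5L) stop("need at least 5 timepoints")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  m <- length(network$gene_ids)
  Adyn <- t(network$adjacency)          # row target, column regulator
  blocks <- vector("list", n_blocks)
  if (model == "var1") {
    Adyn <- stabilize_var(Adyn, spectral_radius)
    for (b in seq_len(n_blocks)) {
      x <- matrix(0, m, n_timepoints)
      x[, 1] <- stats::rnorm(m)
      for (t in 2:n_timepoints) {
        x[, t] <- Adyn %*% x[, t - 1] + stats::rnorm(m, sd = noise_sd)
      }
      blocks[[b]] <- x
    }
  } else {
    decay <- 1; basal <- 0.2
    deriv <- function(x) {
      drive <- rep(basal, m)
      for (i in seq_len(m)) {
        parents <- which(Adyn[i, ] != 0)
        for (p in parents) {
          b <- Adyn[i, p]
          drive[i] <- drive[i] + abs(b) * if (b > 0) hill_act(x[p]) else 1 - hill_act(x[p])
        }
      }
      drive - decay * x
    }
    for (b in seq_len(n_blocks)) {
      x <- matrix(0, m, n_timepoints)
      x[, 1] <- stats::runif(m, 0.5, 1.5)
      for (t in 2:n_timepoints) {
        v <- x[, t - 1]
        k1 <- deriv(v)
        k2 <- deriv(v + dt / 2 * k1)
        k3 <- deriv(v + dt / 2 * k2)
        k4 <- deriv(v + dt * k3)
        x[, t] <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      x <- x + matrix(stats::rnorm(m * n_timepoints, sd = noise_sd), m, n_timepoints)
      blocks[[b]] <- x
    }
  }
  lo <- min(vapply(blocks, min, 0))
  if (lo < 1) blocks <- lapply(blocks, function(x) x - lo + 1)  # expression-like positive
  blocks <- lapply(blocks, function(x) { rownames(x) <- network$gene_ids; x })
  expression_table(blocks, gene_ids = network$gene_ids)
}

#' Write a complete synthetic fixture to disk
#'
#' Samples a network, simulates expression, and writes a DREAM4-dialect
#' time-series TSV plus a gold-standard TSV that round-trip through the
#' package readers.
#'
#' @param out_dir output directory (created if missing).
#' @param m,density,topology,coef_range network parameters
#'   (see [sample_network()]).
#' @param model,noise_sd,n_timepoints,n_blocks,dt dynamics parameters (see
#'   [simulate_timeseries()]).
#' @param seed integer seed (network and dynamics draw from it).
#' @param prefix file name prefix, default `"synthetic"`.
#' @return list with `expr_path`, `gold_path`, `network`, `table`.
#' @export
make_fixture <- function(out_dir, m = 10L, density = 0.15,
                         topology = "erdos_renyi", coef_range = c(0.5, 1),
                         model = "var1", noise_sd = 0.1,
                         n_timepoints = 21L, n_blocks = 5L, dt = 0.5,
                         seed = 1L, prefix = "synthetic") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  net <- sample_network(m, density = density, topology = topology,
                        coef_range = coef_range, seed = seed)
  table <- simulate_timeseries(net, model = model, noise_sd = noise_sd,
                               n_timepoints = n_timepoints, n_blocks = n_blocks,
                               dt = dt, seed = seed + 1L)
  expr_path <- file.path(out_dir, paste0(prefix, "_timeseries.tsv"))
  gold_path <- file.path(out_dir, paste0(prefix, "_goldstandard.tsv"))
  write_timeseries_tsv(table, expr_path, dialect = "dream4")
  ed <- net$edges
  writeLines(sprintf("%s\t%s\t1", ed$regulator, ed$target), gold_path)
  list(expr_path = expr_path, gold_path = gold_path, network = net, table = table)
}
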