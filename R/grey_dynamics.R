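## Dynamic grey association: entropy-adaptive sliding windows + grey
## relational analysis. The target gene's first-differenced trajectory drives
## the window lengths; within each window the grey relational grade between
## the target and every comparative gene is computed and the grades are
## averaged over windows into the dynamic grey association (DGA) score.

#' First-order difference of a series
#'
#' The discrete time derivative: `out[i] = series[i+1] - series[i]`.
#'
#' @param series numeric vector of length >= 2.
#' @return numeric vector of length `length(series) - 1`.
#' @export
first_difference <- function(series) {
  if (length(series) < 2L) stop("series must have at least 2 points")
  diff(series)
}

#' Softmax probabilities and Shannon entropy of a derivative segment
#'
#' The absolute first differences inside a window are pushed through a
#' softmax to obtain a probability vector, whose Shannon entropy (bits)
#' measures how evenly the expression change is spread over the window.
#'
#' @param diff_segment numeric vector (a segment of first differences);
#'   absolute values are taken internally.
#' @return list with `probabilities` (sums to 1) and `entropy` (bits,
#'   in `[0, log2(length(diff_segment))]`).
#' @export
softmax_entropy <- function(diff_segment) {
  if (length(diff_segment) == 0L) stop("empty segment")
  a <- abs(diff_segment)
  a <- a - max(a)                       # stable softmax
  p <- exp(a) / sum(exp(a))
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  list(probabilities = p, entropy = entropy)
}

#' Next adaptive window length
#'
#' The current window length is the previous length scaled by the ratio of
#' the two most recent window entropies, rounded half-to-even and clamped
#' into `[L_min, L_max]`. A zero previous entropy (degenerate window) leaves
#' the length unchanged.
#'
#' @param E_curr entropy of the most recently completed window (bits).
#' @param E_prev entropy of the window before that (bits).
#' @param L_prev previous window length (>= 2).
#' @param L_min,L_max inclusive clamp bounds.
#' @return integer window length.
#' @export
next_window_length <- function(E_curr, E_prev, L_prev, L_min = 2L, L_max = Inf) {
  if (L_prev < 2L) stop("L_prev must be >= 2")
  if (E_prev <= 0) return(as.integer(L_prev))
  L <- round(E_curr / E_prev * L_prev)  # round() is round-half-to-even
  as.integer(min(max(L, L_min), L_max))
}

#' Build the entropy-adaptive window schedule for one target series
#'
#' Windows tile the first-difference axis of the (already normalized) target
#' series without gaps or overlaps. The first window has length `L_init`;
#' each subsequent length is [next_window_length()] applied to the entropies
#' of the two preceding windows, with the pre-first entropy fixed at the
#' maximum-entropy baseline `log2(L_init)`. Trailing points too few to form
#' a window of length `L_min` are absorbed into a final short window (>= 2
#' points) or, if a single point remains, appended to the last window.
#'
#' @param target_series numeric vector (one gene's series, one block).
#' @param L_init initial window length; default `max(3, round((n-1)/5))`.
#' @param L_min,L_max length bounds; defaults 2 and `n - 1`.
#' @return a `window_schedule`: list with `windows` (data.frame `start`
#'   0-based on the difference axis, `length`), `entropies` per window,
#'   `bounds`, and `L_init`.
#' @export
build_window_schedule <- function(target_series, L_init = NULL, L_min = 2L, L_max = NULL) {
  n <- length(target_series)
  d <- first_difference(target_series)
  nd <- length(d)
  if (is.null(L_init)) L_init <- max(3L, as.integer(round(nd / 5)))
  if (is.null(L_max)) L_max <- nd
  L_init <- as.integer(L_init); L_min <- as.integer(L_min); L_max <- as.integer(L_max)
  if (L_min < 2L) stop("L_min must be >= 2")
  if (nd < L_init) stop("series too short for initial window of length ", L_init)
  if (L_init < L_min || L_init > L_max) stop("L_init outside [L_min, L_max]")

  starts <- integer(0); lens <- integer(0); ents <- numeric(0)
  E_prev2 <- log2(L_init)               # maximum-entropy baseline before window 1
  start <- 0L; L <- L_init
  repeat {
    starts <- c(starts, start); lens <- c(lens, L)
    E_curr <- softmax_entropy(d[(start + 1L):(start + L)])$entropy
    ents <- c(ents, E_curr)
    start <- start + L
    remaining <- nd - start
    if (remaining < L_min) {
      if (remaining >= 2L) {
        starts <- c(starts, start); lens <- c(lens, remaining)
        ents <- c(ents, softmax_entropy(d[(start + 1L):nd])$entropy)
      } else if (remaining >= 1L) {
        k <- length(lens)
        lens[k] <- lens[k] + remaining
        ents[k] <- softmax_entropy(d[(starts[k] + 1L):nd])$entropy
      }
      break
    }
    E_nxt_prev <- if (length(ents) >= 2L) ents[length(ents) - 1L] else E_prev2
    L <- next_window_length(E_curr, E_nxt_prev, L, L_min, min(L_max, remaining))
  }
  structure(list(windows = data.frame(start = starts, length = lens),
                 entropies = ents,
                 bounds = c(L_min = L_min, L_max = L_max),
                 L_init = L_init),
            class = "window_schedule")
}

#' @export
print.window_schedule <- function(x, ...) {
  cat("window_schedule:", nrow(x$windows), "windows, lengths",
      paste(x$windows$length, collapse = ","), "\n")
  invisible(x)
}

#' Grey relational coefficients and grades within one window
#'
#' For each comparative series the absolute residual against the target is
#' taken pointwise; the grey relational coefficient contrasts each residual
#' against the pooled extrema over all comparatives and positions in the
#' window, moderated by the distinguished coefficient `rho`:
#' `xi = (min + rho * max) / (resid + rho * max)`. The per-gene grade is the
#' within-window mean of its coefficients. When every residual is zero the
#' coefficients are defined as 1 (limit of perfect coincidence).
#'
#' @param y_window numeric vector, the target's values in the window.
#' @param X_windows matrix (comparatives x window length) or list of vectors.
#' @param rho distinguished coefficient in (0, 1]; default 0.5.
#' @param extrema optional `c(min, max)` pooled externally (used for global
#'   extrema pooling); default pools within this window.
#' @return list with `xi` (comparatives x positions matrix of coefficients),
#'   `grade` (per-comparative mean), and `rho`.
#' @export
window_relational_grade <- function(y_window, X_windows, rho = 0.5, extrema = NULL) {
  if (is.list(X_windows)) X_windows <- do.call(rbind, X_windows)
  X_windows <- as.matrix(X_windows)
  if (nrow(X_windows) == 0L) stop("at least one comparative series is required")
  if (ncol(X_windows) != length(y_window)) stop("comparative windows must match target window length")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  resid <- abs(sweep(X_windows, 2, y_window, "-"))
  if (is.null(extrema)) extrema <- c(min(resid), max(resid))
  mn <- extrema[1]; mx <- extrema[2]
  if (mx <= 0) {
    xi <- matrix(1, nrow(resid), ncol(resid))
  } else {
    xi <- (mn + rho * mx) / (resid + rho * mx)
  }
  dimnames(xi) <- dimnames(resid)
  list(xi = xi, grade = rowMeans(xi), rho = rho)
}

## per-gene, per-block normalization used ahead of both the window schedule
## and the grey residuals
normalize_block <- function(block, normalization) {
  switch(normalization,
    none = block,
    zscore = t(apply(block, 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })),
    minmax = t(apply(block, 1, function(v) {
      r <- max(v) - min(v)
      if (r == 0) rep(0, length(v)) else (v - min(v)) / r
    })),
    stop("unknown normalization: ", normalization)
  )
}

## map a window on the difference axis (0-based start s, length L) to the
## raw-series timepoints s+1 .. s+L (1-based)
window_indices <- function(start, length) (start + 1L):(start + length)

#' Dynamic grey association matrix
#'
#' For every target gene, windows are scheduled on its normalized,
#' first-differenced trajectory; within each window the grey relational
#' grade of every other gene against the target is computed; grades are
#' averaged over windows (unweighted) into the dynamic grey association.
#' With several replicate blocks the per-block scores are averaged.
#'
#' @param table an [expression_table()].
#' @param rho distinguished coefficient in (0, 1]; default 0.5.
#' @param L_init,L_min,L_max window-schedule parameters (see
#'   [build_window_schedule()]); defaults derived per block.
#' @param normalization `"zscore"` (default), `"minmax"` or `"none"`,
#'   applied per gene per block before everything else.
#' @param pool_extrema `"window"` (default) pools the residual extrema of
#'   the grey coefficient within each window; `"global"` pools them over all
#'   windows of a target.
#' @return an m x m matrix: entry `[k, j]` is the association of comparative
#'   gene k with target gene j; diagonal 0. All off-diagonal entries in
#'   (0, 1].
#' @export
dynamic_grey_association <- function(table, rho = 0.5, L_init = NULL,
                                     L_min = 2L, L_max = NULL,
                                     normalization = c("zscore", "minmax", "none"),
                                     pool_extrema = c("window", "global")) {
  normalization <- match.arg(normalization)
  pool_extrema <- match.arg(pool_extrema)
  m <- n_genes(table)
  if (m < 2L) stop("need at least 2 genes")
  ids <- table$gene_ids
  acc <- matrix(0, m, m, dimnames = list(ids, ids))
  for (block in table$series) {
    norm <- normalize_block(block, normalization)
    scores <- matrix(0, m, m, dimnames = list(ids, ids))
    for (j in seq_len(m)) {
      sched <- build_window_schedule(norm[j, ], L_init = L_init, L_min = L_min, L_max = L_max)
      wins <- sched$windows
      comp <- setdiff(seq_len(m), j)
      extrema <- NULL
      if (pool_extrema == "global") {
        allres <- unlist(lapply(seq_len(nrow(wins)), function(w) {
          idx <- window_indices(wins$start[w], wins$length[w])
          abs(sweep(norm[comp, idx, drop = FALSE], 2, norm[j, idx], "-"))
        }))
        extrema <- c(min(allres), max(allres))
      }
      grades <- matrix(0, length(comp), nrow(wins))
      for (w in seq_len(nrow(wins))) {
        idx <- window_indices(wins$start[w], wins$length[w])
        res <- window_relational_grade(norm[j, idx], norm[comp, idx, drop = FALSE],
                                       rho = rho, extrema = extrema)
        grades[, w] <- res$grade
      }
      scores[comp, j] <- rowMeans(grades)
    }
    acc <- acc + scores
  }
  acc <- acc / length(table$series)
  diag(acc) <- 0
  acc
}
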