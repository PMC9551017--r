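## Independent, deliberately literal oracles used to cross-check the
## package's vectorized implementations. Everything here is plain loops and
## shares no code with R/.

## small random expression table for property tests
random_table <- function(m, n, blocks = 1L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("g%d", seq_len(m))
  bl <- lapply(seq_len(blocks), function(b) {
    x <- matrix(stats::rnorm(m * n, mean = 5, sd = 2), m, n)
    rownames(x) <- ids
    x
  })
  expression_table(bl, gene_ids = ids)
}

oracle_softmax_entropy <- function(seg) {
  a <- abs(seg)
  denom <- 0
  for (v in a) denom <- denom + exp(v)
  p <- numeric(length(a))
  for (i in seq_along(a)) p[i] <- exp(a[i]) / denom
  e <- 0
  for (pi in p) if (pi > 0) e <- e - pi * log2(pi)
  list(p = p, entropy = e)
}

## step-by-step window schedule: first window L_init, then each length is
## round(E_curr/E_prev * L_prev) clamped, E_0 = log2(L_init); trailing
## points < L_min absorbed (>=2 its own window, a lone point appended)
oracle_schedule <- function(series, L_init, L_min, L_max) {
  d <- numeric(length(series) - 1L)
  for (i in seq_along(d)) d[i] <- series[i + 1L] - series[i]
  nd <- length(d)
  starts <- c(); lens <- c()
  E_older <- log2(L_init)
  E_prev <- NA
  start <- 0L
  L <- L_init
  repeat {
    starts <- c(starts, start)
    lens <- c(lens, L)
    E_here <- oracle_softmax_entropy(d[(start + 1L):(start + L)])$entropy
    start <- start + L
    rem <- nd - start
    if (rem < L_min) {
      if (rem >= 2L) {
        starts <- c(starts, start)
        lens <- c(lens, rem)
      } else if (rem == 1L) {
        lens[length(lens)] <- lens[length(lens)] + 1L
      }
      break
    }
    E_base <- if (is.na(E_prev)) E_older else E_prev
    Lnext <- if (E_base <= 0) L else round(E_here / E_base * L)
    if (Lnext < L_min) Lnext <- L_min
    cap <- min(L_max, rem)
    if (Lnext > cap) Lnext <- cap
    E_prev <- E_here
    L <- as.integer(Lnext)
  }
  data.frame(start = starts, length = lens)
}

## literal re-computation of the dynamic grey association for one table:
## per-gene z-score per block, schedule per target, pooled-extrema grey
## coefficients per window, grades averaged over windows then blocks
oracle_dga <- function(table, rho = 0.5, L_init = NULL, L_min = 2L, L_max = NULL) {
  m <- length(table$gene_ids)
  total <- matrix(0, m, m, dimnames = list(table$gene_ids, table$gene_ids))
  for (block in table$series) {
    n <- ncol(block)
    nd <- n - 1L
    Li <- if (is.null(L_init)) max(3L, as.integer(round(nd / 5))) else L_init
    Lx <- if (is.null(L_max)) nd else L_max
    norm <- block
    for (g in seq_len(m)) {
      v <- block[g, ]
      mu <- sum(v) / n
      s <- sqrt(sum((v - mu)^2) / (n - 1))
      norm[g, ] <- if (s == 0) rep(0, n) else (v - mu) / s
    }
    scores <- matrix(0, m, m)
    for (j in seq_len(m)) {
      sched <- oracle_schedule(norm[j, ], Li, L_min, Lx)
      comp <- setdiff(seq_len(m), j)
      grades <- matrix(0, length(comp), nrow(sched))
      for (w in seq_len(nrow(sched))) {
        idx <- (sched$start[w] + 1L):(sched$start[w] + sched$length[w])
        resid <- matrix(0, length(comp), length(idx))
        for (a in seq_along(comp)) for (b in seq_along(idx)) {
          resid[a, b] <- abs(norm[j, idx[b]] - norm[comp[a], idx[b]])
        }
        mn <- min(resid); mx <- max(resid)
        for (a in seq_along(comp)) {
          tot <- 0
          for (b in seq_along(idx)) {
            xi <- if (mx <= 0) 1 else (mn + rho * mx) / (resid[a, b] + rho * mx)
            tot <- tot + xi
          }
          grades[a, w] <- tot / length(idx)
        }
      }
      for (a in seq_along(comp)) scores[comp[a], j] <- mean(grades[a, ])
    }
    total <- total + scores
  }
  total / length(table$series)
}

## pairwise-comparison AUROC: fraction of (positive, negative) pairs ranked
## correctly, ties counting one half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## stepwise average precision down an explicitly ordered label sequence
oracle_average_precision <- function(ordered_labels) {
  tp <- 0; s <- 0
  for (i in seq_along(ordered_labels)) {
    if (ordered_labels[i]) {
      tp <- tp + 1
      s <- s + tp / i
    }
  }
  s / sum(ordered_labels)
}

## exact one-sided signed-rank p-value by enumerating all sign assignments
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    v <- 0
    for (i in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) v <- v + r[i]
    vs[mask + 1L] <- v
  }
  if (alternative == "greater") mean(vs >= v_obs) else mean(vs <= v_obs)
}

## write text lines to a fresh temp file
tmp_file_with <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## run the command-line script in a child R process that sees the same
## library paths as this session
run_cli <- function(args, stdout = FALSE) {
  system2("Rscript", args, stdout = stdout, stderr = FALSE,
          env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
}
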