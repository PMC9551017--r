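#' Construct an expression table
#'
#' An `expression_table` holds a time-course expression experiment: one or
#' more replicate series (blocks), each a genes x timepoints numeric matrix
#' sharing the same ordered gene identifiers.
#'
#' @param series list of numeric matrices, genes x timepoints; all blocks
#'   must have identical rownames in identical order.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the rownames of the first block.
#' @param timepoints optional list of numeric time labels, one vector per
#'   block; defaults to `1..n` per block.
#' @return an object of class `expression_table` with fields `gene_ids`,
#'   `series` (list of matrices) and `timepoints`.
#' @export
expression_table <- function(series, gene_ids = NULL, timepoints = NULL) {
  if (is.matrix(series)) series <- list(series)
  if (length(series) == 0L) stop("expression_table needs at least one block")
  series <- lapply(series, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  if (is.null(gene_ids)) gene_ids <- rownames(series[[1]])
  if (is.null(gene_ids)) stop("gene_ids missing and first block has no rownames")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  series <- lapply(series, function(b) {
    if (nrow(b) != length(gene_ids)) stop("block has ", nrow(b), " rows but ", length(gene_ids), " gene ids")
    rownames(b) <- gene_ids
    b
  })
  if (is.null(timepoints)) timepoints <- lapply(series, function(b) seq_len(ncol(b)))
  if (is.numeric(timepoints)) timepoints <- list(timepoints)
  for (i in seq_along(series)) {
    if (ncol(series[[i]]) < 3L) stop("block ", i, " has fewer than 3 timepoints")
    if (anyNA(series[[i]])) stop("block ", i, " contains missing values")
    if (length(timepoints[[i]]) != ncol(series[[i]])) stop("block ", i, ": timepoint labels do not match columns")
  }
  structure(list(gene_ids = gene_ids, series = series, timepoints = timepoints),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", length(x$gene_ids), "genes,",
      length(x$series), "replicate block(s) of",
      paste(vapply(x$series, ncol, 1L), collapse = "/"), "timepoints\n")
  invisible(x)
}

#' Number of genes in an expression table
#' @param table an `expression_table`.
#' @return integer gene count.
#' @export
n_genes <- function(table) length(table$gene_ids)

#' Read a time-series expression table
#'
#' Two dialects are supported. `dream4`: tab-separated with a header row
#' starting `Time` followed by gene names, one row per timepoint; blank lines
#' separate replicate blocks; genes arrive as columns and are transposed into
#' the internal genes x timepoints layout. `plain`: genes as rows, first
#' column the gene id, remaining columns the timepoints, a single block.
#'
#' @param path file path.
#' @param dialect `"dream4"` (default) or `"plain"`.
#' @return an [expression_table()].
#' @export
read_timeseries_tsv <- function(path, dialect = c("dream4", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "plain") {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty expression file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    widths <- lengths(parts)
    if (length(unique(widths)) != 1L) {
      bad <- which(widths != widths[1])[1]
      stop("ragged row at line ", bad, " of ", path, ": expected ", widths[1], " fields, got ", widths[bad])
    }
    ids <- vapply(parts, `[[`, "", 1L)
    vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
    mat <- do.call(rbind, vals)
    if (anyNA(mat)) {
      bad <- which(apply(is.na(mat), 1, any))[1]
      stop("non-numeric or missing value at line ", bad, " of ", path)
    }
    rownames(mat) <- ids
    return(expression_table(list(mat), gene_ids = ids))
  }
  ## dream4 dialect
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank)) stop("empty expression file: ", path)
  first <- which(nonblank)[1]
  header <- strsplit(lines[first], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || tolower(trimws(header[1])) != "time") {
    stop("dream4 header must start with 'Time': ", path)
  }
  genes <- trimws(header[-1])
  nf <- length(header)
  blocks <- list(); times <- list()
  cur <- NULL; cur_t <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur) > 0L) {
      mat <- t(do.call(rbind, cur))
      rownames(mat) <- genes
      blocks[[length(blocks) + 1L]] <<- mat
      times[[length(times) + 1L]] <<- cur_t
    }
    cur <<- NULL; cur_t <<- NULL
  }
  for (i in seq_along(lines)[-seq_len(first)]) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (tolower(trimws(fields[1])) == "time") next  # repeated header before a block
    if (length(fields) != nf) {
      stop("ragged row at line ", i, " of ", path, ": expected ", nf, " fields, got ", length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop("non-numeric or missing value at line ", i, " of ", path)
    cur <- c(cur, list(vals[-1]))
    cur_t <- c(cur_t, vals[1])
  }
  flush()
  if (length(blocks) == 0L) stop("no data rows in ", path)
  expression_table(blocks, gene_ids = genes, timepoints = times)
}

#' Write a time-series expression table
#'
#' Inverse of [read_timeseries_tsv()]; `dream4` writes a `Time`-headed,
#' blank-line-block-separated file, `plain` writes genes as rows (first block
#' only permitted).
#'
#' @param table an [expression_table()].
#' @param path output file path.
#' @param dialect `"dream4"` or `"plain"`.
#' @param digits significant digits used for formatting values.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(table, path, dialect = c("dream4", "plain"), digits = 12) {
  dialect <- match.arg(dialect)
  fmt <- function(x) sprintf("%.*g", digits, x)
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "plain") {
    if (length(table$series) != 1L) stop("plain dialect supports a single block")
    b <- table$series[[1]]
    for (i in seq_len(nrow(b))) {
      writeLines(paste(c(table$gene_ids[i], fmt(b[i, ])), collapse = "\t"), con)
    }
  } else {
    header <- paste(c("Time", table$gene_ids), collapse = "\t")
    for (k in seq_along(table$series)) {
      if (k > 1L) writeLines("", con)
      writeLines(header, con)
      b <- table$series[[k]]
      tp <- table$timepoints[[k]]
      for (j in seq_len(ncol(b))) {
        writeLines(paste(c(fmt(tp[j]), fmt(b[, j])), collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read a gold-standard directed edge list
#'
#' Rows are `regulator<TAB>target[<TAB>label]` with label in {0, 1}; a
#' missing label means 1. Positives are the label-1 rows; every other
#' ordered non-self pair of `gene_ids` is an implicit negative.
#'
#' @param path file path.
#' @param gene_ids gene universe the edges must come from.
#' @return a `gold_standard` object: list with `edges` (data.frame
#'   regulator/target of positives) and `gene_ids`.
#' @export
read_gold_standard <- function(path, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  reg <- character(0); tgt <- character(0); lab <- integer(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed gold-standard row at line ", i)
    l <- if (length(f) >= 3L) suppressWarnings(as.integer(f[3])) else 1L
    if (is.na(l) || !(l %in% c(0L, 1L))) stop("label must be 0 or 1 at line ", i)
    reg <- c(reg, trimws(f[1])); tgt <- c(tgt, trimws(f[2])); lab <- c(lab, l)
  }
  unknown <- setdiff(unique(c(reg, tgt)), gene_ids)
  if (length(unknown) > 0L) stop("unknown gene id(s) in gold standard: ", paste(unknown, collapse = ", "))
  if (any(reg == tgt)) {
    bad <- which(reg == tgt)[1]
    stop("self-edge in gold standard at line ", bad, ": ", reg[bad])
  }
  keep <- lab == 1L
  edges <- unique(data.frame(regulator = reg[keep], target = tgt[keep], stringsAsFactors = FALSE))
  gold_standard(edges, gene_ids)
}

#' Construct a gold standard in memory
#' @param edges data.frame with columns `regulator`, `target` (positives).
#' @param gene_ids gene universe; pairs not listed are negatives.
#' @return a `gold_standard` object.
#' @export
gold_standard <- function(edges, gene_ids) {
  gene_ids <- as.character(gene_ids)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges$regulator == edges$target)) stop("gold standard contains self-edges")
    unknown <- setdiff(unique(c(edges$regulator, edges$target)), gene_ids)
    if (length(unknown) > 0L) stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(edges) == 0L) {
    edges <- data.frame(regulator = character(0), target = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- edges[, c("regulator", "target"), drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, gene_ids = gene_ids), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  m <- length(x$gene_ids)
  cat("gold_standard:", nrow(x$edges), "positive edges over", m * (m - 1L), "ordered pairs\n")
  invisible(x)
}

#' Read a transcription-factor list
#'
#' One identifier per line; restricts the candidate regulator set.
#'
#' @param path file path.
#' @param gene_ids optional universe to validate against.
#' @return character vector of TF ids.
#' @export
read_tf_list <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tfs <- trimws(readLines(path))
  tfs <- tfs[nzchar(tfs)]
  if (anyDuplicated(tfs)) tfs <- unique(tfs)
  if (!is.null(gene_ids)) {
    unknown <- setdiff(tfs, gene_ids)
    if (length(unknown) > 0L) stop("TF id(s) not in expression table: ", paste(unknown, collapse = ", "))
  }
  tfs
}

#' Read a probe-to-gene mapping table
#' @param path tab-separated file with columns `probe_id`, `gene_symbol`
#'   (header optional; detected when the first row matches those names).
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("probe_id", "gene_symbol"), colClasses = "character")
  if (nrow(df) > 0L && identical(tolower(df$probe_id[1]), "probe_id")) df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a ranked edge list
#'
#' Tab-separated `regulator<TAB>target<TAB>score`, sorted by descending
#' score; ties broken lexicographically by (regulator, target) so output is
#' deterministic.
#'
#' @param ranked data.frame with columns `regulator`, `target`, `score`.
#' @param path output path.
#' @param digits significant digits for the score column.
#' @return `path`, invisibly.
#' @export
write_edge_ranking <- function(ranked, path, digits = 12) {
  ranked <- sort_ranking(ranked)
  lines <- sprintf("%s\t%s\t%s", ranked$regulator, ranked$target,
                   sprintf("%.*g", digits, ranked$score))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ranking to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a ranked edge list written by [write_edge_ranking()]
#' @param path file path.
#' @return data.frame `regulator`, `target`, `score` sorted descending.
#' @export
read_edge_ranking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(regulator = character(0), target = character(0), score = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed ranking row in ", path)
  df <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                   target = vapply(parts, `[[`, "", 2L),
                   score = as.numeric(vapply(parts, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  sort_ranking(df)
}

## deterministic ordering used everywhere a ranking is materialized
sort_ranking <- function(ranked) {
  ranked <- as.data.frame(ranked, stringsAsFactors = FALSE)
  if (any(ranked$regulator == ranked$target)) stop("ranking contains self-edges")
  if (anyDuplicated(paste(ranked$regulator, ranked$target))) stop("ranking contains duplicate pairs")
  if (any(!is.finite(ranked$score))) stop("ranking scores must be finite")
  o <- order(-ranked$score, ranked$regulator, ranked$target, method = "radix")
  ranked <- ranked[o, , drop = FALSE]
  rownames(ranked) <- NULL
  ranked
}

#' Collapse microarray probes to genes by maximum IQR
#'
#' When several probes map to one gene symbol, the probe with the largest
#' interquartile range (Q3 - Q1 across samples, linear-interpolation
#' quantiles) is kept; single-probe genes pass through unchanged. Ties on
#' IQR are broken by the lexicographically smaller probe id.
#'
#' @param probe_matrix numeric matrix, probes x samples, rownames probe ids.
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`
#'   covering every probe in `probe_matrix`.
#' @return numeric matrix, one row per distinct gene symbol (rows ordered by
#'   first appearance of the symbol in `probe_map`), with attribute
#'   `selected_probe` naming the retained probe per gene.
#' @export
collapse_probes_by_iqr <- function(probe_matrix, probe_map) {
  probe_matrix <- as.matrix(probe_matrix)
  probes <- rownames(probe_matrix)
  if (is.null(probes)) stop("probe_matrix must have probe ids as rownames")
  unmapped <- setdiff(probes, probe_map$probe_id)
  if (length(unmapped) > 0L) stop("unmapped probe(s): ", paste(unmapped, collapse = ", "))
  map <- probe_map[probe_map$probe_id %in% probes, , drop = FALSE]
  genes <- unique(map$gene_symbol)
  iqr <- apply(probe_matrix, 1, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
  picked <- vapply(genes, function(g) {
    cand <- sort(map$probe_id[map$gene_symbol == g])
    cand[which.max(iqr[cand])]  # which.max keeps the first (lexicographic) on ties
  }, "")
  out <- probe_matrix[picked, , drop = FALSE]
  rownames(out) <- genes
  attr(out, "selected_probe") <- stats::setNames(picked, genes)
  out
}
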