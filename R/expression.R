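#' Drop low-count genes from a count matrix
#'
#' @param counts nonnegative genes x samples matrix.
#' @param min_total genes with total counts below this across all samples
#'   are removed (default 5).
#' @return the filtered matrix.
#' @export
lowCountFilter <- function(counts, min_total = 5) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) stop("no gene passes the low-count filter")
  counts[keep, , drop = FALSE]
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column = gene ids (must be unique), remaining columns = samples.
#' No missing values are tolerated.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
readExpression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  genes <- d[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in expression matrix ", path)
  rownames(m) <- genes
  m
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' gene ids. Categories default to `"neutral"` unless a sidecar tag table
#' (TSV with columns `signature`, `category`, optional `excluded`) is
#' given; signatures flagged `excluded` (downregulated duplicates of an
#' upregulated signature) are dropped at load.
#'
#' @param path GMT path.
#' @param tags optional path to the sidecar category TSV.
#' @return list of [SignatureSet].
#' @export
readGMT <- function(path, tags = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  tag_tab <- NULL
  if (!is.null(tags)) tag_tab <- utils::read.delim(tags,
                                                   stringsAsFactors = FALSE)
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    name <- parts[1]
    cat <- "neutral"; excl <- FALSE
    if (!is.null(tag_tab) && name %in% tag_tab$signature) {
      row <- tag_tab[match(name, tag_tab$signature), ]
      cat <- row$category
      if (!is.null(row$excluded)) excl <- isTRUE(as.logical(row$excluded))
    }
    new("SignatureSet", name = name, genes = unique(parts[-(1:2)]),
        category = cat, excluded = excl)
  })
  out[!vapply(out, function(s) s@excluded, logical(1))]
}

#' Write gene signatures to a GMT file
#'
#' @param signatures list of [SignatureSet].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGMT <- function(signatures, path) {
  lines <- vapply(signatures, function(s)
    paste(c(s@name, s@category, s@genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Rank-walk single-sample signature enrichment scores
#'
#' A rank-based enrichment statistic in the spirit of single-sample
#' gene-set variation scoring. Each gene is first standardized across
#' samples by its empirical cross-sample rank (an ecdf statistic: in how
#' many samples is this gene lower than here?), with the gene's
#' within-sample rank as a sub-unit tie-break. Per sample, genes are then
#' ordered by that statistic (decreasing) and a two-sided
#' Kolmogorov-Smirnov-style random walk is run down the list: signature
#' genes step up by `1/|S|`, non-members step down by `1/(N - |S|)`. The
#' enrichment score is the maximum positive deviation of the walk minus
#' the magnitude of its maximum negative deviation, giving a score in
#' `[-1, 1]`. Because both rank statistics are preserved by any monotone
#' transformation of expression, so are the scores. A signature spanning
#' the whole universe scores exactly 0; signatures with fewer than 5
#' genes matched in the matrix are skipped with a warning.
#'
#' @param expr genes x samples numeric matrix (normalized /
#'   variance-stabilized; synthetic matrices can be used as-is, counts
#'   should be log-transformed first).
#' @param signatures list of [SignatureSet].
#' @param min_genes minimum matched genes for a signature to be scored.
#' @return a [SignatureScores] (samples x signatures).
#' @export
scoreSignatures <- function(expr, signatures, min_genes = 5L) {
  N <- nrow(expr)
  # cross-sample rank per gene (ecdf standardization), within-sample rank
  # as a sub-unit tie-break; both invariant to monotone transforms
  cross_rank <- t(apply(expr, 1, rank))
  within_rank <- apply(expr, 2, rank)
  stat <- cross_rank + within_rank / (4 * (N + 1))
  rank_order <- apply(stat, 2, order, decreasing = TRUE)
  keep <- vapply(signatures, function(s)
    sum(s@genes %in% rownames(expr)) >= min_genes, logical(1))
  if (!all(keep))
    warning(sum(!keep), " signature(s) with < ", min_genes,
            " matched genes skipped")
  sigs <- signatures[keep]
  scores <- matrix(0, ncol(expr), length(sigs),
                   dimnames = list(colnames(expr),
                                   vapply(sigs, function(s) s@name,
                                          character(1))))
  gene_idx <- stats::setNames(seq_len(N), rownames(expr))
  for (k in seq_along(sigs)) {
    member <- logical(N)
    member[gene_idx[intersect(sigs[[k]]@genes, rownames(expr))]] <- TRUE
    nS <- sum(member)
    if (nS == N) { scores[, k] <- 0; next }  # whole-universe set
    up <- 1 / nS; down <- 1 / (N - nS)
    for (j in seq_len(ncol(expr))) {
      hits <- member[rank_order[, j]]
      walk <- cumsum(ifelse(hits, up, -down))
      scores[j, k] <- max(0, max(walk)) + min(0, min(walk))
    }
  }
  tags <- stats::setNames(vapply(sigs, function(s) s@category,
                                 character(1)), colnames(scores))
  new("SignatureScores", scores = scores, tags = tags)
}

#' Extract the NIR gradient from a signature score matrix
#'
#' Column-standardizes the samples x signatures score matrix and takes
#' its first principal component: the neurodevelopmental-to-injury-
#' response (NIR) gradient. The component is oriented so that the mean
#' loading over neurodevelopmental-tagged signatures is non-negative —
#' high coordinate = neurodevelopmental, low = mesenchymal/injury-
#' response — which also makes the gradient invariant to a global sign
#' flip of the scores.
#'
#' @param scores a [SignatureScores] (>= 3 samples, >= 2 signatures).
#' @return a [NIRGradient].
#' @export
nirGradient <- function(scores) {
  m <- scoreMatrix(scores)
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need >= 3 samples and >= 2 signatures")
  x <- scale_safe(m)
  if (all(abs(x) < 1e-12)) stop("degenerate (rank-0) score matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  coord <- pc$x[, 1]
  load1 <- pc$rotation[, 1]
  nd <- names(categoryTags(scores))[categoryTags(scores) ==
                                      "neurodevelopmental"]
  if (length(nd) && mean(load1[nd]) < 0) coord <- -coord
  new("NIRGradient",
      coordinates = stats::setNames(coord, rownames(m)),
      varianceFraction = pc$sdev[1]^2 / sum(pc$sdev^2),
      orientation = "high = neurodevelopmental, low = mesenchymal/injury-response")
}
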