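# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Column standardization that maps zero-variance columns to 0 instead of NaN.
scale_safe <- function(x, tol = 1e-12) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  out <- sweep(x, 2, mu, "-")
  live <- sdv > tol
  out[, live] <- sweep(out[, live, drop = FALSE], 2, sdv[live], "/")
  out[, !live] <- 0
  attr(out, "center") <- mu
  attr(out, "scale") <- ifelse(live, sdv, 1)
  out
}

# Canonical ordering of the 29 feature columns.
glcm_feature_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm", "sum_avg",
    "sum_var", "sum_ent", "entropy", "diff_var", "diff_ent", "imc1", "imc2")
}

granularity_feature_names <- function(n = 16L) {
  sprintf("gran_%02d", seq_len(n))
}

all_feature_names <- function() {
  c(glcm_feature_names(), granularity_feature_names())
}

# Deterministic TSV writer used by the pipeline outputs (byte-stable given
# identical inputs: fixed 15 significant digits, no quoting, "." decimal).
write_tsv_stable <- function(df, path) {
  df2 <- df
  num <- vapply(df2, is.numeric, logical(1))
  df2[num] <- lapply(df2[num], function(v) sprintf("%.15g", v))
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
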