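# Fixture builders shared across test files.

# A FeatureTable built directly from random numbers (no image rendering):
# n_samples lines x n_tp time-points x n_rep images per group, confluency
# increasing with time-point.
make_feature_table <- function(n_samples = 5, n_tp = 18, n_rep = 1,
                               seed = 1) {
  set.seed(seed)
  fn <- c(morpholink:::glcm_feature_names(),
          morpholink:::granularity_feature_names())
  rows <- expand.grid(rep = seq_len(n_rep), timepoint_hours = seq_len(n_tp) * 8,
                      sample_id = sprintf("S%02d", seq_len(n_samples)),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  fm <- matrix(rnorm(n * 29, mean = 2, sd = 1), n, 29,
               dimnames = list(NULL, fn))
  dat <- data.frame(sample_id = rows$sample_id,
                    timepoint_hours = rows$timepoint_hours, fm,
                    confluency = pmin(0.95, rows$timepoint_hours / (8 * n_tp) +
                                        runif(n, 0, 0.02)),
                    plls = rnorm(n, -1.5, 0.1), check.names = FALSE)
  new("FeatureTable", data = dat, featureNames = fn, normalization = list())
}

# A small simulated line for image-level tests.
small_line <- function(state = 0.5, seed = 7, n_tp = 6, shape = 96L,
                       capacity = 80L) {
  simulateLine(lineConfig(sprintf("S%+.1f", state), state, seed = seed,
                          n_timepoints = n_tp,
                          frame_shape = c(shape, shape),
                          initial_cells = 10L, carrying_capacity = capacity))
}
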