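# Memoised end-to-end products of a synthetic cohort, shared by the
# acceptance tests (several criteria measure different aspects of the
# same cohorts). The chain is generator -> feature extraction ->
# normalization -> confluency binning -> per-level PCA with alignment ->
# profiles, plus expression scoring; synthetic cohorts carry no aberrant
# frames, so the QC filter (tested separately) is not part of this chain.

cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function(seed, n_lines = 15L) {
  key <- sprintf("s%d_n%d", seed, n_lines)
  if (!is.null(cohort_cache[[key]])) return(cohort_cache[[key]])
  ds <- simulateCohort(n_lines = n_lines, seed = seed)
  ft <- extractFeatures(ds@frames)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn)
  mp <- alignSigns(pcaPerLevel(ftn, lv))
  prof <- meanPCBySample(mp)
  sc <- scoreSignatures(ds@expression, ds@signatures)
  nir <- nirGradient(sc)
  X <- aggregateImageFeatures(ftn, lv)
  res <- list(st = truthState(ds), truthActivity = ds@truthActivity,
              prof = prof, mp = mp, sc = sc, nir = nir, X = X)
  cohort_cache[[key]] <- res
  res
}
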