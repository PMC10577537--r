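# small in-code fixtures shared across test files

make_callset <- function(id, pos, meth, unmeth, chrom = "chr1",
                         assembly = "GRCh38") {
  methylation_callset(id, data.frame(chrom = chrom, pos = pos,
                                     meth = meth, unmeth = unmeth),
                      assembly)
}

# write a CpG-report file from a record data.frame (chrom, pos, strand,
# meth, unmeth), returning its path
write_report_lines <- function(records, path = tempfile(fileext = ".txt")) {
  data.table::fwrite(records, path, sep = "\t", col.names = FALSE, quote = FALSE)
  path
}

# a fake admitted/unadmitted prediction result, for stats tests
fake_result <- function(id, age, admitted = TRUE) {
  structure(list(test_sample_id = id, n_intersected_sites = 10000L,
                 admitted = admitted,
                 fold_predictions = rep(age, 5), predicted_age = age,
                 cv_r = NA_real_, cv_medae = NA_real_),
            class = "PredictionResult")
}

# small training world used by clock tests: 40 samples x 500 sites
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- generator_spec(n_samples = 40L, n_sites = 500L,
                             n_informative = 60L, rng_seed = 424242L)
      coh <- generate_training_cohort(spec)
      cache <<- list(spec = spec,
                     table = build_feature_table(coh$callsets, coh$metadata))
    }
    cache
  }
})
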