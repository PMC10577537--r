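# Synthetic bisulfite-sequencing data with the statistical structure the
# clock assumes: a fixed panel of CpG sites, a subset of which drift linearly
# in methylation with age, observed through binomially sampled reads at
# negative-binomial depths, with optional per-sample site missingness.

#' Specification of the synthetic methylation generator
#'
#' The generator emulates an RRBS-like training cohort: each CpG site has a
#' baseline methylation percent; informative sites additionally change
#' linearly with age. Observed counts arise by binomial thinning of a sampled
#' read depth at the (noise-perturbed, \[0,100\]-clipped) latent percent.
#'
#' @param n_samples Training cohort size (default 182, a blood RRBS cohort).
#' @param n_sites Number of CpG sites on the panel (default 20000).
#' @param n_informative Number of age-linear sites (default 300).
#' @param age_range Chronological age range in years, sampled uniformly
#'   (default 4-40, a young-to-middle-aged blood cohort).
#' @param slope_range Magnitude range of the per-year methylation-percent
#'   change at informative sites; signs are random (default 0.1-0.5).
#' @param baseline_range Range of per-site baseline percents (default 10-90).
#' @param noise_sd Gaussian noise on the latent percent, in percent points
#'   (default 2).
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (default mean 30, size 5 — moderate overdispersion, so the five-read
#'   coverage filter occasionally bites).
#' @param depth_max Depth cap (default 200).
#' @param train_min_depth Depth floor for training samples (default 5, so the
#'   full panel survives the coverage filter in every training sample).
#' @param missing_fraction Per-test-sample fraction of sites left uncovered
#'   (default 0; [generate_test_sample()] also takes `covered_fraction`
#'   directly).
#' @param missing_mode `"independent"` (site-wise) or `"block"` (contiguous
#'   chunks, emulating RRBS fragment structure).
#' @param block_size Sites per block in block mode.
#' @param rng_seed Master seed; every draw derives from it.
#' @return A `GeneratorSpec` list.
#' @export
generator_spec <- function(n_samples = 182L, n_sites = 20000L,
                           n_informative = 300L, age_range = c(4, 40),
                           slope_range = c(0.1, 0.5),
                           baseline_range = c(10, 90), noise_sd = 2,
                           depth_mean = 30, depth_dispersion = 5,
                           depth_max = 200L, train_min_depth = 5L,
                           missing_fraction = 0,
                           missing_mode = c("independent", "block"),
                           block_size = 50L, rng_seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (n_informative > n_sites)
    stop("spec error: n_informative must not exceed n_sites")
  if (missing_fraction < 0 || missing_fraction > 1)
    stop("spec error: missing_fraction must be in [0, 1]")
  stopifnot(n_samples >= 1, n_sites >= 1, noise_sd >= 0, depth_mean > 0,
            age_range[1] >= 0, age_range[2] >= age_range[1])
  structure(as.list(environment()), class = "GeneratorSpec")
}

# the fixed site panel implied by a spec: coordinates, baselines, slopes.
# Derived deterministically from the spec seed so that training cohorts and
# test samples generated from the same spec share one latent site model.
site_model <- function(spec) {
  set.seed(derive_seed(spec$rng_seed, "site_model"))
  n <- spec$n_sites
  pos <- sort(sample.int(50L * n, n))      # irregular spacing, CpG-island-ish
  informative <- sort(sample.int(n, spec$n_informative))
  slopes <- numeric(n)
  slopes[informative] <- runif(spec$n_informative, spec$slope_range[1],
                               spec$slope_range[2]) *
    sample(c(-1, 1), spec$n_informative, replace = TRUE)
  baselines <- runif(n, spec$baseline_range[1], spec$baseline_range[2])
  list(sites = data.table(chrom = "chr1", pos = as.integer(pos)),
       baselines = baselines, slopes = slopes, informative = informative)
}

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# latent percents for one sample at a given age (noise drawn by caller's RNG)
latent_percent <- function(model, age, noise_sd) {
  clip01(model$baselines + model$slopes * age +
           if (noise_sd > 0) rnorm(length(model$baselines), 0, noise_sd) else 0)
}

sample_depths <- function(spec, n, min_depth) {
  d <- rnbinom(n, size = spec$depth_dispersion, mu = spec$depth_mean)
  pmin(pmax(d, min_depth), spec$depth_max)
}

draw_callset <- function(spec, model, sample_id, age, covered, min_depth,
                         assembly) {
  n <- sum(covered)
  depth <- sample_depths(spec, n, min_depth)
  p <- latent_percent(model, age, spec$noise_sd)[covered]
  meth <- rbinom(n, depth, p / 100)
  keep <- depth > 0
  methylation_callset(
    sample_id,
    data.table(chrom = model$sites$chrom[covered][keep],
               pos = model$sites$pos[covered][keep],
               meth = meth[keep], unmeth = (depth - meth)[keep]),
    assembly)
}

#' Generate a synthetic training cohort
#'
#' Draws `n_samples` call sets with ages uniform over `age_range`; every site
#' is covered at depth `>= train_min_depth` in every sample, so
#' [build_feature_table()] retains the full panel.
#'
#' @param spec A [generator_spec()].
#' @param assembly Assembly label attached to the call sets.
#' @return List with `callsets` (list of [methylation_callset()]) and
#'   `metadata` (data.table: `sample_id`, `age`, `group = "training"`).
#' @export
generate_training_cohort <- function(spec, assembly = "GRCh38") {
  stopifnot(inherits(spec, "GeneratorSpec"))
  model <- site_model(spec)
  set.seed(derive_seed(spec$rng_seed, "training_cohort"))
  ages <- runif(spec$n_samples, spec$age_range[1], spec$age_range[2])
  ids <- sprintf("train_%03d", seq_len(spec$n_samples))
  covered <- rep(TRUE, spec$n_sites)
  callsets <- lapply(seq_len(spec$n_samples), function(i)
    draw_callset(spec, model, ids[i], ages[i], covered,
                 spec$train_min_depth, assembly))
  list(callsets = callsets,
       metadata = data.table(sample_id = ids, age = ages, group = "training"))
}

#' Generate one synthetic test sample
#'
#' Latent percents come from the same site model as the training cohort at
#' the given age; a seeded random subset of sites (`covered_fraction`)
#' receives reads. Depths are not floored, so some covered sites may fall
#' below a downstream coverage filter (apply [filter_coverage()] as for real
#' data).
#'
#' @param spec A [generator_spec()].
#' @param age Latent age in years (may lie outside the training range, for
#'   extrapolation experiments).
#' @param covered_fraction Fraction of panel sites covered, in \[0, 1\].
#' @param sample_id Sample id; also seeds this sample's draw, so different
#'   ids give independent samples and the same id reproduces exactly.
#' @param min_depth Depth floor (default 0; set 5 to guarantee the site
#'   survives a five-read filter).
#' @param assembly Assembly label.
#' @return A [methylation_callset()].
#' @export
generate_test_sample <- function(spec, age, covered_fraction = 1,
                                 sample_id = "test_1", min_depth = 0L,
                                 assembly = "GRCh38") {
  stopifnot(inherits(spec, "GeneratorSpec"))
  if (covered_fraction < 0 || covered_fraction > 1)
    stop("spec error: covered_fraction must be in [0, 1]")
  model <- site_model(spec)
  set.seed(derive_seed(spec$rng_seed, "test_sample", sample_id))
  covered <- if (spec$missing_mode == "block") {
    blocks <- ceiling(seq_len(spec$n_sites) / spec$block_size)
    keep_block <- runif(max(blocks)) < covered_fraction
    keep_block[blocks]
  } else {
    runif(spec$n_sites) < covered_fraction
  }
  draw_callset(spec, model, sample_id, age, covered, min_depth, assembly)
}

#' Apply a coverage filter to a call set
#'
#' Drops sites with fewer than `min_coverage` total reads — the same filter
#' the file readers apply, for call sets built in memory.
#'
#' @param callset A [methylation_callset()].
#' @param min_coverage Minimum summed read count.
#' @return The filtered call set.
#' @export
filter_coverage <- function(callset, min_coverage = 5L) {
  calls <- callset$calls[meth + unmeth >= min_coverage]
  methylation_callset(callset$sample_id, calls, callset$assembly)
}

#' Generate a two-group rejuvenation cohort
#'
#' Two groups of synthetic test samples whose latent epigenetic ages are
#' `age_a` and `age_b` — the scenario in which a downstream group comparison
#' should detect a rejuvenation-like shift in predicted age.
#'
#' @param spec A [generator_spec()].
#' @param age_a,age_b Latent ages (years) of the two groups.
#' @param n_per_group Samples per group (>= 2).
#' @param covered_fraction Coverage fraction passed to each test sample.
#' @param min_depth Depth floor per sample.
#' @param id_prefix Prefix for the generated sample ids. Sample draws are
#'   seeded by id, so distinct prefixes give independent replicate cohorts
#'   from the same site model.
#' @return List with `tests` (call sets, group a first) and `labels` (named
#'   vector sample id -> `"a"` / `"b"`).
#' @export
generate_rejuvenation_cohort <- function(spec, age_a, age_b, n_per_group,
                                         covered_fraction = 1,
                                         min_depth = 5L, id_prefix = "") {
  if (n_per_group < 2) stop("spec error: n_per_group must be >= 2")
  ids_a <- sprintf("%sgroupA_%02d", id_prefix, seq_len(n_per_group))
  ids_b <- sprintf("%sgroupB_%02d", id_prefix, seq_len(n_per_group))
  tests <- c(
    lapply(ids_a, function(id)
      generate_test_sample(spec, age_a, covered_fraction, id, min_depth)),
    lapply(ids_b, function(id)
      generate_test_sample(spec, age_b, covered_fraction, id, min_depth)))
  labels <- setNames(rep(c("a", "b"), each = n_per_group), c(ids_a, ids_b))
  list(tests = tests, labels = labels)
}

#' Write a call set as a Bismark-style CpG report
#'
#' With `split_strands = TRUE` each site's counts are written as two records
#' (plus-strand C at `pos`, minus-strand C at `pos + 1`), splitting counts
#' deterministically, so that reading the file exercises strand collapsing
#' and recovers the original call set exactly.
#'
#' @param callset A [methylation_callset()].
#' @param path Output path.
#' @param split_strands Write two per-strand records per site?
#' @return `path`, invisibly.
#' @export
write_cpg_report <- function(callset, path, split_strands = FALSE) {
  calls <- callset$calls
  if (!split_strands) {
    out <- data.table(chrom = calls$chrom, pos = calls$pos, strand = "+",
                      meth = calls$meth, unmeth = calls$unmeth)
  } else {
    meth_p <- calls$meth %/% 2L + calls$meth %% 2L
    unmeth_p <- calls$unmeth %/% 2L + calls$unmeth %% 2L
    plus <- data.table(chrom = calls$chrom, pos = calls$pos, strand = "+",
                       meth = meth_p, unmeth = unmeth_p)
    minus <- data.table(chrom = calls$chrom, pos = calls$pos + 1L,
                        strand = "-", meth = calls$meth - meth_p,
                        unmeth = calls$unmeth - unmeth_p)
    out <- rbind(plus, minus)
    setorder(out, chrom, pos, strand)
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes one CpG-report file per call set plus a `metadata.tsv`, so
#' fixtures feed the same readers as real data.
#'
#' @param cohort Output of [generate_training_cohort()].
#' @param dir Output directory (created if needed).
#' @param split_strands Passed to [write_cpg_report()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, split_strands = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cohort$callsets)
    write_cpg_report(cs, file.path(dir, paste0(cs$sample_id, ".CpG_report.txt")),
                     split_strands = split_strands)
  fwrite(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}
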