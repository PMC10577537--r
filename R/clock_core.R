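# The intersection clock: for each test sample, intersect CpG sites with the
# training table, retrain an elastic-net clock ensemble on exactly those
# sites by fivefold outer CV, and predict age as the ensemble mean.

#' Clock configuration
#'
#' @param alpha Elastic-net mixing parameter in \[0,1\] (0 = ridge,
#'   1 = lasso); default 0.5.
#' @param inner_splits Folds of the inner cross-validation used to pick the
#'   penalty `lambda` (default 10, minimum-MSE rule on the solver's default
#'   lambda path).
#' @param outer_folds Outer folds; each fold yields one clock and the test
#'   prediction is the mean over clocks (default 5).
#' @param min_intersection Minimum number of intersected CpG sites for a test
#'   sample to be admitted to prediction (default 10000).
#' @param rng_seed Integer master seed; all fold draws derive from it.
#' @param share_partition If `TRUE`, the outer fold partition is drawn once
#'   from `rng_seed` and reused for every test sample; by default each test
#'   sample gets its own partition from a stream derived from its sample id,
#'   so results do not depend on cohort order.
#' @return A `ClockConfig` list.
#' @export
clock_config <- function(alpha = 0.5, inner_splits = 10L, outer_folds = 5L,
                         min_intersection = 10000L, rng_seed = 1L,
                         share_partition = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, outer_folds >= 2, min_intersection >= 1,
            inner_splits >= 2)
  structure(list(alpha = alpha, inner_splits = as.integer(inner_splits),
                 outer_folds = as.integer(outer_folds),
                 min_intersection = as.integer(min_intersection),
                 rng_seed = as.integer(rng_seed),
                 share_partition = isTRUE(share_partition)),
            class = "ClockConfig")
}

# stable 31-bit string hash; used to derive per-sample RNG streams that do not
# depend on cohort order
hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (key in list(...)) {
    k <- if (is.character(key)) hash_string(key) else as.numeric(key) %% 2147483647
    h <- (h * 48271 + k + 1) %% 2147483647
  }
  as.integer(h)
}

#' Intersect CpG sites between training table and a test sample
#'
#' @param training A `FeatureTable` ([build_feature_table()]).
#' @param test A [methylation_callset()] on the same assembly.
#' @return An `IntersectionResult`: list with `test_sample_id`, `sites`
#'   (data.table of `chrom`, `pos`, sorted by chromosome then position) and
#'   `n_sites`.
#' @export
intersect_sites <- function(training, test) {
  stopifnot(inherits(training, "FeatureTable"),
            inherits(test, "MethylationCallSet"))
  if (!identical(training$assembly, test$assembly))
    stop(sprintf("configuration error: training assembly '%s' != test assembly '%s'",
                 training$assembly, test$assembly))
  train_keys <- site_key(training$sites$chrom, training$sites$pos)
  test_keys <- site_key(test$calls$chrom, test$calls$pos)
  keep <- train_keys %in% test_keys
  sites <- training$sites[keep]
  setorder(sites, chrom, pos)
  structure(list(test_sample_id = test$sample_id, sites = sites,
                 n_sites = nrow(sites)),
            class = "IntersectionResult")
}

#' Restrict a feature table to a set of sites
#'
#' @param training A `FeatureTable`.
#' @param sites data.table/data.frame of `chrom`, `pos`; must be a subset of
#'   the table's sites. Column order of the result follows `sites`.
#' @return The restricted `FeatureTable` (same samples and ages).
#' @export
restrict <- function(training, sites) {
  stopifnot(inherits(training, "FeatureTable"))
  keys <- site_key(sites$chrom, sites$pos)
  idx <- match(keys, site_key(training$sites$chrom, training$sites$pos))
  if (any(is.na(idx)))
    stop(sprintf("contract violation: %d site(s) absent from training table",
                 sum(is.na(idx))))
  out <- training
  out$sites <- training$sites[idx]
  out$values <- training$values[, idx, drop = FALSE]
  out
}

# near-equal random partition into k folds, invariant to input order: ids are
# sorted before the seeded shuffle, so fold membership depends only on the id
# set and the seed
assign_folds <- function(sample_ids, k, seed) {
  ids <- sort(sample_ids)
  set.seed(seed)
  shuffled <- sample(ids)
  folds <- setNames(rep_len(seq_len(k), length(ids)), shuffled)
  as.integer(folds[sample_ids])
}

#' Train one fold's clock
#'
#' Fits an elastic-net regression of age on methylation percentages using the
#' samples *not* in `fold_id` (for the default five folds, a random 80% of
#' the restricted training set), choosing `lambda` by inner
#' `config$inner_splits`-fold cross-validation (minimum mean squared error),
#' and predicts the held-out fold.
#'
#' @param restricted_training A `FeatureTable` already restricted to the
#'   intersected sites.
#' @param config A [clock_config()].
#' @param fold_assignment Integer fold id per sample (same order as rows).
#' @param fold_id Which fold to hold out.
#' @param seed Seed for the inner fold draw.
#' @return List with `model` (a `ClockModel`: `intercept`, `weights` named by
#'   site key, `lambda`, `alpha`, `fold_id`) and `holdout` (data.table of
#'   `sample_id`, `age`, `prediction` for the held-out fold).
#' @export
train_one_clock <- function(restricted_training, config, fold_assignment,
                            fold_id, seed = config$rng_seed) {
  ft <- restricted_training
  stopifnot(inherits(ft, "FeatureTable"),
            length(fold_assignment) == nrow(ft$values))
  in_train <- fold_assignment != fold_id
  x <- ft$values[in_train, , drop = FALSE]
  y <- ft$ages[in_train]
  if (nrow(x) < config$inner_splits + 1)
    stop(sprintf("too few samples: %d in training portion, need >= %d",
                 nrow(x), config$inner_splits + 1))
  if (ncol(x) < 2)
    stop("too few sites: elastic-net fitting needs at least 2 CpG sites")
  if (sd(y) == 0)
    stop("degenerate target: all training ages identical")
  set.seed(seed)
  inner_foldid <- sample(rep_len(seq_len(config$inner_splits), nrow(x)))
  cvfit <- glmnet::cv.glmnet(x, y, alpha = config$alpha, foldid = inner_foldid,
                             family = "gaussian", type.measure = "mse",
                             standardize = TRUE)
  beta <- as.matrix(coef(cvfit, s = "lambda.min"))[, 1]
  model <- structure(list(intercept = unname(beta[1]),
                          weights = beta[-1],
                          lambda = cvfit$lambda.min,
                          alpha = config$alpha,
                          fold_id = as.integer(fold_id),
                          sites = ft$sites),
                     class = "ClockModel")
  holdout <- data.table(
    sample_id = ft$sample_ids[!in_train],
    age = ft$ages[!in_train],
    prediction = as.numeric(
      predict(cvfit, newx = ft$values[!in_train, , drop = FALSE],
              s = "lambda.min")))
  list(model = model, holdout = holdout)
}

#' Predict age with one clock
#'
#' @param model A `ClockModel` from [train_one_clock()].
#' @param x Named numeric vector of methylation percentages; names are
#'   `"chrom:pos"` site keys and must cover every clock site.
#' @return Predicted age in years.
#' @export
predict_clock <- function(model, x) {
  keys <- names(model$weights)
  if (!all(keys %in% names(x)))
    stop("contract violation: test sample is missing clock sites")
  model$intercept + sum(model$weights * x[keys])
}

# trains the outer-fold ensemble on a (canonically ordered) restricted table;
# returns models plus pooled out-of-fold CV performance
train_ensemble <- function(restricted, config, seed) {
  folds <- assign_folds(restricted$sample_ids, config$outer_folds, seed)
  fits <- lapply(seq_len(config$outer_folds), function(k)
    train_one_clock(restricted, config, folds, k, seed = derive_seed(seed, k)))
  holdout <- data.table::rbindlist(lapply(fits, `[[`, "holdout"))
  list(models = lapply(fits, `[[`, "model"),
       folds = folds,
       cv_r = cor(holdout$prediction, holdout$age),
       cv_medae = median(abs(holdout$prediction - holdout$age)),
       holdout = holdout)
}

empty_prediction <- function(sample_id, n_sites, config) {
  structure(list(test_sample_id = sample_id,
                 n_intersected_sites = n_sites, admitted = FALSE,
                 fold_predictions = rep(NA_real_, config$outer_folds),
                 predicted_age = NA_real_, cv_r = NA_real_,
                 cv_medae = NA_real_),
            class = "PredictionResult")
}

#' Predict the epigenetic age of one test sample
#'
#' Runs the full intersection-clock workflow for a single sample: site
#' intersection, admission check (`min_intersection`), restriction of the
#' training table, outer fivefold cross-validation yielding
#' `config$outer_folds` clocks, and the ensemble-mean prediction. Pooled
#' out-of-fold predictions on the restricted training set give the CV
#' performance (`cv_r`, `cv_medae`).
#'
#' @param training A `FeatureTable`.
#' @param test A coverage-filtered [methylation_callset()].
#' @param config A [clock_config()].
#' @param keep_models Attach the fitted `ClockModel`s to the result?
#' @return A `PredictionResult`: list with `test_sample_id`,
#'   `n_intersected_sites`, `admitted`, `fold_predictions`, `predicted_age`
#'   (mean of fold predictions), `cv_r`, `cv_medae`.
#' @export
predict_sample <- function(training, test, config = clock_config(),
                           keep_models = FALSE) {
  isect <- intersect_sites(training, test)
  if (isect$n_sites < config$min_intersection)
    return(empty_prediction(test$sample_id, isect$n_sites, config))
  restricted <- restrict(training, isect$sites)
  # canonical row order: fits depend only on sample identity, not input order
  ord <- order(restricted$sample_ids)
  restricted$sample_ids <- restricted$sample_ids[ord]
  restricted$ages <- restricted$ages[ord]
  if (!is.null(restricted$groups)) restricted$groups <- restricted$groups[ord]
  restricted$values <- restricted$values[ord, , drop = FALSE]

  seed <- if (config$share_partition) derive_seed(config$rng_seed, "shared")
          else derive_seed(config$rng_seed, test$sample_id)
  ens <- train_ensemble(restricted, config, seed)
  finish_prediction(test, isect, ens, config, keep_models)
}

finish_prediction <- function(test, isect, ens, config, keep_models) {
  keys <- site_key(isect$sites$chrom, isect$sites$pos)
  calls <- test$calls
  idx <- match(keys, site_key(calls$chrom, calls$pos))
  x <- setNames(methylation_percent(calls$meth[idx], calls$unmeth[idx]), keys)
  fold_preds <- vapply(ens$models, predict_clock, numeric(1), x = x)
  structure(list(test_sample_id = test$sample_id,
                 n_intersected_sites = isect$n_sites, admitted = TRUE,
                 fold_predictions = fold_preds,
                 predicted_age = mean(fold_preds),
                 cv_r = ens$cv_r, cv_medae = ens$cv_medae,
                 models = if (keep_models) ens$models else NULL),
            class = "PredictionResult")
}

#' @method print PredictionResult
#' @export
print.PredictionResult <- function(x, ...) {
  if (x$admitted)
    cat(sprintf("PredictionResult '%s': %d intersected sites, predicted age %.2f years (cv r = %.3f, MedAE = %.2f)\n",
                x$test_sample_id, x$n_intersected_sites, x$predicted_age,
                x$cv_r, x$cv_medae))
  else
    cat(sprintf("PredictionResult '%s': NOT admitted (%d intersected sites < threshold)\n",
                x$test_sample_id, x$n_intersected_sites))
  invisible(x)
}

#' Predict a cohort of test samples
#'
#' Applies [predict_sample()] independently to each test sample (each gets
#' its own site intersection and its own clock ensemble). With
#' `share_partition = TRUE` in the config, ensembles are reused across test
#' samples whose intersected site sets are identical, since the fit is then
#' provably the same.
#'
#' @param training A `FeatureTable`.
#' @param tests List of [methylation_callset()] objects.
#' @param config A [clock_config()].
#' @param verbose Log one line per sample (intersected sites, admission)?
#' @return List of `PredictionResult`, in input order.
#' @export
predict_cohort <- function(training, tests, config = clock_config(),
                           verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  results <- lapply(tests, function(test) {
    res <- tryCatch({
      if (config$share_partition) {
        isect <- intersect_sites(training, test)
        if (isect$n_sites < config$min_intersection)
          empty_prediction(test$sample_id, isect$n_sites, config)
        else {
          keys <- site_key(isect$sites$chrom, isect$sites$pos)
          cache_key <- paste0("s", hash_string(paste(keys, collapse = ",")),
                              "_", isect$n_sites)
          if (is.null(cache[[cache_key]])) {
            restricted <- restrict(training, isect$sites)
            ord <- order(restricted$sample_ids)
            restricted$sample_ids <- restricted$sample_ids[ord]
            restricted$ages <- restricted$ages[ord]
            restricted$values <- restricted$values[ord, , drop = FALSE]
            cache[[cache_key]] <- train_ensemble(
              restricted, config, derive_seed(config$rng_seed, "shared"))
          }
          finish_prediction(test, isect, cache[[cache_key]], config, FALSE)
        }
      } else {
        predict_sample(training, test, config)
      }
    }, error = function(e)
      stop(sprintf("sample '%s': %s", test$sample_id, conditionMessage(e)),
           call. = FALSE))
    if (verbose)
      message(sprintf("%s: %d intersected sites, admitted = %s",
                      res$test_sample_id, res$n_intersected_sites,
                      res$admitted))
    res
  })
  results
}

#' Write prediction results as TSV
#'
#' One row per test sample: `sample_id`, `group`, `n_intersected_sites`,
#' `admitted`, `fold_pred_1..k`, `predicted_age`, `cv_r`, `cv_medae`.
#'
#' @param results List of `PredictionResult` (from [predict_cohort()]).
#' @param path Output path.
#' @param groups Optional named character vector mapping sample id to group.
#' @return The results as a data.table, invisibly; written to `path` if given.
#' @export
write_predictions <- function(results, path = NULL, groups = NULL) {
  k <- length(results[[1]]$fold_predictions)
  rows <- lapply(results, function(r) {
    fp <- as.list(setNames(r$fold_predictions, paste0("fold_pred_", seq_len(k))))
    c(list(sample_id = r$test_sample_id,
           group = if (is.null(groups)) NA_character_
                   else unname(groups[r$test_sample_id]),
           n_intersected_sites = r$n_intersected_sites,
           admitted = r$admitted),
      fp,
      list(predicted_age = r$predicted_age, cv_r = r$cv_r,
           cv_medae = r$cv_medae))
  })
  dt <- data.table::rbindlist(rows)
  if (!is.null(path)) fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(dt)
}
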