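# Group-level epigenetic-age comparisons used to call rejuvenation events
# (a drop in mean predicted age between developmental stages or cell states).

#' Significance star coding
#'
#' Maps a p-value to the conventional star bands: `ns` for p > 0.05, `*` for
#' 0.01 < p <= 0.05, `**` for 0.001 < p <= 0.01, `***` for 1e-4 < p <= 1e-3,
#' `****` for p <= 1e-4. Upper band edges are inclusive.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector of star labels.
#' @export
star_code <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("domain error: p must be in [0, 1]")
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = TRUE) |> as.character()
}

#' Compare predicted ages between two groups
#'
#' Two-sided t-test on the predicted epigenetic ages of two groups of
#' admitted test samples: Student's two-sample test by default, a paired test
#' on per-pair differences when `paired = TRUE` (pairs are matched by
#' `pairing_key`, e.g. a donor id shared by a fibroblast line and its derived
#' iPSC line). Non-admitted samples never contribute.
#'
#' @param results List of `PredictionResult` ([predict_cohort()]).
#' @param labels Named character vector: sample id -> group label.
#' @param a,b The two group labels to compare (difference reported as a - b).
#' @param paired Use a paired t-test?
#' @param pairing_key Named vector sample id -> pair key; required when
#'   `paired = TRUE`.
#' @param var_equal Assume equal variances for the unpaired test (default
#'   `TRUE`, Student's test; `FALSE` gives Welch).
#' @return A `GroupComparison`: list with `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `statistic`, `p_value`, `paired`, `stars`.
#' @export
compare_groups <- function(results, labels, a, b, paired = FALSE,
                           pairing_key = NULL, var_equal = TRUE) {
  admitted <- Filter(function(r) isTRUE(r$admitted), results)
  ids <- vapply(admitted, `[[`, "", "test_sample_id")
  ages <- vapply(admitted, `[[`, numeric(1), "predicted_age")
  grp <- unname(labels[ids])
  xa <- ages[!is.na(grp) & grp == a]
  xb <- ages[!is.na(grp) & grp == b]
  names(xa) <- ids[!is.na(grp) & grp == a]
  names(xb) <- ids[!is.na(grp) & grp == b]
  if (length(xa) < 2 || length(xb) < 2)
    stop(sprintf("insufficient data: need >= 2 admitted samples per group (got %d in '%s', %d in '%s')",
                 length(xa), a, length(xb), b))
  if (paired) {
    if (is.null(pairing_key)) stop("pairing error: pairing_key required for paired test")
    ka <- unname(pairing_key[names(xa)])
    kb <- unname(pairing_key[names(xb)])
    if (anyNA(ka) || anyNA(kb) || anyDuplicated(ka) || anyDuplicated(kb))
      stop("pairing error: every sample needs a unique pair key")
    common <- intersect(ka, kb)
    if (length(common) < length(ka) || length(common) < length(kb))
      stop("pairing error: missing pair member")
    xb <- xb[match(ka, kb)]
    tt <- t.test(xa, xb, paired = TRUE)
  } else {
    tt <- t.test(xa, xb, var.equal = var_equal)
  }
  structure(list(group_a = a, group_b = b,
                 n_a = length(xa), n_b = length(xb),
                 mean_a = mean(xa), mean_b = mean(xb),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 paired = paired,
                 stars = star_code(tt$p.value)),
            class = "GroupComparison")
}

#' @method print GroupComparison
#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean %.2f y) vs %s (n=%d, mean %.2f y): %s t = %.3f, p = %.4g %s\n",
              x$group_a, x$n_a, x$mean_a, x$group_b, x$n_b, x$mean_b,
              if (x$paired) "paired" else "unpaired",
              x$statistic, x$p_value, x$stars))
  invisible(x)
}

#' Prediction performance metrics
#'
#' Pearson correlation and median absolute error between predicted and
#' chronological ages — the two numbers used to summarize clock performance.
#'
#' @param predicted,true Equal-length numeric vectors of ages in years.
#' @return Named list `pearson_r`, `medae_years`.
#' @export
performance_metrics <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("length mismatch")
  if (length(predicted) < 2) stop("need >= 2 observations")
  if (sd(predicted) == 0 || sd(true) == 0)
    stop("undefined value: Pearson r requires variance in both vectors")
  list(pearson_r = cor(predicted, true),
       medae_years = median(abs(predicted - true)))
}
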