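#' @importFrom data.table data.table fread fwrite setorder setnames as.data.table :=
#' @importFrom stats median rbinom rnbinom runif rnorm sd setNames t.test cor coef predict
#' @importFrom utils head
NULL

# site keys are "chrom:pos"; all internal coordinates are 1-based positions of
# the plus-strand C of the CpG dinucleotide
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Construct a methylation call set
#'
#' A `MethylationCallSet` holds one sample's strand-collapsed CpG-level
#' methylation calls: for every covered CpG site the number of methylated and
#' unmethylated reads summed over both strands, keyed by the 1-based position
#' of the plus-strand cytosine.
#'
#' @param sample_id Sample identifier string.
#' @param calls A data.frame/data.table with columns `chrom` (character),
#'   `pos` (integer, 1-based), `meth` and `unmeth` (non-negative read counts).
#' @param assembly Genome assembly label (e.g. `"GRCh38"`).
#' @return An object of class `MethylationCallSet`.
#' @export
methylation_callset <- function(sample_id, calls, assembly = "GRCh38") {
  calls <- as.data.table(calls)
  required <- c("chrom", "pos", "meth", "unmeth")
  if (!all(required %in% names(calls)))
    stop("calls must have columns chrom, pos, meth, unmeth")
  calls <- calls[, required, with = FALSE]
  calls[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
               meth = as.integer(meth), unmeth = as.integer(unmeth))]
  if (nrow(calls) > 0) {
    if (any(calls$pos < 1)) stop("coordinate error: positions must be >= 1")
    if (any(calls$meth < 0) || any(calls$unmeth < 0))
      stop("read counts must be non-negative")
    if (anyDuplicated(calls, by = c("chrom", "pos")))
      stop("duplicate coordinates in call set")
  }
  setorder(calls, chrom, pos)
  structure(list(sample_id = sample_id, calls = calls, assembly = assembly),
            class = "MethylationCallSet")
}

#' @method print MethylationCallSet
#' @export
print.MethylationCallSet <- function(x, ...) {
  cat(sprintf("MethylationCallSet '%s' (%s): %d CpG sites\n",
              x$sample_id, x$assembly, nrow(x$calls)))
  invisible(x)
}

#' Number of sites in a call set
#' @param x A `MethylationCallSet`.
#' @return Integer site count.
#' @export
n_sites <- function(x) nrow(x$calls)

# collapse per-strand records onto plus-strand CpG coordinates and sum counts.
# A minus-strand C at position p belongs to the CpG whose plus-strand C is at
# p - 1; unpaired minus records are re-keyed the same way.
collapse_strands <- function(dt) {
  bad <- setdiff(unique(dt$strand), c("+", "-"))
  if (length(bad) > 0)
    stop(sprintf("parse error: unknown strand symbol '%s'", bad[[1]]))
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stop("parse error: duplicate record for the same (chrom, pos, strand)")
  minus <- dt$strand == "-"
  dt$pos[minus] <- dt$pos[minus] - 1L
  if (any(dt$pos < 1L))
    stop("coordinate error: minus-strand record at position 1 has no plus-strand partner position")
  dt[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, pos)]
}

#' Read a Bismark-style CpG report
#'
#' Parses a tab-separated CpG report (columns: chromosome, 1-based position,
#' strand, methylated count, unmethylated count; any further columns such as
#' context are ignored), sums the read counts of the two strands of each CpG
#' dinucleotide onto the plus-strand coordinate, and drops sites whose summed
#' coverage is below `min_coverage`.
#'
#' @param path Path to the report file.
#' @param min_coverage Minimum summed read coverage for a site to be kept
#'   (default 5, applied after strand collapse).
#' @param sample_id Sample id; defaults to the file name without extension.
#' @param assembly Assembly label attached to the call set.
#' @param normalize_chrom If `TRUE`, strip a leading `"chr"` prefix from
#'   chromosome names. Off by default so that naming mismatches between
#'   datasets fail loudly at intersection time rather than silently.
#' @return A [methylation_callset()].
#' @export
read_cpg_report <- function(path, min_coverage = 5L,
                            sample_id = sub("\\.[^.]*$", "", basename(path)),
                            assembly = "GRCh38", normalize_chrom = FALSE) {
  stopifnot(min_coverage >= 0)
  empty_calls <- data.table(chrom = character(), pos = integer(),
                            meth = integer(), unmeth = integer())
  if (file.size(path) == 0)
    return(methylation_callset(sample_id, empty_calls, assembly))
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE,
          colClasses = list(character = 1)),
    error = function(e) stop(sprintf("parse error reading '%s': %s",
                                     path, conditionMessage(e))))
  if (nrow(dt) == 0)
    return(methylation_callset(sample_id, empty_calls, assembly))
  if (ncol(dt) < 5)
    stop(sprintf("parse error: '%s' has %d columns, expected >= 5", path, ncol(dt)))
  dt <- dt[, 1:5]
  setnames(dt, c("chrom", "pos", "strand", "meth", "unmeth"))
  bad_num <- which(is.na(suppressWarnings(as.integer(dt$pos))) |
                   is.na(suppressWarnings(as.integer(dt$meth))) |
                   is.na(suppressWarnings(as.integer(dt$unmeth))))
  if (length(bad_num) > 0)
    stop(sprintf("parse error at line %d of '%s': non-numeric field",
                 bad_num[[1]], path))
  dt[, `:=`(pos = as.integer(pos), meth = as.integer(meth),
            unmeth = as.integer(unmeth))]
  if (normalize_chrom) dt[, chrom := sub("^chr", "", chrom)]
  collapsed <- collapse_strands(dt)
  collapsed <- collapsed[meth + unmeth >= min_coverage]
  methylation_callset(sample_id, collapsed, assembly)
}

#' Declare the layout of a processed methylation table
#'
#' Processed tables deposited in public repositories come in many shapes; a
#' dialect names the column roles and the position basis so the reader can
#' normalize them to the internal 1-based, strand-collapsed, count-based
#' convention.
#'
#' @param chrom,pos Column indices (1-based) of chromosome and position.
#' @param basis Position basis of the file: 1 (default) or 0. 0-based
#'   positions are shifted by +1 on read.
#' @param level Column index of the methylation level, interpreted per
#'   `level_type`; ignored when `meth`/`unmeth` count columns are given.
#' @param level_type `"fraction"` (level in \[0,1\]) or `"percent"`
#'   (level in \[0,100\]).
#' @param coverage Column index of total read coverage (required with `level`).
#' @param meth,unmeth Column indices of methylated/unmethylated read counts,
#'   for dialects that store counts directly (preferred when available).
#' @param header Does the file have a header line?
#' @return A `table_dialect` object for [read_processed_table()].
#' @export
table_dialect <- function(chrom = 1L, pos = 2L, basis = 1L,
                          level = NULL, level_type = c("fraction", "percent"),
                          coverage = NULL, meth = NULL, unmeth = NULL,
                          header = FALSE) {
  level_type <- match.arg(level_type)
  if (!basis %in% c(0L, 1L)) stop("configuration error: basis must be 0 or 1")
  has_counts <- !is.null(meth) && !is.null(unmeth)
  if (!has_counts && (is.null(level) || is.null(coverage)))
    stop("configuration error: dialect needs either meth+unmeth columns or level+coverage columns")
  structure(list(chrom = chrom, pos = pos, basis = as.integer(basis),
                 level = level, level_type = level_type, coverage = coverage,
                 meth = meth, unmeth = unmeth, header = header),
            class = "table_dialect")
}

round_half_up <- function(x) floor(x + 0.5)

#' Read a processed methylation table
#'
#' Reads a per-sample methylation table whose layout is described by a
#' [table_dialect()]. When the file stores a methylation fraction `f` and a
#' coverage `c` instead of counts, counts are reconstructed as
#' `meth = round(f * c)` (half-up) and `unmeth = c - meth`. Positions are
#' converted to the 1-based convention and the coverage filter is applied as
#' in [read_cpg_report()].
#'
#' @inheritParams read_cpg_report
#' @param dialect A [table_dialect()].
#' @return A [methylation_callset()].
#' @export
read_processed_table <- function(path, dialect, min_coverage = 5L,
                                 sample_id = sub("\\.[^.]*$", "", basename(path)),
                                 assembly = "GRCh38", normalize_chrom = FALSE) {
  stopifnot(inherits(dialect, "table_dialect"), min_coverage >= 0)
  dt <- fread(path, header = dialect$header, sep = "\t",
              colClasses = list(character = dialect$chrom))
  empty <- data.table(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer())
  if (nrow(dt) == 0) return(methylation_callset(sample_id, empty, assembly))
  need <- max(dialect$chrom, dialect$pos, dialect$level, dialect$coverage,
              dialect$meth, dialect$unmeth)
  if (ncol(dt) < need)
    stop(sprintf("configuration error: '%s' has %d columns but dialect references column %d",
                 path, ncol(dt), need))
  chrom <- as.character(dt[[dialect$chrom]])
  if (normalize_chrom) chrom <- sub("^chr", "", chrom)
  pos <- as.integer(dt[[dialect$pos]]) + (1L - dialect$basis)
  if (!is.null(dialect$meth)) {
    meth <- as.integer(dt[[dialect$meth]])
    unmeth <- as.integer(dt[[dialect$unmeth]])
  } else {
    lev <- as.numeric(dt[[dialect$level]])
    cov <- as.integer(dt[[dialect$coverage]])
    hi <- if (dialect$level_type == "fraction") 1 else 100
    if (any(is.na(lev)) || any(lev < 0) || any(lev > hi))
      stop(sprintf("parse error: methylation level outside [0, %d] in '%s'", hi, path))
    frac <- if (dialect$level_type == "fraction") lev else lev / 100
    meth <- as.integer(round_half_up(frac * cov))
    unmeth <- cov - meth
  }
  out <- data.table(chrom = chrom, pos = pos, meth = meth, unmeth = unmeth)
  out <- out[meth + unmeth >= min_coverage]
  methylation_callset(sample_id, out, assembly)
}

#' Methylation percentage of a site
#'
#' `100 * meth / (meth + unmeth)`; defined only for covered sites.
#'
#' @param meth,unmeth Read counts (vectors allowed).
#' @return Percentages in \[0, 100\].
#' @export
methylation_percent <- function(meth, unmeth) {
  cov <- meth + unmeth
  if (any(cov == 0))
    stop("undefined value: methylation percentage requires coverage > 0")
  100 * meth / cov
}

#' Assemble the training feature table
#'
#' Builds the samples x CpG-sites matrix of methylation percentages from
#' coverage-filtered call sets. Only sites present in every call set are
#' retained, so the matrix has no missing entries; columns are ordered by
#' chromosome then position, rows follow the input call-set order.
#'
#' @param callsets List of [methylation_callset()] objects (already
#'   coverage-filtered).
#' @param metadata A data.frame with columns `sample_id`, `age` (years) and
#'   optionally `group`; every call-set sample id must appear with a valid age.
#' @return A `FeatureTable`: list with `sample_ids`, `ages`, `groups`,
#'   `sites` (data.table of `chrom`, `pos`), `values` (numeric matrix of
#'   percentages, rows = samples, columns = sites, dimnames set) and
#'   `assembly`.
#' @export
build_feature_table <- function(callsets, metadata) {
  stopifnot(length(callsets) > 0)
  metadata <- as.data.table(metadata)
  if (!all(c("sample_id", "age") %in% names(metadata)))
    stop("metadata error: need columns sample_id, age")
  ids <- vapply(callsets, function(cs) cs$sample_id, character(1))
  missing_meta <- setdiff(ids, metadata$sample_id)
  if (length(missing_meta) > 0)
    stop(sprintf("metadata error: no age for sample(s) %s",
                 paste(missing_meta, collapse = ", ")))
  meta <- metadata[match(ids, metadata$sample_id)]
  if (any(is.na(meta$age)) || any(meta$age < 0))
    stop("metadata error: ages must be non-negative and non-missing")
  assemblies <- unique(vapply(callsets, function(cs) cs$assembly, character(1)))
  if (length(assemblies) > 1)
    stop(sprintf("configuration error: mixed assemblies: %s",
                 paste(assemblies, collapse = ", ")))

  keysets <- lapply(callsets, function(cs) site_key(cs$calls$chrom, cs$calls$pos))
  common <- Reduce(intersect, keysets)
  if (length(common) == 0)
    stop("empty-table error: no CpG site is covered in all samples")
  sites <- callsets[[1]]$calls[site_key(chrom, pos) %in% common, .(chrom, pos)]
  setorder(sites, chrom, pos)
  keys <- site_key(sites$chrom, sites$pos)

  values <- matrix(NA_real_, nrow = length(callsets), ncol = length(keys),
                   dimnames = list(ids, keys))
  for (i in seq_along(callsets)) {
    calls <- callsets[[i]]$calls
    idx <- match(keys, site_key(calls$chrom, calls$pos))
    values[i, ] <- methylation_percent(calls$meth[idx], calls$unmeth[idx])
  }
  structure(list(sample_ids = ids, ages = as.numeric(meta$age),
                 groups = if ("group" %in% names(meta)) as.character(meta$group) else NULL,
                 sites = sites, values = values, assembly = assemblies),
            class = "FeatureTable")
}

#' @method print FeatureTable
#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable (%s): %d samples x %d CpG sites, ages %.1f-%.1f years\n",
              x$assembly, nrow(x$values), ncol(x$values),
              min(x$ages), max(x$ages)))
  invisible(x)
}

#' Write / read a feature table as TSV
#'
#' The TSV has columns `sample_id`, `age`, `group`, then one column per site
#' named `"chrom:pos"`. The round trip is lossless up to numeric printing
#' (percentages are written in full precision).
#'
#' @param table A `FeatureTable`.
#' @param path Output path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `FeatureTable`.
#' @export
write_feature_table <- function(table, path) {
  out <- data.table(sample_id = table$sample_ids, age = table$ages,
                    group = if (is.null(table$groups)) NA_character_ else table$groups)
  out <- cbind(out, as.data.table(table$values))
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param assembly Assembly label to attach (not stored in the TSV body).
#' @export
read_feature_table <- function(path, assembly = "GRCh38") {
  dt <- fread(path, sep = "\t", header = TRUE)
  keys <- names(dt)[-(1:3)]
  parts <- strsplit(keys, ":", fixed = TRUE)
  sites <- data.table(chrom = vapply(parts, `[[`, "", 1),
                      pos = as.integer(vapply(parts, `[[`, "", 2)))
  values <- as.matrix(dt[, -(1:3), with = FALSE])
  rownames(values) <- dt$sample_id
  groups <- if (all(is.na(dt$group))) NULL else as.character(dt$group)
  structure(list(sample_ids = dt$sample_id, ages = as.numeric(dt$age),
                 groups = groups, sites = sites, values = values,
                 assembly = assembly),
            class = "FeatureTable")
}
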