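# Coordinate handling for test datasets: basis shifts (0-based public tables
# are shifted by +1 before any mapping) and a pluggable assembly map with
# identity and lookup-table implementations.

#' Shift the position basis of a call set
#'
#' Adds `offset` to every position, e.g. `+1` to convert 0-based public-table
#' coordinates to the internal 1-based convention before assembly mapping.
#'
#' @param callset A [methylation_callset()].
#' @param offset One of -1, 0, +1.
#' @return The shifted call set; counts unchanged.
#' @export
shift_basis <- function(callset, offset) {
  stopifnot(inherits(callset, "MethylationCallSet"))
  if (!offset %in% c(-1L, 0L, 1L)) stop("offset must be -1, 0 or +1")
  if (offset == 0L) return(callset)
  calls <- data.table::copy(callset$calls)
  calls[, pos := pos + as.integer(offset)]
  if (nrow(calls) > 0 && any(calls$pos < 1))
    stop("coordinate error: shift produces position < 1")
  methylation_callset(callset$sample_id, calls, callset$assembly)
}

#' Assembly position maps
#'
#' An `AssemblyMap` maps `(chrom, pos)` coordinates from a source to a target
#' assembly. Two implementations are provided: the identity map (for data
#' already on the training assembly) and a lookup-table map loaded from a TSV
#' with columns `source_chrom`, `source_pos`, `target_chrom`, `target_pos`.
#' Real chain-file lifting is delegated to external tools; their output can be
#' expressed as a lookup table.
#'
#' @param source,target Assembly labels.
#' @return An `AssemblyMap` object.
#' @export
identity_map <- function(source = "GRCh38", target = source) {
  structure(list(source = source, target = target,
                 lookup = NULL),
            class = "AssemblyMap")
}

#' @rdname identity_map
#' @param path TSV with columns source_chrom, source_pos, target_chrom,
#'   target_pos (header optional, detected by `fread`).
#' @export
lookup_map <- function(path, source, target) {
  dt <- fread(path, sep = "\t", header = "auto")
  if (ncol(dt) < 4)
    stop("configuration error: lookup map needs 4 columns (source_chrom, source_pos, target_chrom, target_pos)")
  setnames(dt, 1:4, c("source_chrom", "source_pos", "target_chrom", "target_pos"))
  dt[, `:=`(source_chrom = as.character(source_chrom),
            source_pos = as.integer(source_pos),
            target_chrom = as.character(target_chrom),
            target_pos = as.integer(target_pos))]
  assembly_map_from_table(dt, source, target)
}

#' @rdname identity_map
#' @param table data.frame with columns source_chrom, source_pos,
#'   target_chrom, target_pos.
#' @export
assembly_map_from_table <- function(table, source, target) {
  dt <- as.data.table(table)
  if (anyDuplicated(dt, by = c("source_chrom", "source_pos")))
    stop("configuration error: duplicate source coordinate in map")
  structure(list(source = source, target = target, lookup = dt),
            class = "AssemblyMap")
}

utils::globalVariables(c("source_chrom", "source_pos", "target_chrom", "target_pos"))

#' Map a call set to another assembly
#'
#' Re-keys every site through an [identity_map()] / [lookup_map()]. Sites with
#' no target coordinate are dropped (default) or raise an error
#' (`on_unmapped = "strict"`); a report of mapped/dropped counts is attached.
#'
#' @param callset A [methylation_callset()]; its `assembly` must equal the
#'   map's `source`.
#' @param map An `AssemblyMap`.
#' @param on_unmapped `"drop"` (default) or `"strict"`.
#' @return The mapped call set, with attribute `"lift_report"`: a list with
#'   `n_input`, `n_mapped`, `n_dropped`.
#' @export
lift_callset <- function(callset, map, on_unmapped = c("drop", "strict")) {
  stopifnot(inherits(callset, "MethylationCallSet"), inherits(map, "AssemblyMap"))
  on_unmapped <- match.arg(on_unmapped)
  if (!identical(callset$assembly, map$source))
    stop(sprintf("configuration error: call set assembly '%s' != map source '%s'",
                 callset$assembly, map$source))
  calls <- callset$calls
  n_in <- nrow(calls)
  if (is.null(map$lookup)) {
    out <- methylation_callset(callset$sample_id, calls, map$target)
    attr(out, "lift_report") <- list(n_input = n_in, n_mapped = n_in, n_dropped = 0L)
    return(out)
  }
  idx <- map$lookup[calls, on = c(source_chrom = "chrom", source_pos = "pos")]
  mapped <- !is.na(idx$target_pos)
  if (on_unmapped == "strict" && any(!mapped))
    stop(sprintf("unmapped coordinate(s): %d site(s) have no target position",
                 sum(!mapped)))
  new_calls <- data.table(chrom = idx$target_chrom[mapped],
                          pos = idx$target_pos[mapped],
                          meth = calls$meth[mapped],
                          unmeth = calls$unmeth[mapped])
  if (anyDuplicated(new_calls, by = c("chrom", "pos")))
    stop("collision error: two source sites map to one target coordinate")
  out <- methylation_callset(callset$sample_id, new_calls, map$target)
  attr(out, "lift_report") <- list(n_input = n_in, n_mapped = sum(mapped),
                                   n_dropped = sum(!mapped))
  out
}
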