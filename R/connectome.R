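#' Read a synapse table
#'
#' Loads a neuPrint-export-style CSV, one row per synaptic contact, and
#' validates the schema. Unknown columns are preserved. Tracing-status
#' columns default to `TRUE` when absent.
#'
#' @param path CSV file path.
#' @return A data frame of class `synapse_table`.
#' @export
load_synapse_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_synapse_table(df)
}

#' Coerce and validate a synapse table
#'
#' @param df Data frame with at least `pre_id`, `pre_type`, `post_id`,
#'   `post_type`, `roi`, `x`, `y`, `z`.
#' @return A validated `synapse_table`.
#' @export
as_synapse_table <- function(df) {
  req <- c("pre_id", "pre_type", "post_id", "post_type", "roi", "x", "y", "z")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("synapse table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) && any(!nzchar(df$pre_id) | !nzchar(df$post_id))) {
    stop("synapse table has empty body ids")
  }
  if (!"pre_traced" %in% names(df)) df$pre_traced <- TRUE
  if (!"post_traced" %in% names(df)) df$post_traced <- TRUE
  class(df) <- c("synapse_table", "data.frame")
  df
}

#' Write a synapse table to CSV
#'
#' @param table A `synapse_table`.
#' @param path Output CSV path.
#' @export
write_synapse_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Filter synapses by tracing status, ROI and hemisphere
#'
#' Applies the inclusion filters used for connectome quantification: keep a
#' contact only if both endpoints are fully traced (avoids sampling bias
#' from partial reconstructions), only if it falls in one of the requested
#' compartment ROIs (e.g. a dendritic whitelist), and only on the requested
#' hemisphere when a `side` column is present (the source volume covers
#' predominantly one hemisphere). A `side` filter on a table without a
#' `side` column is a no-op with a warning.
#'
#' @param table A `synapse_table`.
#' @param require_traced Keep only contacts with both endpoints traced.
#' @param rois Character vector of ROI labels to keep, or `NULL` for all.
#'   An empty vector keeps nothing.
#' @param side Hemisphere label to keep, or `NULL`.
#' @return Filtered `synapse_table` (possibly empty).
#' @export
filter_synapses <- function(table, require_traced = FALSE, rois = NULL,
                            side = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (require_traced) keep <- keep & table$pre_traced & table$post_traced
  if (!is.null(rois)) keep <- keep & table$roi %in% rois
  if (!is.null(side)) {
    if ("side" %in% names(table)) {
      keep <- keep & table$side == side
    } else {
      warning("no 'side' column; hemisphere filter skipped")
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synapse_table", "data.frame")
  out
}

#' Pairwise synapse counts between two cell types
#'
#' Groups contacts by (presynaptic cell, postsynaptic cell) for the
#' requested type pair and reports per-pair counts, the type-pair mean and
#' the total. When cell rosters are supplied, candidate pairs with zero
#' contacts are included in the pair list and the mean (the denominator is
#' then every roster pair, matching "mean synapse count per candidate
#' pair"); without rosters only observed pairs enter the mean.
#'
#' @param table A `synapse_table` (already filtered as desired).
#' @param pre_type,post_type Type labels to restrict to.
#' @param pre_roster,post_roster Optional character vectors of all member
#'   cell ids of each type; required if `include_zero_pairs = TRUE`.
#' @param include_zero_pairs Count zero-contact candidate pairs in the mean.
#' @return A list with `pairs` (data frame `pre_id`, `post_id`, `count`),
#'   `n_pairs`, `mean_count`, `total`.
#' @export
pair_counts <- function(table, pre_type, post_type,
                        pre_roster = NULL, post_roster = NULL,
                        include_zero_pairs = !is.null(pre_roster)) {
  if (include_zero_pairs && (is.null(pre_roster) || is.null(post_roster))) {
    stop("zero-pair inclusion requires both cell rosters")
  }
  sub <- table[table$pre_type == pre_type & table$post_type == post_type, ,
               drop = FALSE]
  if (nrow(sub)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(sub))),
                            by = list(pre_id = sub$pre_id, post_id = sub$post_id),
                            FUN = sum)
  } else {
    agg <- data.frame(pre_id = character(), post_id = character(),
                      count = integer(), stringsAsFactors = FALSE)
  }
  if (include_zero_pairs) {
    grid <- expand.grid(pre_id = pre_roster, post_id = post_roster,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    agg <- merge(grid, agg, by = c("pre_id", "post_id"), all.x = TRUE)
    agg$count[is.na(agg$count)] <- 0L
  }
  agg <- agg[order(agg$pre_id, agg$post_id), , drop = FALSE]
  rownames(agg) <- NULL
  list(pairs = agg, n_pairs = nrow(agg),
       mean_count = if (nrow(agg)) mean(agg$count) else 0,
       total = sum(agg$count))
}

#' Type-by-type connectivity matrix of synapse totals
#'
#' `matrix[i, j]` is the total number of contacts from cells of
#' `pre_types[i]` onto cells of `post_types[j]` in the (pre-filtered) table;
#' row and column order follow the arguments.
#'
#' @param table A `synapse_table`.
#' @param pre_types,post_types Character vectors of type labels.
#' @return Integer matrix with dimnames `pre_types` x `post_types`.
#' @export
connectivity_matrix <- function(table, pre_types, post_types) {
  M <- matrix(0L, length(pre_types), length(post_types),
              dimnames = list(pre_types, post_types))
  sub <- table[table$pre_type %in% pre_types & table$post_type %in% post_types, ,
               drop = FALSE]
  if (nrow(sub)) {
    tab <- base::table(factor(sub$pre_type, levels = pre_types),
                       factor(sub$post_type, levels = post_types))
    M[] <- as.integer(tab)
  }
  M
}
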