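# Downstream pulsed-SILAC analysis: proteinGroups-style record filtering,
# log2 ratio normalisation, cross-timepoint co-regulation and a Table-1-style
# pathway over-representation report.

#' Filter SILAC protein records
#'
#' Sequentially removes records flagged reverse (decoy), contaminant, or
#' identified only by modified peptides, then records with no valid H/M
#' ratio at either timepoint. Removal counts per rule (in that order) are
#' reported.
#'
#' @param records data.frame with columns `protein_id`, `ratio_hm_t24`,
#'   `ratio_hm_t48`, `reverse`, `contaminant`, `only_modified`.
#' @return list with `records` (survivors) and `removed` (named integer
#'   vector: `decoy`, `contaminant`, `modified_only`, `no_valid_value`).
#' @export
filter_records <- function(records) {
  req <- c("protein_id", "ratio_hm_t24", "ratio_hm_t48",
           "reverse", "contaminant", "only_modified")
  stopifnot(all(req %in% names(records)))
  n0 <- nrow(records)
  r <- records[!records$reverse, , drop = FALSE]
  n1 <- nrow(r)
  r <- r[!r$contaminant, , drop = FALSE]
  n2 <- nrow(r)
  r <- r[!r$only_modified, , drop = FALSE]
  n3 <- nrow(r)
  valid <- !(is.na(r$ratio_hm_t24) & is.na(r$ratio_hm_t48))
  r <- r[valid, , drop = FALSE]
  n4 <- nrow(r)
  rownames(r) <- NULL
  list(records = r,
       removed = c(decoy = n0 - n1, contaminant = n1 - n2,
                   modified_only = n2 - n3, no_valid_value = n3 - n4))
}

#' Convert H/M ratios to centred log2 values
#'
#' Per timepoint, ratios are log2-transformed and centred on the timepoint
#' median (default) or mean, so the bulk of the proteome sits at 0 and only
#' relative synthesis changes remain.
#'
#' @param records filtered records ([filter_records()] output `$records`).
#' @param method `"median-center"` (default) or `"mean-center"`.
#' @return data.frame `protein_id`, `log2_t24`, `log2_t48` (NA preserved).
#' @export
log2_normalize <- function(records, method = c("median-center", "mean-center")) {
  method <- match.arg(method)
  for (col in c("ratio_hm_t24", "ratio_hm_t48")) {
    bad <- !is.na(records[[col]]) & records[[col]] <= 0
    if (any(bad))
      stop("non-positive ratio for protein(s): ",
           paste(head(records$protein_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  centre <- if (method == "median-center") {
    function(x) x - median(x, na.rm = TRUE)
  } else {
    function(x) x - mean(x, na.rm = TRUE)
  }
  data.frame(protein_id = records$protein_id,
             log2_t24 = centre(log2(records$ratio_hm_t24)),
             log2_t48 = centre(log2(records$ratio_hm_t48)),
             stringsAsFactors = FALSE)
}

#' Cross-timepoint co-regulation classification
#'
#' Proteins with both timepoints present are classified: co-down if the
#' normalised log2 ratio is below `-margin` at both timepoints, co-up
#' symmetrically, discordant if the two timepoints disagree in sign (both
#' beyond the margin), otherwise unclassified. Proteins missing a timepoint
#' are unclassified.
#'
#' @param result data.frame from [log2_normalize()].
#' @param margin non-negative dead zone around zero (default 0).
#' @return list of id vectors: `co_down`, `co_up`, `discordant`,
#'   `unclassified`.
#' @export
cross_coregulation <- function(result, margin = 0) {
  stop_if_not_scalar_number(margin, "margin", lower = 0)
  x <- result$log2_t24; y <- result$log2_t48
  both <- !is.na(x) & !is.na(y)
  dn <- both & x < -margin & y < -margin
  up <- both & x > margin & y > margin
  dis <- both & ((x > margin & y < -margin) | (x < -margin & y > margin))
  list(co_down = result$protein_id[dn],
       co_up = result$protein_id[up],
       discordant = result$protein_id[dis],
       unclassified = result$protein_id[!(dn | up | dis)])
}

#' Table-1-style pathway over-representation report
#'
#' Two-sided Fisher exact test per pathway on the 2x2 table (in `co_down`
#' vs not) x (in pathway vs not) over the given universe, BH correction
#' across pathways; the report retains pathways with `q <= q_max` and
#' enrichment factor strictly greater than `min_enrichment`, sorted by
#' enrichment factor descending.
#'
#' @param co_down character vector of co-downregulated protein ids
#'   (subset of `universe`).
#' @param universe character vector of all quantified proteins.
#' @param db named list of pathway sets.
#' @param q_max BH FDR cutoff (default 0.05).
#' @param min_enrichment enrichment-factor cutoff (default 2; strict `>`).
#' @return list with `report` (filtered + sorted data.frame) and `all`
#'   (every tested pathway).
#' @export
pathway_report <- function(co_down, universe, db, q_max = 0.05,
                           min_enrichment = 2) {
  universe <- unique(universe)
  co_down <- unique(co_down)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  bad <- setdiff(co_down, universe)
  if (length(bad) > 0)
    stop("co_down not contained in universe: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  N <- length(universe); n <- length(co_down)
  rows <- lapply(names(db), function(pw) {
    members <- intersect(unique(db[[pw]]), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, co_down))
    p <- fisher_exact_2x2(k, n - k, K - k, N - n - K + k)
    data.frame(set = pw, k = k, K = K, n = n, N = N,
               enrichment_factor = if (k == 0) 0 else enrichment_factor(k, K, n, N),
               p = p, stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows)) stop("no pathway overlaps the universe", call. = FALSE)
  all_rows$q <- bh_adjust(all_rows$p)
  rownames(all_rows) <- NULL
  rep_rows <- all_rows[all_rows$q <= q_max &
                         all_rows$enrichment_factor > min_enrichment, , drop = FALSE]
  rep_rows <- rep_rows[order(-rep_rows$enrichment_factor), , drop = FALSE]
  rownames(rep_rows) <- NULL
  list(report = rep_rows, all = all_rows)
}
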