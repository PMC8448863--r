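# Set-enrichment machinery shared by the phosphoproteomic (KSEA, ontology
# over-representation) and pulsed-SILAC (pathway report) stages.

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical BH step-up: for p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, clipped at 1, returned in
#' the input order. `NA` entries are ignored for the correction (as in
#' [stats::p.adjust()]) and returned as `NA`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv)
  qs <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
  q[ok][o] <- qs
  q
}

#' Upper-tail hypergeometric p-value
#'
#' Inclusive upper tail \eqn{P[X \ge k]} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}: `k` hits among `n` draws from a
#' universe of `N` containing `K` marked members. Computed by summing exact
#' log-binomial terms.
#'
#' @param k observed hits; `K` marked members in universe; `n` draws;
#'   `N` universe size.
#' @param K,n,N see `k`.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  k <- stop_if_not_count(k, "k"); K <- stop_if_not_count(K, "K")
  n <- stop_if_not_count(n, "n"); N <- stop_if_not_count(N, "N")
  if (K > N || n > N || k > min(K, n) || k < max(0L, n + K - N))
    stop("hypergeometric bounds violated: need max(0, n+K-N) <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  j <- k:min(K, n)
  p <- sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
  min(1, p)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability rule: the two-sided p is the sum of probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' that of the observed table (within relative tolerance 1e-7).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`a b / c d`).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  a <- stop_if_not_count(a, "a"); b <- stop_if_not_count(b, "b")
  c <- stop_if_not_count(c, "c"); d <- stop_if_not_count(d, "d")
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  N <- m1 + m2
  if (N == 0) return(1)
  lo <- max(0L, n1 - m2); hi <- min(m1, n1)
  x <- lo:hi
  logp <- lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(N, n1)
  pobs <- logp[x == a]
  min(1, sum(exp(logp[logp <= pobs + log1p(1e-7)])))
}

#' Fold over-representation of a set among hits
#'
#' `(k/n) / (K/N)`: the factor by which set members are over-represented among
#' the `n` hits relative to their share of the `N`-member universe.
#'
#' @inheritParams hypergeom_pvalue
#' @return non-negative ratio.
#' @export
enrichment_factor <- function(k, K, n, N) {
  k <- stop_if_not_count(k, "k"); K <- stop_if_not_count(K, "K")
  n <- stop_if_not_count(n, "n"); N <- stop_if_not_count(N, "N")
  if (n == 0 || K == 0 || N == 0) stop("enrichment factor undefined for n = 0, K = 0 or N = 0",
                                       call. = FALSE)
  (k / n) / (K / N)
}

#' Fold-change z-score for a member set
#'
#' \eqn{z = (\bar{x}_m - \bar{x}) \sqrt{m} / s}, where \eqn{\bar{x}_m} is the
#' mean fold change of the `m` set members and \eqn{\bar{x}}, \eqn{s} are the
#' mean and standard deviation over all fold changes. Under random membership
#' z is approximately standard normal.
#'
#' @param fold_changes_all numeric vector of all (log2) fold changes.
#' @param member_fold_changes numeric vector for the set members.
#' @return z-score.
#' @export
ksea_zscore <- function(fold_changes_all, member_fold_changes) {
  if (length(member_fold_changes) == 0) stop("member set is empty", call. = FALSE)
  s <- sd(fold_changes_all)
  if (!is.finite(s) || s == 0) stop("global fold-change standard deviation is zero", call. = FALSE)
  m <- length(member_fold_changes)
  (mean(member_fold_changes) - mean(fold_changes_all)) * sqrt(m) / s
}

#' Classify a z-score against a symmetric threshold
#'
#' `overrepresented` if `z >= threshold`, `underrepresented` if
#' `z <= -threshold` (both inclusive), otherwise `neutral`.
#'
#' @param z finite z-score (vectorised).
#' @param threshold positive cutoff, default 1.5.
#' @return character vector of labels.
#' @export
classify_z <- function(z, threshold = 1.5) {
  stop_if_not_scalar_number(threshold, "threshold", lower = 0)
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  ifelse(z >= threshold, "overrepresented",
         ifelse(z <= -threshold, "underrepresented", "neutral"))
}

# Shared row builder: one enrichment test, with all bookkeeping columns.
enrichment_row <- function(set, direction, k, K, n, N) {
  ef <- if (k == 0) 0 else enrichment_factor(k, K, n, N)
  p <- if (n == 0 || K == 0) 1 else hypergeom_pvalue(k, K, n, N)
  data.frame(set = set, direction = direction, k = k, K = K, n = n, N = N,
             enrichment_factor = ef, p = p, stringsAsFactors = FALSE)
}

#' Kinase-substrate enrichment analysis (KSEA)
#'
#' Groups differentially phosphorylated peptides (raw `p < sig_p`) into
#' kinase substrate sets and tests each kinase for over-representation of its
#' substrates among the up- and down-regulated peptides separately
#' (upper-tail hypergeometric), with BH correction pooled across all
#' kinase-direction tests. The universe is, by default, the tested peptides
#' that map to at least one substrate set. Each kinase also receives a
#' fold-change z-score ([ksea_zscore()]) over all its measured substrates and
#' a `class` label from [classify_z()].
#'
#' @param diff data.frame with columns `peptide_id`, `log2fc`, `p`
#'   (as produced by [differential()]).
#' @param db named list of character vectors: kinase -> substrate peptide ids.
#' @param sig_p raw p-value cutoff defining regulated peptides (default 0.05).
#' @param universe `"annotated"` (default: tested peptides mapping to >= 1
#'   set) or `"all"` (all tested peptides).
#' @param z_threshold cutoff for [classify_z()].
#' @return data.frame with one row per kinase x direction: `set`, `direction`,
#'   `k`, `K`, `n`, `N`, `enrichment_factor`, `p`, `q`, `z`, `z_p`, `class`.
#' @export
ksea <- function(diff, db, sig_p = 0.05, universe = c("annotated", "all"),
                 z_threshold = 1.5) {
  universe <- match.arg(universe)
  if (length(db) == 0) stop("substrate set database is empty", call. = FALSE)
  stopifnot(all(c("peptide_id", "log2fc", "p") %in% names(diff)))
  db <- lapply(db, unique)
  tested <- diff[!is.na(diff$p) & !is.na(diff$log2fc), , drop = FALSE]
  annotated <- unique(unlist(db, use.names = FALSE))
  uni <- if (universe == "annotated")
    tested[tested$peptide_id %in% annotated, , drop = FALSE] else tested
  N <- nrow(uni)
  if (N == 0) stop("empty KSEA universe", call. = FALSE)
  up <- uni$peptide_id[uni$p < sig_p & uni$log2fc > 0]
  dn <- uni$peptide_id[uni$p < sig_p & uni$log2fc < 0]
  fc <- setNames(uni$log2fc, uni$peptide_id)
  rows <- lapply(names(db), function(kin) {
    members <- intersect(db[[kin]], uni$peptide_id)
    K <- length(members)
    r <- rbind(
      enrichment_row(kin, "up", length(intersect(members, up)), K, length(up), N),
      enrichment_row(kin, "down", length(intersect(members, dn)), K, length(dn), N))
    r$z <- if (K > 0) ksea_zscore(fc, fc[members]) else NA_real_
    r
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$z_p <- ifelse(is.na(out$z), NA_real_, 2 * pnorm(-abs(out$z)))
  out$class <- NA_character_
  has_z <- !is.na(out$z)
  out$class[has_z] <- classify_z(out$z[has_z], z_threshold)
  rownames(out) <- NULL
  out[, c("set", "direction", "k", "K", "n", "N",
          "enrichment_factor", "p", "q", "z", "z_p", "class")]
}

#' Ontology / term over-representation analysis
#'
#' Upper-tail hypergeometric test per term against a fixed universe, BH
#' correction across terms.
#'
#' @param hits character vector of significant identifiers (subset of
#'   `universe`).
#' @param universe character vector of all eligible identifiers.
#' @param db named list of character vectors: term -> member ids.
#' @return data.frame of enrichment rows (one per term with >= 1 member in
#'   the universe), BH-adjusted.
#' @export
ontology_enrichment <- function(hits, universe, db) {
  hits <- unique(hits); universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  bad <- setdiff(hits, universe)
  if (length(bad) > 0)
    stop("hits not contained in universe: ", paste(head(bad, 10), collapse = ", "),
         call. = FALSE)
  db <- lapply(db, unique)
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(db), function(term) {
    members <- intersect(db[[term]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    enrichment_row(term, "both", length(intersect(members, hits)), K, n, N)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the universe", call. = FALSE)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
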