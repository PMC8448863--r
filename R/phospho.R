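# XIC peak-height quantification of identified phosphopeptides and
# differential analysis between two conditions: extracted-ion chromatograms
# within a ppm m/z window around each identified peptide, peak height = the
# maximum point intensity, per-sample total normalisation, log2 fold changes
# with equal-variance t tests and BH correction.

#' XIC extraction parameters
#'
#' @param ppm_tol m/z tolerance in parts per million (default 10).
#' @param rt_half_window_s retention-time half window around the expected
#'   apex, seconds (default 30).
#' @param min_points minimum points in a trace for a valid peak height
#'   (default 10).
#' @param smooth apply a 3-point moving-average to the trace before taking
#'   the height (default FALSE).
#' @return validated list of class `xic_params`.
#' @export
xic_params <- function(ppm_tol = 10, rt_half_window_s = 30, min_points = 10,
                       smooth = FALSE) {
  stop_if_not_scalar_number(ppm_tol, "ppm_tol", lower = 1e-12)
  stop_if_not_scalar_number(rt_half_window_s, "rt_half_window_s", lower = 1e-12)
  stop_if_not_count(min_points, "min_points", lower = 1)
  structure(list(ppm_tol = ppm_tol, rt_half_window_s = rt_half_window_s,
                 min_points = as.integer(min_points), smooth = isTRUE(smooth)),
            class = "xic_params")
}

#' Extract an ion chromatogram for one peptide from one sample's ion map
#'
#' Returns all points with relative m/z deviation at most `ppm_tol` ppm from
#' the peptide's target m/z and retention time within `rt_half_window_s` of
#' the expected apex, ordered by retention time. An empty trace is a valid
#' result (missing measurement downstream).
#'
#' @param raw data.frame with columns `rt_s`, `mz`, `intensity` (one
#'   sample's points).
#' @param pep one-row data.frame (or list) with `mz` and `rt_apex_s`.
#' @param params an [xic_params()] object.
#' @return data.frame `rt_s`, `mz`, `intensity` ordered by `rt_s`.
#' @export
extract_xic <- function(raw, pep, params = xic_params()) {
  stopifnot(inherits(params, "xic_params"))
  target <- pep$mz; apex <- pep$rt_apex_s
  sel <- abs(raw$mz - target) / target <= params$ppm_tol * 1e-6 &
    abs(raw$rt_s - apex) <= params$rt_half_window_s
  tr <- raw[sel, c("rt_s", "mz", "intensity"), drop = FALSE]
  tr <- tr[order(tr$rt_s), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Peak height of a chromatographic trace
#'
#' Maximum point intensity over the trace if it holds at least `min_points`
#' points, otherwise `NA` (missing measurement). With `params$smooth` a
#' 3-point moving average is applied first.
#'
#' @param trace data.frame from [extract_xic()].
#' @param params an [xic_params()] object.
#' @return numeric height or `NA`.
#' @export
peak_height <- function(trace, params = xic_params()) {
  if (is.null(trace) || nrow(trace) < params$min_points) return(NA_real_)
  y <- trace$intensity
  if (params$smooth && length(y) >= 3) {
    y <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    y <- y[!is.na(y)]
  }
  max(y)
}

#' Quantify all peptides across all samples
#'
#' Runs [extract_xic()] + [peak_height()] for every peptide in every sample.
#'
#' @param raw data.frame with columns `sample`, `rt_s`, `mz`, `intensity`.
#' @param peptides data.frame with `peptide_id`, `mz`, `rt_apex_s`.
#' @param samples data.frame with `sample`, `condition` (or NULL: samples
#'   taken from `raw` with no condition labels).
#' @param params an [xic_params()] object.
#' @return numeric matrix peptides x samples of peak heights (NA = missing),
#'   with `condition` attribute when `samples` is given.
#' @export
quantify_peptides <- function(raw, peptides, samples = NULL,
                              params = xic_params()) {
  sample_ids <- if (!is.null(samples)) samples$sample else unique(raw$sample)
  m <- matrix(NA_real_, nrow(peptides), length(sample_ids),
              dimnames = list(peptides$peptide_id, sample_ids))
  for (s in sample_ids) {
    sub <- raw[raw$sample == s, , drop = FALSE]
    o <- order(sub$mz)
    sub <- sub[o, , drop = FALSE]
    mzv <- sub$mz
    for (i in seq_len(nrow(peptides))) {
      target <- peptides$mz[i]
      tol <- target * params$ppm_tol * 1e-6
      lo <- findInterval(target - tol, mzv) + 1L
      hi <- findInterval(target + tol, mzv)
      if (hi < lo) next
      blk <- sub[lo:hi, , drop = FALSE]
      blk <- blk[abs(blk$rt_s - peptides$rt_apex_s[i]) <= params$rt_half_window_s, ,
                 drop = FALSE]
      if (nrow(blk) >= params$min_points) {
        y <- blk$intensity
        if (params$smooth && length(y) >= 3) {
          y <- stats::filter(y, rep(1 / 3, 3), sides = 2)
          y <- y[!is.na(y)]
        }
        m[i, s] <- max(y)
      }
    }
  }
  if (!is.null(samples)) attr(m, "condition") <- samples$condition
  m
}

#' Normalise peak heights to per-sample totals
#'
#' Each sample's heights are divided by that sample's total (over present
#' values) and rescaled by the mean of the original totals, so per-sample
#' totals become equal while magnitudes stay interpretable.
#'
#' @param m peptides x samples matrix of heights (NA allowed).
#' @return matrix of the same shape; attributes preserved.
#' @export
normalize_heights <- function(m) {
  tot <- colSums(m, na.rm = TRUE)
  n_present <- colSums(!is.na(m))
  bad <- n_present == 0 | tot <= 0
  if (any(bad))
    stop("sample(s) with no positive heights: ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  out <- sweep(m, 2, tot, "/") * mean(tot)
  attributes(out)$condition <- attr(m, "condition")
  out
}

#' Differential analysis between two conditions
#'
#' Per-peptide mean log2 fold change (condition B vs A) and two-sided
#' equal-variance Student t test on log2 heights (Welch by flag), BH-adjusted
#' across all tested peptides. A peptide is tested only if it has at least
#' two present values in each condition; untested peptides are returned with
#' `NA` p/q. Missing values are never imputed.
#'
#' @param m peptides x samples height matrix.
#' @param condition character vector of condition labels per column (two
#'   levels; defaults to the matrix's `condition` attribute). The first level
#'   in sort order is the reference (A).
#' @param welch use Welch's t instead of equal-variance Student t.
#' @return data.frame `peptide_id`, `log2fc`, `t`, `p`, `q`, `n_a`, `n_b`.
#' @export
differential <- function(m, condition = attr(m, "condition"), welch = FALSE) {
  if (is.null(condition)) stop("condition labels required", call. = FALSE)
  lv <- sort(unique(condition))
  if (length(lv) != 2) stop("exactly two conditions required", call. = FALSE)
  ia <- which(condition == lv[1]); ib <- which(condition == lv[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 samples per condition", call. = FALSE)
  la <- log2(m[, ia, drop = FALSE]); lb <- log2(m[, ib, drop = FALSE])
  na_ <- rowSums(!is.na(la)); nb_ <- rowSums(!is.na(lb))
  ma <- rowMeans(la, na.rm = TRUE); mb <- rowMeans(lb, na.rm = TRUE)
  va <- apply(la, 1, stats::var, na.rm = TRUE)
  vb <- apply(lb, 1, stats::var, na.rm = TRUE)
  fc <- ifelse(na_ >= 1 & nb_ >= 1, mb - ma, NA_real_)
  testable <- na_ >= 2 & nb_ >= 2
  tstat <- p <- rep(NA_real_, nrow(m))
  if (welch) {
    se2 <- va / na_ + vb / nb_
    df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  } else {
    sp2 <- ((na_ - 1) * va + (nb_ - 1) * vb) / (na_ + nb_ - 2)
    se2 <- sp2 * (1 / na_ + 1 / nb_)
    df <- na_ + nb_ - 2
  }
  ok <- testable & is.finite(se2) & se2 > 0
  tstat[ok] <- (mb[ok] - ma[ok]) / sqrt(se2[ok])
  p[ok] <- 2 * pt(-abs(tstat[ok]), df[ok])
  degen <- testable & !ok                 # zero pooled variance
  p[degen] <- ifelse(abs(fc[degen]) < 1e-12, 1, 0)
  q <- bh_adjust(p)
  data.frame(peptide_id = rownames(m), log2fc = fc, t = tstat, p = p, q = q,
             n_a = na_, n_b = nb_, row.names = NULL, stringsAsFactors = FALSE)
}
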