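# Synthetic phosphopeptide LC-MS level-1 data: each identified peptide gets a
# Gaussian elution peak (~30 s base width, >= 10 points) at its theoretical
# m/z (with ppm jitter) in every sample; regulated peptides carry a planted
# log2 fold change between the two conditions. Kinase-substrate ground truth
# is planted so KSEA can be benchmarked against decoy kinases.

#' Parameters for the synthetic phosphoproteomics generator
#'
#' @param n_peptides number of identified peptides.
#' @param n_samples_per_condition replicates per condition (two conditions,
#'   `A` and `B`).
#' @param peak_width_s chromatographic peak base width, seconds (default 30).
#' @param points_per_peak minimum number of acquired points within the peak
#'   base width (default 10, must be >= 2).
#' @param mz_jitter_ppm uniform m/z jitter on each raw point, ppm.
#' @param fraction_regulated fraction of peptides with a planted fold change.
#' @param planted_log2fc log2 fold change (condition B vs A) for substrates
#'   of planted kinases; other regulated peptides get a random sign.
#' @param planted_kinases named integer vector: kinase name -> number of
#'   (regulated) substrate peptides. May be empty.
#' @param n_decoy_kinases number of decoy kinase sets drawn from unregulated
#'   peptides.
#' @param decoy_set_size substrates per decoy kinase.
#' @param noise_sd_log2 log2-scale amplitude noise per peptide x sample.
#' @param amplitude_log2_range range of per-peptide baseline log2 amplitudes.
#' @param rt_range_s retention-time range over which apexes are scattered.
#' @param seed RNG seed.
#' @return validated list of class `phospho_sim_params`.
#' @export
phospho_sim_params <- function(n_peptides = 1000, n_samples_per_condition = 3,
                               peak_width_s = 30, points_per_peak = 10,
                               mz_jitter_ppm = 2, fraction_regulated = 0.1,
                               planted_log2fc = 1,
                               planted_kinases = c(K1 = 30),
                               n_decoy_kinases = 0, decoy_set_size = 30,
                               noise_sd_log2 = 0.1,
                               amplitude_log2_range = c(18, 24),
                               rt_range_s = c(600, 3600), seed = 1) {
  stop_if_not_count(n_peptides, "n_peptides", lower = 1)
  stop_if_not_count(n_samples_per_condition, "n_samples_per_condition", lower = 1)
  stop_if_not_scalar_number(peak_width_s, "peak_width_s", lower = 1e-9)
  stop_if_not_count(points_per_peak, "points_per_peak", lower = 2)
  stop_if_not_scalar_number(mz_jitter_ppm, "mz_jitter_ppm", lower = 0)
  stop_if_not_scalar_number(fraction_regulated, "fraction_regulated",
                            lower = 0, upper = 1)
  stop_if_not_scalar_number(planted_log2fc, "planted_log2fc")
  stop_if_not_count(n_decoy_kinases, "n_decoy_kinases", lower = 0)
  stop_if_not_count(decoy_set_size, "decoy_set_size", lower = 1)
  stop_if_not_scalar_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  if (length(planted_kinases) > 0 &&
      (is.null(names(planted_kinases)) || any(names(planted_kinases) == "")))
    stop("'planted_kinases' must be a named vector (kinase -> n substrates)",
         call. = FALSE)
  if (sum(planted_kinases) + 0 > n_peptides)
    stop("planted kinase substrates exceed n_peptides", call. = FALSE)
  structure(list(n_peptides = as.integer(n_peptides),
                 n_samples_per_condition = as.integer(n_samples_per_condition),
                 peak_width_s = peak_width_s,
                 points_per_peak = as.integer(points_per_peak),
                 mz_jitter_ppm = mz_jitter_ppm,
                 fraction_regulated = fraction_regulated,
                 planted_log2fc = planted_log2fc,
                 planted_kinases = planted_kinases,
                 n_decoy_kinases = as.integer(n_decoy_kinases),
                 decoy_set_size = as.integer(decoy_set_size),
                 noise_sd_log2 = noise_sd_log2,
                 amplitude_log2_range = amplitude_log2_range,
                 rt_range_s = rt_range_s, seed = as.integer(seed)),
            class = "phospho_sim_params")
}

#' Generate synthetic raw ion maps plus peptide identifications and truth
#'
#' @param params a [phospho_sim_params()] object.
#' @return list with `raw` (data.frame: `sample`, `rt_s`, `mz`, `intensity`),
#'   `peptides` (data.frame: `peptide_id`, `mz`, `charge`, `rt_apex_s`,
#'   `site`), `samples` (data.frame: `sample`, `condition`), `truth`
#'   (data.frame: `peptide_id`, per-sample planted amplitudes `amp_<sample>`,
#'   `regulated`, `true_log2fc`, `kinase`), and `setdb` (named list of
#'   substrate sets: planted kinases plus decoys).
#' @export
gen_phospho_raw <- function(params) {
  stopifnot(inherits(params, "phospho_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_peptides
    nspc <- p$n_samples_per_condition
    samples <- data.frame(
      sample = c(paste0("A", seq_len(nspc)), paste0("B", seq_len(nspc))),
      condition = rep(c("A", "B"), each = nspc), stringsAsFactors = FALSE)
    ids <- sprintf("pep%04d", seq_len(n))
    peptides <- data.frame(
      peptide_id = ids,
      mz = runif(n, 400, 1200),
      charge = sample(2:3, n, replace = TRUE),
      rt_apex_s = runif(n, p$rt_range_s[1], p$rt_range_s[2]),
      site = sprintf("GENE%04d_S%d", seq_len(n), sample(1:999, n, replace = TRUE)),
      stringsAsFactors = FALSE)

    # Regulation assignment: planted kinase substrates first, then extras up
    # to fraction_regulated, with random sign.
    kinase <- rep(NA_character_, n)
    true_lfc <- rep(0, n)
    cursor <- 0L
    for (kin in names(p$planted_kinases)) {
      m <- p$planted_kinases[[kin]]
      kinase[(cursor + 1L):(cursor + m)] <- kin
      true_lfc[(cursor + 1L):(cursor + m)] <- p$planted_log2fc
      cursor <- cursor + m
    }
    n_target <- round(p$fraction_regulated * n)
    extra <- max(0L, n_target - cursor)
    if (extra > 0) {
      sl <- (cursor + 1L):(cursor + extra)
      true_lfc[sl] <- p$planted_log2fc * sample(c(-1, 1), extra, replace = TRUE)
    }
    regulated <- true_lfc != 0

    base_log2 <- runif(n, p$amplitude_log2_range[1], p$amplitude_log2_range[2])
    ns <- nrow(samples)
    amp <- matrix(0, n, ns, dimnames = list(ids, samples$sample))
    for (j in seq_len(ns)) {
      shift <- if (samples$condition[j] == "B") true_lfc else 0
      amp[, j] <- 2^(base_log2 + shift + rnorm(n, 0, p$noise_sd_log2))
    }

    # Acquisition grid: symmetric around the apex, spacing chosen so the base
    # width (+/- peak_width_s/2) always holds >= points_per_peak points, with
    # one point exactly at the apex.
    half_k <- ceiling(p$points_per_peak / 2)
    offs <- (-half_k:half_k) * (p$peak_width_s / p$points_per_peak)
    sigma <- p$peak_width_s / 4
    shape <- exp(-offs^2 / (2 * sigma^2))
    npts <- length(offs)
    rt <- rep(peptides$rt_apex_s, each = npts) + rep(offs, n)
    mz0 <- rep(peptides$mz, each = npts)
    raws <- vector("list", ns)
    for (j in seq_len(ns)) {
      inten <- rep(amp[, j], each = npts) * rep(shape, n)
      jit <- if (p$mz_jitter_ppm > 0)
        runif(n * npts, -p$mz_jitter_ppm, p$mz_jitter_ppm) * 1e-6 else 0
      raws[[j]] <- data.frame(sample = samples$sample[j], rt_s = rt,
                              mz = mz0 * (1 + jit), intensity = inten,
                              stringsAsFactors = FALSE)
    }
    raw <- do.call(rbind, raws)
    rownames(raw) <- NULL

    # Decoy kinase sets: unregulated, unannotated peptides.
    setdb <- list()
    for (kin in names(p$planted_kinases)) {
      setdb[[kin]] <- ids[!is.na(kinase) & kinase == kin]
    }
    pool <- ids[!regulated & is.na(kinase)]
    if (p$n_decoy_kinases > 0) {
      if (length(pool) < p$decoy_set_size)
        stop("not enough unregulated peptides to build decoy kinase sets", call. = FALSE)
      for (d in seq_len(p$n_decoy_kinases)) {
        setdb[[sprintf("decoy%03d", d)]] <- sample(pool, p$decoy_set_size)
      }
    }

    truth <- data.frame(peptide_id = ids, regulated = regulated,
                        true_log2fc = true_lfc, kinase = kinase,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(amp)[, samples$sample, drop = FALSE])
    names(truth)[-(1:4)] <- paste0("amp_", samples$sample)
    rownames(truth) <- NULL

    list(raw = raw, peptides = peptides, samples = samples,
         truth = truth, setdb = setdb)
  })
}
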