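# Synthetic pulsed-SILAC protein tables: H/M ratios at two pulse timepoints
# (+24 h and +48 h) in a minimal proteinGroups-like dialect, with decoy /
# contaminant / modified-only flags, planted co-downregulated proteins and
# planted enriched pathways for the Table-1-style report.

#' Parameters for the synthetic pulsed-SILAC generator
#'
#' @param n_proteins total records (including flagged ones).
#' @param fraction_decoy,fraction_contaminant,fraction_modified_only
#'   fractions of records flagged reverse / contaminant / identified only by
#'   modified peptides (disjoint, applied in that order).
#' @param fraction_missing fraction of present ratios knocked out at random
#'   (independently per timepoint).
#' @param fraction_co_down fraction of clean proteins planted as
#'   co-downregulated (true log2 ratio `effect_log2` at both timepoints).
#' @param effect_log2 planted log2 effect for co-down proteins (negative).
#' @param noise_sd_log2 log2-scale noise per protein x timepoint.
#' @param planted_pathways list of lists with fields `name`, `n_members`,
#'   `hit_fraction` (fraction of members drawn from co-down proteins).
#' @param n_background_sets,background_set_size decoy pathway sets drawn
#'   uniformly from all clean proteins (size may be a length-2 range).
#' @param seed RNG seed.
#' @return validated list of class `silac_sim_params`.
#' @export
silac_sim_params <- function(n_proteins = 470, fraction_decoy = 0.05,
                             fraction_contaminant = 0.03,
                             fraction_modified_only = 0.02,
                             fraction_missing = 0, fraction_co_down = 0.3,
                             effect_log2 = -1, noise_sd_log2 = 0.1,
                             planted_pathways = list(
                               list(name = "ribosome", n_members = 20,
                                    hit_fraction = 0.9)),
                             n_background_sets = 30,
                             background_set_size = c(10, 40), seed = 1) {
  stop_if_not_count(n_proteins, "n_proteins", lower = 1)
  for (f in c("fraction_decoy", "fraction_contaminant", "fraction_modified_only",
              "fraction_missing", "fraction_co_down")) {
    stop_if_not_scalar_number(get(f), f, lower = 0, upper = 1)
  }
  stop_if_not_scalar_number(effect_log2, "effect_log2")
  stop_if_not_scalar_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  stop_if_not_count(n_background_sets, "n_background_sets", lower = 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 fraction_decoy = fraction_decoy,
                 fraction_contaminant = fraction_contaminant,
                 fraction_modified_only = fraction_modified_only,
                 fraction_missing = fraction_missing,
                 fraction_co_down = fraction_co_down,
                 effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
                 planted_pathways = planted_pathways,
                 n_background_sets = as.integer(n_background_sets),
                 background_set_size = background_set_size,
                 seed = as.integer(seed)),
            class = "silac_sim_params")
}

#' Generate a synthetic pulsed-SILAC protein table with ground truth
#'
#' @param params a [silac_sim_params()] object.
#' @return list with `records` (data.frame: `protein_id`, `ratio_hm_t24`,
#'   `ratio_hm_t48`, `reverse`, `contaminant`, `only_modified`), `setdb`
#'   (named list of pathway sets), and `truth` (data.frame: `protein_id`,
#'   `true_log2_t24`, `true_log2_t48`, `co_down`, `flagged`).
#' @export
gen_silac_table <- function(params) {
  stopifnot(inherits(params, "silac_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_proteins
    ids <- sprintf("prot%04d", seq_len(n))
    nd <- round(p$fraction_decoy * n)
    nc <- round(p$fraction_contaminant * n)
    nm <- round(p$fraction_modified_only * n)
    if (nd + nc + nm > n) stop("flag fractions sum past 1", call. = FALSE)
    reverse <- contaminant <- only_modified <- rep(FALSE, n)
    if (nd > 0) reverse[seq_len(nd)] <- TRUE
    if (nc > 0) contaminant[nd + seq_len(nc)] <- TRUE
    if (nm > 0) only_modified[nd + nc + seq_len(nm)] <- TRUE
    clean <- !(reverse | contaminant | only_modified)

    true24 <- true48 <- rep(0, n)
    n_clean <- sum(clean)
    n_down <- round(p$fraction_co_down * n_clean)
    down_idx <- sample(which(clean), n_down)
    true24[down_idx] <- p$effect_log2
    true48[down_idx] <- p$effect_log2

    r24 <- 2^(true24 + rnorm(n, 0, p$noise_sd_log2))
    r48 <- 2^(true48 + rnorm(n, 0, p$noise_sd_log2))
    if (p$fraction_missing > 0) {
      r24[runif(n) < p$fraction_missing] <- NA
      r48[runif(n) < p$fraction_missing] <- NA
    }

    records <- data.frame(protein_id = ids, ratio_hm_t24 = r24,
                          ratio_hm_t48 = r48, reverse = reverse,
                          contaminant = contaminant,
                          only_modified = only_modified,
                          stringsAsFactors = FALSE)

    clean_ids <- ids[clean]
    down_ids <- ids[sort(down_idx)]
    other_ids <- setdiff(clean_ids, down_ids)
    setdb <- list()
    for (pw in p$planted_pathways) {
      m <- pw$n_members
      n_hit <- round(pw$hit_fraction * m)
      n_hit <- min(n_hit, length(down_ids))
      n_bg <- min(m - n_hit, length(other_ids))
      setdb[[pw$name]] <- c(sample(down_ids, n_hit), sample(other_ids, n_bg))
    }
    if (p$n_background_sets > 0) {
      sz <- p$background_set_size
      for (b in seq_len(p$n_background_sets)) {
        m <- if (length(sz) == 2) sample(sz[1]:sz[2], 1) else sz
        m <- min(m, length(clean_ids))
        setdb[[sprintf("bgset%03d", b)]] <- sample(clean_ids, m)
      }
    }

    truth <- data.frame(protein_id = ids, true_log2_t24 = true24,
                        true_log2_t48 = true48,
                        co_down = ids %in% down_ids, flagged = !clean,
                        stringsAsFactors = FALSE)
    list(records = records, setdb = setdb, truth = truth)
  })
}
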