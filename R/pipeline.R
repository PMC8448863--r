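# Orchestration: validated YAML configs, deterministic per-stage seeds,
# TSV/PNG artifacts and a machine-readable run report.

pipeline_schema <- function() {
  list(
    seed = "integer", out_dir = "character", stages = "character",
    histo = c("image", "segmentation"),
    phospho = c("sim", "xic", "sig_p"),
    silac = c("sim", "margin", "q_max", "min_enrichment"))
}

default_config <- function() {
  list(seed = 1L, out_dir = "marrowniche_run",
       stages = c("histo", "phospho", "silac"),
       histo = list(image = list(width_px = 384, height_px = 384,
                                 n_adipocytes = 20),
                    segmentation = list()),
       phospho = list(sim = list(n_peptides = 100, n_decoy_kinases = 10),
                      xic = list(), sig_p = 0.05),
       silac = list(sim = list(), margin = 0, q_max = 0.05,
                    min_enrichment = 2))
}

check_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
}

#' Validate and default a pipeline configuration
#'
#' Reads a YAML config, rejects unknown keys at the top and stage level,
#' applies documented defaults and checks stage parameter blocks against
#' their constructors. The effective (fully defaulted) config is returned.
#'
#' @param path YAML file path, or a list already in memory.
#' @return list of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y) || length(y) == 0) stop("config file is empty", call. = FALSE)
    y
  } else if (is.list(path)) path else stop("config must be a path or list", call. = FALSE)
  schema <- pipeline_schema()
  check_keys(cfg, names(schema), "top level")
  for (st in c("histo", "phospho", "silac")) {
    if (!is.null(cfg[[st]])) check_keys(cfg[[st]], schema[[st]], st)
  }
  eff <- utils::modifyList(default_config(), cfg)
  if (!is.numeric(eff$seed) || eff$seed != round(eff$seed))
    stop("seed must be an integer", call. = FALSE)
  eff$seed <- as.integer(eff$seed)
  bad <- setdiff(eff$stages, c("histo", "phospho", "silac"))
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  # construct stage parameter objects now so errors surface before any run
  eff$histo$image_params <- do.call(marrow_image_params,
                                    c(eff$histo$image,
                                      list(seed = derive_seed(eff$seed, "histo"))))
  eff$histo$seg_params <- do.call(segmentation_params, eff$histo$segmentation)
  eff$phospho$sim_params <- do.call(phospho_sim_params,
                                    c(eff$phospho$sim,
                                      list(seed = derive_seed(eff$seed, "phospho"))))
  eff$phospho$xic_params <- do.call(xic_params, eff$phospho$xic)
  eff$silac$sim_params <- do.call(silac_sim_params,
                                  c(eff$silac$sim,
                                    list(seed = derive_seed(eff$seed, "silac"))))
  structure(eff, class = "run_config")
}

#' Execute a configured pipeline run
#'
#' Runs the requested stages in order (synthesis feeding each analysis),
#' writes all tabular artifacts as TSV, images/masks as PNG, and a JSON run
#' report listing every output file with its MD5 digest, the effective
#' parameters and wall time. Re-running with the same config reproduces
#' byte-identical tabular outputs.
#'
#' @param config a `run_config` from [validate_config()], a path, or a list.
#' @return the run report, invisibly; written as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(x, name, writer = write_tsv) {
    path <- file.path(out, name)
    writer(x, path)
    manifest <<- c(manifest, path)
    path
  }

  if ("histo" %in% config$stages) {
    sim <- gen_marrow_image(config$histo$image_params)
    seg <- segment_adipocytes(sim$image, sim$roi, config$histo$seg_params)
    emit(seg$objects, "histo_objects.tsv")
    emit(sim$truth$objects, "histo_truth.tsv")
    emit(as.data.frame(seg$summary[c("n_adipocytes", "roi_area_mm2",
                                     "density_per_mm2", "mean_size_um2",
                                     "median_size_um2")]),
         "histo_summary.tsv")
    emit(sim$image$data, "histo_image.png", write_image_png)
    emit(sim$roi$mask, "histo_roi.png", write_image_png)
    emit(seg$labels, "histo_labels.png", write_image_png)
  }

  if ("phospho" %in% config$stages) {
    sim <- gen_phospho_raw(config$phospho$sim_params)
    hm <- quantify_peptides(sim$raw, sim$peptides, sim$samples,
                            config$phospho$xic_params)
    hm <- normalize_heights(hm)
    diff <- differential(hm)
    emit(diff, "phospho_differential.tsv")
    heights <- data.frame(peptide_id = rownames(hm), as.data.frame(unclass(hm)),
                          check.names = FALSE)
    emit(heights, "phospho_heights.tsv")
    if (length(sim$setdb) > 0) {
      ks <- ksea(diff, sim$setdb, sig_p = config$phospho$sig_p)
      emit(ks, "phospho_ksea.tsv")
      emit(sim$setdb, "phospho_sets.gmt", write_gmt)
    }
  }

  if ("silac" %in% config$stages) {
    sim <- gen_silac_table(config$silac$sim_params)
    flt <- filter_records(sim$records)
    norm <- log2_normalize(flt$records)
    cls <- cross_coregulation(norm, margin = config$silac$margin)
    norm$class <- "unclassified"
    norm$class[norm$protein_id %in% cls$co_down] <- "co_down"
    norm$class[norm$protein_id %in% cls$co_up] <- "co_up"
    norm$class[norm$protein_id %in% cls$discordant] <- "discordant"
    rep <- pathway_report(cls$co_down, norm$protein_id, sim$setdb,
                          q_max = config$silac$q_max,
                          min_enrichment = config$silac$min_enrichment)
    emit(sim$records, "silac_records.tsv")
    emit(norm, "silac_classified.tsv")
    emit(rep$all, "silac_pathways_all.tsv")
    emit(rep$report, "silac_report.tsv")
    emit(sim$setdb, "silac_sets.gmt", write_gmt)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("marrowniche")),
    seed = config$seed, stages = config$stages,
    parameters = list(
      histo = config$histo[c("image", "segmentation")],
      phospho = config$phospho[c("sim", "xic", "sig_p")],
      silac = config$silac[c("sim", "margin", "q_max", "min_enrichment")]),
    outputs = data.frame(file = basename(manifest),
                         md5 = unname(tools::md5sum(manifest)),
                         stringsAsFactors = FALSE),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
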