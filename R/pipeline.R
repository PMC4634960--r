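# Config-driven end-to-end pipeline: simulate -> families -> phase ->
# crossovers -> maps -> hotspots -> usage -> gwas -> diagnostics.  Every stage
# writes a headered TSV into the run directory and a manifest records the
# configuration, seed and package version; deterministic stages are
# bit-identical across reruns with the same config and seed.

#' Default pipeline configuration
#'
#' @param ... overrides of the default fields (\code{sim} list passed to
#'   \code{\link{sim_config}}, \code{n_families}, stage toggles in
#'   \code{stages}, thresholds in \code{params}, \code{seed}).
#' @return a named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sim = list(),
    n_families = 200,
    seed = 1L,
    stages = list(map = TRUE, hotspots = TRUE, usage = TRUE,
                  gwas = FALSE, diagnostics = TRUE),
    params = list(min_support = 3, k_sd = 2.5, maf_min = 0.001,
                  r_max = 0.95, trim_bp = 2e6, spline_df = 5)
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(cfg[[nm]]) && is.list(mods[[nm]]))
      cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
    else cfg[[nm]] <- mods[[nm]]
  }
  cfg
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  do.call(pipeline_config, config)
}

#' Run the full recombination pipeline
#'
#' @param config a list from \code{\link{pipeline_config}} or a path to a YAML
#'   file with the same structure.
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the paths of
#'   all written files.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    paths[[name]] <<- p
  }

  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_pedigree(scfg, cfg$n_families)
  emit(sim$pedigree, "pedigree.tsv")
  emit(sim$genotypes$map, "snp_map.tsv")
  emit(sim$truth$crossovers, "truth_crossovers.tsv")

  fams <- extract_families(sim$pedigree, rownames(sim$genotypes$geno))
  if (!nrow(fams)) abort("pipeline: no analyzable three-generation families")
  emit(as.data.frame(fams), "families.tsv")

  phased <- phase_families(sim$genotypes, fams)
  calls <- call_crossover_set(phased, sim$genotypes$map, sim$genotypes,
                              min_support = cfg$params$min_support)
  emit(as.data.frame(calls), "crossovers.tsv")
  meta <- attr(calls, "meioses")
  emit(meta, "meioses.tsv")

  res <- list(config = cfg, sim = sim, families = fams, calls = calls)

  if (isTRUE(cfg$stages$map) || isTRUE(cfg$stages$hotspots) ||
      isTRUE(cfg$stages$usage) || isTRUE(cfg$stages$diagnostics)) {
    maps <- list()
    for (sx in c("M", "F")) {
      sel <- calls[calls$parent_sex == sx, , drop = FALSE]
      n_sx <- sum(meta$parent_sex == sx)
      if (n_sx == 0) abort("pipeline: no meioses for sex ", sx)
      maps[[sx]] <- em_fit(sel, n_sx, sim$genotypes$map, sex = sx)
    }
    write_map(maps$M, maps$F, file.path(out_dir, "map.tsv"))
    paths[["map.tsv"]] <- file.path(out_dir, "map.tsv")
    res$maps <- maps
  }

  if (isTRUE(cfg$stages$hotspots)) {
    hs <- lapply(res$maps, call_hotspots, k_sd = cfg$params$k_sd)
    write_hotspots(hs$M, file.path(out_dir, "hotspots_male.bed"),
                   file.path(out_dir, "hotspots_male.tsv"))
    write_hotspots(hs$F, file.path(out_dir, "hotspots_female.bed"),
                   file.path(out_dir, "hotspots_female.tsv"))
    res$hotspots <- hs
    res$shared <- shared_hotspots(hs$M, hs$F)
  }

  if (isTRUE(cfg$stages$usage) && isTRUE(cfg$stages$hotspots)) {
    usage <- rbind(
      hotspot_usage(calls[calls$parent_sex == "M", , drop = FALSE],
                    res$hotspots$M, res$maps$M),
      hotspot_usage(calls[calls$parent_sex == "F", , drop = FALSE],
                    res$hotspots$F, res$maps$F))
    emit(usage, "usage.tsv")
    res$usage <- usage
  }

  if (isTRUE(cfg$stages$gwas)) {
    pheno <- build_phenotypes(calls, kind = "rate")
    scans <- list()
    for (sx in c("M", "F")) {
      ps <- pheno[pheno$sex == sx, , drop = FALSE]
      if (nrow(ps) < 30) next
      gt_s <- sim$genotypes
      gt_s$geno <- gt_s$geno[ps$animal_id, , drop = FALSE]
      kept <- filter_snps(gt_s, cfg$params$maf_min, cfg$params$r_max)
      gt_k <- drop_snps(gt_s, setdiff(gt_s$map$snp_id, kept))
      A <- grm(gt_k)
      fit <- fit_null(ps, A)
      sc <- lmm_scan(fit, gt_k)
      emit(as.data.frame(sc), sprintf("gwas_rate_%s.tsv", sx))
      scans[[sx]] <- sc
    }
    res$gwas <- scans
  }

  if (isTRUE(cfg$stages$diagnostics)) {
    lens <- stats::setNames(scfg$chrom_lengths_bp, seq_len(scfg$n_chromosomes))
    prof <- position_profile(res$maps$M, lens, trim_bp = cfg$params$trim_bp,
                             spline_df = cfg$params$spline_df)
    emit(prof$fit, "profile_male.tsv")
    counts <- as.numeric(table(factor(calls$meiosis_id,
                                      levels = meta$meiosis_id)))
    yr <- sim$pedigree[meta$parent_id, "birth_year"]
    tr <- time_trend(counts, yr, spline_df = cfg$params$spline_df)
    emit(tr$trend, "trend.tsv")
    res$diagnostics <- list(profile = prof, trend = tr)
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest <- list(
    package = "recpipe",
    version = as.character(utils::packageVersion("recpipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
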