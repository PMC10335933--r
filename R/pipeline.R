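#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected. Every numeric default is the convention used
#' throughout the package (FDR 0.01 with frequency shift 0.25 for the PAV
#' scan; 20-kb/2-kb diversity windows with the 1% tail; MAF 0.05 and
#' missingness 0.1 marker QC; significance 7.81e-8 with 50-kb / R^2 0.3
#' locus clustering; ROF 0.99; 100 x 85%/15% prediction splits; top-20
#' haplotype enumeration).
#'
#' @param sim A [sim_config()] for the synthetic-data stage (its seed is the
#'   pipeline seed).
#' @param stages Character vector of stages to run, a subset of
#'   `c("synthdata", "pangene", "pavscan", "divscan", "gwasloci", "gsbreed")`.
#'   Dependencies are implicit: later stages read the synthetic stage's
#'   in-memory objects.
#' @param ... Named parameter overrides; see the listed defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("synthdata", "pangene", "pavscan",
                                       "divscan", "gwasloci", "gsbreed"),
                            ...) {
  defaults <- list(
    growth_R = 50,
    q_max = 0.01, min_delta = 0.25, promoter_len = 2000,
    te_n_perm = 199,
    window_size = 20000, window_step = 2000, scan_quantile = 0.01,
    maf = 0.05, miss = 0.1, n_pc = 10,
    p_max = 7.81e-8, dist_max = 50000, r2_min = 0.3,
    gene_window = 50000, ld_flank = 50000, ld_r2_cut = 0.5,
    rof_max = 0.99, cv_reps = 20, top_k = 10,
    gs_method = "ridge"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  stages <- match.arg(stages, c("synthdata", "pangene", "pavscan", "divscan",
                                "gwasloci", "gsbreed"), several.ok = TRUE)
  structure(c(list(sim = validate_sim_config(unclass(sim)), stages = stages),
              utils::modifyList(defaults, over)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Executes the stages in dependency order (synthetic data, then pan-gene
#' classification, PAV selection scan, diversity scan, mixed-model GWAS with
#' locus clustering, and genomic selection with breeding-potential
#' enumeration), writes each stage's outputs as plain-text files under
#' `out_dir` (VCF/BED/GFF3/TSV), and emits a provenance manifest
#' (`manifest.json`) with the resolved configuration, seed and per-file MD5
#' checksums. Re-running with the same configuration reproduces identical
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stages <- config$stages
  if (!"synthdata" %in% stages) {
    abort("the synthdata stage is required (it provides all inputs)")
  }

  sim <- simulate_population(config$sim)
  res$sim <- sim
  genome <- config$sim$genome
  write_snp_vcf(sim$snp, file.path(out_dir, "snps.vcf"), genome)
  write_pav_vcf(sim$pav, file.path(out_dir, "pavs.vcf"), genome)
  write_intervals(sim$genes %>% rename(name = "gene_id"),
                  file.path(out_dir, "genes.gff3"), feature = "gene")
  write_intervals(sim$tes %>% rename(name = "te_id") %>%
                    mutate(score = as.integer(.data$intact)),
                  file.path(out_dir, "tes.bed"))
  write_presence_tsv(sim$presence, file.path(out_dir, "presence.tsv"))
  readr::write_tsv(sim$groups, file.path(out_dir, "groups.tsv"))
  readr::write_tsv(sim$pheno, file.path(out_dir, "phenotypes.tsv"))
  readr::write_tsv(sim$truth$selected_pavs,
                   file.path(out_dir, "truth_selected_pavs.tsv"))

  if ("pangene" %in% stages) {
    comp <- classify_families(sim$presence)
    curve <- growth_curves(sim$presence, R = config$growth_R,
                           seed = config$sim$seed)
    closure <- fit_closure(curve)
    res$pangene <- list(composition = comp, curve = curve, closure = closure)
    readr::write_tsv(comp, file.path(out_dir, "pan_composition.tsv"))
    readr::write_tsv(curve, file.path(out_dir, "growth_curve.tsv"))
    readr::write_tsv(glance(closure), file.path(out_dir, "closure.tsv"))
  }

  if ("pavscan" %in% stages) {
    freqs <- pav_frequencies(sim$pav, sim$groups)
    calls <- bind_rows(
      scan_selected(freqs, "domestication", config$q_max, config$min_delta),
      scan_selected(freqs, "improvement", config$q_max, config$min_delta))
    fav <- classify_favpav(calls, freqs)
    assoc <- map_pavs_to_genes(sim$pav, sim$genes, config$promoter_len)
    fav_genes <- assoc %>%
      filter(.data$pav %in% fav$pav[fav$favpav]) %>%
      distinct(.data$gene_id)
    profile <- pav_distance_profile(sim$pav, sim$genes)
    te_enr <- te_overlap_enrichment(sim$pav, sim$tes, genome,
                                    n_perm = config$te_n_perm,
                                    seed = config$sim$seed)
    ted <- classify_te_derived(sim$pav, sim$tes)
    res$pavscan <- list(freqs = freqs, calls = calls, favpav = fav,
                        gene_assoc = assoc, favorable_genes = fav_genes,
                        profile = profile, te_enrichment = te_enr,
                        te_derived = ted)
    readr::write_tsv(calls, file.path(out_dir, "selection_calls.tsv"))
    readr::write_tsv(fav, file.path(out_dir, "favpav.tsv"))
    readr::write_tsv(fav_genes, file.path(out_dir, "favorable_genes.tsv"))
    readr::write_tsv(profile, file.path(out_dir, "pav_distance_profile.tsv"))
    readr::write_tsv(te_enr, file.path(out_dir, "te_enrichment.tsv"))
    readr::write_tsv(ted, file.path(out_dir, "te_derived.tsv"))
  }

  if ("divscan" %in% stages) {
    windows <- make_windows(genome, config$window_size, config$window_step)
    stats <- diversity_scan(sim$snp$geno, sim$snp$info, windows, sim$groups)
    flagged <- scan_candidates(stats, config$scan_quantile)
    res$divscan <- list(stats = stats, flagged = flagged,
                        thresholds = scan_thresholds(flagged))
    readr::write_tsv(flagged, file.path(out_dir, "diversity_windows.tsv"))
    readr::write_tsv(scan_thresholds(flagged),
                     file.path(out_dir, "diversity_thresholds.tsv"))
  }

  pheno_vec <- sim$pheno %>%
    filter(.data$trait == "trait1") %>%
    group_by(.data$accession) %>%
    summarise(value = mean(.data$value), .groups = "drop")

  if ("gwasloci" %in% stages) {
    snp_f <- filter_markers(sim$snp$geno, config$maf, config$miss, ploidy = 2)
    pav_f <- filter_markers(sim$pav$geno, config$maf, config$miss, ploidy = 1)
    G <- cbind(snp_f, pav_f)
    info <- bind_rows(
      sim$snp$info %>% select("id", "chrom", "pos") %>% mutate(type = "SNP"),
      sim$pav$records %>%
        select("id", "chrom", pos = "start") %>% mutate(type = "SV"))
    K <- kinship(G)
    assoc <- lmm_assoc(G, pheno_vec, K, n_pc = config$n_pc, info = info)
    meff <- effective_marker_number(G)
    loci <- cluster_loci(assoc, G, config$p_max, config$dist_max,
                         config$r2_min)
    cand <- candidate_genes(loci, sim$genes, config$gene_window)
    ld <- sv_snp_ld_complement(pav_f, sim$pav$records, snp_f, sim$snp$info,
                               config$ld_flank, config$ld_r2_cut)
    res$gwasloci <- list(assoc = assoc, meff = meff, loci = loci,
                         candidates = cand, ld = ld)
    readr::write_tsv(assoc, file.path(out_dir, "association.tsv"))
    readr::write_tsv(meff$thresholds, file.path(out_dir, "meff.tsv"))
    readr::write_tsv(loci, file.path(out_dir, "loci.tsv"))
    readr::write_tsv(cand, file.path(out_dir, "candidate_genes.tsv"))
    readr::write_tsv(ld, file.path(out_dir, "ld_complement.tsv"))
  }

  if ("gsbreed" %in% stages) {
    snp_f <- filter_markers(sim$snp$geno, config$maf, config$miss, ploidy = 2)
    pav_f <- filter_markers(sim$pav$geno, config$maf, config$miss, ploidy = 1)
    G <- cbind(snp_f, pav_f)
    imp <- feature_gain(G, pheno_vec, seed = config$sim$seed)
    type_of <- c(setNames(rep("SNP", ncol(snp_f)), colnames(snp_f)),
                 setNames(rep("SV", ncol(pav_f)), colnames(pav_f)))
    cg <- rof_select(imp, config$rof_max)
    gwas_sig <- if (!is.null(res$gwasloci)) {
      res$gwasloci$assoc %>% filter(.data$p <= config$p_max)
    } else NULL
    panels <- build_panels(
      cg_snp = cg[type_of[cg] == "SNP"], cg_sv = cg[type_of[cg] == "SV"],
      gwas_snp = if (is.null(gwas_sig)) character(0) else
        gwas_sig$id[gwas_sig$type == "SNP"],
      gwas_sv = if (is.null(gwas_sig)) character(0) else
        gwas_sig$id[gwas_sig$type == "SV"])
    panel_use <- panel_markers(panels, "SNPSV_cg_gwas")
    if (length(panel_use) == 0) panel_use <- colnames(G)
    cv <- cross_validate(G[, panel_use, drop = FALSE], pheno_vec,
                         reps = config$cv_reps, seed = config$sim$seed,
                         method = config$gs_method)
    model <- gebv_fit(G[, panel_use, drop = FALSE], pheno_vec,
                      method = config$gs_method, seed = config$sim$seed)
    breeding <- enumerate_breeding(model, G, imp,
                                   top_k = min(config$top_k,
                                               length(panel_use)),
                                   groups = sim$groups)
    res$gsbreed <- list(importance = imp, panels = panels, cv = cv,
                        model = model, breeding = breeding)
    readr::write_tsv(imp, file.path(out_dir, "marker_importance.tsv"))
    readr::write_tsv(panels, file.path(out_dir, "panels.tsv"))
    readr::write_tsv(tidy(cv), file.path(out_dir, "cv_precision.tsv"))
    readr::write_tsv(glance(breeding), file.path(out_dir, "breeding.tsv"))
  }

  # resolved config + manifest
  cfg_list <- unclass(config)
  cfg_list$sim <- unclass(cfg_list$sim)
  cfg_list$sim$genome <- as.list(cfg_list$sim$genome)
  cfg_list$sim$family_shares <- as.list(cfg_list$sim$family_shares)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config_resolved.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$sim$seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(file.path(out_dir,
                                                "config_resolved.yaml"))),
    files = setNames(as.list(unname(tools::md5sum(file.path(out_dir,
                                                            files)))), files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a `sim` block and top-level parameter keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$genome)) sim_args$genome <- unlist(sim_args$genome)
  if (!is.null(sim_args$family_shares)) {
    sim_args$family_shares <- unlist(sim_args$family_shares)
  }
  sim <- do.call(sim_config, sim_args)
  rest <- y[setdiff(names(y), c("sim", "stages"))]
  do.call(pipeline_config,
          c(list(sim = sim, stages = y$stages %||%
                   c("synthdata", "pangene", "pavscan", "divscan",
                     "gwasloci", "gsbreed")),
            rest))
}
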