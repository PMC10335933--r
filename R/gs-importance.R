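#' Feature gain of markers from a gradient-boosted tree model
#'
#' Fits a gradient-boosted decision-tree regression of the phenotype on the
#' marker dosages and attributes to each marker its feature gain (FG): the
#' total split gain accumulated over all trees. Markers never used in a
#' split have FG = 0. The reduction-of-feature-gain statistic
#' `ROF_i = 1 - FG_i / FG_max` is attached for [rof_select()]. (The
#' orientation matters: written the other way round, as 1 - FG_max/FG_i, the
#' statistic is non-positive for every marker and a 0.99 cutoff would select
#' everything; the form used here makes the conventional 0.99 threshold mean
#' "FG at least 1% of the maximum".)
#'
#' @param geno Dosage matrix, accessions x markers (NA mean-imputed).
#' @param pheno Phenotype vector (named by accession) or tibble with
#'   `accession`/`value`.
#' @param params Optional xgboost parameter overrides (list); sensible
#'   defaults: depth 4, eta 0.1, subsample 0.9.
#' @param nrounds Boosting rounds (default 150).
#' @param seed RNG seed for the boosting run.
#' @return A `marker_importance` tibble: `marker`, `fg`, `rof`.
#' @export
feature_gain <- function(geno, pheno, params = list(), nrounds = 150,
                         seed = 1) {
  if (is.data.frame(pheno)) pheno <- setNames(pheno$value, pheno$accession)
  if (!is.null(names(pheno)) && !is.null(rownames(geno))) {
    pheno <- pheno[rownames(geno)]
  }
  y <- as.numeric(pheno)
  if (sd(y) == 0) abort("phenotype is constant; feature gain undefined")
  Z <- impute_mean(geno)
  colnames(Z) <- colnames(geno) %||% sprintf("m%05d", seq_len(ncol(geno)))
  p <- utils::modifyList(list(objective = "reg:squarederror", max_depth = 4,
                              eta = 0.1, subsample = 0.9,
                              colsample_bytree = 0.9, nthread = 1), params)
  fit <- with_seed(seed, {
    xgboost::xgb.train(params = p,
                       data = xgboost::xgb.DMatrix(Z, label = y, nthread = 1),
                       nrounds = nrounds, verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = fit)
  fg <- setNames(rep(0, ncol(Z)), colnames(Z))
  if (!is.null(imp) && nrow(imp) > 0) {
    fg[imp$Feature] <- imp$Gain
  }
  fg_max <- max(fg)
  out <- tibble(marker = names(fg), fg = unname(fg),
                rof = if (fg_max > 0) 1 - unname(fg) / fg_max else NA_real_)
  class(out) <- c("marker_importance", class(out))
  out
}

#' Select highly effective markers by reduction of feature gain
#'
#' Selects markers with `ROF_i = 1 - FG_i / FG_max <= rof_max`, i.e.
#' `FG_i >= (1 - rof_max) * FG_max`. The selection is invariant to rescaling
#' all FG values by a positive constant; the maximum-FG marker (ROF = 0) is
#' always selected. When every FG is zero the selection is empty, with a
#' warning.
#'
#' @param importance A `marker_importance` tibble from [feature_gain()], or
#'   any tibble with `marker` and `fg` columns.
#' @param rof_max ROF threshold (default 0.99).
#' @return Character vector of selected marker ids.
#' @export
rof_select <- function(importance, rof_max = 0.99) {
  fg <- importance$fg
  fg_max <- max(fg)
  if (fg_max <= 0) {
    warn("all feature gains are zero; empty selection")
    return(character(0))
  }
  rof <- 1 - fg / fg_max
  importance$marker[rof <= rof_max]
}

#' Build the six genomic-selection marker panels
#'
#' Combines highly effective ("cg") markers with GWAS-significant markers
#' into the six standard panels: `SNP_cg`, `SNP_cg_gwas = SNP_cg + GWAS
#' SNPs`, `SV_cg`, `SV_cg_gwas = SV_cg + GWAS SVs`, `SNPSV_cg = SNP_cg +
#' SV_cg`, and `SNPSV_cg_gwas = SNPSV_cg + GWAS SNPs + GWAS SVs` (all set
#' unions). With empty GWAS sets the `*_gwas` panels equal their `*_cg`
#' counterparts; every `*_gwas` panel is a superset of its `*_cg` panel.
#'
#' @param cg_snp,cg_sv Character vectors of highly effective SNP / SV ids
#'   (e.g. from [rof_select()]).
#' @param gwas_snp,gwas_sv Character vectors of GWAS-significant SNP / SV
#'   ids (may be empty).
#' @return A `marker_panels` tibble: `panel`, `marker`, `type`
#'   ("SNP"/"SV"), `provenance` ("cg", "gwas" or "both").
#' @export
build_panels <- function(cg_snp, cg_sv, gwas_snp = character(0),
                         gwas_sv = character(0)) {
  one <- function(panel, cg, gwas, types) {
    ids <- union(cg, gwas)
    if (length(ids) == 0) {
      return(tibble(panel = character(), marker = character(),
                    type = character(), provenance = character()))
    }
    tibble(panel = panel, marker = ids,
           type = types[ids],
           provenance = dplyr::case_when(
             ids %in% cg & ids %in% gwas ~ "both",
             ids %in% cg ~ "cg", TRUE ~ "gwas"))
  }
  types <- c(setNames(rep("SNP", length(union(cg_snp, gwas_snp))),
                      union(cg_snp, gwas_snp)),
             setNames(rep("SV", length(union(cg_sv, gwas_sv))),
                      union(cg_sv, gwas_sv)))
  out <- bind_rows(
    one("SNP_cg", cg_snp, character(0), types),
    one("SNP_cg_gwas", cg_snp, gwas_snp, types),
    one("SV_cg", cg_sv, character(0), types),
    one("SV_cg_gwas", cg_sv, gwas_sv, types),
    one("SNPSV_cg", union(cg_snp, cg_sv), character(0), types),
    one("SNPSV_cg_gwas", union(cg_snp, cg_sv), union(gwas_snp, gwas_sv), types)
  )
  class(out) <- c("marker_panels", class(out))
  out
}

#' @rdname build_panels
#' @param panels A `marker_panels` tibble.
#' @param name Panel name.
#' @export
panel_markers <- function(panels, name) {
  panels$marker[panels$panel == name]
}
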