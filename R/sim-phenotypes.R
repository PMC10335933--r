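#' Simulate additive multi-environment phenotypes
#'
#' Draws `n_causal` causal markers per trait from the combined SNP + PAV
#' dosage matrix, assigns N(0, 1) additive effects, and emits one phenotype
#' record per accession and environment:
#' `value = sum(effect * dosage) + env_effect + noise`, with Gaussian noise
#' scaled so the realized genic variance fraction equals the configured
#' heritability `h2` (noise sd = `sqrt(var(g) (1 - h2) / h2)`). With `h2 = 1`
#' the phenotype equals the additive genetic value plus the environment main
#' effect exactly; with `h2 = 0` the genic term is dropped and unit-variance
#' noise is used.
#'
#' @param genotypes Output of [simulate_genotypes()] (components `snp`, `pav`,
#'   `groups` are used). Missing dosages are mean-imputed for the genic value.
#' @param config A [sim_config()] object.
#' @return A list with `pheno` (tibble: accession, group, env, trait, value)
#'   and `truth` (tibble: trait, marker, type, effect; plus attribute
#'   `env_effects`).
#' @examples
#' cfg <- sim_config(n_snp = 100, n_pav = 50, n_causal = 5, seed = 1)
#' ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' head(ph$pheno)
#' @export
simulate_phenotypes <- function(genotypes, config) {
  cfg <- validate_sim_config(unclass(config))
  if (cfg$h2 > 0 && cfg$n_causal == 0) {
    abort("h2 > 0 requires at least one causal marker")
  }
  Z <- cbind(impute_mean(genotypes$snp$geno), impute_mean(genotypes$pav$geno))
  marker_type <- rep(c("SNP", "SV"),
                     c(ncol(genotypes$snp$geno), ncol(genotypes$pav$geno)))
  n_acc <- nrow(Z)
  groups <- genotypes$groups

  with_seed(sub_seed(cfg$seed, "phenotypes"), {
    env_eff <- cfg$env_effects %||% rnorm(cfg$n_env)
    envs <- sprintf("env%d", seq_len(cfg$n_env))
    out <- vector("list", cfg$n_trait)
    eff_tabs <- vector("list", cfg$n_trait)
    for (t in seq_len(cfg$n_trait)) {
      trait <- sprintf("trait%d", t)
      if (cfg$n_causal > 0) {
        causal <- sample.int(ncol(Z), cfg$n_causal)
        beta <- rnorm(cfg$n_causal)
        g <- drop(Z[, causal, drop = FALSE] %*% beta)
      } else {
        causal <- integer(0); beta <- numeric(0); g <- rep(0, n_acc)
      }
      vg <- var(g)
      if (cfg$h2 == 0 || vg == 0) {
        g <- rep(0, n_acc)
        noise_sd <- 1
      } else if (cfg$h2 == 1) {
        noise_sd <- 0
      } else {
        noise_sd <- sqrt(vg * (1 - cfg$h2) / cfg$h2)
      }
      rows <- map(seq_len(cfg$n_env), function(e) {
        tibble(accession = groups$accession, group = groups$group,
               env = envs[e], trait = trait,
               value = g + env_eff[e] + rnorm(n_acc, 0, noise_sd))
      })
      out[[t]] <- list_rbind(rows)
      eff_tabs[[t]] <- tibble(trait = trait,
                              marker = colnames(Z)[causal],
                              type = marker_type[causal],
                              effect = beta)
    }
    truth <- list_rbind(eff_tabs)
    attr(truth, "env_effects") <- setNames(env_eff, envs)
    list(pheno = list_rbind(out), truth = truth)
  })
}

#' Simulate a complete synthetic pan-genome study population
#'
#' One-call wrapper around the component generators: genotypes (SNPs + PAVs
#' with planted selected variants), gene-family presence matrix with designed
#' category shares, gene/TE annotations with planted TSDs and TE-derived PAVs,
#' and additive multi-environment phenotypes. Identical configurations
#' (including the seed) produce identical objects.
#'
#' @param config A [sim_config()] object.
#' @return A `pan_sim` list: `config`, `snp`, `pav` (records include flank and
#'   insert sequences), `groups`, `presence`, `genes`, `tes`, `pheno`, and
#'   `truth` (list: selected_pavs, families, tsd, causal_effects).
#' @examples
#' sim <- simulate_population(sim_config(n_snp = 100, n_pav = 50,
#'                                       n_family = 50, seed = 1))
#' names(sim)
#' @export
simulate_population <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  geno <- simulate_genotypes(cfg)
  fam <- simulate_families(cfg)
  ann <- simulate_annotations(cfg, pav = geno$pav)
  geno$pav$records <- ann$pav_records
  ph <- simulate_phenotypes(geno, cfg)
  structure(list(
    config = cfg,
    snp = geno$snp,
    pav = geno$pav,
    groups = geno$groups,
    presence = fam$presence,
    genes = ann$genes,
    tes = ann$tes,
    pheno = ph$pheno,
    truth = list(selected_pavs = geno$truth, families = fam$truth,
                 tsd = ann$truth, causal_effects = ph$truth)
  ), class = "pan_sim")
}

#' @export
print.pan_sim <- function(x, ...) {
  cat(sprintf(
    "<pan_sim> %d accessions (%s), %d SNPs, %d PAVs, %d families, %d genes, %d TEs\n",
    nrow(x$groups), paste(table(x$groups$group), collapse = "/"),
    ncol(x$snp$geno), nrow(x$pav$records), nrow(x$presence),
    nrow(x$genes), nrow(x$tes)))
  invisible(x)
}
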