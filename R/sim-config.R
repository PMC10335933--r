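#' Simulation configuration for a synthetic pan-genome population
#'
#' Builds and validates the configuration object consumed by
#' [simulate_population()] and the individual `simulate_*()` generators.
#' Defaults emulate a three-group (wild / landrace / cultivar) diversity panel
#' of 35/40/35 accessions with independent-locus Balding-Nichols drift between
#' groups, planted monotone-frequency "selected" PAVs, TE annotations with
#' planted target-site duplications, and additive multi-environment phenotypes
#' with known marker effects.
#'
#' @param n_wild,n_landrace,n_cultivar Accession counts per group.
#' @param n_snp Number of biallelic SNP markers.
#' @param n_pav Number of presence/absence variants (insertions/deletions
#'   >= 50 bp with binary carrier genotypes).
#' @param n_family Number of gene families in the presence matrix.
#' @param n_gene Number of gene models placed on the genome.
#' @param F_drift Balding-Nichols differentiation parameter in `[0, 1)`; the
#'   expected F_ST between any group and the ancestral pool is approximately
#'   `F_drift`. `0` means all groups share the ancestral frequencies.
#' @param n_selected_pav Number of planted monotone-frequency selected PAVs
#'   (split between domestication and improvement contrasts, gain and loss
#'   directions).
#' @param delta_f Planted frequency shift magnitude in the labeled contrast,
#'   in `(0, 1]`.
#' @param n_causal Causal markers per trait (drawn from SNPs and PAVs).
#' @param h2 Narrow-sense heritability per trait in `[0, 1]`.
#' @param n_env Number of environments; each accession is phenotyped once per
#'   environment.
#' @param n_trait Number of traits.
#' @param env_effects Optional numeric vector of environment main effects
#'   (length `n_env`); drawn from N(0, 1) when `NULL`.
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param te_fraction Fraction of the genome covered by TE intervals, `[0, 1]`.
#' @param tsd_fraction Fraction of insertion PAVs that carry a planted
#'   target-site duplication.
#' @param tsd_range Integer range (min, max) of planted TSD lengths in bp.
#' @param flank_len Length of simulated breakpoint flank sequences in bp.
#' @param missing_rate Per-genotype missingness rate.
#' @param family_shares Designed category shares (core, softcore, dispensable,
#'   private); must sum to 1.
#' @param seed Master RNG seed; identical configs (including seed) give
#'   byte-identical outputs.
#'
#' @return A `sim_config` object (validated named list).
#' @examples
#' cfg <- sim_config(n_snp = 200, n_pav = 100, n_family = 100, seed = 1)
#' cfg$F_drift
#' @export
sim_config <- function(n_wild = 35, n_landrace = 40, n_cultivar = 35,
                       n_snp = 2000, n_pav = 1000, n_family = 1000,
                       n_gene = 400,
                       F_drift = 0.05,
                       n_selected_pav = 30, delta_f = 0.5,
                       n_causal = 20, h2 = 0.5, n_env = 2, n_trait = 1,
                       env_effects = NULL,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       te_fraction = 0.6,
                       tsd_fraction = 0.5, tsd_range = c(4L, 10L),
                       flank_len = 50L,
                       missing_rate = 0.02,
                       family_shares = c(core = 0.25, softcore = 0.40,
                                         dispensable = 0.30, private = 0.05),
                       seed = 1L) {
  cfg <- list(
    n_wild = n_wild, n_landrace = n_landrace, n_cultivar = n_cultivar,
    n_snp = n_snp, n_pav = n_pav, n_family = n_family, n_gene = n_gene,
    F_drift = F_drift, n_selected_pav = n_selected_pav, delta_f = delta_f,
    n_causal = n_causal, h2 = h2, n_env = n_env, n_trait = n_trait,
    env_effects = env_effects, genome = genome, te_fraction = te_fraction,
    tsd_fraction = tsd_fraction, tsd_range = as.integer(tsd_range),
    flank_len = as.integer(flank_len), missing_rate = missing_rate,
    family_shares = family_shares, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_wild", "n_landrace", "n_cultivar", "n_snp", "n_pav",
              "n_family", "n_gene", "n_selected_pav", "n_causal", "n_env",
              "n_trait")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      abort(paste0("config field '", f, "' must be a single count >= 0"))
    }
  }
  if (cfg$F_drift < 0 || cfg$F_drift >= 1) abort("F_drift must be in [0, 1)")
  if (cfg$h2 < 0 || cfg$h2 > 1) abort("h2 must be in [0, 1]")
  if (cfg$delta_f <= 0 || cfg$delta_f > 1) abort("delta_f must be in (0, 1]")
  if (cfg$te_fraction < 0 || cfg$te_fraction > 1) {
    abort("te_fraction must be in [0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (is.null(names(cfg$genome)) || any(cfg$genome <= 0)) {
    abort("genome must be a named vector of positive chromosome lengths")
  }
  if (abs(sum(cfg$family_shares) - 1) > 1e-8) {
    abort("family_shares must sum to 1")
  }
  if (cfg$n_selected_pav > cfg$n_pav) {
    abort("n_selected_pav cannot exceed n_pav")
  }
  if (cfg$n_snp + cfg$n_pav > sum(cfg$genome)) {
    abort("marker counts exceed genome capacity")
  }
  if (!is.null(cfg$env_effects) && length(cfg$env_effects) != cfg$n_env) {
    abort("env_effects must have length n_env")
  }
  if (cfg$tsd_range[1] < 1 || cfg$tsd_range[2] < cfg$tsd_range[1]) {
    abort("tsd_range must be an increasing positive integer range")
  }
  if (cfg$flank_len < cfg$tsd_range[2]) {
    abort("flank_len must be at least the maximum TSD length")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  accessions: %d wild / %d landrace / %d cultivar\n",
              x$n_wild, x$n_landrace, x$n_cultivar))
  cat(sprintf("  markers: %d SNPs, %d PAVs (%d planted selected), %d families\n",
              x$n_snp, x$n_pav, x$n_selected_pav, x$n_family))
  cat(sprintf("  drift F = %.3f, delta_f = %.2f, h2 = %.2f, %d env, seed = %d\n",
              x$F_drift, x$delta_f, x$h2, x$n_env, x$seed))
  cat(sprintf("  genome: %s (TE fraction %.2f)\n",
              paste(sprintf("%s:%.1fMb", names(x$genome), x$genome / 1e6),
                    collapse = ", "), x$te_fraction))
  invisible(x)
}

n_accessions <- function(cfg) cfg$n_wild + cfg$n_landrace + cfg$n_cultivar

accession_table <- function(cfg) {
  tibble(
    accession = sprintf("acc%03d", seq_len(n_accessions(cfg))),
    group = factor(rep(group_levels,
                       c(cfg$n_wild, cfg$n_landrace, cfg$n_cultivar)),
                   levels = group_levels)
  )
}
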