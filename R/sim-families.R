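#' Simulate a gene-family presence matrix with designed category shares
#'
#' Generates a boolean family x accession occupancy matrix in which each
#' family's occupancy count is drawn inside the range of its designed
#' pan-genome category, so the truth labels are recovered exactly by
#' [classify_families()]: core families occupy all N accessions, soft-core
#' families `ceil(0.9 N) .. N-1`, dispensable families `2 .. ceil(0.9 N) - 1`,
#' and private families exactly one accession.
#'
#' @param config A [sim_config()] object; `family_shares` fixes the expected
#'   share of each category and `n_family` the number of families.
#' @return A list with `presence` (logical matrix, families x accessions) and
#'   `truth` (tibble: family, category, occupancy).
#' @examples
#' fam <- simulate_families(sim_config(n_family = 40, seed = 1))
#' table(fam$truth$category)
#' @export
simulate_families <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  if (cfg$n_family < 4) abort("n_family must be at least 4")
  N <- n_accessions(cfg)
  soft_lo <- ceiling(0.9 * N)
  if (soft_lo >= N || soft_lo <= 2) {
    abort("accession count too small for four distinct categories")
  }

  shares <- cfg$family_shares[c("core", "softcore", "dispensable", "private")]
  counts <- floor(shares * cfg$n_family)
  # largest-remainder rounding so counts sum to n_family
  rem <- shares * cfg$n_family - counts
  short <- cfg$n_family - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1
  }

  with_seed(sub_seed(cfg$seed, "families"), {
    occ <- c(
      rep(N, counts[["core"]]),
      sample(soft_lo:(N - 1), counts[["softcore"]], replace = TRUE),
      sample(2:(soft_lo - 1), counts[["dispensable"]], replace = TRUE),
      rep(1L, counts[["private"]])
    )
    category <- rep(c("core", "softcore", "dispensable", "private"), counts)
    ord <- sample.int(cfg$n_family)  # shuffle so categories are interleaved
    occ <- occ[ord]
    category <- category[ord]

    acc <- accession_table(cfg)$accession
    m <- matrix(FALSE, nrow = cfg$n_family, ncol = N,
                dimnames = list(sprintf("fam%05d", seq_len(cfg$n_family)), acc))
    for (i in seq_len(cfg$n_family)) {
      m[i, sample.int(N, occ[i])] <- TRUE
    }
    list(
      presence = m,
      truth = tibble(family = rownames(m), category = category,
                     occupancy = as.integer(occ))
    )
  })
}
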