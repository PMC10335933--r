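# Shared fixtures, built in code.

toy_presence <- function() {
  # 6 families x 5 accessions, occupancy 5,4,3,2,1,5
  m <- rbind(
    f1 = c(1, 1, 1, 1, 1),
    f2 = c(1, 1, 1, 1, 0),
    f3 = c(0, 1, 1, 1, 0),
    f4 = c(1, 0, 0, 1, 0),
    f5 = c(0, 0, 1, 0, 0),
    f6 = c(1, 1, 1, 1, 1)
  )
  colnames(m) <- paste0("a", 1:5)
  m
}

toy_groups <- function(n_w = 2, n_l = 2, n_c = 2) {
  n <- n_w + n_l + n_c
  tibble::tibble(
    accession = paste0("a", seq_len(n)),
    group = factor(rep(c("wild", "landrace", "cultivar"), c(n_w, n_l, n_c)),
                   levels = c("wild", "landrace", "cultivar"))
  )
}

small_cfg <- function(...) {
  sim_config(n_snp = 100, n_pav = 60, n_family = 60, n_gene = 40,
             n_causal = 5, genome = c(chr1 = 1e6, chr2 = 1e6), ...)
}

# Exhaustive growth-curve oracle: naive cumulative union/intersection over
# explicit accession sets, averaged over all orderings.
oracle_growth <- function(m) {
  N <- ncol(m)
  perms <- gtools_permutations(N)
  pan <- matrix(0, length(perms), N)
  core <- matrix(0, length(perms), N)
  for (k in seq_along(perms)) {
    ord <- perms[[k]]
    u <- rep(FALSE, nrow(m)); i <- rep(TRUE, nrow(m))
    for (j in seq_len(N)) {
      u <- u | m[, ord[j]] > 0
      i <- i & m[, ord[j]] > 0
      pan[k, j] <- sum(u); core[k, j] <- sum(i)
    }
  }
  list(pan_mean = colMeans(pan), core_mean = colMeans(core))
}

gtools_permutations <- function(N) {
  if (N == 1) return(list(1L))
  sub <- gtools_permutations(N - 1L)
  out <- list()
  for (p in sub) {
    for (i in seq_len(N)) out[[length(out) + 1]] <- append(p, N, after = i - 1)
  }
  out
}

# Brute-force two-sided Fisher p by enumeration over tables with fixed
# margins, probabilities from choose() products.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) return(1)
  xs <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, xs) * choose(m2, k - xs) / choose(n, k)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# All-pairs nucleotide diversity oracle over haplotype rows (0/1 matrix),
# per window of span L: mean pairwise difference per site summed over sites.
oracle_pi_haploid <- function(hap, span) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(hap[i, ] != hap[j, ], na.rm = TRUE)
    }
  }
  tot / choose(n, 2) / span
}
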