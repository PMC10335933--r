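#' Sliding windows tiling a genome
#'
#' @param genome Named vector of chromosome lengths (bp).
#' @param size Window size in bp (default 20000).
#' @param step Step between window starts in bp (default 2000).
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open; the last
#'   window on each chromosome is truncated at the chromosome end).
#' @export
make_windows <- function(genome, size = 20000, step = 2000) {
  stopifnot(size > 0, step > 0)
  list_rbind(imap(as.list(genome), function(len, chr) {
    start <- seq(0, max(0, len - 1), by = step)
    tibble(chrom = chr, start = start, end = pmin(start + size, len))
  }))
}

# per-site unbiased heterozygosity sum(2 * cA * ca / (n * (n - 1))) pieces:
# returns list(pi_site, n_alleles) for a dosage matrix (acc x site).
site_pi <- function(geno, ploidy = 2) {
  n_called <- colSums(!is.na(geno)) * ploidy
  alt <- colSums(geno, na.rm = TRUE)
  ref <- n_called - alt
  pi <- ifelse(n_called > 1, 2 * alt * ref / (n_called * (n_called - 1)), NA_real_)
  list(pi = pi, n = n_called)
}

#' Windowed nucleotide diversity
#'
#' Computes per-window nucleotide diversity for one accession group:
#' `pi = sum_sites 2 p q n/(n-1) / window_span`, i.e. unbiased per-site
#' heterozygosity computed from non-missing allele counts, summed over
#' variant sites in the window and divided by the full window span
#' (monomorphic and unobserved sites contribute zero difference). Windows
#' with zero genotyped haplotypes at every site are still reported (their
#' variant sum is zero); a window is masked (`NA`) only when it contains
#' sites but none with two called alleles.
#'
#' @param geno Dosage matrix, accessions x sites (0..ploidy, NA allowed).
#' @param positions Tibble with `chrom` and `pos` (0-based) per site, in
#'   column order of `geno`.
#' @param windows Window tibble from [make_windows()].
#' @param groups,group Optional groups table and group name to subset
#'   accessions; defaults to all rows of `geno`.
#' @param ploidy 2 for diploid dosages (default), 1 for haplotype matrices.
#' @return Tibble: `chrom`, `start`, `end`, `n_variants`, `pi`.
#' @export
window_pi <- function(geno, positions, windows, groups = NULL, group = NULL,
                      ploidy = 2) {
  if (!is.null(groups) && !is.null(group)) {
    acc <- groups$accession[groups$group == group]
    geno <- geno[rownames(geno) %in% acc, , drop = FALSE]
  }
  sp <- site_pi(geno, ploidy)
  window_sum(positions, windows, values = sp$pi,
             out_name = "pi", denom = "span")
}

# Shared machinery: sum per-site values over (possibly overlapping) windows
# via cumulative sums on position-sorted sites.
window_sum <- function(positions, windows, values, out_name, denom,
                       extra = NULL) {
  out <- windows
  out$n_variants <- 0L
  acc_cols <- c(out_name, names(extra))
  for (cn in acc_cols) out[[cn]] <- NA_real_

  for (chr in unique(windows$chrom)) {
    sel <- which(positions$chrom == chr)
    wsel <- which(windows$chrom == chr)
    if (length(wsel) == 0) next
    pos <- positions$pos[sel]
    ord <- order(pos)
    pos <- pos[ord]
    n_w <- length(wsel)
    lo <- findInterval(windows$start[wsel] - 0.5, pos)
    hi <- findInterval(windows$end[wsel] - 0.5, pos)
    count_in <- hi - lo
    out$n_variants[wsel] <- count_in

    sum_in_window <- function(v) {
      v <- v[sel][ord]
      ok <- !is.na(v)
      cs <- cumsum(ifelse(ok, v, 0))
      cs_n <- cumsum(ok)
      csum <- c(0, cs); cn <- c(0, cs_n)
      list(sum = csum[hi + 1] - csum[lo + 1], n_ok = cn[hi + 1] - cn[lo + 1])
    }

    main <- sum_in_window(values)
    span <- windows$end[wsel] - windows$start[wsel]
    main_val <- if (denom == "span") {
      ifelse(count_in > 0 & main$n_ok == 0, NA_real_, main$sum / span)
    } else {
      main$sum
    }
    out[[out_name]][wsel] <- main_val
    if (!is.null(extra)) {
      for (cn2 in names(extra)) {
        e <- sum_in_window(extra[[cn2]])
        out[[cn2]][wsel] <- e$sum
      }
    }
  }
  out
}

# Weir & Cockerham (1984) per-site variance components for two groups of
# diploids. Returns list(a, b, c) vectors over sites.
wc_components <- function(genoA, genoB) {
  comp_group <- function(g) {
    n <- colSums(!is.na(g))
    p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(g == 1, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- comp_group(genoA); B <- comp_group(genoB)
  r <- 2
  nbar <- (A$n + B$n) / r
  usable <- A$n >= 2 & B$n >= 2
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA; b[!usable] <- NA; cc[!usable] <- NA
  # monomorphic sites have a = b = c = 0 and are excluded from ratios
  poly <- pbar > 0 & pbar < 1
  a[!poly] <- NA; b[!poly] <- NA; cc[!poly] <- NA
  list(a = a, b = b, c = cc)
}

#' Windowed Weir & Cockerham F_ST
#'
#' Computes the Weir & Cockerham (1984) theta estimator between two groups,
#' windowed as a ratio of sums of the per-site variance components:
#' `F_ST(window) = sum(a) / sum(a + b + c)`. Monomorphic or unusable sites
#' (fewer than two genotyped accessions in either group) are excluded;
#' windows with no usable site are masked.
#'
#' @param geno Dosage matrix, accessions x sites (0/1/2, NA allowed).
#' @param positions Site positions tibble (`chrom`, `pos`).
#' @param windows Window tibble.
#' @param groups Groups table (`accession`, `group`).
#' @param group_a,group_b The two group labels (defaults wild, landrace).
#' @return Tibble: `chrom`, `start`, `end`, `n_variants`, `fst`.
#' @export
window_fst <- function(geno, positions, windows, groups,
                       group_a = "wild", group_b = "landrace") {
  accA <- groups$accession[groups$group == group_a]
  accB <- groups$accession[groups$group == group_b]
  if (length(intersect(accA, accB)) > 0) abort("groups must be disjoint")
  comp <- wc_components(geno[rownames(geno) %in% accA, , drop = FALSE],
                        geno[rownames(geno) %in% accB, , drop = FALSE])
  out <- window_sum(positions, windows, values = comp$a, out_name = "a_sum",
                    denom = "sum",
                    extra = list(abc_sum = comp$a + comp$b + comp$c))
  out$fst <- ifelse(!is.na(out$abc_sum) & out$abc_sum != 0,
                    out$a_sum / out$abc_sum, NA_real_)
  out %>% select("chrom", "start", "end", "n_variants", "fst")
}

#' Joint windowed diversity statistics for a selection scan
#'
#' Convenience wrapper computing, per window, the nucleotide diversity of two
#' groups, their ratio `pi_a / pi_b` (by convention pi_wild / pi_landrace: a
#' high ratio marks diversity loss in the derived group), and the Weir &
#' Cockerham F_ST.
#'
#' @inheritParams window_fst
#' @return A `window_stats` tibble: `chrom`, `start`, `end`, `n_variants`,
#'   `pi_a`, `pi_b`, `pi_ratio`, `fst`.
#' @export
diversity_scan <- function(geno, positions, windows, groups,
                           group_a = "wild", group_b = "landrace") {
  pa <- window_pi(geno, positions, windows, groups, group_a)
  pb <- window_pi(geno, positions, windows, groups, group_b)
  fs <- window_fst(geno, positions, windows, groups, group_a, group_b)
  out <- pa %>%
    rename(pi_a = "pi") %>%
    mutate(pi_b = pb$pi,
           pi_ratio = ifelse(!is.na(.data$pi_a) & !is.na(pb$pi) & pb$pi > 0,
                             .data$pi_a / pb$pi, NA_real_),
           fst = fs$fst)
  class(out) <- c("window_stats", class(out))
  out
}

#' Flag candidate selection windows by empirical quantile thresholds
#'
#' Computes, for each statistic column, the empirical `1 - quantile` cutoff
#' over finite window values and flags windows at or above it; a joint flag
#' marks windows exceeding every cutoff, the usual intersection rule for
#' combining pi-ratio and F_ST evidence.
#'
#' @param stats A `window_stats` tibble (or any window table).
#' @param quantile Upper tail mass per statistic (default 0.01).
#' @param columns Statistic columns to threshold
#'   (default `c("pi_ratio", "fst")`).
#' @return The input with logical `flag_<col>` columns and `flag_joint`,
#'   plus a `thresholds` attribute tibble (`statistic`, `quantile`,
#'   `cutoff`). Retrieve with [scan_thresholds()].
#' @export
scan_candidates <- function(stats, quantile = 0.01,
                            columns = c("pi_ratio", "fst")) {
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  columns <- intersect(columns, names(stats))
  thr <- map_dbl(columns, function(cn) {
    v <- stats[[cn]][is.finite(stats[[cn]])]
    if (length(v) < 1 / quantile) {
      warn(sprintf("fewer finite windows (%d) than 1/quantile for '%s'",
                   length(v), cn))
    }
    stats::quantile(v, 1 - quantile, na.rm = TRUE, names = FALSE)
  })
  out <- stats
  for (i in seq_along(columns)) {
    out[[paste0("flag_", columns[i])]] <-
      is.finite(out[[columns[i]]]) & out[[columns[i]]] >= thr[i]
  }
  flag_cols <- paste0("flag_", columns)
  out$flag_joint <- Reduce(`&`, out[flag_cols])
  attr(out, "thresholds") <- tibble(statistic = columns,
                                    quantile = quantile, cutoff = thr)
  out
}

#' @rdname scan_candidates
#' @export
scan_thresholds <- function(stats) attr(stats, "thresholds")
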