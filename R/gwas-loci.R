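#' Effective number of independent markers and significance thresholds
#'
#' Estimates the effective number of independent tests by a blockwise
#' eigenvalue (Li-Ji-style) method: markers are split into consecutive
#' non-overlapping blocks, the eigenvalues `lambda_i` of each block's LD
#' correlation matrix are mapped through
#' `f(lambda) = I(lambda >= 1) + (lambda - floor(lambda))`, and block
#' contributions are summed. Mutually independent markers give `M_eff = M`;
#' duplicating every marker halves it. Bonferroni thresholds `alpha / M_eff`
#' are reported for alpha 0.05 and 0.01, alongside plain Bonferroni on the
#' raw marker count.
#'
#' @param geno Dosage matrix, accessions x markers (mean-imputed internally;
#'   zero-variance markers dropped).
#' @param block_size Markers per block (default 1000).
#' @return List: `m_eff`, `m`, `thresholds` tibble (`alpha`, `threshold`,
#'   `bonferroni_raw`).
#' @export
effective_marker_number <- function(geno, block_size = 1000) {
  Z <- impute_mean(geno)
  keep <- apply(Z, 2, var) > 0
  Z <- Z[, keep, drop = FALSE]
  m <- ncol(Z)
  if (m == 0) abort("no polymorphic markers")
  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))
  m_eff <- sum(map_dbl(blocks, function(ix) {
    if (length(ix) == 1) return(1)
    cr <- suppressWarnings(cor(Z[, ix, drop = FALSE]))
    cr[!is.finite(cr)] <- 0; diag(cr) <- 1
    lam <- pmax(eigen(cr, symmetric = TRUE, only.values = TRUE)$values, 0)
    # snap to integers so exact duplicates (lambda = 2 up to rounding) do not
    # fall on the wrong side of the floor discontinuity
    lam <- ifelse(abs(lam - round(lam)) < 1e-9, round(lam), lam)
    sum((lam >= 1) + (lam - floor(lam)))
  }))
  alpha <- c(0.05, 0.01)
  list(
    m_eff = m_eff, m = m,
    thresholds = tibble(alpha = alpha,
                        threshold = alpha / m_eff,
                        bonferroni_raw = alpha / m)
  )
}

#' Greedy clustering of significant markers into association loci
#'
#' Repeatedly takes the unassigned significant marker with the smallest
#' p-value as a locus lead and assigns to its locus every unassigned
#' significant marker on the same chromosome within `dist_max` of the lead
#' and with genotype-dosage LD `R^2 >= r2_min` against the lead (pairwise
#' complete correlation). Equal p-values are broken by chromosome order then
#' position. The default significance cutoff `7.81e-8` is the Bonferroni
#' threshold `0.05 / 640288` on the effective marker number of the original
#' panel; pass your own (e.g. from [effective_marker_number()]).
#'
#' @param assoc An `assoc_result` tibble with `id`, `chrom`, `pos`, `p`.
#' @param geno Dosage matrix over the same markers (columns named by id).
#' @param p_max Significance cutoff (default 7.81e-8).
#' @param dist_max Maximum distance to the lead in bp (default 50000).
#' @param r2_min Minimum LD R^2 with the lead (default 0.3).
#' @return A `locus_set` tibble: one row per significant marker with
#'   `locus`, `lead` (logical), `id`, `chrom`, `pos`, `p`, `r2_with_lead`.
#'   [glance()] summarizes spans and detection class per locus.
#' @export
cluster_loci <- function(assoc, geno, p_max = 7.81e-8, dist_max = 50000,
                         r2_min = 0.3) {
  sig <- assoc %>%
    filter(!is.na(.data$p), .data$p <= p_max) %>%
    arrange(.data$p, match(.data$chrom, unique(assoc$chrom)), .data$pos)
  out <- sig %>%
    mutate(locus = NA_integer_, lead = FALSE, r2_with_lead = NA_real_)
  if (nrow(sig) == 0) {
    class(out) <- c("locus_set", class(out))
    return(out)
  }
  unassigned <- rep(TRUE, nrow(sig))
  locus_id <- 0L
  while (any(unassigned)) {
    locus_id <- locus_id + 1L
    i <- which(unassigned)[1]  # smallest p among unassigned (pre-sorted)
    g_lead <- geno[, sig$id[i]]
    cand <- which(unassigned & sig$chrom == sig$chrom[i] &
                    abs(sig$pos - sig$pos[i]) <= dist_max)
    r2 <- vapply(cand, function(j) {
      suppressWarnings(cor(g_lead, geno[, sig$id[j]],
                           use = "pairwise.complete.obs"))^2
    }, numeric(1))
    take <- cand[cand == i | (!is.na(r2) & r2 >= r2_min)]
    out$locus[take] <- locus_id
    out$r2_with_lead[take] <- r2[match(take, cand)]
    out$lead[i] <- TRUE
    unassigned[take] <- FALSE
  }
  class(out) <- c("locus_set", class(out))
  out
}

#' @export
glance.locus_set <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(locus = integer(), chrom = character(), start = numeric(),
                  end = numeric(), n_markers = integer(),
                  lead_id = character(), lead_p = numeric(),
                  detection = character()))
  }
  x %>%
    group_by(.data$locus) %>%
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos), end = max(.data$pos),
      n_markers = n(),
      lead_id = .data$id[.data$lead][1],
      lead_p = min(.data$p),
      detection = {
        tps <- if ("type" %in% names(x)) unique(.data$type) else "unknown"
        if (all(tps == "SNP")) "SNP-only"
        else if (all(tps == "SV")) "SV-only"
        else if (all(tps == "unknown")) "unknown" else "both"
      },
      .groups = "drop"
    )
}

#' Candidate genes around locus leads
#'
#' Lists genes whose interval intersects the window
#' `[lead_pos - window, lead_pos + window]` around each locus lead marker.
#'
#' @param loci A `locus_set` from [cluster_loci()].
#' @param genes Gene tibble (gene_id, chrom, start, end).
#' @param window Half-window in bp (default 50000).
#' @return Tibble: `locus`, `lead_id`, `gene_id`, `distance` (0 when the
#'   lead lies inside the gene).
#' @export
candidate_genes <- function(loci, genes, window = 50000) {
  leads <- loci %>% filter(.data$lead)
  if (nrow(leads) == 0) {
    return(tibble(locus = integer(), lead_id = character(),
                  gene_id = character(), distance = numeric()))
  }
  res <- pmap(list(leads$locus, leads$id, leads$chrom, leads$pos),
              function(loc, id, chr, pos) {
    sel <- genes$chrom == chr &
      genes$end >= pos - window & genes$start <= pos + window
    g <- genes[sel, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    dist <- pmax(0, pmax(g$start - pos, pos - g$end))
    tibble(locus = loc, lead_id = id, gene_id = g$gene_id, distance = dist)
  })
  list_rbind(res[!vapply(res, is.null, logical(1))])
}

#' SV-SNP linkage-disequilibrium complementarity
#'
#' For each SV, computes the maximum squared Pearson correlation between its
#' carrier dosage vector and every SNP within `flank` bp of the SV interval
#' on the same chromosome (pairwise-complete accessions). An SV is untagged
#' when no flanking SNP reaches `R^2 >= r2_cut` (or no flanking SNP exists);
#' the untagged fraction measures the association signal that SNP-only scans
#' would miss. Monomorphic SVs are excluded and counted.
#'
#' @param sv_geno SV carrier matrix (accessions x SVs, columns named).
#' @param sv_records SV records tibble (id, chrom, start, end).
#' @param snp_geno SNP dosage matrix.
#' @param snp_info SNP info tibble (id, chrom, pos).
#' @param flank Flanking distance in bp (default 50000).
#' @param r2_cut Tagging threshold (default 0.5).
#' @return An `ld_complement` tibble: `sv`, `n_snps`, `max_r2`, `tagged`;
#'   attributes `untagged_fraction`, `n_excluded`. [glance()] summarizes.
#' @export
sv_snp_ld_complement <- function(sv_geno, sv_records, snp_geno, snp_info,
                                 flank = 50000, r2_cut = 0.5) {
  v <- apply(sv_geno, 2, function(x) var(x, na.rm = TRUE))
  poly <- !is.na(v) & v > 0
  n_excluded <- sum(!poly)
  recs <- sv_records[sv_records$id %in% colnames(sv_geno)[poly], , drop = FALSE]
  # only SNPs actually present in the (possibly filtered) genotype matrix
  snp_info <- snp_info[snp_info$id %in% colnames(snp_geno), , drop = FALSE]

  rows <- pmap(list(recs$id, recs$chrom, recs$start, recs$end),
               function(id, chr, s, e) {
    sel <- which(snp_info$chrom == chr &
                   snp_info$pos >= s - flank & snp_info$pos <= e + flank)
    if (length(sel) == 0) {
      return(tibble(sv = id, n_snps = 0L, max_r2 = NA_real_, tagged = FALSE))
    }
    r <- suppressWarnings(
      cor(sv_geno[, id], snp_geno[, snp_info$id[sel], drop = FALSE],
          use = "pairwise.complete.obs"))
    mx <- suppressWarnings(max(r^2, na.rm = TRUE))
    if (!is.finite(mx)) mx <- NA_real_
    tibble(sv = id, n_snps = length(sel), max_r2 = mx,
           tagged = !is.na(mx) && mx >= r2_cut)
  })
  out <- list_rbind(rows)
  attr(out, "untagged_fraction") <- mean(!out$tagged)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "r2_cut") <- r2_cut
  attr(out, "flank") <- flank
  class(out) <- c("ld_complement", class(out))
  out
}

#' @export
glance.ld_complement <- function(x, ...) {
  tibble(n_sv = nrow(x),
         untagged_fraction = attr(x, "untagged_fraction"),
         n_excluded = attr(x, "n_excluded"),
         r2_cut = attr(x, "r2_cut"), flank = attr(x, "flank"))
}
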