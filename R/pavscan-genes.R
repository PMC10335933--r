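# Interval helpers: panpav uses 0-based half-open coordinates internally and
# converts to 1-based closed only when building IRanges/GRanges objects.

pav_granges <- function(records) {
  # zero-length insertion intervals are represented by their 1-bp breakpoint
  end0 <- pmax(records$end, records$start + 1)
  GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1, end = end0),
    id = records$id
  )
}

interval_granges <- function(df, id_col = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = pmax(df$end, df$start + 1)),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if (!is.null(id_col)) S4Vectors::mcols(gr)$id <- df[[id_col]]
  gr
}

#' Map PAVs to genes and promoters
#'
#' Associates a PAV with a gene when it intersects the gene body or the
#' promoter window of `promoter_len` bp upstream of the annotated
#' transcription start, taken strand-aware (upstream of `start` on `+`
#' genes, upstream of `end` on `-` genes). Genes with unknown strand (`*` or
#' `.`) take the promoter on both sides and are flagged in the output.
#'
#' @param pav_records Tibble of PAV records (id, chrom, start, end; 0-based
#'   half-open), or a `pav_set`.
#' @param genes Tibble of gene intervals (gene_id, chrom, start, end, strand).
#' @param promoter_len Promoter window length in bp (default 2000).
#' @return Tibble of associations: `pav`, `gene_id`, `region` ("body" or
#'   "promoter"), `strand_unknown`.
#' @export
map_pavs_to_genes <- function(pav_records, genes, promoter_len = 2000) {
  if (inherits(pav_records, "pav_set")) pav_records <- pav_records$records
  pav_gr <- pav_granges(pav_records)

  body <- interval_granges(genes)
  unknown <- !(genes$strand %in% c("+", "-"))
  prom_start <- ifelse(genes$strand == "-", genes$end,
                       pmax(genes$start - promoter_len, 0))
  prom_end <- ifelse(genes$strand == "-", genes$end + promoter_len,
                     genes$start)
  prom <- list(
    tibble(chrom = genes$chrom, start = prom_start, end = prom_end,
           gene_id = genes$gene_id, unknown = unknown)
  )
  if (any(unknown)) {
    # both-sided promoter for unknown strand: add the other side too
    g2 <- genes[unknown, ]
    prom[[2]] <- tibble(chrom = g2$chrom, start = g2$end,
                        end = g2$end + promoter_len,
                        gene_id = g2$gene_id, unknown = TRUE)
  }
  prom <- list_rbind(prom) %>% filter(.data$end > .data$start)

  hits_body <- GenomicRanges::findOverlaps(pav_gr, body)
  assoc_body <- tibble(
    pav = pav_records$id[S4Vectors::queryHits(hits_body)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits_body)],
    region = "body",
    strand_unknown = unknown[S4Vectors::subjectHits(hits_body)]
  )
  assoc_prom <- if (nrow(prom) > 0) {
    prom_gr <- interval_granges(prom)
    hits_prom <- GenomicRanges::findOverlaps(pav_gr, prom_gr)
    tibble(
      pav = pav_records$id[S4Vectors::queryHits(hits_prom)],
      gene_id = prom$gene_id[S4Vectors::subjectHits(hits_prom)],
      region = "promoter",
      strand_unknown = prom$unknown[S4Vectors::subjectHits(hits_prom)]
    )
  } else {
    tibble(pav = character(), gene_id = character(), region = character(),
           strand_unknown = logical())
  }
  bind_rows(assoc_body, assoc_prom) %>%
    distinct(.data$pav, .data$gene_id, .data$region, .keep_all = TRUE) %>%
    arrange(.data$pav, .data$gene_id)
}

#' Distance profile of PAVs to the nearest gene
#'
#' Bins the distance from each PAV to its nearest gene into doubling bins
#' (0 for overlapping, then (0,1kb], (1,2kb], (2,4kb], (4,8kb], (8,16kb],
#' (16,32kb], >32kb), the standard display of PAV density against gene
#' distance.
#'
#' @inheritParams map_pavs_to_genes
#' @return Tibble: `bin` (ordered factor), `n`.
#' @export
pav_distance_profile <- function(pav_records, genes) {
  if (inherits(pav_records, "pav_set")) pav_records <- pav_records$records
  pav_gr <- pav_granges(pav_records)
  gene_gr <- interval_granges(genes)
  d <- rep(NA_real_, length(pav_gr))
  hits <- GenomicRanges::distanceToNearest(pav_gr, gene_gr)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  breaks <- c(-1, 0, 1000, 2000, 4000, 8000, 16000, 32000, Inf)
  labels <- c("0", "(0,1kb]", "(1,2kb]", "(2,4kb]", "(4,8kb]",
              "(8,16kb]", "(16,32kb]", ">32kb")
  bin <- cut(d, breaks = breaks, labels = labels, right = TRUE)
  tibble(bin = factor(labels, levels = labels)) %>%
    left_join(tibble(bin = bin) %>% count(.data$bin), by = "bin") %>%
    mutate(n = if_else(is.na(.data$n), 0L, .data$n))
}

#' TE overlap fraction of PAVs with a permutation enrichment test
#'
#' Computes the fraction of PAVs intersecting at least one TE interval, and a
#' one-sided enrichment p-value against a null in which each PAV is placed
#' uniformly at random on its own chromosome (length preserved) `n_perm`
#' times: `p = (1 + #[null >= observed]) / (1 + n_perm)`.
#'
#' @param pav_records PAV records tibble or `pav_set`.
#' @param tes TE interval tibble (chrom, start, end; 0-based half-open).
#' @param genome Named vector of chromosome lengths.
#' @param n_perm Number of placements (default 999).
#' @param seed RNG seed for placements.
#' @return A `te_enrichment` tibble (one row): `observed_fraction`,
#'   `null_mean_fraction`, `p_value`, `n_perm`, `n_pav`, `n_skipped`.
#' @export
te_overlap_enrichment <- function(pav_records, tes, genome, n_perm = 999,
                                  seed = 1) {
  if (inherits(pav_records, "pav_set")) pav_records <- pav_records$records
  width <- pmax(pav_records$end - pav_records$start, 1)
  ok <- width <= genome[pav_records$chrom]
  if (any(!ok)) {
    warn(sprintf("%d PAV(s) longer than their chromosome skipped", sum(!ok)))
  }
  recs <- pav_records[ok, , drop = FALSE]
  width <- width[ok]
  n_pav <- nrow(recs)
  if (n_pav == 0 || nrow(tes) == 0) {
    return(structure(
      tibble(observed_fraction = 0, null_mean_fraction = 0, p_value = 1,
             n_perm = n_perm, n_pav = n_pav, n_skipped = sum(!ok)),
      class = c("te_enrichment", class(tibble()))))
  }
  te_gr <- interval_granges(tes)
  obs <- overlap_fraction(recs$chrom, recs$start, width, te_gr)

  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      start <- floor(runif(n_pav, 0, genome[recs$chrom] - width + 1))
      overlap_fraction(recs$chrom, start, width, te_gr)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(
    tibble(observed_fraction = obs, null_mean_fraction = mean(null),
           p_value = p, n_perm = n_perm, n_pav = n_pav, n_skipped = sum(!ok)),
    class = c("te_enrichment", class(tibble())))
}

overlap_fraction <- function(chrom, start0, width, te_gr) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1,
                                                width = width))
  mean(IRanges::overlapsAny(gr, te_gr))
}
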