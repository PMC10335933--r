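#' Simulate gene models, TE intervals and PAV breakpoint sequences
#'
#' Places non-overlapping gene intervals along the configured genome, tiles TE
#' intervals so that they cover approximately `te_fraction` of the genome, and
#' (when a PAV set is supplied) attaches breakpoint flank sequences to
#' insertion/deletion records. A configured fraction of insertion PAVs carries
#' a planted target-site duplication (TSD): an exact duplicated k-mer ending at
#' the left breakpoint and beginning at the right breakpoint, with length drawn
#' uniformly from `tsd_range`. A subset of deletion PAVs is re-positioned to
#' span a single intact TE (reciprocal overlap 1) with a planted TSD, forming
#' the planted high-confidence TE-derived set.
#'
#' Planted TSDs are guaranteed recoverable at their exact length: single-base
#' run TSDs are resampled and the bases immediately outside the duplicated
#' k-mer are forced to differ from its termini, so the duplication cannot
#' extend by chance.
#'
#' @param config A [sim_config()] object.
#' @param pav Optional `pav_set` from [simulate_genotypes()]; when supplied,
#'   flank sequences, TSDs and planted TE-derived PAVs are generated and the
#'   updated records are returned.
#' @return A list with `genes` (tibble: gene_id, chrom, start, end, strand;
#'   0-based half-open), `tes` (tibble: te_id, chrom, start, end, intact),
#'   `pav_records` (updated records with flank_left/flank_right/seq columns,
#'   or NULL), and `truth` (tibble of planted TSDs / TE-derived labels).
#' @examples
#' ann <- simulate_annotations(sim_config(seed = 1))
#' head(ann$genes)
#' @export
simulate_annotations <- function(config, pav = NULL) {
  cfg <- validate_sim_config(unclass(config))
  with_seed(sub_seed(cfg$seed, "annotations"), {
    genes <- sim_genes(cfg)
    tes <- sim_tes(cfg)
    out <- list(genes = genes, tes = tes, pav_records = NULL,
                truth = tibble(pav = character(), tsd = character(),
                               tsd_len = integer(), te_derived = logical()))
    if (!is.null(pav)) {
      seqs <- sim_pav_sequences(cfg, pav$records, tes)
      out$pav_records <- seqs$records
      out$tes <- seqs$tes
      out$truth <- seqs$truth
    }
    out
  })
}

# Non-overlapping gene models: one gene per slot of a regular partition.
sim_genes <- function(cfg) {
  per_chr <- setNames(pmax(1L, round(cfg$n_gene * cfg$genome /
                                       sum(cfg$genome))),
                      names(cfg$genome))
  recs <- imap(as.list(per_chr), function(k, chr) {
    len <- cfg$genome[[chr]]
    slot <- floor(len / k)
    glen <- pmin(pmax(round(exp(rnorm(k, log(3000), 0.5))), 500),
                 floor(slot * 0.5))
    start <- (seq_len(k) - 1) * slot +
      floor(runif(k, 0, pmax(1, slot - glen - 1)))
    tibble(chrom = chr, start = as.numeric(start),
           end = as.numeric(start + glen),
           strand = sample(c("+", "-"), k, replace = TRUE))
  })
  genes <- list_rbind(recs)
  genes %>%
    mutate(gene_id = sprintf("gene%05d", seq_len(nrow(genes)))) %>%
    select("gene_id", "chrom", "start", "end", "strand")
}

# Alternating TE / gap tiling; expected coverage equals te_fraction.
sim_tes <- function(cfg) {
  f <- cfg$te_fraction
  if (f == 0) {
    return(tibble(te_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), intact = logical()))
  }
  mean_te <- 3000
  recs <- imap(as.list(cfg$genome), function(len, chr) {
    # draw enough intervals to cross the chromosome
    n_guess <- ceiling(len / (mean_te / f)) + 50
    te_len <- pmax(round(exp(rnorm(n_guess, log(mean_te) - 0.245, 0.7))), 100)
    gap <- if (f >= 1) rep(0, n_guess) else {
      round(stats::rexp(n_guess, rate = f / (mean_te * (1 - f))))
    }
    start <- cumsum(gap) + cumsum(c(0, head(te_len, -1)))
    end <- start + te_len
    keep <- start < len
    tibble(chrom = chr, start = as.numeric(start[keep]),
           end = as.numeric(pmin(end[keep], len)))
  })
  tes <- list_rbind(recs)
  tes %>%
    mutate(te_id = sprintf("te%05d", seq_len(nrow(tes))),
           intact = runif(nrow(tes)) < 0.7) %>%
    select("te_id", "chrom", "start", "end", "intact")
}

# Breakpoint flanks, planted TSDs, and planted TE-derived deletions.
sim_pav_sequences <- function(cfg, records, tes) {
  n <- nrow(records)
  fl <- cfg$flank_len
  records$flank_left <- random_dna(n, fl)
  records$flank_right <- random_dna(n, fl)
  records$seq <- NA_character_
  ins <- which(records$type == "INS")
  records$seq[ins] <- random_dna(length(ins), records$length[ins])

  truth <- tibble(pav = character(), tsd = character(), tsd_len = integer(),
                  te_derived = logical())

  plant <- function(rec_idx) {
    k <- sample(seq(cfg$tsd_range[1], cfg$tsd_range[2]), length(rec_idx),
                replace = TRUE)
    vapply(seq_along(rec_idx), function(j) {
      i <- rec_idx[j]
      repeat {
        tsd <- random_dna(1, k[j])
        if (length(unique(strsplit(tsd, "")[[1]])) > 1) break
      }
      bases <- c("A", "C", "G", "T")
      first <- substr(tsd, 1, 1); last <- substr(tsd, k[j], k[j])
      guard_l <- sample(setdiff(bases, first), 1)
      guard_r <- sample(setdiff(bases, last), 1)
      left <- records$flank_left[i]
      records$flank_left[i] <<- paste0(
        substr(left, 1, fl - k[j] - 1), guard_l, tsd)
      right <- records$flank_right[i]
      records$flank_right[i] <<- paste0(
        tsd, guard_r, substr(right, k[j] + 2, fl))
      tsd
    }, character(1))
  }

  tsd_ids <- character(0); tsd_seqs <- character(0)
  if (cfg$tsd_fraction > 0 && length(ins) > 0) {
    n_tsd <- round(cfg$tsd_fraction * length(ins))
    if (n_tsd > 0) {
      pick <- sort(sample(ins, n_tsd))
      tsd_seqs <- plant(pick)
      tsd_ids <- records$id[pick]
    }
  }

  # planted TE-derived deletions: re-position some DELs onto single intact TEs
  dels <- which(records$type == "DEL")
  intact <- tes[tes$intact, , drop = FALSE]
  ted_ids <- character(0)
  if (length(dels) > 0 && nrow(intact) > 0) {
    n_ted <- min(length(dels), max(5L, round(0.1 * length(dels))))
    pick_del <- sort(sample(dels, n_ted))
    pick_te <- sample.int(nrow(intact), n_ted,
                          replace = n_ted > nrow(intact))
    records$chrom[pick_del] <- intact$chrom[pick_te]
    records$start[pick_del] <- intact$start[pick_te]
    records$end[pick_del] <- intact$end[pick_te]
    records$length[pick_del] <- intact$end[pick_te] - intact$start[pick_te]
    ted_seqs <- plant(pick_del)
    ted_ids <- records$id[pick_del]
    tsd_ids <- c(tsd_ids, ted_ids)
    tsd_seqs <- c(tsd_seqs, ted_seqs)
  }

  truth <- tibble(pav = tsd_ids, tsd = tsd_seqs,
                  tsd_len = nchar(tsd_seqs),
                  te_derived = tsd_ids %in% ted_ids)
  list(records = records, tes = tes, truth = truth)
}
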