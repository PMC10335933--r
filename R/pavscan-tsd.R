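#' Detect a target-site duplication at an insertion breakpoint
#'
#' Searches for the longest exact duplicated k-mer that ends at the left
#' breakpoint and begins at the right breakpoint (i.e. a suffix of the left
#' flank equal to a prefix of the right flank), for k in `[k_min, k_max]`
#' (default 4-10 bp). Such a duplication is the classic footprint of a
#' transposon insertion. The longest match is reported; at a given length
#' the breakpoint-anchored candidate is unique, so longer matches take
#' precedence over shorter ones.
#'
#' @param flank_left Sequence ending at the left breakpoint (its last base is
#'   the base immediately before the insertion point).
#' @param flank_right Sequence beginning at the right breakpoint.
#' @param k_min,k_max Inclusive TSD length range searched.
#' @return A list with `found` (logical), `length`, `seq`, and `reason`
#'   (NA when found; "no duplication" or "flank too short" otherwise).
#' @examples
#' detect_tsd("TTTTTACGTA", "ACGTAGGGGG")  # recovers ACGTA, length 5
#' @export
detect_tsd <- function(flank_left, flank_right, k_min = 4, k_max = 10) {
  nl <- nchar(flank_left); nr <- nchar(flank_right)
  if (is.na(nl) || is.na(nr) || nl < k_min || nr < k_min) {
    return(list(found = FALSE, length = NA_integer_, seq = NA_character_,
                reason = "flank too short"))
  }
  for (k in seq(min(k_max, nl, nr), k_min)) {
    suf <- substr(flank_left, nl - k + 1, nl)
    pre <- substr(flank_right, 1, k)
    if (suf == pre) {
      return(list(found = TRUE, length = as.integer(k), seq = suf,
                  reason = NA_character_))
    }
  }
  list(found = FALSE, length = NA_integer_, seq = NA_character_,
       reason = "no duplication")
}

#' Scan a PAV table for target-site duplications
#'
#' Applies [detect_tsd()] to every record carrying both flank sequences.
#'
#' @param pav_records PAV records tibble (or `pav_set`) with `flank_left` and
#'   `flank_right` columns.
#' @inheritParams detect_tsd
#' @return Tibble: `pav`, `tsd_found`, `tsd_len`, `tsd_seq`, `reason`.
#' @export
tsd_scan <- function(pav_records, k_min = 4, k_max = 10) {
  if (inherits(pav_records, "pav_set")) pav_records <- pav_records$records
  if (!all(c("flank_left", "flank_right") %in% names(pav_records))) {
    abort("pav_records must carry flank_left and flank_right sequences")
  }
  res <- map2(pav_records$flank_left, pav_records$flank_right,
              function(l, r) detect_tsd(l, r, k_min, k_max))
  tibble(
    pav = pav_records$id,
    tsd_found = map_dbl(res, function(x) x$found) > 0,
    tsd_len = map_int(res, function(x) x$length),
    tsd_seq = vapply(res, function(x) x$seq, character(1)),
    reason = vapply(res, function(x) x$reason, character(1))
  )
}

#' Call high-confidence TE-derived PAVs
#'
#' A PAV is classified as high-confidence TE-derived when (i) its reference
#' interval intersects exactly one intact TE, (ii) the reciprocal overlap
#' (overlap length divided by each interval's length) is at least
#' `min_overlap`, and (iii) a target-site duplication is detected at its
#' breakpoints. Breakpoint-to-junction distances
#' (`|start - TE start|`, `|end - TE end|`) are emitted for the single-TE
#' candidates. Zero-length insertion records cannot satisfy the reciprocal
#' overlap rule and are reported as not TE-derived.
#'
#' @param pav_records PAV records tibble or `pav_set` (flank columns required
#'   for the TSD condition).
#' @param tes TE tibble with `intact` logical column.
#' @param min_overlap Reciprocal overlap fraction (default 0.8).
#' @inheritParams detect_tsd
#' @return Tibble: `pav`, `te_derived`, `n_intact_te`, `te_id`,
#'   `reciprocal_overlap`, `tsd_found`, `dist_left_junction`,
#'   `dist_right_junction`.
#' @export
classify_te_derived <- function(pav_records, tes, min_overlap = 0.8,
                                k_min = 4, k_max = 10) {
  if (inherits(pav_records, "pav_set")) pav_records <- pav_records$records
  intact <- tes[tes$intact, , drop = FALSE]
  tsd <- tsd_scan(pav_records, k_min, k_max)

  pav_gr <- pav_granges(pav_records)
  out <- tibble(
    pav = pav_records$id, te_derived = FALSE, n_intact_te = 0L,
    te_id = NA_character_, reciprocal_overlap = NA_real_,
    tsd_found = tsd$tsd_found,
    dist_left_junction = NA_real_, dist_right_junction = NA_real_
  )
  if (nrow(intact) == 0) return(out)

  te_gr <- interval_granges(intact, id_col = "te_id")
  hits <- GenomicRanges::findOverlaps(pav_gr, te_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n_hits <- tabulate(qh, nbins = nrow(pav_records))
  out$n_intact_te <- as.integer(n_hits)

  single <- which(n_hits == 1)
  if (length(single) == 0) return(out)
  te_of <- sh[match(single, qh)]

  p_len <- pav_records$end[single] - pav_records$start[single]
  t_len <- intact$end[te_of] - intact$start[te_of]
  ov <- pmax(0, pmin(pav_records$end[single], intact$end[te_of]) -
                pmax(pav_records$start[single], intact$start[te_of]))
  recip <- ifelse(p_len > 0 & t_len > 0, pmin(ov / p_len, ov / t_len), 0)

  out$te_id[single] <- intact$te_id[te_of]
  out$reciprocal_overlap[single] <- recip
  out$dist_left_junction[single] <-
    abs(pav_records$start[single] - intact$start[te_of])
  out$dist_right_junction[single] <-
    abs(pav_records$end[single] - intact$end[te_of])
  out$te_derived <- out$n_intact_te == 1L &
    !is.na(out$reciprocal_overlap) & out$reciprocal_overlap >= min_overlap &
    out$tsd_found
  out
}
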