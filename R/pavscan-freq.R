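#' Per-group PAV carrier frequencies
#'
#' Computes, for every PAV, the carrier frequency within each accession group
#' as carriers / non-missing genotypes; missing genotypes are excluded from
#' both numerator and denominator. Translocation (TRA) records are excluded
#' from frequency computation (their carrier semantics are ambiguous) but are
#' retained in the input object.
#'
#' @param pav A `pav_set` (list with `records` tibble and accession x PAV
#'   carrier matrix `geno` in 0/1/NA), or a bare carrier matrix.
#' @param groups Tibble with columns `accession` and `group` (levels wild,
#'   landrace, cultivar).
#' @return A `pav_frequencies` tibble: `pav`, then per group `f_<group>`
#'   (NaN when the group has zero non-missing calls), carrier counts
#'   `k_<group>` and non-missing counts `n_<group>`.
#' @examples
#' g <- matrix(c(1, 1, 0, NA), nrow = 4,
#'             dimnames = list(paste0("a", 1:4), "pav1"))
#' grp <- tibble::tibble(accession = paste0("a", 1:4),
#'                       group = c("wild", "wild", "landrace", "cultivar"))
#' pav_frequencies(g, grp)
#' @export
pav_frequencies <- function(pav, groups) {
  geno <- if (is.matrix(pav)) pav else pav$geno
  ids <- colnames(geno) %||% sprintf("pav%05d", seq_len(ncol(geno)))
  if (!is.matrix(pav) && !is.null(pav$records$type)) {
    keep <- pav$records$type != "TRA"
    geno <- geno[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  groups <- check_groups(groups, rownames(geno))
  out <- tibble(pav = ids)
  for (g in group_levels) {
    acc <- groups$accession[groups$group == g]
    sub <- geno[rownames(geno) %in% acc, , drop = FALSE]
    k <- unname(colSums(sub == 1, na.rm = TRUE))
    n <- unname(colSums(!is.na(sub)))
    out[[paste0("f_", g)]] <- ifelse(n > 0, k / n, NaN)
    out[[paste0("k_", g)]] <- as.integer(k)
    out[[paste0("n_", g)]] <- as.integer(n)
  }
  class(out) <- c("pav_frequencies", class(out))
  out
}

#' Vectorized two-sided Fisher exact test for 2x2 tables
#'
#' Computes the two-sided Fisher exact p-value for tables
#' `[[a, b], [c, d]]` by summing all hypergeometric point probabilities not
#' exceeding that of the observed table (with the conventional `1 + 1e-7`
#' relative tolerance for ties). Inputs are recycled; duplicate tables are
#' de-duplicated internally, so scanning many markers with bounded group
#' sizes is fast. A table with an empty margin returns p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer vectors: row one is `a, b` (e.g.
#'   carriers / non-carriers in group one), row two is `c, d`.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_exact(5, 5, 5, 5)        # 1
#' fisher_exact(10, 0, 0, 10)      # ~1.08e-5
#' @export
fisher_exact <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    abort("fisher_exact requires non-negative integer counts")
  }
  key <- paste(a, b, c, d, sep = ",")
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    fisher_p_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
  unname(pu[match(key, key[uk])])
}

fisher_p_one <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Scan PAV frequencies for domestication- or improvement-selected variants
#'
#' Tests each PAV's carrier counts between the two groups of the requested
#' contrast (domestication: wild vs landrace; improvement: landrace vs
#' cultivar) with a two-sided Fisher exact test, applies Benjamini-Hochberg
#' adjustment across all tested PAVs, and flags PAVs with `q <= q_max` and
#' `|delta_f| >= min_delta`. PAVs with zero non-missing calls in either group
#' are masked (not tested). The defaults operationalize "substantially
#' different frequencies" as FDR 0.01 together with a 0.25 absolute
#' frequency shift.
#'
#' @param freqs A `pav_frequencies` tibble from [pav_frequencies()].
#' @param contrast `"domestication"` or `"improvement"`.
#' @param q_max Maximum BH-adjusted q-value (default 0.01).
#' @param min_delta Minimum absolute carrier-frequency difference
#'   (default 0.25).
#' @return A `selection_calls` tibble: `pav`, `contrast`, `f_low`, `f_high`
#'   (frequencies in the earlier and later group of the contrast), `delta_f`
#'   (later minus earlier), `p`, `q`, `flagged`.
#' @export
scan_selected <- function(freqs, contrast = c("domestication", "improvement"),
                          q_max = 0.01, min_delta = 0.25) {
  contrast <- match.arg(contrast)
  pair <- if (contrast == "domestication") c("wild", "landrace")
          else c("landrace", "cultivar")
  k1 <- freqs[[paste0("k_", pair[1])]]; n1 <- freqs[[paste0("n_", pair[1])]]
  k2 <- freqs[[paste0("k_", pair[2])]]; n2 <- freqs[[paste0("n_", pair[2])]]
  testable <- n1 > 0 & n2 > 0
  p <- rep(NA_real_, nrow(freqs))
  p[testable] <- fisher_exact(k1[testable], n1[testable] - k1[testable],
                              k2[testable], n2[testable] - k2[testable])
  q <- rep(NA_real_, nrow(freqs))
  q[testable] <- p.adjust(p[testable], method = "BH")
  delta <- k2 / n2 - k1 / n1
  out <- tibble(
    pav = freqs$pav, contrast = contrast,
    f_low = k1 / n1, f_high = k2 / n2, delta_f = delta,
    p = p, q = q,
    flagged = testable & !is.na(q) & q <= q_max & abs(delta) >= min_delta
  )
  class(out) <- c("selection_calls", class(out))
  out
}

#' Classify favorable PAVs from selection calls
#'
#' A flagged domestication or improvement PAV is a favorable PAV (favPAV)
#' when its carrier frequency changes monotonically across
#' wild -> landrace -> cultivar: direction "gain" requires
#' `f_wild <= f_landrace <= f_cultivar`, direction "loss" the reverse, with
#' the inequality strict in the flagged contrast. PAVs flagged in both
#' contrasts qualify if either contrast's rule holds.
#'
#' @param calls A `selection_calls` tibble (rows from one or both contrasts,
#'   e.g. `dplyr::bind_rows(scan_selected(f, "domestication"),
#'   scan_selected(f, "improvement"))`).
#' @param freqs The `pav_frequencies` tibble used for the scan.
#' @return Tibble: `pav`, `favpav` (logical), `direction` ("gain", "loss" or
#'   NA), `source_contrast` (contrast justifying the call, NA when none); one
#'   row per PAV appearing in `calls`.
#' @export
classify_favpav <- function(calls, freqs) {
  fr <- freqs %>% select("pav", "f_wild", "f_landrace", "f_cultivar")
  flagged <- calls %>% filter(.data$flagged) %>%
    left_join(fr, by = "pav")

  eval_one <- function(f_w, f_l, f_c, contrast) {
    if (anyNA(c(f_w, f_l, f_c))) return(NA_character_)
    strict_dom <- contrast == "domestication"
    gain <- (f_w <= f_l) && (f_l <= f_c) &&
      (if (strict_dom) f_w < f_l else f_l < f_c)
    loss <- (f_w >= f_l) && (f_l >= f_c) &&
      (if (strict_dom) f_w > f_l else f_l > f_c)
    if (gain) "gain" else if (loss) "loss" else NA_character_
  }

  verdicts <- flagged %>%
    mutate(direction = pmap(list(.data$f_wild, .data$f_landrace,
                                 .data$f_cultivar, .data$contrast),
                            eval_one) %>% unlist()) %>%
    filter(!is.na(.data$direction)) %>%
    group_by(.data$pav) %>%
    slice(1) %>%
    ungroup() %>%
    select("pav", "direction", source_contrast = "contrast")

  tibble(pav = unique(calls$pav)) %>%
    left_join(verdicts, by = "pav") %>%
    mutate(favpav = !is.na(.data$direction)) %>%
    select("pav", "favpav", "direction", "source_contrast")
}
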