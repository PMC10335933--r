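test_that("windows tile each chromosome with the configured size and step", {
  w <- make_windows(c(chr1 = 100000, chr2 = 4500), size = 20000, step = 2000)
  w1 <- w[w$chrom == "chr1", ]
  expect_equal(w1$start, seq(0, 98000, by = 2000))
  expect_true(all(w1$end - w1$start <= 20000))
  expect_equal(max(w1$end), 100000)
  # every bp is covered by the window starting at its own offset class
  w2 <- w[w$chrom == "chr2", ]
  expect_equal(w2$end[nrow(w2)], 4500)
})

test_that("identical accessions give zero diversity everywhere", {
  geno <- matrix(2L, 10, 20, dimnames = list(paste0("a", 1:10), NULL))
  pos <- tibble::tibble(chrom = "chr1", pos = seq(100, 2000, by = 100))
  w <- make_windows(c(chr1 = 2100), size = 1000, step = 500)
  pi <- window_pi(geno, pos, w)
  expect_true(all(pi$pi == 0))
})

test_that("two haplotypes differing at d sites over L bp give pi = d/L", {
  L <- 1000; d <- 7
  hap <- rbind(a1 = rep(0L, 10), a2 = c(rep(1L, 7), rep(0L, 3)))
  pos <- tibble::tibble(chrom = "chr1", pos = seq(50, 950, by = 100))
  w <- tibble::tibble(chrom = "chr1", start = 0, end = L)
  pi <- window_pi(hap, pos, w, ploidy = 1)
  expect_equal(pi$pi, d / L, tolerance = 1e-15)
})

test_that("windowed pi equals the all-pairs difference oracle", {
  set.seed(41)
  hap <- matrix(rbinom(8 * 30, 1, 0.4), 8, 30,
                dimnames = list(paste0("h", 1:8), NULL))
  pos <- tibble::tibble(chrom = "chr1", pos = sort(sample(0:999, 30)))
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  pi <- window_pi(hap, pos, w, ploidy = 1)
  expect_equal(pi$pi, oracle_pi_haploid(hap, 1000), tolerance = 1e-12)
})

test_that("pi is invariant to accession order and fully-missing sites", {
  set.seed(43)
  hap <- matrix(rbinom(6 * 20, 1, 0.5), 6, 20,
                dimnames = list(paste0("h", 1:6), NULL))
  pos <- tibble::tibble(chrom = "chr1", pos = seq(0, 950, by = 50))
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  base <- window_pi(hap, pos, w, ploidy = 1)$pi
  shuf <- window_pi(hap[sample(6), , drop = FALSE], pos, w, ploidy = 1)$pi
  expect_equal(shuf, base, tolerance = 1e-15)
  hap_na <- cbind(hap, matrix(NA_integer_, 6, 3))
  pos_na <- dplyr::bind_rows(pos, tibble::tibble(chrom = "chr1",
                                                 pos = c(10, 20, 30)))
  expect_equal(window_pi(hap_na, pos_na, w, ploidy = 1)$pi, base,
               tolerance = 1e-15)
})

test_that("single-site F_ST matches hand-evaluated Weir-Cockerham components", {
  # group A: genotypes 0,0,1,2 ; group B: 2,2,1,1 (diploid dosages)
  geno <- matrix(c(0, 0, 1, 2, 2, 2, 1, 1), ncol = 1,
                 dimnames = list(paste0("a", 1:8), "s1"))
  grp <- tibble::tibble(accession = paste0("a", 1:8),
                        group = rep(c("wild", "landrace"), each = 4))
  pos <- tibble::tibble(chrom = "chr1", pos = 10)
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  got <- window_fst(geno, pos, w, grp)$fst

  # direct transcription of Weir & Cockerham (1984), r = 2
  n1 <- 4; n2 <- 4
  p1 <- sum(c(0, 0, 1, 2)) / 8; p2 <- sum(c(2, 2, 1, 1)) / 8
  h1 <- 1 / 4; h2 <- 2 / 4
  r <- 2; nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(got, a / (a + b + cc), tolerance = 1e-12)
})

test_that("fixed differences drive F_ST towards 1 and identical groups to 0", {
  n <- 200
  geno_fix <- rbind(matrix(0L, n, 5), matrix(2L, n, 5))
  rownames(geno_fix) <- paste0("a", 1:(2 * n))
  grp <- tibble::tibble(accession = paste0("a", 1:(2 * n)),
                        group = rep(c("wild", "landrace"), each = n))
  pos <- tibble::tibble(chrom = "chr1", pos = (1:5) * 10)
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  expect_gt(window_fst(geno_fix, pos, w, grp)$fst, 0.99)

  set.seed(47)
  p <- runif(50, 0.2, 0.8)
  geno_same <- matrix(rbinom(2 * n * 50, 2, rep(p, each = 2 * n)), 2 * n, 50,
                      dimnames = list(paste0("a", 1:(2 * n)), NULL))
  pos2 <- tibble::tibble(chrom = "chr1", pos = seq(1, 99, by = 2))
  fst0 <- window_fst(geno_same, pos2, w, grp)$fst
  expect_lt(abs(fst0), 0.02)
})

test_that("monomorphic windows are masked", {
  geno <- matrix(2L, 10, 4, dimnames = list(paste0("a", 1:10), NULL))
  grp <- tibble::tibble(accession = paste0("a", 1:10),
                        group = rep(c("wild", "landrace"), each = 5))
  pos <- tibble::tibble(chrom = "chr1", pos = (1:4) * 10)
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  expect_true(is.na(window_fst(geno, pos, w, grp)$fst))
})

test_that("scan_candidates flags the configured upper tail and the median", {
  stats <- tibble::tibble(chrom = "chr1", start = 0:999 * 100,
                          end = 0:999 * 100 + 100, n_variants = 1L,
                          pi_ratio = seq(0, 1, length.out = 1000),
                          fst = seq(0, 1, length.out = 1000))
  flagged <- scan_candidates(stats, quantile = 0.01)
  expect_equal(sum(flagged$flag_pi_ratio), 10, tolerance = 1)
  thr <- scan_thresholds(flagged)
  expect_equal(thr$cutoff[thr$statistic == "fst"],
               quantile(stats$fst, 0.99, names = FALSE), tolerance = 1e-12)
  med <- scan_candidates(stats, quantile = 0.5)
  thr_med <- scan_thresholds(med)
  expect_equal(thr_med$cutoff[1], median(stats$pi_ratio), tolerance = 0.01)
})

test_that("a synthetic sweep region is flagged by the pi-ratio scan", {
  set.seed(53)
  n_site <- 400
  pos <- tibble::tibble(chrom = "chr1", pos = sort(sample(0:99999, n_site)))
  p <- runif(n_site, 0.2, 0.8)
  n_per <- 40
  wild <- matrix(rbinom(n_per * n_site, 2, rep(p, each = n_per)), n_per)
  land <- matrix(rbinom(n_per * n_site, 2, rep(p, each = n_per)), n_per)
  # ablate diversity in landrace over 40-60 kb: near-fixation
  sweep_sites <- which(pos$pos >= 40000 & pos$pos < 60000)
  land[, sweep_sites] <- rbinom(n_per * length(sweep_sites), 2, 0.005)
  geno <- rbind(wild, land)
  rownames(geno) <- paste0("a", 1:(2 * n_per))
  grp <- tibble::tibble(accession = rownames(geno),
                        group = rep(c("wild", "landrace"), each = n_per))
  w <- make_windows(c(chr1 = 1e5), size = 20000, step = 2000)
  stats <- diversity_scan(geno, pos, w, grp)
  flagged <- scan_candidates(stats, quantile = 0.1)
  inside <- flagged$flag_pi_ratio[flagged$start >= 40000 &
                                    flagged$end <= 60000]
  outside <- flagged$flag_pi_ratio[flagged$end <= 30000]
  expect_gt(mean(inside), 0.8)
  expect_lt(mean(outside, na.rm = TRUE), 0.2)
})
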