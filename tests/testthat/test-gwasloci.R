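test_that("kinship matches a naive centered cross-product oracle", {
  set.seed(61)
  G <- matrix(rbinom(10 * 20, 2, 0.4), 10, 20,
              dimnames = list(paste0("a", 1:10), paste0("m", 1:20)))
  K <- kinship(G)
  # naive double loop
  p <- colMeans(G) / 2
  Zc <- sweep(G, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K_naive <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    K_naive[i, j] <- sum(Zc[i, ] * Zc[j, ]) / denom
  }
  expect_equal(unname(K), K_naive, tolerance = 1e-12)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("identical accessions give a constant kinship matrix", {
  # identical rows make every marker monomorphic across the panel
  G <- matrix(rep(rbinom(15, 2, 0.5), each = 6), nrow = 6)
  rownames(G) <- paste0("a", 1:6)
  expect_warning(K <- kinship(G), "polymorphic")
  expect_equal(max(K) - min(K), 0, tolerance = 1e-12)
})

test_that("with identity kinship and no PCs the LMM reduces to OLS", {
  set.seed(63)
  n <- 80
  G <- matrix(rbinom(n * 40, 2, 0.4), n, 40,
              dimnames = list(paste0("a", 1:n), paste0("m", 1:40)))
  y <- rnorm(n) + G[, 3] * 0.5
  res <- lmm_assoc(G, setNames(y, rownames(G)), diag(n), n_pc = 0)
  for (j in c(1, 3, 17, 40)) {
    ols <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(res$p[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(res$beta[j], ols[2, 1], tolerance = 1e-8)
  }
})

test_that("permuted phenotypes give approximately uniform p-values", {
  cfg <- sim_config(n_wild = 70, n_landrace = 70, n_cultivar = 60,
                    n_snp = 1000, n_pav = 0, n_family = 10, n_gene = 10,
                    n_selected_pav = 0, n_causal = 5, h2 = 0.5, n_env = 1,
                    env_effects = 0, seed = 64)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)$pheno
  y <- setNames(ph$value, ph$accession)
  set.seed(1)
  y_perm <- setNames(sample(y), names(y))
  G <- filter_markers(geno$snp$geno)
  K <- kinship(G)
  res <- lmm_assoc(G, y_perm, K, n_pc = 5)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the mixed model controls structure-driven inflation better than OLS", {
  # two strongly drifted groups and a structured phenotype: naive OLS p-values
  # are inflated; the LMM with kinship should be closer to uniform
  ks_stat <- function(p) suppressWarnings(ks.test(p, "punif"))$statistic
  stats <- vapply(1:5, function(s) {
    cfg <- sim_config(n_wild = 60, n_landrace = 60, n_cultivar = 0,
                      n_snp = 400, n_pav = 0, n_family = 10, n_gene = 10,
                      n_selected_pav = 0, n_causal = 0, h2 = 0,
                      F_drift = 0.2, n_env = 1, env_effects = 0,
                      seed = 700 + s)
    geno <- simulate_genotypes(cfg)
    grp_eff <- ifelse(geno$groups$group == "wild", 0, 1.5)
    y <- setNames(grp_eff + rnorm(nrow(geno$groups)),
                  geno$groups$accession)
    G <- filter_markers(geno$snp$geno)
    lmm <- lmm_assoc(G, y, kinship(G), n_pc = 0)
    ols <- lmm_assoc(G, y, diag(length(y)), n_pc = 0)
    c(lmm = ks_stat(lmm$p), ols = ks_stat(ols$p))
  }, numeric(2))
  expect_lt(mean(stats["lmm.D", ]), mean(stats["ols.D", ]))
})

test_that("a marker explaining 20% of variance is found at Bonferroni level", {
  hits <- vapply(1:10, function(s) {
    set.seed(800 + s)
    n <- 300; m <- 500
    G <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m, byrow = TRUE,
                dimnames = list(paste0("a", 1:n), paste0("m", 1:m)))
    g <- G[, 250]
    beta <- sqrt(0.2 / 0.8 / var(g))
    y <- setNames(g * beta + rnorm(n), rownames(G))
    res <- lmm_assoc(G, y, kinship(G), n_pc = 0)
    res$p[250] < 0.05 / m
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("effective marker number handles independent and duplicated markers", {
  set.seed(67)
  n <- 500
  G <- matrix(rbinom(n * 40, 2, 0.5), n, 40,
              dimnames = list(NULL, paste0("m", 1:40)))
  m_ind <- effective_marker_number(G, block_size = 40)
  expect_equal(m_ind$m_eff, 40, tolerance = 2)
  # duplicated-pair blocks: eigenvalues (2, 0) per block, so M_eff = M
  G2 <- G[, rep(1:40, each = 2)]
  colnames(G2) <- paste0("m", 1:80)
  m_dup <- effective_marker_number(G2, block_size = 2)
  expect_equal(m_dup$m_eff, 40, tolerance = 1e-9)
  expect_equal(m_dup$thresholds$threshold, 0.05 / m_dup$m_eff * c(1, 0.2),
               tolerance = 1e-12)
  # invariance to marker order within a block
  m_one <- effective_marker_number(G2, block_size = 80)
  m_shuf <- effective_marker_number(G2[, sample(80)], block_size = 80)
  expect_equal(m_shuf$m_eff, m_one$m_eff, tolerance = 1e-8)
})

test_that("exactly orthogonal columns give M_eff = M", {
  G <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  colnames(G) <- paste0("m", 1:3)
  expect_equal(effective_marker_number(G, block_size = 3)$m_eff, 3,
               tolerance = 1e-9)
})

test_that("two exactly duplicated columns give M_eff = M / 2", {
  set.seed(68)
  g <- rbinom(200, 2, 0.5)
  G <- cbind(m1 = g, m2 = g)
  expect_equal(effective_marker_number(G, block_size = 2)$m_eff, 1,
               tolerance = 1e-9)
})

test_that("locus clustering follows the distance and LD rules", {
  n <- 100
  set.seed(71)
  g1 <- rbinom(n, 2, 0.5)
  g_ld <- g1; flip <- sample(n, 3); g_ld[flip] <- 2 - g_ld[flip]  # high R2
  g_far <- rbinom(n, 2, 0.5)
  g_lowld <- rbinom(n, 2, 0.5)
  G <- cbind(mA = g1, mB = g_ld, mC = g_far, mD = g_lowld)
  rownames(G) <- paste0("a", 1:n)
  assoc <- tibble::tibble(
    id = c("mA", "mB", "mC", "mD"),
    chrom = "chr1",
    pos = c(100000, 110000, 170000, 115000),
    p = c(1e-12, 1e-9, 1e-10, 1e-9))
  loci <- cluster_loci(assoc, G, p_max = 1e-5)
  by_id <- setNames(loci$locus, loci$id)
  # mB: 10 kb away, high R2 -> same locus as the mA lead
  expect_equal(by_id[["mB"]], by_id[["mA"]])
  # mC: 70 kb away -> separate locus regardless of LD
  expect_false(by_id[["mC"]] == by_id[["mA"]])
  # mD: 15 kb away but independent genotype (R2 < 0.3) -> separate locus
  expect_false(by_id[["mD"]] == by_id[["mA"]])
  # leads carry the smallest p of their locus; output partitions markers
  expect_true(all(table(loci$locus) >= 1))
  expect_true(loci$lead[loci$id == "mA"])
  gl <- glance(loci)
  expect_equal(nrow(gl), length(unique(loci$locus)))
})

test_that("clustering returns an empty set with no significant markers", {
  assoc <- tibble::tibble(id = "m1", chrom = "chr1", pos = 1, p = 0.5)
  G <- cbind(m1 = rbinom(10, 2, 0.5))
  expect_equal(nrow(cluster_loci(assoc, G)), 0)
})

test_that("candidate genes respect the 50-kb window boundary", {
  loci <- structure(
    tibble::tibble(locus = 1L, lead = TRUE, id = "m1", chrom = "chr1",
                   pos = 100000, p = 1e-10),
    class = c("locus_set", class(tibble::tibble())))
  genes <- tibble::tibble(
    gene_id = c("at_lead", "near", "far"),
    chrom = "chr1",
    start = c(99000, 149000, 150100), end = c(101000, 149900, 151000))
  got <- candidate_genes(loci, genes, window = 50000)
  expect_setequal(got$gene_id, c("at_lead", "near"))
  expect_equal(got$distance[got$gene_id == "at_lead"], 0)
  # brute force check
  brute <- genes$gene_id[genes$end >= 50000 & genes$start <= 150000]
  expect_setequal(got$gene_id, brute)
})

test_that("SV-SNP LD complement matches a brute-force correlation oracle", {
  set.seed(73)
  n <- 60
  snp <- matrix(rbinom(n * 30, 2, 0.5), n, 30,
                dimnames = list(paste0("a", 1:n), paste0("s", 1:30)))
  snp_info <- tibble::tibble(id = paste0("s", 1:30), chrom = "chr1",
                             pos = (1:30) * 10000)
  sv <- cbind(v1 = snp[, 5] > 0, v2 = rbinom(n, 1, 0.5),
              v3 = rep(0L, n))  # v3 monomorphic
  storage.mode(sv) <- "integer"
  rownames(sv) <- rownames(snp)
  sv_rec <- tibble::tibble(id = c("v1", "v2", "v3"), chrom = "chr1",
                           start = c(50000, 1e6, 50), end = c(50100, 1e6 + 100, 150))
  got <- sv_snp_ld_complement(sv, sv_rec, snp, snp_info, flank = 50000,
                              r2_cut = 0.5)
  expect_equal(nrow(got), 2)           # monomorphic excluded
  expect_equal(attr(got, "n_excluded"), 1L)
  # v2 has no SNP within 50 kb of 1 Mb -> untagged
  expect_false(got$tagged[got$sv == "v2"])
  # brute force max R2 for v1 over SNPs within [0, 100100]
  sel <- snp_info$pos >= 0 & snp_info$pos <= 100100
  r2 <- cor(sv[, "v1"], snp[, sel])^2
  expect_equal(got$max_r2[got$sv == "v1"], max(r2), tolerance = 1e-12)
})

test_that("untagged fraction is monotone in flank and r2 cutoff", {
  set.seed(74)
  n <- 50
  snp <- matrix(rbinom(n * 40, 2, 0.5), n, 40,
                dimnames = list(paste0("a", 1:n), paste0("s", 1:40)))
  snp_info <- tibble::tibble(id = paste0("s", 1:40), chrom = "chr1",
                             pos = (1:40) * 5000)
  sv <- matrix(rbinom(n * 10, 1, 0.5), n, 10,
               dimnames = list(rownames(snp), paste0("v", 1:10)))
  sv_rec <- tibble::tibble(id = paste0("v", 1:10), chrom = "chr1",
                           start = (1:10) * 18000, end = (1:10) * 18000 + 100)
  uf <- function(flank, cut) {
    attr(sv_snp_ld_complement(sv, sv_rec, snp, snp_info, flank, cut),
         "untagged_fraction")
  }
  expect_gte(uf(10000, 0.5), uf(50000, 0.5))
  expect_lte(uf(50000, 0.3), uf(50000, 0.8))
})
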