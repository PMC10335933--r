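make_gs_data <- function(n = 200, m = 50, h2 = 0.8, n_causal = 5, seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m, byrow = TRUE,
              dimnames = list(paste0("a", 1:n), paste0("m", 1:m)))
  causal <- seq_len(n_causal)
  beta <- rnorm(n_causal, 0, 1)
  g <- drop(G[, causal, drop = FALSE] %*% beta)
  noise_sd <- if (h2 >= 1) 0 else sqrt(var(g) * (1 - h2) / h2)
  y <- setNames(g + rnorm(n, 0, noise_sd), rownames(G))
  list(G = G, y = y, beta = beta, causal = causal, g = g)
}

test_that("feature gain is non-negative and zero for constant markers", {
  d <- make_gs_data(seed = 2)
  d$G[, 50] <- 1L  # constant marker
  imp <- feature_gain(d$G, d$y, nrounds = 50)
  expect_true(all(is.finite(imp$fg)))
  expect_true(all(imp$fg >= 0))
  expect_equal(imp$fg[imp$marker == "m50"], 0)
  expect_equal(min(imp$rof), 0)
  expect_error(feature_gain(d$G, setNames(rep(1, 200), rownames(d$G))),
               "constant")
})

test_that("a single strong causal marker attains the maximum feature gain", {
  hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 500; m <- 100
    G <- matrix(rbinom(n * m, 2, 0.5), n, m,
                dimnames = list(paste0("a", 1:n), paste0("m", 1:m)))
    g <- G[, 42]
    y <- setNames(g + rnorm(n, 0, sqrt(var(g))), rownames(G))  # h2 = 0.5
    imp <- feature_gain(G, y, nrounds = 80, seed = s)
    imp$marker[which.max(imp$fg)] == "m42"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("rof_select keeps exactly the markers with FG >= 1% of the max", {
  imp <- tibble::tibble(marker = paste0("m", 1:5),
                        fg = c(1, 0.5, 0.011, 0.01, 0.005))
  sel <- rof_select(imp, rof_max = 0.99)
  expect_setequal(sel, c("m1", "m2", "m3", "m4"))  # 0.005 -> ROF 0.995
  # scale invariance
  imp2 <- imp; imp2$fg <- imp$fg * 1234.5
  expect_identical(rof_select(imp2, 0.99), sel)
  # all equal -> all selected; all zero -> empty with warning
  imp3 <- tibble::tibble(marker = c("a", "b"), fg = c(2, 2))
  expect_setequal(rof_select(imp3), c("a", "b"))
  imp0 <- tibble::tibble(marker = c("a", "b"), fg = c(0, 0))
  expect_warning(sel0 <- rof_select(imp0), "zero")
  expect_length(sel0, 0)
})

test_that("the six panels follow their set-algebra definitions", {
  p <- build_panels(cg_snp = c("s1", "s2"), cg_sv = c("v1"),
                    gwas_snp = c("s2", "s3"), gwas_sv = c("v2"))
  expect_setequal(panel_markers(p, "SNP_cg"), c("s1", "s2"))
  expect_setequal(panel_markers(p, "SNP_cg_gwas"), c("s1", "s2", "s3"))
  expect_setequal(panel_markers(p, "SV_cg"), "v1")
  expect_setequal(panel_markers(p, "SV_cg_gwas"), c("v1", "v2"))
  expect_setequal(panel_markers(p, "SNPSV_cg"), c("s1", "s2", "v1"))
  expect_setequal(panel_markers(p, "SNPSV_cg_gwas"),
                  c("s1", "s2", "s3", "v1", "v2"))
  # provenance of a marker in both sources
  expect_identical(
    p$provenance[p$panel == "SNP_cg_gwas" & p$marker == "s2"], "both")
  # empty GWAS sets leave the cg panels unchanged
  p0 <- build_panels(c("s1"), c("v1"))
  expect_setequal(panel_markers(p0, "SNP_cg_gwas"),
                  panel_markers(p0, "SNP_cg"))
  # disjoint sets of sizes a and b give a union of size a + b
  pd <- build_panels(paste0("s", 1:3), character(0), paste0("t", 1:4))
  expect_length(panel_markers(pd, "SNP_cg_gwas"), 7)
  # every *_gwas panel is a superset of its *_cg panel
  for (nm in c("SNP", "SV", "SNPSV")) {
    expect_true(all(panel_markers(p, paste0(nm, "_cg")) %in%
                      panel_markers(p, paste0(nm, "_cg_gwas"))))
  }
})

test_that("cross-validation is deterministic and near-perfect without noise", {
  d <- make_gs_data(n = 150, m = 30, h2 = 1, seed = 3)
  cv1 <- cross_validate(d$G, d$y, reps = 10, seed = 5)
  cv2 <- cross_validate(d$G, d$y, reps = 10, seed = 5)
  expect_identical(cv1$r, cv2$r)
  expect_gte(glance(cv1)$mean_r, 0.99)
  # unchanged (up to fitting noise) when non-causal markers join the panel
  cv_small <- cross_validate(d$G[, d$causal, drop = FALSE], d$y,
                             reps = 10, seed = 5)
  expect_equal(glance(cv_small)$mean_r, glance(cv1)$mean_r, tolerance = 0.01)
})

test_that("pure-noise phenotypes give precision centred on zero", {
  set.seed(7)
  n <- 200
  G <- matrix(rbinom(n * 20, 2, 0.5), n, 20,
              dimnames = list(paste0("a", 1:n), paste0("m", 1:20)))
  y <- setNames(rnorm(n), rownames(G))
  cv <- cross_validate(G, y, reps = 50, seed = 9)
  n_test <- attr(cv, "n_test")
  expect_lt(abs(glance(cv)$mean_r), 3 / sqrt(50 * n_test))
})

test_that("the 580/100 split convention applies at exactly 680 accessions", {
  d <- make_gs_data(n = 680, m = 10, seed = 11)
  cv <- cross_validate(d$G, d$y, reps = 2, seed = 1)
  expect_equal(attr(cv, "n_train"), 580)
  expect_equal(attr(cv, "n_test"), 100)
})

test_that("breeding enumeration matches the closed-form additive optimum", {
  d <- make_gs_data(n = 100, m = 12, h2 = 1, n_causal = 12, seed = 13)
  model <- gebv_fit(d$G, d$y, method = "ridge", lambda = 1e-8)
  imp <- tibble::tibble(marker = colnames(d$G), fg = abs(model$fit$beta))
  rep_ <- enumerate_breeding(model, d$G, imp, top_k = 12)
  expect_equal(rep_$n_combinations, 4096)
  # closed form: set markers with positive effect to max dosage, others to 0
  beta <- model$fit$beta
  alt <- apply(d$G, 2, max)
  best_geno <- ifelse(beta > 0, alt, 0)
  pred_best <- predict(model, matrix(best_geno, nrow = 1,
                                     dimnames = list(NULL, names(beta))))
  expect_equal(rep_$gebv_max_haplotype, unname(pred_best), tolerance = 1e-8)
  gebv_all <- predict(model, d$G)
  expect_equal(rep_$gebv_max_cultivated, max(gebv_all), tolerance = 1e-10)
  expect_equal(rep_$improvement_pct,
               (unname(pred_best) - max(gebv_all)) / max(gebv_all) * 100,
               tolerance = 1e-8)
  expect_gte(rep_$gebv_max_haplotype, max(gebv_all) - 1e-10)
})

test_that("enumeration refuses above the cap and is exact at the boundary", {
  d <- make_gs_data(n = 50, m = 25, seed = 15)
  model <- gebv_fit(d$G, d$y)
  imp <- tibble::tibble(marker = colnames(d$G), fg = 25:1)
  expect_error(enumerate_breeding(model, d$G, imp, top_k = 21), "cap")
  ok <- enumerate_breeding(model, d$G, imp, top_k = 8)
  expect_equal(ok$n_combinations, 256)
  expect_identical(ok$top_markers, paste0("m", 1:8))
})

test_that("zero improvement when the best haplotype equals the best accession", {
  # all negative effects: optimal haplotype zeroes every enumerated marker
  n <- 40
  G <- matrix(rbinom(n * 5, 2, 0.5), n, 5,
              dimnames = list(paste0("a", 1:n), paste0("m", 1:5)))
  G[1, ] <- 0  # an accession already at the optimum
  y <- setNames(drop(G %*% rep(-1, 5)), rownames(G))
  model <- gebv_fit(G, y, lambda = 1e-8)
  imp <- tibble::tibble(marker = colnames(G), fg = 5:1)
  rep_ <- enumerate_breeding(model, G, imp, top_k = 5)
  expect_equal(rep_$improvement_pct, 0, tolerance = 1e-6)
})

test_that("SV-causal traits favor panels that include SVs", {
  set.seed(17)
  n <- 250
  snp <- matrix(rbinom(n * 30, 2, 0.5), n, 30,
                dimnames = list(paste0("a", 1:n), paste0("s", 1:30)))
  sv <- matrix(rbinom(n * 10, 1, 0.5), n, 10,
               dimnames = list(paste0("a", 1:n), paste0("v", 1:10)))
  g <- drop(sv[, 1:3] %*% c(2, -1.5, 1))
  y <- setNames(g + rnorm(n, 0, sd(g) * 0.5), paste0("a", 1:n))
  cv_snp <- cross_validate(snp, y, reps = 15, seed = 3)
  cv_both <- cross_validate(cbind(snp, sv), y, reps = 15, seed = 3)
  expect_gt(glance(cv_both)$mean_r, glance(cv_snp)$mean_r - 0.02)
})

test_that("gbm and ridge predictors share the model contract", {
  d <- make_gs_data(n = 150, m = 20, h2 = 0.9, seed = 19)
  for (method in c("ridge", "gbm")) {
    m <- gebv_fit(d$G, d$y, method = method, nrounds = 60)
    pred <- predict(m, d$G)
    expect_length(pred, 150)
    expect_gt(cor(pred, d$y), 0.6)
  }
})
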