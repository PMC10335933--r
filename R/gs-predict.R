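#' Fit a genomic-prediction (GEBV) model on a marker panel
#'
#' One model contract behind two predictors: `"gbm"` fits gradient-boosted
#' regression trees (the primary model, matching the boosted-tree family used
#' for feature gain), `"ridge"` a closed-form ridge regression
#' `beta = (X'X + lambda I)^{-1} X'y` on centered dosages (a GBLUP-style
#' linear predictor, used as cross-check and for exact haplotype-enumeration
#' arithmetic). Genomic estimated breeding values (GEBVs) of new accessions
#' come from [predict()].
#'
#' @param geno Dosage matrix restricted to the panel markers (accessions x
#'   markers; NA mean-imputed).
#' @param pheno Phenotype vector (named) or tibble with `accession`/`value`.
#' @param method `"ridge"` (default) or `"gbm"`.
#' @param lambda Ridge penalty (default 1e-6; effectively OLS when the
#'   panel is small).
#' @param params,nrounds xgboost overrides for `method = "gbm"`.
#' @param seed RNG seed (gbm only).
#' @return A `gebv_model` object with `predict()` method.
#' @export
gebv_fit <- function(geno, pheno, method = c("ridge", "gbm"), lambda = 1e-6,
                     params = list(), nrounds = 150, seed = 1) {
  method <- match.arg(method)
  if (is.data.frame(pheno)) pheno <- setNames(pheno$value, pheno$accession)
  if (!is.null(names(pheno)) && !is.null(rownames(geno))) {
    pheno <- pheno[rownames(geno)]
  }
  y <- as.numeric(pheno)
  Z <- impute_mean(geno)
  markers <- colnames(Z) %||% sprintf("m%05d", seq_len(ncol(Z)))
  colnames(Z) <- markers

  fit <- if (method == "ridge") {
    mu_x <- colMeans(Z); mu_y <- mean(y)
    Xc <- sweep(Z, 2, mu_x)
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    beta <- drop(solve(A, crossprod(Xc, y - mu_y)))
    list(beta = setNames(beta, markers), mu_x = mu_x, mu_y = mu_y,
         lambda = lambda)
  } else {
    p <- utils::modifyList(list(objective = "reg:squarederror", max_depth = 4,
                                eta = 0.1, subsample = 0.9,
                                colsample_bytree = 0.9, nthread = 1), params)
    booster <- with_seed(seed, {
      xgboost::xgb.train(params = p,
                         data = xgboost::xgb.DMatrix(Z, label = y,
                                                     nthread = 1),
                         nrounds = nrounds, verbose = 0)
    })
    list(booster = booster)
  }
  structure(list(method = method, markers = markers, fit = fit,
                 col_means = colMeans(Z)),
            class = "gebv_model")
}

#' @export
predict.gebv_model <- function(object, newdata, ...) {
  Z <- newdata[, object$markers, drop = FALSE]
  if (anyNA(Z)) {
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- object$col_means[idx[, 2]]
  }
  if (object$method == "ridge") {
    f <- object$fit
    drop(sweep(Z, 2, f$mu_x) %*% f$beta) + f$mu_y
  } else {
    as.numeric(stats::predict(object$fit$booster,
                              xgboost::xgb.DMatrix(Z, nthread = 1)))
  }
}

#' @export
print.gebv_model <- function(x, ...) {
  cat(sprintf("<gebv_model> method=%s, %d markers\n",
              x$method, length(x$markers)))
  invisible(x)
}

#' Repeated-split genomic-prediction precision
#'
#' Repeatedly splits the accessions into training and held-out sets, fits the
#' GEBV model on the training set and records the Pearson correlation between
#' observed phenotypes and predicted GEBVs on the held-out set (the standard
#' prediction-precision measure). By default 85%/15% splits are used; when
#' the panel has exactly 680 accessions the conventional 580/100 split is
#' taken. Replicates whose held-out phenotypes are constant are recorded as
#' `NA` and excluded from the mean, with a count.
#'
#' @param geno Dosage matrix restricted to the panel markers.
#' @param pheno Phenotype vector (named) or tibble with `accession`/`value`.
#' @param n_train,n_test Split sizes; `NULL` for the defaults above.
#' @param reps Number of replicate splits (default 100).
#' @param seed RNG seed; the full replicate sequence is reproducible.
#' @param method,lambda,params,nrounds Passed to [gebv_fit()].
#' @return A `prediction_report` tibble: `rep`, `r`; attributes
#'   `n_train`, `n_test`, `n_undefined`. [tidy()] returns the replicate
#'   table, [glance()] the mean/sd summary.
#' @export
cross_validate <- function(geno, pheno, n_train = NULL, n_test = NULL,
                           reps = 100, seed = 1,
                           method = c("ridge", "gbm"), lambda = 1e-6,
                           params = list(), nrounds = 150) {
  method <- match.arg(method)
  if (is.data.frame(pheno)) pheno <- setNames(pheno$value, pheno$accession)
  if (!is.null(names(pheno)) && !is.null(rownames(geno))) {
    pheno <- pheno[rownames(geno)]
  }
  y <- as.numeric(pheno)
  n <- length(y)
  if (is.null(n_train) || is.null(n_test)) {
    if (n == 680) { n_train <- 580; n_test <- 100 }
    else { n_test <- max(1, round(0.15 * n)); n_train <- n - n_test }
  }
  if (n_train + n_test > n) abort("n_train + n_test exceeds accession count")

  rs <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      test <- sample.int(n, n_test)
      train <- setdiff(sample.int(n, n), test)[seq_len(n_train)]
      if (sd(y[test]) == 0) return(NA_real_)
      m <- gebv_fit(geno[train, , drop = FALSE], y[train], method = method,
                    lambda = lambda, params = params, nrounds = nrounds,
                    seed = i)
      pred <- predict(m, geno[test, , drop = FALSE])
      if (sd(pred) == 0) return(NA_real_)
      cor(y[test], pred)
    }, numeric(1))
  })
  out <- tibble(rep = seq_len(reps), r = rs)
  attr(out, "n_train") <- n_train
  attr(out, "n_test") <- n_test
  attr(out, "n_undefined") <- sum(is.na(rs))
  class(out) <- c("prediction_report", class(out))
  out
}

#' @export
tidy.prediction_report <- function(x, ...) {
  tibble(rep = x$rep, r = x$r)
}

#' @export
glance.prediction_report <- function(x, ...) {
  tibble(mean_r = mean(x$r, na.rm = TRUE),
         sd_r = sd(x$r, na.rm = TRUE),
         reps = nrow(x),
         n_undefined = attr(x, "n_undefined"),
         n_train = attr(x, "n_train"), n_test = attr(x, "n_test"))
}

#' Breeding-potential haplotype enumeration
#'
#' Takes the genotype of the highest-GEBV accession (among the cultivated
#' group when group labels are given) as background and enumerates all
#' `2^top_k` allele assignments of the `top_k` highest-feature-gain markers,
#' each marker set either to the reference state (0) or to its maximum
#' observed alternate dosage. The report gives the best simulated haplotype
#' GEBV and the improvement percentage
#' `(GEBV_max_haplotype - GEBV_max_cultivated) / GEBV_max_cultivated x 100`.
#' With `top_k = 20` exactly 1,048,576 combinations are evaluated.
#'
#' @param model A fitted `gebv_model` (fit on the full data).
#' @param geno Dosage matrix over the model's markers (all accessions).
#' @param importance `marker_importance` tibble ranking markers by FG.
#' @param top_k Number of markers to enumerate (default 20).
#' @param groups Optional groups table; when given, the background accession
#'   and `GEBV_max_cultivated` are taken over the cultivar group.
#' @param cap Refusal cap on `2^top_k` (default `2^20`); larger requests
#'   error with guidance rather than attempt a combinatorial blow-up.
#' @param chunk Rows per prediction chunk for tree models.
#' @return A `breeding_report` list: `gebv_max_cultivated`,
#'   `gebv_max_haplotype`, `n_combinations`, `improvement_pct` (NA when the
#'   cultivated maximum is 0), `background_accession`, `top_markers`,
#'   `best_haplotype` (tibble: marker, allele). [glance()] method available.
#' @export
enumerate_breeding <- function(model, geno, importance, top_k = 20,
                               groups = NULL, cap = 2^20, chunk = 65536L) {
  if (2^top_k > cap) {
    abort(paste0("2^top_k = ", format(2^top_k, big.mark = ","),
                 " exceeds the enumeration cap (", format(cap, big.mark = ","),
                 "); lower top_k or raise cap explicitly"))
  }
  Z <- impute_mean(geno[, model$markers, drop = FALSE])
  gebv <- predict(model, Z)
  pool <- seq_len(nrow(Z))
  if (!is.null(groups)) {
    cult <- groups$accession[groups$group == "cultivar"]
    pool <- which(rownames(Z) %in% cult)
    if (length(pool) == 0) pool <- seq_len(nrow(Z))
  }
  best_i <- pool[which.max(gebv[pool])]
  gebv_max_cult <- unname(gebv[best_i])

  ranked <- importance %>%
    filter(.data$marker %in% model$markers) %>%
    arrange(dplyr::desc(.data$fg))
  top <- head(ranked$marker, top_k)
  k <- length(top)
  n_comb <- 2^k
  alt_dose <- apply(Z[, top, drop = FALSE], 2, max)

  background <- Z[best_i, ]
  idx <- 0:(n_comb - 1)
  bits <- vapply(seq_len(k), function(j) {
    as.numeric(bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L)
  }, numeric(n_comb))
  bits <- matrix(bits, nrow = n_comb)

  if (model$method == "ridge") {
    base_row <- background
    base_row[top] <- 0
    base <- predict(model, matrix(base_row, nrow = 1,
                                  dimnames = list(NULL, names(base_row))))
    delta <- model$fit$beta[top] * alt_dose
    vals <- drop(base + bits %*% delta)
  } else {
    vals <- numeric(n_comb)
    other <- setdiff(model$markers, top)
    for (s in seq(1, n_comb, by = chunk)) {
      e <- min(s + chunk - 1, n_comb)
      block <- matrix(rep(background, e - s + 1), nrow = e - s + 1,
                      byrow = TRUE, dimnames = list(NULL, names(background)))
      block[, top] <- bits[s:e, , drop = FALSE] *
        rep(alt_dose, each = e - s + 1)
      vals[s:e] <- predict(model, block)
    }
  }
  best <- which.max(vals)
  improvement <- if (gebv_max_cult == 0) NA_real_ else {
    (vals[best] - gebv_max_cult) / gebv_max_cult * 100
  }
  structure(list(
    gebv_max_cultivated = unname(gebv_max_cult),
    gebv_max_haplotype = unname(vals[best]),
    n_combinations = n_comb,
    improvement_pct = improvement,
    background_accession = rownames(Z)[best_i],
    top_markers = top,
    best_haplotype = tibble(marker = top, allele = bits[best, ] * alt_dose)
  ), class = "breeding_report")
}

#' @export
print.breeding_report <- function(x, ...) {
  cat(sprintf(
    "<breeding_report> %s combinations over %d markers\n",
    format(x$n_combinations, big.mark = ","), length(x$top_markers)))
  cat(sprintf("  GEBV max cultivated %.4g -> max haplotype %.4g (%s%%)\n",
              x$gebv_max_cultivated, x$gebv_max_haplotype,
              ifelse(is.na(x$improvement_pct), "NA",
                     sprintf("%+.2f", x$improvement_pct))))
  invisible(x)
}

#' @export
glance.breeding_report <- function(x, ...) {
  tibble(gebv_max_cultivated = x$gebv_max_cultivated,
         gebv_max_haplotype = x$gebv_max_haplotype,
         n_combinations = x$n_combinations,
         improvement_pct = x$improvement_pct)
}
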