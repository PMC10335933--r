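#' Simulate SNP and PAV genotypes for a structured population
#'
#' Draws ancestral allele frequencies from Uniform(0.05, 0.95) and per-group
#' frequencies by the Balding-Nichols construction
#' `p_g ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with differentiation parameter
#' `F = F_drift` (for `F_drift = 0` the group frequencies equal the ancestral
#' frequencies). SNP dosages are sampled Binomial(2, p_g); PAV carrier states
#' are Bernoulli(f_g). A configured number of "selected" PAVs is planted with
#' monotone wild -> landrace -> cultivar carrier frequencies whose shift in the
#' labeled contrast (domestication: wild vs landrace; improvement: landrace vs
#' cultivar) is at least `delta_f`.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{snp}{list: `geno` (accession x SNP dosage matrix, 0/1/2/NA),
#'       `info` (tibble: id, chrom, pos (0-based), ref, alt).}
#'     \item{pav}{a `pav_set`: `records` tibble (id, chrom, start, end, type,
#'       length, 0-based half-open) and `geno` (accession x PAV carrier
#'       matrix, 0/1/NA).}
#'     \item{groups}{tibble: accession, group.}
#'     \item{truth}{tibble of planted selected PAVs: pav, contrast, direction,
#'       and the generating group frequencies.}
#'   }
#' @examples
#' g <- simulate_genotypes(sim_config(n_snp = 50, n_pav = 20, seed = 1))
#' dim(g$snp$geno)
#' @export
simulate_genotypes <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  groups <- accession_table(cfg)
  n_acc <- nrow(groups)
  sizes <- c(wild = cfg$n_wild, landrace = cfg$n_landrace,
             cultivar = cfg$n_cultivar)

  # marker positions: allocate to chromosomes proportional to length
  pos_tab <- with_seed(sub_seed(cfg$seed, "pav_records"), {
    n_mark <- cfg$n_snp + cfg$n_pav
    chrom <- sample(names(cfg$genome), n_mark, replace = TRUE,
                    prob = cfg$genome / sum(cfg$genome))
    pos <- floor(runif(n_mark, min = 0, max = cfg$genome[chrom] - 1))
    is_snp <- rep(c(TRUE, FALSE), c(cfg$n_snp, cfg$n_pav))
    lens <- pmin(pmax(round(exp(rnorm(cfg$n_pav, log(500), 1))), 50L), 20000L)
    type <- sample(c("INS", "DEL"), cfg$n_pav, replace = TRUE,
                   prob = c(0.55, 0.45))
    refalt <- t(vapply(seq_len(cfg$n_snp), function(i) {
      sample(c("A", "C", "G", "T"), 2)
    }, character(2)))
    list(chrom = chrom, pos = pos, is_snp = is_snp, lens = lens, type = type,
         refalt = refalt)
  })

  # group allele frequencies
  freqs <- with_seed(sub_seed(cfg$seed, "frequencies"), {
    n_mark <- cfg$n_snp + cfg$n_pav
    p0 <- runif(n_mark, 0.05, 0.95)
    pg <- if (cfg$F_drift == 0) {
      matrix(p0, nrow = n_mark, ncol = 3)
    } else {
      a <- p0 * (1 - cfg$F_drift) / cfg$F_drift
      b <- (1 - p0) * (1 - cfg$F_drift) / cfg$F_drift
      cbind(rbeta(n_mark, a, b), rbeta(n_mark, a, b), rbeta(n_mark, a, b))
    }
    colnames(pg) <- group_levels

    # plant selected PAVs with monotone group frequencies
    truth <- tibble(pav = character(), contrast = character(),
                    direction = character(), f_wild = numeric(),
                    f_landrace = numeric(), f_cultivar = numeric())
    if (cfg$n_selected_pav > 0) {
      sel_idx <- cfg$n_snp + sample.int(cfg$n_pav, cfg$n_selected_pav)
      contrast <- rep_len(c("domestication", "improvement"), cfg$n_selected_pav)
      direction <- rep_len(c("gain", "gain", "loss", "loss"), cfg$n_selected_pav)
      d <- cfg$delta_f
      buffer <- runif(cfg$n_selected_pav, 0.15, 0.30)
      f <- matrix(NA_real_, cfg$n_selected_pav, 3)
      for (i in seq_len(cfg$n_selected_pav)) {
        lo <- runif(1, 0.02, max(0.02, min(0.08, 1 - d - buffer[i] - 0.02)))
        if (contrast[i] == "domestication") {
          up <- c(lo, lo + d, min(lo + d + buffer[i], 0.98))
        } else {
          mid <- runif(1, 0.12, max(0.12, min(0.25, 1 - d - 0.02)))
          up <- c(max(mid - buffer[i], 0.01), mid, min(mid + d, 0.98))
        }
        f[i, ] <- if (direction[i] == "gain") up else 1 - up
      }
      pg[sel_idx, ] <- f
      truth <- tibble(
        idx = sel_idx, contrast = contrast, direction = direction,
        f_wild = f[, 1], f_landrace = f[, 2], f_cultivar = f[, 3]
      )
    }
    list(pg = pg, truth = truth)
  })

  geno_all <- with_seed(sub_seed(cfg$seed, "genotypes"), {
    pg <- freqs$pg
    draw_group <- function(g, n_ind) {
      snp <- matrix(rbinom(n_ind * cfg$n_snp, 2, rep(pg[seq_len(cfg$n_snp), g],
                                                     each = n_ind)),
                    nrow = n_ind, ncol = cfg$n_snp)
      pav <- matrix(rbinom(n_ind * cfg$n_pav, 1,
                           rep(pg[cfg$n_snp + seq_len(cfg$n_pav), g],
                               each = n_ind)),
                    nrow = n_ind, ncol = cfg$n_pav)
      list(snp = snp, pav = pav)
    }
    gs <- lapply(group_levels, function(g) draw_group(g, sizes[[g]]))
    list(snp = do.call(rbind, lapply(gs, `[[`, "snp")),
         pav = do.call(rbind, lapply(gs, `[[`, "pav")))
  })

  if (cfg$missing_rate > 0) {
    geno_all <- with_seed(sub_seed(cfg$seed, "missing"), {
      for (nm in c("snp", "pav")) {
        m <- geno_all[[nm]]
        miss <- runif(length(m)) < cfg$missing_rate
        m[miss] <- NA_integer_
        geno_all[[nm]] <- m
      }
      geno_all
    })
  }

  # assemble marker tables, sorted by chrom/pos within each marker class
  snp_info <- tibble(
    id = sprintf("snp%05d", seq_len(cfg$n_snp)),
    chrom = pos_tab$chrom[pos_tab$is_snp],
    pos = pos_tab$pos[pos_tab$is_snp],
    ref = pos_tab$refalt[, 1], alt = pos_tab$refalt[, 2]
  )
  ord_snp <- order(match(snp_info$chrom, names(cfg$genome)), snp_info$pos)

  pav_chrom <- pos_tab$chrom[!pos_tab$is_snp]
  pav_start <- pmin(pos_tab$pos[!pos_tab$is_snp],
                    cfg$genome[pav_chrom] - pos_tab$lens - 1)
  pav_start <- pmax(pav_start, 0)
  pav_rec <- tibble(
    id = sprintf("pav%05d", seq_len(cfg$n_pav)),
    chrom = pav_chrom,
    start = as.numeric(pav_start),
    end = as.numeric(ifelse(pos_tab$type == "INS", pav_start,
                            pav_start + pos_tab$lens)),
    type = pos_tab$type,
    length = as.numeric(pos_tab$lens)
  )
  ord_pav <- order(match(pav_rec$chrom, names(cfg$genome)), pav_rec$start)

  snp_geno <- geno_all$snp[, ord_snp, drop = FALSE]
  snp_info <- snp_info[ord_snp, ]
  pav_geno <- geno_all$pav[, ord_pav, drop = FALSE]
  pav_rec <- pav_rec[ord_pav, ]
  dimnames(snp_geno) <- list(groups$accession, snp_info$id)
  dimnames(pav_geno) <- list(groups$accession, pav_rec$id)

  truth <- freqs$truth
  if (nrow(truth) > 0) {
    # planted indices refer to pre-sort PAV order
    pav_ids_presort <- sprintf("pav%05d", seq_len(cfg$n_pav))
    truth <- truth %>%
      mutate(pav = pav_ids_presort[.data$idx - cfg$n_snp]) %>%
      select("pav", "contrast", "direction",
             "f_wild", "f_landrace", "f_cultivar")
  }

  list(
    snp = list(geno = snp_geno, info = snp_info),
    pav = structure(list(records = pav_rec, geno = pav_geno),
                    class = "pav_set"),
    groups = groups,
    truth = truth
  )
}

#' @export
print.pav_set <- function(x, ...) {
  cat(sprintf("<pav_set> %d PAVs x %d accessions (%s)\n",
              nrow(x$records), nrow(x$geno),
              paste(names(table(x$records$type)),
                    table(x$records$type), sep = ":", collapse = ", ")))
  invisible(x)
}
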