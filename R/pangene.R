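#' Classify gene families into pan-genome categories
#'
#' Assigns each family a category from its occupancy count `c` over the `N`
#' accessions of a presence/absence matrix: `c = N` is core, families present
#' in more than 90% of accessions but not all (`ceil(0.9 N) <= c <= N - 1`)
#' are soft-core, `2 <= c < ceil(0.9 N)` are dispensable, and `c = 1` is
#' private. At `N = 111` the soft-core band is 100-110 accessions and the
#' dispensable band 2-99.
#'
#' @param presence Logical or 0/1 matrix, families in rows and accessions in
#'   columns (rownames used as family ids), or a data frame in the same
#'   layout with a first column of family ids.
#' @return A `pan_composition` tibble with columns `family`, `occupancy`,
#'   `category` (factor core/softcore/dispensable/private) and attribute `N`.
#'   [glance()] returns per-category counts and proportions.
#' @examples
#' m <- rbind(a = c(1, 1, 1, 1), b = c(1, 1, 1, 0), c = c(0, 1, 0, 0))
#' classify_families(m)
#' @export
classify_families <- function(presence) {
  m <- as_presence_matrix(presence)
  N <- ncol(m)
  if (N < 4) abort("need at least 4 accessions to classify families")
  occ <- as.integer(rowSums(m))
  if (any(occ == 0)) {
    abort("presence matrix contains all-absent families (occupancy 0)")
  }
  soft_lo <- ceiling(0.9 * N)
  category <- dplyr::case_when(
    occ == N ~ "core",
    occ >= soft_lo ~ "softcore",
    occ >= 2 ~ "dispensable",
    TRUE ~ "private"
  )
  out <- tibble(
    family = rownames(m) %||% sprintf("fam%05d", seq_along(occ)),
    occupancy = occ,
    category = factor(category,
                      levels = c("core", "softcore", "dispensable", "private"))
  )
  attr(out, "N") <- N
  class(out) <- c("pan_composition", class(out))
  out
}

#' @export
glance.pan_composition <- function(x, ...) {
  tab <- table(x$category)
  tibble(category = names(tab),
         n = as.integer(tab),
         proportion = as.numeric(tab) / nrow(x))
}

as_presence_matrix <- function(presence) {
  if (is.data.frame(presence)) {
    ids <- presence[[1]]
    m <- as.matrix(presence[, -1, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "numeric"
    presence <- m
  }
  if (!is.matrix(presence)) abort("presence must be a matrix or data frame")
  m <- presence > 0
  if (anyNA(m)) abort("presence matrix must not contain missing values")
  m
}

#' Permutation growth curves of the pan- and core-genome
#'
#' For each of `R` uniformly random accession orderings, computes the
#' cumulative pan (union) and core (intersection) gene-family counts as
#' accessions are added one at a time, then summarizes the mean and standard
#' deviation at each panel size. Within every single permutation the pan count
#' is non-decreasing and the core count non-increasing by construction. The
#' increment series `dpan(n) = pan(n) - pan(n-1)` is the detrended form of the
#' curve used by [fit_closure()].
#'
#' @param presence Presence matrix as in [classify_families()].
#' @param R Number of random orderings (ignored when `exhaustive = TRUE`).
#' @param seed RNG seed for the orderings.
#' @param exhaustive If `TRUE`, average over all `N!` orderings (only
#'   permitted for `N <= 8`).
#' @return A `growth_curve` tibble with columns `n`, `pan_mean`, `pan_sd`,
#'   `core_mean`, `core_sd`, `dpan_mean`, and attributes `N`, `R`,
#'   `total_families`.
#' @examples
#' m <- matrix(runif(50) > 0.4, nrow = 10)
#' m <- m[rowSums(m) > 0, ]
#' growth_curves(m, R = 20, seed = 1)
#' @export
growth_curves <- function(presence, R = 100, seed = 1, exhaustive = FALSE) {
  m <- as_presence_matrix(presence)
  N <- ncol(m)
  if (any(rowSums(m) == 0)) abort("presence matrix contains all-absent families")
  if (exhaustive) {
    if (N > 8) abort("exhaustive enumeration limited to N <= 8")
    perms <- all_orderings(N)
  } else {
    if (R < 1) abort("R must be >= 1")
    perms <- with_seed(seed, replicate(R, sample.int(N), simplify = FALSE))
  }

  one_perm <- function(ord) {
    mo <- m[, ord, drop = FALSE]
    # index of first presence / first absence per family
    first_p <- max.col(mo + 0, ties.method = "first")
    pan <- cumsum(tabulate(first_p, nbins = N))
    any_absent <- rowSums(mo) < N
    first_a <- max.col(1 - mo, ties.method = "first")
    first_a[!any_absent] <- N + 1L
    core <- nrow(mo) - cumsum(tabulate(first_a, nbins = N))
    cbind(pan = pan, core = core)
  }
  curves <- lapply(perms, one_perm)
  pan <- vapply(curves, function(x) x[, "pan"], numeric(N))
  core <- vapply(curves, function(x) x[, "core"], numeric(N))
  pan <- matrix(pan, nrow = N); core <- matrix(core, nrow = N)

  out <- tibble(
    n = seq_len(N),
    pan_mean = rowMeans(pan),
    pan_sd = apply(pan, 1, sd),
    core_mean = rowMeans(core),
    core_sd = apply(core, 1, sd)
  )
  out$dpan_mean <- c(NA_real_, diff(out$pan_mean))
  attr(out, "N") <- N
  attr(out, "R") <- length(perms)
  attr(out, "total_families") <- nrow(m)
  class(out) <- c("growth_curve", class(out))
  out
}

all_orderings <- function(N) {
  if (N == 1) return(list(1L))
  sub <- all_orderings(N - 1L)
  unlist(lapply(sub, function(p) {
    lapply(seq_len(N), function(i) append(p, N, after = i - 1L))
  }), recursive = FALSE)
}

#' Fit a power-law closure model to a pan-genome growth curve
#'
#' Fits `pan(n) = K n^gamma + C` to the mean growth curve by nonlinear least
#' squares. The pan-genome is called closed when the fitted exponent satisfies
#' `gamma < 1 - tol` and the final mean increment is below `eps * pan(N)`;
#' the plateau size `n*` is the smallest `n` whose increment falls below that
#' threshold. A constant curve is reported as `gamma = 0`, closed.
#'
#' @param curve A `growth_curve` from [growth_curves()], or a numeric vector
#'   of mean pan counts for n = 1..N.
#' @param tol Openness tolerance on the exponent (default 0.05).
#' @param eps Relative increment threshold (default 1e-3).
#' @return A `closure_fit` list: `gamma`, `K`, `C`, `verdict` ("closed" or
#'   "open"), `plateau_n` (NA when never reached), `final_increment`,
#'   `pan_total`, `tol`, `eps`. [tidy()] and [glance()] methods available.
#' @examples
#' fit_closure(1000 * (1 - 0.7^(1:30)))
#' @export
fit_closure <- function(curve, tol = 0.05, eps = 1e-3) {
  pan <- if (is.numeric(curve)) as.numeric(curve) else curve$pan_mean
  N <- length(pan)
  if (N < 5) abort("need a curve with N >= 5")
  n <- seq_len(N)
  incr <- diff(pan)
  pan_total <- pan[N]
  thr <- eps * pan_total

  if (all(abs(incr) <= .Machine$double.eps * max(1, pan_total))) {
    fitted <- list(gamma = 0, K = 0, C = pan_total)
  } else {
    start <- closure_start(n, pan)
    fit <- tryCatch(
      minpack.lm::nlsLM(pan ~ K * n^gamma + C,
                        data = data.frame(n = n, pan = pan),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    fitted <- if (is.null(fit)) {
      list(gamma = start$gamma, K = start$K, C = start$C)
    } else {
      as.list(coef(fit))
    }
  }

  final_incr <- if (N >= 2) incr[N - 1] else 0
  below <- which(incr < thr)
  plateau_n <- if (length(below)) below[1] + 1L else NA_integer_
  verdict <- if (fitted$gamma < 1 - tol && final_incr < thr) "closed" else "open"

  structure(list(
    gamma = unname(fitted$gamma), K = unname(fitted$K), C = unname(fitted$C),
    verdict = verdict, plateau_n = plateau_n,
    final_increment = unname(final_incr), pan_total = unname(pan_total),
    tol = tol, eps = eps
  ), class = "closure_fit")
}

# log-log regression starting values for the power-law fit
closure_start <- function(n, pan) {
  C0 <- min(pan) * 0.5
  y <- pmax(pan - C0, 1e-9)
  lf <- stats::lm(log(y) ~ log(n))
  list(K = exp(unname(coef(lf)[1])), gamma = unname(coef(lf)[2]), C = C0)
}

#' @export
print.closure_fit <- function(x, ...) {
  cat(sprintf("<closure_fit> pan(n) ~ %.3g * n^%.3f + %.3g  ->  %s\n",
              x$K, x$gamma, x$C, x$verdict))
  cat(sprintf("  final increment %.3g (threshold %.3g), plateau n* = %s\n",
              x$final_increment, x$eps * x$pan_total,
              ifelse(is.na(x$plateau_n), "not reached", x$plateau_n)))
  invisible(x)
}

#' @export
tidy.closure_fit <- function(x, ...) {
  tibble(term = c("K", "gamma", "C"),
         estimate = c(x$K, x$gamma, x$C))
}

#' @export
glance.closure_fit <- function(x, ...) {
  tibble(gamma = x$gamma, verdict = x$verdict, plateau_n = x$plateau_n,
         final_increment = x$final_increment, pan_total = x$pan_total)
}
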