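# Internal helpers shared across modules.

# Deterministic sub-stream seeds: each generator component draws under its own
# seed derived from the master seed, so e.g. adding markers does not perturb
# the phenotype stream. Offsets are fixed per component name.
.substream_offsets <- c(
  genotypes = 101L, frequencies = 211L, pav_records = 307L,
  families = 401L, annotations = 503L, tsd = 601L,
  phenotypes = 701L, missing = 809L
)

sub_seed <- function(seed, component) {
  off <- .substream_offsets[[component]]
  if (is.null(off)) abort(paste0("unknown RNG component '", component, "'"))
  # keep within 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Random DNA string(s) of given lengths.
random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Column means ignoring NA, with all-NA columns falling back to 0.
col_means_na <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  mu
}

# Mean-impute missing entries column-wise (markers in columns).
impute_mean <- function(m) {
  if (!anyNA(m)) return(m)
  mu <- col_means_na(m)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2]]
  m
}

# Validate a groups table (accession, group) against a set of accession ids.
check_groups <- function(groups, accessions) {
  stopifnot(is.data.frame(groups), all(c("accession", "group") %in% names(groups)))
  missing_acc <- setdiff(accessions, groups$accession)
  if (length(missing_acc) > 0) {
    abort(paste0("accessions without a group label: ",
                 paste(head(missing_acc, 5), collapse = ", ")))
  }
  groups
}

group_levels <- c("wild", "landrace", "cultivar")
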