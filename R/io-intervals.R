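# Interval and table I/O. BED input is 0-based half-open (kept as is);
# GFF3 input is 1-based inclusive (converted). All internal intervals are
# 0-based half-open.

#' Read genomic intervals from BED or GFF3
#'
#' Parses the file with rtracklayer and returns a unified interval tibble in
#' internal 0-based half-open coordinates with strand and (for GFF3) the
#' record attributes.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"BED"` or `"GFF3"`.
#' @return Tibble: `chrom`, `start`, `end`, `name`, `strand` plus any
#'   attribute columns.
#' @export
read_intervals <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "GFF3"
              else "BED"
  }
  gr <- if (format == "BED") {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "GFF3")
  }
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  out <- tibble(
    chrom = as.character(df$seqnames),
    start = df$start - 1,   # GRanges is 1-based closed
    end = df$end,
    name = if ("Name" %in% names(df)) as.character(df$Name)
           else if ("name" %in% names(df)) as.character(df$name)
           else if ("ID" %in% names(df)) as.character(df$ID)
           else NA_character_,
    strand = as.character(df$strand)
  )
  if (any(out$start >= out$end)) {
    abort(paste0("interval with start >= end after conversion at line(s): ",
                 paste(head(which(out$start >= out$end), 5), collapse = ", ")))
  }
  extra <- setdiff(names(df), c("seqnames", "start", "end", "width",
                                "strand", "name", "Name"))
  for (cn in extra) out[[cn]] <- df[[cn]]
  out
}

#' Write genomic intervals to BED6 or GFF3
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`, `strand`, `score`.
#' @param path Output path.
#' @param format `"BED"` or `"GFF3"` (inferred from the extension when
#'   `"auto"`).
#' @param source,feature GFF3 source and type fields.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("auto", "BED", "GFF3"),
                            source = "panpav", feature = "region") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "GFF3"
              else "BED"
  }
  nm <- intervals[["name"]] %||% intervals[["gene_id"]] %||%
    intervals[["te_id"]] %||% sprintf("iv%05d", seq_len(nrow(intervals)))
  strand <- intervals[["strand"]] %||% rep(".", nrow(intervals))
  strand[!strand %in% c("+", "-")] <- "."
  score <- intervals[["score"]] %||% rep(0, nrow(intervals))
  lines <- if (format == "BED") {
    paste(intervals$chrom, as.integer(intervals$start),
          as.integer(intervals$end), nm, score, strand, sep = "\t")
  } else {
    c("##gff-version 3",
      paste(intervals$chrom, source, feature,
            as.integer(intervals$start) + 1, as.integer(intervals$end),
            ".", strand, ".", paste0("ID=", nm), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene-family presence matrix as TSV
#'
#' The TSV layout is families in rows, accessions in columns, 0/1 entries,
#' with a header row of accession ids and a first column of family ids.
#'
#' @param path TSV path.
#' @return Logical presence matrix (families x accessions).
#' @export
read_presence_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_presence_tsv
#' @param presence Presence matrix.
#' @export
write_presence_tsv <- function(presence, path) {
  df <- as.data.frame(presence * 1L)
  df <- cbind(family = rownames(presence), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
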