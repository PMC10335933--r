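# VCF I/O. Internal coordinates are 0-based half-open; conversion to the
# 1-based VCF convention happens only here. SNP genotypes are written as
# diploid GT (0/0, 0/1, 1/1, ./.), PAV carrier states as haploid GT (0, 1, .).

vcf_header <- function(genome, kind) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome),
            as.integer(genome)),
    if (kind == "sv") c(
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
      '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length, negative for deletions">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
}

#' Write SNP genotypes to a VCF 4.2 file
#'
#' @param snp List with `geno` (accession x SNP dosage matrix) and `info`
#'   (tibble: id, chrom, pos (0-based), ref, alt).
#' @param path Output path (plain text).
#' @param genome Named vector of chromosome lengths for the contig header.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snp, path, genome) {
  geno <- snp$geno; info <- snp$info
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1], nrow = nrow(geno))
  gt[is.na(geno)] <- "./."
  body <- paste(info$chrom, info$pos + 1, info$id, info$ref, info$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  hdr <- c(vcf_header(genome, "snp"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write PAV/SV records and carrier genotypes to a VCF 4.2 file
#'
#' Insertions with a resolved sequence are written sequence-resolved
#' (`REF = N`, `ALT = N<seq>`); other records use symbolic ALTs
#' (`<DEL>`, `<INS>`, `<INV>`, `<TRA>`) with `SVTYPE`, `SVLEN` (negative for
#' deletions) and `END` INFO keys. `POS` is the 1-based position of the
#' first affected base (`start + 1`); for insertions `END = POS` and the
#' internal zero-length interval is reconstructed on reading.
#'
#' @param pav A `pav_set` (records + geno).
#' @inheritParams write_snp_vcf
#' @return `path`, invisibly.
#' @export
write_pav_vcf <- function(pav, path, genome) {
  rec <- pav$records; geno <- pav$geno
  gt <- matrix(c("0", "1")[geno + 1], nrow = nrow(geno))
  gt[is.na(geno)] <- "."
  svlen <- ifelse(rec$type == "DEL", -rec$length, rec$length)
  end1 <- ifelse(rec$type == "INS", rec$start + 1, rec$end)
  has_seq <- "seq" %in% names(rec) & rec$type == "INS" & !is.na(rec$seq %||% NA)
  alt <- ifelse(has_seq, paste0("N", rec$seq), paste0("<", rec$type, ">"))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", rec$type, as.integer(svlen),
                  as.integer(end1))
  body <- paste(rec$chrom, rec$start + 1, rec$id, "N", alt, ".", "PASS",
                info, "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  hdr <- c(vcf_header(genome, "sv"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a SNP dosage matrix or PAV set
#'
#' Parses a VCF 4.x file with vcfR. For `kind = "snp"` biallelic records
#' become a 0/1/2 dosage matrix (multiallelic records are skipped with a
#' warning); for `kind = "sv"` the SVTYPE/SVLEN/END INFO keys (or a
#' sequence-resolved ALT) define PAV records and any non-reference genotype
#' marks a carrier. VCF 1-based positions are converted to internal 0-based
#' half-open coordinates.
#'
#' @param path VCF file path.
#' @param kind `"snp"` or `"sv"`.
#' @return For `"snp"`: list(`geno`, `info`). For `"sv"`: a `pav_set`.
#' @export
read_vcf <- function(path, kind = c("snp", "sv")) {
  kind <- match.arg(kind)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("%d multiallelic record(s) skipped", sum(multi)))
    fix <- fix[!multi, , drop = FALSE]
    gt_raw <- gt_raw[!multi, , drop = FALSE]
  }
  pos1 <- as.numeric(fix$POS)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("var%05d", seq_len(nrow(fix))), fix$ID)

  if (kind == "snp") {
    alt_count <- function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
      alleles <- strsplit(x, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(alleles != "0")
    }
    geno <- t(apply(gt_raw, 1, function(r) vapply(r, alt_count, integer(1))))
    geno <- matrix(as.integer(geno), nrow = nrow(gt_raw),
                   dimnames = list(ids, colnames(gt_raw)))
    list(
      geno = t(geno),
      info = tibble(id = ids, chrom = fix$CHROM, pos = pos1 - 1,
                    ref = fix$REF, alt = fix$ALT)
    )
  } else {
    info_get <- function(key) {
      m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"),
                                        fix$INFO))
      out <- rep(NA_character_, nrow(fix))
      hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
      out[hit] <- sub(paste0("^;?", key, "="), "", m)
      out
    }
    svtype <- info_get("SVTYPE")
    svlen <- suppressWarnings(as.numeric(info_get("SVLEN")))
    end1 <- suppressWarnings(as.numeric(info_get("END")))
    seq_alt <- ifelse(grepl("^<", fix$ALT), NA_character_,
                      substr(fix$ALT, 2, nchar(fix$ALT)))
    svtype <- ifelse(is.na(svtype) & !is.na(seq_alt), "INS", svtype)
    len <- ifelse(!is.na(svlen), abs(svlen),
                  ifelse(!is.na(seq_alt), nchar(seq_alt), end1 - pos1 + 1))
    start0 <- pos1 - 1
    end0 <- ifelse(svtype == "INS", start0, start0 + len)
    bad <- is.na(svtype) | is.na(len)
    if (any(bad)) {
      abort(paste0("malformed SV record(s) at line(s): ",
                   paste(head(which(bad), 5), collapse = ", ")))
    }
    carrier <- function(x) {
      if (is.na(x) || x == "." || x == "./." || x == ".|.") return(NA_integer_)
      as.integer(any(strsplit(x, "[/|]")[[1]] == "1"))
    }
    geno <- t(apply(gt_raw, 1, function(r) vapply(r, carrier, integer(1))))
    geno <- matrix(as.integer(geno), nrow = nrow(gt_raw),
                   dimnames = list(ids, colnames(gt_raw)))
    records <- tibble(id = ids, chrom = fix$CHROM, start = start0,
                      end = end0, type = svtype, length = len,
                      seq = seq_alt)
    structure(list(records = records, geno = t(geno)), class = "pav_set")
  }
}
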