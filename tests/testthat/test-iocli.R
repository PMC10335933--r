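test_that("a hand-written VCF parses to the expected dosage matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    "chr1\t101\ts1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t205\ts2\tG\tT\t.\tPASS\t.\tGT\t./.\t1/1\t0/0"
  ), path)
  got <- read_vcf(path, "snp")
  expect_equal(dim(got$geno), c(3L, 2L))
  expect_equal(unname(got$geno[, "s1"]), c(0L, 1L, 2L))
  expect_equal(unname(got$geno[, "s2"]), c(NA_integer_, 2L, 0L))
  expect_equal(got$info$pos, c(100, 204))  # 0-based internally
})

test_that("SV records honor SVLEN sign and symbolic ALT conventions", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB",
    "chr1\t501\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-120;END=620\tGT\t1\t0",
    "chr1\t901\ti1\tN\tNACGTACGTA\t.\tPASS\tSVTYPE=INS;SVLEN=9;END=901\tGT\t0\t."
  ), path)
  got <- read_vcf(path, "sv")
  rec <- got$records
  expect_equal(rec$length[rec$id == "d1"], 120)
  expect_identical(rec$type[rec$id == "d1"], "DEL")
  expect_equal(rec$start[rec$id == "d1"], 500)
  expect_equal(rec$end[rec$id == "d1"], 620)
  expect_identical(rec$type[rec$id == "i1"], "INS")
  expect_equal(rec$start[rec$id == "i1"], rec$end[rec$id == "i1"])
  expect_identical(rec$seq[rec$id == "i1"], "ACGTACGTA")
  expect_equal(unname(got$geno[, "d1"]), c(1L, 0L))
  expect_equal(unname(got$geno[, "i1"]), c(0L, NA_integer_))
})

test_that("SNP and PAV VCF round-trips preserve genotypes and coordinates", {
  sim <- simulate_population(small_cfg(seed = 51))
  dir <- withr::local_tempdir()
  snp_path <- file.path(dir, "snps.vcf")
  pav_path <- file.path(dir, "pavs.vcf")
  write_snp_vcf(sim$snp, snp_path, sim$config$genome)
  write_pav_vcf(sim$pav, pav_path, sim$config$genome)

  snp2 <- read_vcf(snp_path, "snp")
  expect_identical(unname(snp2$geno), unname(sim$snp$geno))
  expect_equal(snp2$info$pos, sim$snp$info$pos)
  expect_identical(snp2$info$id, sim$snp$info$id)

  pav2 <- read_vcf(pav_path, "sv")
  expect_identical(unname(pav2$geno), unname(sim$pav$geno))
  expect_equal(pav2$records$start, sim$pav$records$start)
  expect_equal(pav2$records$end, sim$pav$records$end)
  expect_identical(pav2$records$type, sim$pav$records$type)
  expect_equal(pav2$records$length, sim$pav$records$length)
  ins <- sim$pav$records$type == "INS"
  expect_identical(pav2$records$seq[ins], sim$pav$records$seq[ins])

  # write-after-read reproduces the identical file
  pav2$records$flank_left <- NA; pav2$records$flank_right <- NA
  pav_path2 <- file.path(dir, "pavs2.vcf")
  write_pav_vcf(pav2, pav_path2, sim$config$genome)
  expect_identical(readLines(pav_path), readLines(pav_path2))
})

test_that("BED and GFF3 coordinate conventions convert to 0-based half-open", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "x.bed")
  writeLines("chr1\t100\t200\tfeat1\t0\t+", bed)
  got_bed <- read_intervals(bed)
  expect_equal(got_bed$start, 100)
  expect_equal(got_bed$end, 200)

  gff <- file.path(dir, "x.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=feat1"), gff)
  got_gff <- read_intervals(gff)
  expect_equal(got_gff$start, 100)
  expect_equal(got_gff$end, 200)
})

test_that("interval round-trips are the identity on canonical files", {
  iv <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0, 5000),
                       end = c(1500, 5100), name = c("a", "b"),
                       strand = c("+", "-"))
  dir <- withr::local_tempdir()
  for (fmt in c("bed", "gff3")) {
    p <- file.path(dir, paste0("iv.", fmt))
    write_intervals(iv, p)
    got <- read_intervals(p)
    expect_equal(got$chrom, iv$chrom)
    expect_equal(got$start, iv$start)
    expect_equal(got$end, iv$end)
    expect_equal(got$name, iv$name)
    expect_equal(got$strand, iv$strand)
  }
})

test_that("presence matrix TSV round-trips", {
  m <- toy_presence() > 0
  dir <- withr::local_tempdir()
  p <- file.path(dir, "pm.tsv")
  write_presence_tsv(m, p)
  got <- read_presence_tsv(p)
  expect_identical(unname(got), unname(m))
  expect_identical(rownames(got), rownames(m))
})

test_that("pipeline config rejects unknown keys and honors overrides", {
  expect_error(pipeline_config(nonsense_key = 1), "unknown")
  cfg <- pipeline_config(sim = small_cfg(seed = 1), q_max = 0.05)
  expect_equal(cfg$q_max, 0.05)
  expect_equal(cfg$p_max, 7.81e-8)
})

test_that("the pipeline runs end-to-end, deterministically, with manifest", {
  cfg <- pipeline_config(
    sim = sim_config(n_snp = 300, n_pav = 200, n_family = 200, n_gene = 60,
                     n_causal = 5, genome = c(chr1 = 1e6, chr2 = 1e6),
                     seed = 99),
    growth_R = 10, te_n_perm = 49, cv_reps = 3, top_k = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, d1)
  r2 <- run_pipeline(cfg, d2)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_identical(r1$manifest$files, r2$manifest$files)
  # stage outputs exist and the resolved config is emitted
  for (f in c("snps.vcf", "pavs.vcf", "pan_composition.tsv",
              "selection_calls.tsv", "diversity_windows.tsv",
              "association.tsv", "panels.tsv", "breeding.tsv",
              "config_resolved.yaml")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
  }
})

test_that("disabling a stage skips it and its outputs only", {
  cfg <- pipeline_config(
    sim = sim_config(n_snp = 100, n_pav = 80, n_family = 80, n_gene = 40,
                     n_causal = 3, genome = c(chr1 = 5e5), seed = 5),
    stages = c("synthdata", "pangene"), growth_R = 5)
  d <- withr::local_tempdir()
  res <- run_pipeline(cfg, d)
  expect_true(file.exists(file.path(d, "pan_composition.tsv")))
  expect_false(file.exists(file.path(d, "association.tsv")))
  expect_null(res$gsbreed)
})

test_that("a YAML config round-trips through read_pipeline_config", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    sim = list(n_snp = 50, n_pav = 30, n_family = 20, n_gene = 10,
               genome = list(chr1 = 2e5), seed = 3),
    stages = c("synthdata", "pangene"),
    growth_R = 7), p)
  cfg <- read_pipeline_config(p)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$growth_R, 7)
  expect_equal(cfg$sim$n_snp, 50)
  expect_identical(cfg$stages, c("synthdata", "pangene"))
})
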