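vcfLines <- function(body, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body)
}

test_that("multiallelic sites split into biallelic records with remapped dosages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcfLines("chr1\t100\t.\tA\tT,G\t.\t.\t.\tGT\t1/2\t2/2"), path)
  co <- readVcfCohort(path)
  v <- variantTable(co)
  expect_equal(nrow(v), 2)
  expect_equal(v$alt, c("T", "G"))
  g <- genoMatrix(co)
  # the 1/2 sample is het-alt in each split record
  expect_equal(unname(g[, "S1"]), c(1, 1))
  # 2/2: hom for the second alt, missing in the record for the first
  expect_equal(unname(g[, "S2"]), c(NA, 2))
})

test_that("missing calls and GQ parse; format errors are raised", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
               "chr1\t5\t.\tC\tT\t.\t.\t.\tGT:GQ\t./.:.\t0/1:35"), path)
  co <- readVcfCohort(path)
  expect_true(is.na(genoMatrix(co)[1, "S1"]))
  expect_equal(unname(genoMatrix(co)[1, "S2"]), 1)
  expect_equal(unname(co@gq[1, "S2"]), 35)

  noHdr <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\t5\t.\tC\tT\t.\t.\t."), noHdr)
  expect_error(readVcfCohort(noHdr), "#CHROM")

  noGT <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcfLines("chr1\t5\t.\tC\tT\t.\t.\t.\tGQ\t30\t40"), noGT)
  expect_error(readVcfCohort(noGT), "GT absent")
})

test_that("VCF write -> read round-trips the supported field subset", {
  g <- matrix(c(0, 1, 2, NA, 1, 0), 3, 2,
              dimnames = list(NULL, c("S1", "S2")))
  co <- toyCohort(g, chrom = c("chr1", "chr1", "chrX"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeVcfCohort(co, path)
  back <- readVcfCohort(path)
  expect_equal(variantTable(back), variantTable(co))
  expect_equal(genoMatrix(back), genoMatrix(co))
})

test_that("multiallelic split conserves each sample's non-reference alleles", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gts <- c("0/0", "0/1", "1/1", "0/2", "2/2", "1/2", "./.")
  body <- paste(c("chr2", "50", ".", "A", "C,T", ".", ".", ".", "GT", gts),
                collapse = "\t")
  writeLines(vcfLines(body, samples = sprintf("S%d", 1:7)), path)
  co <- readVcfCohort(path)
  g <- genoMatrix(co)
  for (s in seq_len(7)) {
    alleles <- strsplit(gts[s], "/")[[1]]
    for (j in 1:2) {
      cnt <- sum(alleles == as.character(j))
      if (cnt > 0) expect_equal(unname(g[j, s]), cnt)
    }
  }
})

test_that("annotation tables read with the documented cell dialect", {
  sim <- simulateCohort(fastConfig("recessive_hom", seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(annotationsOf(sim), path)
  back <- readAnnotations(path)
  orig <- annotationsOf(sim)
  rownames(orig) <- NULL
  expect_equal(back[order(back$key), ], orig[order(orig$key), ],
               ignore_attr = TRUE)
  # empty population cell -> NA frequency; '.' predictor -> NA
  someNA <- which(is.na(orig$EAS))[1]
  expect_true(is.na(back$EAS[back$key == orig$key[someNA]]))
})

test_that("annotation row errors and duplicate-key policy behave as documented", {
  hdr <- paste(c("chrom", "pos", "ref", "alt", "gene", "func_class",
                 "AFR", "AMR", "EAS", "EUR", "SAS", "dbsnp", "esp",
                 "esp_freq", "SIFT", "PolyPhen", "LRT", "MutationTaster",
                 "MutationAssessor", "FATHMM", "MetaSVM", "MetaLR"),
               collapse = "\t")
  row <- function(pos, eas, sift = "D") paste(
    c("chr1", pos, "A", "G", "GENE1", "missense", "", "", eas, "", "",
      "0", "0", "", sift, "T", ".", ".", ".", ".", ".", "."),
    collapse = "\t")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, row(100, "oops")), bad)
  expect_error(readAnnotations(bad), "malformed numeric.*line 2")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, row(100, "0.01", sift = "T"), row(100, "0.02")), dup)
  expect_warning(ann <- readAnnotations(dup), "last row wins")
  expect_equal(nrow(ann), 1)
  expect_equal(ann$EAS, 0.02)     # last row won
  expect_equal(ann$SIFT, "D")
})

test_that("CNV tables validate, sort, and represent the 3p-deletion shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstate\tsample",
               "chr7\t100290000\t100379999\tloss\tchild",
               "chr3\t0\t10349999\tloss\tchild"), path)
  d <- readCnvTable(path)
  expect_equal(d$chrom, c("chr3", "chr7"))       # sorted on read
  expect_equal(d$start[1], 0)
  expect_equal(d$end[1], 10349999)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tstart\tend\tstate\tsample", empty)
  expect_equal(nrow(readCnvTable(empty)), 0)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstate\tsample",
               "chr1\t500\t500\tloss\tx"), bad)
  expect_error(readCnvTable(bad), "start < end")
})

test_that("gene tables validate exon structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("chrom", "start", "end", "symbol", "strand",
                       "exon_starts", "exon_ends", "cds_start", "cds_end"),
                     collapse = "\t"),
               "chr1\t1000\t5000\tB\t+\t1000,3000\t2000,4000\t1200\t3800",
               "chr1\t100\t900\tA\t-\t100\t900\t200\t800"), path)
  d <- readGeneTable(path)
  expect_equal(d$symbol, c("A", "B"))            # sorted
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("chrom", "start", "end", "symbol", "strand",
                       "exon_starts", "exon_ends", "cds_start", "cds_end"),
                     collapse = "\t"),
               "chr1\t1000\t5000\tB\t+\t1000,1500\t2000,4000\t1200\t3800"),
             bad)
  expect_error(readGeneTable(bad), "exon structure")  # overlapping exons
})

test_that("preflight flags mixed chromosome naming and missing samples", {
  g <- matrix(0, 2, 1, dimnames = list(NULL, "S1"))
  co <- toyCohort(g, chrom = c("chr1", "2"))
  expect_match(preflightCohort(co), "mixed chromosome naming")
  ped <- trioPed()
  co2 <- toyCohort(matrix(0, 1, 1, dimnames = list(NULL, "fat")))
  expect_match(preflightCohort(co2, pedigrees = list(F1 = ped)),
               "absent from cohort")
})
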