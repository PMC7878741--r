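gp16 <- function(name = "NM_000001", gene = "GENE1") {
  paste(585L, name, "chr1", "+", 100L, 900L, 200L, 800L, 2L,
        "100,500,", "300,900,", 0L, gene, "cmpl", "cmpl", "0,0,", sep = "\t")
}

test_that("genePred parsing dispatches on the bin column and maps fields", {
  f16 <- withr::local_tempfile(lines = gp16())
  df <- read_genepred(f16)
  expect_equal(nrow(df), 1L)
  expect_equal(df$bin, 585L)
  expect_equal(df$name, "NM_000001")
  expect_equal(df$exonCount, 2L)
  expect_equal(df$exonStarts[[1L]], c(100L, 500L))
  expect_equal(df$name2, "GENE1")
  expect_equal(attr(df, "dialect"), "genePredExtBin")

  # same row without bin parses identically under auto-detection
  f15 <- withr::local_tempfile(
    lines = sub("^585\t", "", gp16()))
  df15 <- read_genepred(f15)
  expect_equal(attr(df15, "dialect"), "genePredExt")
  expect_equal(df15[c("name", "txStart", "txEnd", "exonCount", "name2")],
               df[c("name", "txStart", "txEnd", "exonCount", "name2")])

  # refFlat: gene symbol + basic genePred
  frf <- withr::local_tempfile(lines = paste(
    "GENE1", "NM_000001", "chr1", "+", 100L, 900L, 200L, 800L, 2L,
    "100,500,", "300,900,", sep = "\t"))
  rf <- read_genepred(frf)
  expect_equal(attr(rf, "dialect"), "refFlat")
  expect_equal(rf$name2, "GENE1")
  expect_equal(rf$exonEnds[[1L]], c(300L, 900L))
})

test_that("genePred reader rejects malformed rows with located errors", {
  bad_cds <- sub("\t200\t800\t", "\t850\t800\t", gp16())
  f <- withr::local_tempfile(lines = c(gp16(), bad_cds))
  expect_error(read_genepred(f), "line 2.*cdsStart", ignore.case = TRUE)

  bad_count <- sub("\t2\t", "\t3\t", gp16())
  f2 <- withr::local_tempfile(lines = bad_count)
  expect_error(read_genepred(f2), "line 1.*exon")

  f3 <- withr::local_tempfile(lines = paste("just", "four", "odd", "fields", sep = "\t"))
  expect_error(read_genepred(f3), "column count")
})

test_that("gzip input is sniffed from magic bytes", {
  gz <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(gz, "wt"); writeLines(gp16(), con); close(con)
  df <- read_genepred(gz)
  expect_equal(df$name, "NM_000001")
})

rmsk_line <- function(strand = "+", repStart = 1L, repEnd = 290L, repLeft = -21L) {
  paste(585L, 2000L, 100L, 10L, 10L, "chr1", 10000L, 10290L, -500000L, strand,
        "AluYRa1", "SINE", "Alu", repStart, repEnd, repLeft, 1L, sep = "\t")
}

test_that("rmsk consensus conventions normalize to one view on both strands", {
  f <- withr::local_tempfile(lines = c(
    rmsk_line("+", 1L, 290L, -21L),
    rmsk_line("-", -21L, 290L, 1L)))
  df <- read_rmsk(f)
  expect_true(all(df$conventionOK))
  # independent reverse-engineering of the consensus span from the raw sign
  # trick: the two positive-valued fields bracket the element
  span <- t(apply(df[c("repStart", "repEnd", "repLeft")], 1L, function(v) {
    range(v[v > 0L])
  }))
  expect_equal(unname(df$consensusStart), unname(span[, 1L]))
  expect_equal(unname(df$consensusEnd), unname(span[, 2L]))
  expect_equal(df$consensusLeft, c(21L, 21L))
})

test_that("rmsk sign-convention violations are flagged, not dropped", {
  f <- withr::local_tempfile(lines = c(
    rmsk_line("+", 1L, 290L, -21L),
    rmsk_line("+", 1L, 290L, 21L)))  # positive repLeft on + strand
  expect_warning(df <- read_rmsk(f), "sign convention")
  expect_equal(nrow(df), 2L)
  expect_equal(df$conventionOK, c(TRUE, FALSE))
})

test_that("TAPAS parsing keeps site/abundance lists parallel", {
  f <- withr::local_tempfile(lines = c(
    paste("TK2", "chr1", "+", "100,200,300", "1.5,2,0.25", 4000L, sep = "\t"),
    paste("EMPTY", "chr2", "-", "", "", 10L, sep = "\t")))
  df <- read_tapas(f)
  expect_equal(nrow(df), 2L)
  expect_equal(df$apa_sites[[1L]], c(100L, 200L, 300L))
  expect_equal(df$abundances[[1L]], c(1.5, 2, 0.25))
  expect_length(df$apa_sites[[2L]], 0L)

  # whitespace delimiter accepted too
  fw <- withr::local_tempfile(lines = paste(
    "TK2", "chr1", "+", "100 200", "1 2", 10L, sep = "\t"))
  expect_equal(read_tapas(fw)$apa_sites[[1L]], c(100L, 200L))

  bad <- withr::local_tempfile(lines = paste(
    "GTPBP4", "chr1", "+", "100,200", "1.5", 10L, sep = "\t"))
  expect_error(read_tapas(bad), "GTPBP4.*2 sites but 1")
})

test_that("fixture tables round-trip byte-for-byte through read/write", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 11L, n_genes = 8L,
    planted_repeats = data.frame(repName = "AluYRa1", category = "UTR3_END",
                                 orientation = "SENSE", count = 3L,
                                 stringsAsFactors = FALSE),
    planted_apa = data.frame(region = c("POLY_A_TAIL", "OFF_ELEMENT"),
                             count = c(4L, 3L), stringsAsFactors = FALSE)),
    file.path(dir, "fx"))
  for (pair in list(c("genes", "read_genepred", "write_genepred"),
                    c("repeats", "read_rmsk", "write_rmsk"),
                    c("tapas", "read_tapas", "write_tapas"))) {
    src <- fx$files[[pair[[1L]]]]
    df <- match.fun(pair[[2L]])(src)
    out <- file.path(dir, paste0("rt_", basename(src)))
    match.fun(pair[[3L]])(df, out)
    expect_identical(readLines(out), readLines(src), label = pair[[1L]])
    # parsing is order-preserving and total
    expect_equal(nrow(df), length(readLines(src)))
  }
})

test_that("BED6 writer and reader agree", {
  dir <- withr::local_tempdir()
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(10L, 20L),
                   end = c(15L, 30L), name = c("a", "b"), score = c(0L, 0L),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  p <- file.path(dir, "x.bed")
  write_bed6(df, p)
  back <- read_bed(p)
  expect_equal(back$start, df$start)
  expect_equal(back$strand, df$strand)
})
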