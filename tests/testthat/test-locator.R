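# Gene used throughout: "+" strand, 2 exons, generous UTRs.
big_model <- function(strand = "+") {
  make_model(strand, txStart = 1000L, txEnd = 4000L,
             cdsStart = 1400L, cdsEnd = 3500L,
             exonStarts = c(1000L, 2200L), exonEnds = c(2000L, 4000L))
}

test_that("terminal, internal and near-miss placements classify as published", {
  m <- big_model("+")
  # element spanning the transcript end inside the 3'UTR, same strand
  pc <- classify_pair(make_rep(3850L, 4150L, "+"), m)
  expect_equal(pc$category, "UTR3_END")
  expect_equal(pc$orientation, "SENSE")
  expect_equal(pc$distance_to_terminal, 0L)
  # middle of the 3'UTR, not touching the end (the ZNF575/KCNIP3 pattern)
  pc2 <- classify_pair(make_rep(3550L, 3850L, "+"), m)
  expect_equal(pc2$category, "UTR3_INTERNAL")
  # ends 30 bp short of the terminus: near, but not overlapping (the JOSD1
  # pattern) -- internal at strict proximity, terminal once the window
  # covers the gap
  pc3 <- classify_pair(make_rep(3670L, 3970L, "+"), m)
  expect_equal(pc3$category, "UTR3_INTERNAL")
  expect_equal(pc3$distance_to_terminal, -30L)
  expect_equal(classify_pair(make_rep(3670L, 3970L, "+"), m,
                             proximity_bp = 30L)$category, "UTR3_END")
  # an element starting exactly at the (exclusive) end coordinate abuts it
  expect_equal(classify_pair(make_rep(4000L, 4300L, "+"), m)$category, "UTR3_END")
  # purely intronic
  expect_equal(classify_pair(make_rep(2050L, 2150L, "+"), m)$category,
               "NO_EXONIC_OVERLAP")
  # spanning the first splice junction from inside the CDS
  expect_equal(classify_pair(make_rep(1900L, 2100L, "+"), m)$category,
               "EXON_SPLICING")
  expect_error(classify_pair(make_rep(10L, 50L, "+", chrom = "chr9"), m),
               "chromosome mismatch")
})

test_that("orientation flips with exactly one strand", {
  m_plus <- big_model("+"); m_minus <- big_model("-")
  r_plus <- make_rep(3550L, 3850L, "+"); r_minus <- make_rep(3550L, 3850L, "-")
  expect_equal(classify_pair(r_plus, m_plus)$orientation, "SENSE")
  expect_equal(classify_pair(r_minus, m_plus)$orientation, "ANTISENSE")
  expect_equal(classify_pair(r_plus, m_minus)$orientation, "ANTISENSE")
  expect_equal(classify_pair(r_minus, m_minus)$orientation, "SENSE")
})

test_that("every overlapping pair gets exactly one primary category from its set", {
  withr::local_seed(41L)
  for (i in 1:200) {
    inst <- random_locator_instance()
    pc <- classify_pair(inst$rep, inst$model)
    expect_length(pc$category, 1L)
    expect_true(pc$category %in% pc$all_categories)
    expect_true(all(pc$all_categories %in% POSITIONAL_CATEGORIES))
    if (pc$category == "NO_EXONIC_OVERLAP") expect_equal(pc$overlap_bp, 0L)
    if (pc$overlap_bp == 0L && pc$category != "NO_EXONIC_OVERLAP") {
      # only terminal abutment can be called without exonic overlap
      expect_true(pc$category %in% c("UTR3_END", "UTR5_START"))
    }
  }
})

test_that("locate_all is per-pair, deterministic and respects the subfamily filter", {
  rmsk <- do.call(rbind, lapply(list(
    c(3850L, 4150L, "AluYRa1"), c(1900L, 2100L, "AluSz"),
    c(500L, 700L, "AluYRa1")), function(v) {
      r <- random_rmsk_row("+")
      r$genoStart <- as.integer(v[1L]); r$genoEnd <- as.integer(v[2L])
      r$repName <- v[3L]
      r
    }))
  iso1 <- big_model()
  iso2 <- make_model("+", txStart = 1000L, txEnd = 4100L, cdsStart = 1400L,
                     cdsEnd = 3500L, exonStarts = 1000L, exonEnds = 4100L,
                     name = "NM_000002", gene = "G1")
  calls <- locate_all(rmsk, list(iso1, iso2))
  # repeat 1 overlaps both isoforms -> two calls; repeat 3 is outside
  expect_equal(sum(calls$rep_row == 1L), 2L)
  expect_false(3L %in% calls$rep_row)
  sz <- locate_all(rmsk, list(iso1, iso2), rep_name = "AluSz")
  expect_equal(unique(sz$rep_row), 2L)
  expect_equal(nrow(locate_all(rmsk[0L, ], list(iso1))), 0L)
  expect_equal(nrow(locate_all(rmsk, list())), 0L)
  # deterministic order: chrom, genoStart, accession
  expect_equal(order(calls$chrom, calls$genoStart, calls$transcript),
               seq_len(nrow(calls)))
  expect_identical(locate_all(rmsk, list(iso1, iso2)), calls)
})

planted_calls <- function(n_sense, n_anti, category = "UTR3_END",
                          repName = "AluYRa1") {
  data.frame(
    chrom = "chr1", genoStart = seq_len(n_sense + n_anti), genoEnd = 2L,
    repName = repName, repClass = "SINE", repFamily = "Alu",
    repStrand = rep(c("+", "-"), c(n_sense, n_anti)), rep_row = 1L,
    transcript = "NM_1", gene = "G", txStrand = "+", category = category,
    all_categories = category,
    orientation = rep(c("SENSE", "ANTISENSE"), c(n_sense, n_anti)),
    overlap_bp = 1L, distance_to_terminal = 0L, stringsAsFactors = FALSE)
}

test_that("position summaries conserve counts and expose the sense bias", {
  # composition mimicking the ~3x sense excess at the 3'UTR end
  calls <- planted_calls(30L, 10L)
  tab <- summarize_positions(calls, "repName")
  sense <- tab$n[tab$category == "UTR3_END" & tab$orientation == "SENSE"]
  anti <- tab$n[tab$category == "UTR3_END" & tab$orientation == "ANTISENSE"]
  expect_equal(sense / anti, 3)
  expect_equal(sum(tab$n), nrow(calls))
  # zero cells for the group are present
  expect_equal(nrow(tab), length(POSITIONAL_CATEGORIES) * 2L)
  expect_true(any(tab$n == 0L))
  expect_equal(nrow(summarize_positions(calls[0L, ], "repClass")), 0L)
  expect_error(summarize_positions(calls, "banana"))
})

test_that("per-family composition is recovered exactly", {
  # the published 3'UTR-end Alu breakdown, used as the planted composition
  calls <- rbind(planted_calls(8L, 0L, repName = "AluSz"),
                 planted_calls(7L, 0L, repName = "AluSx1"),
                 planted_calls(7L, 0L, repName = "AluYRa1"))
  tab <- summarize_positions(calls, "repName")
  got <- tab$n[tab$category == "UTR3_END" & tab$orientation == "SENSE"]
  names(got) <- tab$repName[tab$category == "UTR3_END" & tab$orientation == "SENSE"]
  expect_equal(got[c("AluSz", "AluSx1", "AluYRa1")],
               c(AluSz = 8L, AluSx1 = 7L, AluYRa1 = 7L))
  expect_equal(sum(tab$n), 22L)
})

test_that("gene inventory collapses isoforms and splits NM from XM support", {
  mk <- function(gene, acc) {
    df <- planted_calls(1L, 0L)
    df$gene <- gene; df$transcript <- acc
    df
  }
  calls <- rbind(
    do.call(rbind, lapply(1:7, function(i) mk(paste0("REG", i), sprintf("NM_%03d", i)))),
    do.call(rbind, lapply(1:3, function(i) mk(paste0("PRED", i), sprintf("XM_%03d", i)))),
    mk("REG1", "NM_901"))  # second isoform of REG1 collapses
  inv <- gene_inventory(calls, "UTR3_END", "AluYRa1", c("NM", "XM"))
  expect_equal(nrow(inv), 10L)
  expect_equal(sum(inv$support == "NM"), 7L)
  expect_equal(sum(inv$support == "XM"), 3L)
  expect_equal(inv$n_transcripts[inv$gene == "REG1"], 2L)
  expect_equal(nrow(gene_inventory(calls, "UTR3_END", "AluYRa1", "NM")), 7L)
  expect_equal(nrow(gene_inventory(calls, "UTR3_END", "AluMadeUp")), 0L)
})
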