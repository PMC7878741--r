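# A gene plus a sense element spanning its 3' terminus, and a TAPAS table
# with sites planted at chosen offsets.
apa_setup <- function() {
  m <- make_model("+", txStart = 1000L, txEnd = 4000L, cdsStart = 1400L,
                  cdsEnd = 3500L, exonStarts = 1000L, exonEnds = 4000L,
                  name = "NM_000001", gene = "TK2")
  el <- random_rmsk_row("+")
  el$genoStart <- 3850L; el$genoEnd <- 4150L
  el$repStart <- 1L; el$repEnd <- 300L; el$repLeft <- -11L
  anti <- el
  anti$strand <- "-"; anti$repStart <- -11L; anti$repLeft <- 1L
  anti$genoStart <- 3400L; anti$genoEnd <- 3700L
  list(model = m, reps = rbind(el, anti))
}

tapas_df <- function(gene, chrom, strand, sites, ab = rep(1, length(sites))) {
  df <- data.frame(gene = gene, chrom = chrom, strand = strand,
                   read_count = 100L, stringsAsFactors = FALSE)
  df$apa_sites <- list(as.integer(sites))
  df$abundances <- list(ab)
  df[c("gene", "chrom", "strand", "apa_sites", "abundances", "read_count")]
}

test_that("APA sites join onto sense elements with anatomy calls", {
  su <- apa_setup()
  cfg <- anatomy_config()
  # tail-extension site, in-element site, off-element site
  apa <- tapas_df("TK2", "chr1", "+", c(4160L, 3999L, 3600L))
  rows <- join_apa_to_elements(apa, su$reps, list(su$model), cfg,
                               target_rep_name = "AluYRa1", sense_only = TRUE)
  expect_equal(nrow(rows), 3L)
  r <- rows[order(rows$apa_pos), ]
  # 3600 lies inside the antisense element only: gated out under sense_only
  expect_false(r$on_element[1L])
  expect_true(is.na(r$anatomy[1L]))
  # 3999 maps to consensus 150 -> A-rich linker
  expect_true(r$on_element[2L])
  expect_equal(r$anatomy[2L], "A_RICH_LINKER")
  # 4160 is 10 bp past the element end -> poly-A tail
  expect_true(r$on_element[3L])
  expect_equal(r$anatomy[3L], "POLY_A_TAIL")
  expect_equal(unique(r$element_orientation[r$on_element]), "SENSE")
  # without the orientation gate the antisense element captures the site
  rows2 <- join_apa_to_elements(apa, su$reps, list(su$model), cfg,
                                sense_only = FALSE)
  expect_true(rows2$on_element[rows2$apa_pos == 3600L])
  expect_equal(rows2$element_orientation[rows2$apa_pos == 3600L], "ANTISENSE")
})

test_that("strand conflicts and missing 3'UTRs are excluded; absent genes unjoined", {
  su <- apa_setup()
  nc <- make_model("+", txStart = 8000L, txEnd = 9000L, cdsStart = 9000L,
                   cdsEnd = 9000L, exonStarts = 8000L, exonEnds = 9000L,
                   name = "NR_1", gene = "LINC1")
  apa <- rbind(tapas_df("TK2", "chr1", "-", 3999L),   # strand conflict
               tapas_df("LINC1", "chr1", "+", 8500L), # no 3'UTR
               tapas_df("GHOST", "chr1", "+", 100L))  # not annotated
  rows <- join_apa_to_elements(apa, su$reps, list(su$model, nc), anatomy_config())
  expect_equal(nrow(rows), 0L)
  excl <- attr(rows, "excluded")
  expect_setequal(excl$gene, c("TK2", "LINC1"))
  expect_equal(excl$reason[excl$gene == "TK2"], "strand_conflict")
  expect_equal(excl$reason[excl$gene == "LINC1"], "no_utr3")
  expect_equal(attr(rows, "unjoined"), "GHOST")
})

fabricated_rows <- function(n_tail = 40L, n_arich = 34L, n_off = 26L,
                            ab = NULL) {
  n <- n_tail + n_arich + n_off
  anatomy <- c(rep("POLY_A_TAIL", n_tail), rep("A_RICH_LINKER", n_arich),
               rep(NA_character_, n_off))
  df <- data.frame(
    gene = rep(c("TK2", "GTPBP4", "PEX26", "IRF9"), length.out = n),
    transcript = "NM_1", apa_pos = seq_len(n),
    abundance = ab %||% rep(1, n),
    on_element = !is.na(anatomy),
    element_orientation = ifelse(is.na(anatomy), NA, "SENSE"),
    anatomy = anatomy, rep_row = 1L, stringsAsFactors = FALSE)
  class(df) <- c("apa_overlap_rows", "data.frame")
  df
}

test_that("site-weighted summary reproduces the planted 74/40/34 composition", {
  s <- summarize_apa(fabricated_rows())
  expect_equal(s$pct_on_element, 74)
  expect_equal(s$pct_polyA_tail, 40)
  expect_equal(s$pct_a_rich, 34)
  expect_equal(s$pct_other_regions, 0)
  expect_equal(s$n_sites, 100L)
  # partition: region percentages sum to the on-element percentage
  expect_equal(s$pct_polyA_tail + s$pct_a_rich + s$pct_other_regions,
               s$pct_on_element)
  all_off <- fabricated_rows(0L, 0L, 10L)
  s0 <- summarize_apa(all_off)
  expect_equal(s0$pct_on_element, 0)
  expect_error(summarize_apa(fabricated_rows(1L, 0L, 0L)[0L, ]),
               "no joined APA sites")
})

test_that("abundance weighting matches a hand-computed weighted sum", {
  rows <- fabricated_rows(2L, 1L, 1L, ab = c(10, 1, 1, 8))
  s_site <- summarize_apa(rows, weight = "sites")
  s_ab <- summarize_apa(rows, weight = "abundance")
  expect_equal(s_site$pct_on_element, 75)
  expect_equal(s_ab$pct_on_element, 100 * (10 + 1 + 1) / 20)
  expect_equal(s_ab$pct_polyA_tail, 100 * 11 / 20)
  expect_equal(s_ab$pct_a_rich, 100 * 1 / 20)
  # permutation invariance
  perm <- rows[c(3L, 1L, 4L, 2L), ]
  s_perm <- summarize_apa(perm, weight = "abundance")
  expect_equal(s_perm$pct_on_element, s_ab$pct_on_element)
})

test_that("on-element fraction is monotone in the tail window", {
  su <- apa_setup()
  # sites marching away from the element end
  apa <- tapas_df("TK2", "chr1", "+", c(4150L, 4160L, 4175L, 4190L))
  pcts <- vapply(c(0L, 15L, 30L, 45L), function(ext) {
    cfg <- anatomy_config(polyA_max_extension = ext)
    summarize_apa(join_apa_to_elements(apa, su$reps, list(su$model),
                                       cfg))$pct_on_element
  }, numeric(1L))
  expect_true(all(diff(pcts) >= 0))
  expect_equal(pcts[1L], 0)
  expect_equal(pcts[4L], 100)
})
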