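# Builders used across the suite. Everything is constructed in code; no
# stored fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

block_width <- function(blocks) sum(blocks[, "end"] - blocks[, "start"])

make_model <- function(strand = "+", txStart = 0L, txEnd = 150L,
                       cdsStart = 50L, cdsEnd = 100L,
                       exonStarts = txStart, exonEnds = txEnd,
                       name = "NM_000001", gene = "G1", chrom = "chr1") {
  build_transcript_model(list(
    name = name, chrom = chrom, strand = strand,
    txStart = txStart, txEnd = txEnd, cdsStart = cdsStart, cdsEnd = cdsEnd,
    exonStarts = exonStarts, exonEnds = exonEnds, name2 = gene))
}

make_rep <- function(genoStart, genoEnd, strand = "+", chrom = "chr1",
                     repName = "AluYRa1", repClass = "SINE", repFamily = "Alu",
                     consensusStart = 1L,
                     consensusEnd = consensusStart + (genoEnd - genoStart) - 1L) {
  list(chrom = chrom, genoName = chrom, genoStart = as.integer(genoStart),
       genoEnd = as.integer(genoEnd), strand = strand, repName = repName,
       repClass = repClass, repFamily = repFamily,
       consensusStart = as.integer(consensusStart),
       consensusEnd = as.integer(consensusEnd))
}

# A random repeat x transcript instance for oracle-equivalence testing:
# 1-5 exons, both strands, coding and noncoding, repeats dropped anywhere
# around the transcript. Draws from the current RNG stream.
random_locator_instance <- function() {
  k <- sample(1:5, 1L)
  strand <- sample(c("+", "-"), 1L)
  elens <- sample(30:120, k, replace = TRUE)
  ilens <- if (k > 1L) sample(20:80, k - 1L, replace = TRUE) else integer()
  txStart <- sample(200:400, 1L)
  es <- integer(k); ee <- integer(k); pos <- txStart
  for (e in seq_len(k)) {
    es[e] <- pos; ee[e] <- pos + elens[e]
    pos <- ee[e] + if (e < k) ilens[e] else 0L
  }
  txEnd <- ee[k]
  if (stats::runif(1L) < 0.2) {
    cs <- ce <- txEnd  # noncoding
  } else {
    cs <- sample(txStart:(txEnd - 1L), 1L)
    ce <- sample(cs:txEnd, 1L)
  }
  m <- make_model(strand = strand, txStart = txStart, txEnd = txEnd,
                  cdsStart = cs, cdsEnd = ce, exonStarts = es, exonEnds = ee)
  w <- sample(5:150, 1L)
  a <- sample(max(0L, txStart - 200L):(txEnd + 200L), 1L)
  list(rep = make_rep(a, a + w, strand = sample(c("+", "-"), 1L)), model = m)
}

# One rmsk data frame row with consistent consensus fields for either
# strand (genomic length == consensus span, so the affine map is exact).
random_rmsk_row <- function(strand, consensus_length = 311L) {
  glen <- sample(100:consensus_length, 1L)
  cs <- sample(1:(consensus_length - glen + 1L), 1L)
  ce <- cs + glen - 1L
  a <- sample(1000:100000, 1L)
  data.frame(bin = 0L, swScore = 1000L, milliDiv = 50L, milliDel = 5L,
             milliIns = 5L, genoName = "chr1", genoStart = a, genoEnd = a + glen,
             genoLeft = -1000L, strand = strand, repName = "AluYRa1",
             repClass = "SINE", repFamily = "Alu",
             repStart = if (strand == "+") cs else -(consensus_length - ce),
             repEnd = ce,
             repLeft = if (strand == "+") -(consensus_length - ce) else cs,
             id = 1L, stringsAsFactors = FALSE)
}

# Fixture spec planting every positional category in both orientations.
all_category_spec <- function(seed = 7L, per_cell = 5L) {
  plants <- expand.grid(category = POSITIONAL_CATEGORIES,
                        orientation = c("SENSE", "ANTISENSE"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plants$repName <- "AluYRa1"
  plants$count <- per_cell
  fixture_spec(seed = seed, n_genes = 24L, planted_repeats = plants)
}
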