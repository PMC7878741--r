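#' Build a strand-aware transcript model from a genePred record
#'
#' Decomposes a transcript into 5'UTR, CDS and 3'UTR exon blocks and derives
#' the biological landmarks used by the positional classifier: the
#' transcription start/end points, ORF boundary points and internal splice
#' junction coordinates. All coordinates stay 0-based half-open; "points"
#' follow the UCSC convention of the record (so on `+` the transcript end
#' point equals `txEnd`, an exclusive coordinate, and on `-` it equals
#' `txStart`).
#'
#' Noncoding transcripts (`cdsStart == cdsEnd`) are flagged `noncoding` and
#' carry empty UTR/CDS blocks: an ncRNA has no ORF and hence no UTRs, so
#' only exon-body and splice-junction classifications apply to it.
#'
#' @param rec A single genePred record: either a one-row data frame from
#'   [read_genepred()] or a named list with fields `name`, `chrom`,
#'   `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `exonStarts`,
#'   `exonEnds` and optionally `name2`.
#' @return An object of class `transcript_model`: a list with the record
#'   fields plus `exons` (two-column matrix, start/end), `utr5_blocks`,
#'   `cds_blocks`, `utr3_blocks` (same shape), `tx_start_point`,
#'   `tx_end_point`, `orf_start_point`, `orf_end_point`,
#'   `internal_junctions`, `noncoding`.
#' @examples
#' m <- build_transcript_model(list(
#'   name = "NM_000001", chrom = "chr1", strand = "+",
#'   txStart = 0L, txEnd = 150L, cdsStart = 50L, cdsEnd = 100L,
#'   exonStarts = 0L, exonEnds = 150L, name2 = "G1"))
#' m$utr3_blocks
#' @export
build_transcript_model <- function(rec) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- list(name = rec$name, chrom = rec$chrom, strand = rec$strand,
                txStart = rec$txStart, txEnd = rec$txEnd,
                cdsStart = rec$cdsStart, cdsEnd = rec$cdsEnd,
                exonStarts = rec$exonStarts[[1L]], exonEnds = rec$exonEnds[[1L]],
                name2 = if (!is.null(rec$name2)) rec$name2 else rec$name)
  }
  es <- as.integer(rec$exonStarts); ee <- as.integer(rec$exonEnds)
  txStart <- as.integer(rec$txStart); txEnd <- as.integer(rec$txEnd)
  cdsStart <- as.integer(rec$cdsStart); cdsEnd <- as.integer(rec$cdsEnd)
  strand <- rec$strand
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (length(es) != length(ee) || any(ee <= es))
    stop("malformed exon blocks", call. = FALSE)
  if (es[1L] != txStart || ee[length(ee)] != txEnd)
    stop("exons must span [txStart, txEnd)", call. = FALSE)
  if (cdsStart < txStart || cdsEnd > txEnd || cdsStart > cdsEnd)
    stop("CDS outside transcript span", call. = FALSE)
  noncoding <- cdsStart == cdsEnd

  exons <- cbind(start = es, end = ee)
  clip <- function(lo, hi) {
    s <- pmax(es, lo); e <- pmin(ee, hi)
    keep <- e > s
    cbind(start = s[keep], end = e[keep])
  }
  if (noncoding) {
    utr5 <- cds <- utr3 <- cbind(start = integer(), end = integer())
  } else {
    left <- clip(txStart, cdsStart)
    cds <- clip(cdsStart, cdsEnd)
    right <- clip(cdsEnd, txEnd)
    if (strand == "+") { utr5 <- left; utr3 <- right } else { utr5 <- right; utr3 <- left }
  }
  junc <- sort(unique(c(ee[-length(ee)], es[-1L])))

  structure(list(
    name = rec$name, chrom = rec$chrom, strand = strand,
    txStart = txStart, txEnd = txEnd, cdsStart = cdsStart, cdsEnd = cdsEnd,
    name2 = rec$name2 %||% rec$name,
    exons = exons, utr5_blocks = utr5, cds_blocks = cds, utr3_blocks = utr3,
    tx_start_point = if (strand == "+") txStart else txEnd,
    tx_end_point = if (strand == "+") txEnd else txStart,
    orf_start_point = if (noncoding) NA_integer_ else if (strand == "+") cdsStart else cdsEnd,
    orf_end_point = if (noncoding) NA_integer_ else if (strand == "+") cdsEnd else cdsStart,
    internal_junctions = junc,
    noncoding = noncoding
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s]\n",
              x$name, x$name2, x$chrom, x$txStart, x$txEnd, x$strand))
  cat(sprintf("  exons: %d  %s  spliced 3'UTR: %s bp\n",
              nrow(x$exons),
              if (x$noncoding) "noncoding" else "coding",
              if (x$noncoding) "-" else sum(x$utr3_blocks[, "end"] - x$utr3_blocks[, "start"])))
  invisible(x)
}

#' Build transcript models for every row of a genePred table
#'
#' @param df A data frame from [read_genepred()].
#' @return A list of `transcript_model` objects, in row order.
#' @export
transcript_models <- function(df) {
  lapply(seq_len(nrow(df)), function(i) build_transcript_model(df[i, , drop = FALSE]))
}

# Strand-aware terminal and ORF *base* indices (0-based positions of actual
# nucleotides, unlike the point coordinates above). Internal to the
# classifiers.
terminal_bases <- function(model) {
  if (model$strand == "+") {
    list(t5 = model$txStart, t3 = model$txEnd - 1L)
  } else {
    list(t5 = model$txEnd - 1L, t3 = model$txStart)
  }
}

orf_bases <- function(model) {
  if (model$noncoding) return(list(start = NA_integer_, end = NA_integer_))
  if (model$strand == "+") {
    list(start = model$cdsStart, end = model$cdsEnd - 1L)
  } else {
    list(start = model$cdsEnd - 1L, end = model$cdsStart)
  }
}

block_width <- function(blocks) sum(blocks[, "end"] - blocks[, "start"])

base_in_blocks <- function(p, blocks) {
  any(blocks[, "start"] <= p & p < blocks[, "end"])
}

#' Spliced 3'UTR length
#'
#' Sum of exonic bases in the 3'UTR blocks: the spliced 3'UTR length, not
#' the genomic span (the two differ when the 3'UTR is interrupted by an
#' intron).
#'
#' @param model A `transcript_model`.
#' @return Integer length in bp.
#' @export
utr3_length <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  if (model$noncoding) stop("no 3'UTR defined for a noncoding transcript", call. = FALSE)
  as.integer(block_width(model$utr3_blocks))
}

#' Compare 3'UTR lengths of one gene across species
#'
#' Selects one isoform per species for the given gene symbol (by default
#' the longest-3'UTR registered `NM_` isoform; predicted `XM_` isoforms are
#' used only when `include_predicted = TRUE` or no registered isoform
#' exists) and reports the spliced 3'UTR lengths with a verdict for the
#' first species relative to the second: `"shorter"`, `"longer"`, or
#' `"similar"` when the relative difference is at most `tol`.
#'
#' @param models_by_species Named list (species -> list of
#'   `transcript_model`, or a single model).
#' @param gene Gene symbol to compare.
#' @param tol Relative-difference threshold for the `"similar"` verdict
#'   (default 0.1, i.e. 10%).
#' @param include_predicted Also consider `XM_` accessions (default TRUE,
#'   falling back to them only when no `NM_` isoform exists).
#' @return A data frame with one row per species: `gene`, `species`,
#'   `accession`, `utr3_len_bp` (NA when the gene is missing in that
#'   species), and the pairwise `verdict` stored on every row.
#' @export
compare_utr3 <- function(models_by_species, gene, tol = 0.1, include_predicted = TRUE) {
  stopifnot(length(models_by_species) >= 2L, !is.null(names(models_by_species)))
  pick <- function(models) {
    if (inherits(models, "transcript_model")) models <- list(models)
    models <- Filter(function(m) identical(m$name2, gene) && !m$noncoding, models)
    if (!length(models)) return(NULL)
    reg <- Filter(function(m) startsWith(m$name, "NM_"), models)
    pool <- if (length(reg)) reg else if (include_predicted) models else NULL
    if (!length(pool)) return(NULL)
    pool[[which.max(vapply(pool, utr3_length, integer(1L)))]]
  }
  sel <- lapply(models_by_species, pick)
  len <- vapply(sel, function(m) if (is.null(m)) NA_integer_ else utr3_length(m), integer(1L))
  acc <- vapply(sel, function(m) if (is.null(m)) NA_character_ else m$name, character(1L))
  l1 <- len[1L]; l2 <- len[2L]
  verdict <- if (is.na(l1) || is.na(l2)) {
    NA_character_
  } else if (abs(l1 - l2) / max(l1, l2, 1L) <= tol) {
    "similar"
  } else if (l1 < l2) "shorter" else "longer"
  data.frame(gene = gene, species = names(models_by_species),
             accession = acc, utr3_len_bp = len, verdict = verdict,
             row.names = NULL, stringsAsFactors = FALSE)
}
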