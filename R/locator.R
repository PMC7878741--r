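#' Positional categories, in precedence order
#'
#' The nine positional categories a repeat x transcript pair can receive,
#' ordered by the precedence used to pick the primary category when several
#' apply: terminal events first (the 3'UTR terminus is the phenomenon of
#' interest), then ORF boundaries, then splice junctions, then containment
#' classes.
#'
#' @format Character vector of length 9.
#' @export
POSITIONAL_CATEGORIES <- c(
  "UTR3_END", "UTR5_START", "ORF_END", "ORF_START", "EXON_SPLICING",
  "UTR3_INTERNAL", "UTR5_INTERNAL", "INSIDE_EXON", "NO_EXONIC_OVERLAP"
)

as_rep_record <- function(rep) {
  if (is.data.frame(rep)) {
    stopifnot(nrow(rep) == 1L)
    rep <- as.list(rep)
  }
  if (is.null(rep$chrom)) rep$chrom <- rep$genoName
  stopifnot(!is.null(rep$genoStart), !is.null(rep$genoEnd), !is.null(rep$strand))
  rep
}

# Distance (bp) from repeat [a,b) to a terminal base t. Covering is 0. On
# the beyond-end side the transcript boundary coordinate is exclusive, so an
# element that starts exactly at the first post-transcript base abuts the
# terminus at distance 0; on the inside the distance counts bases between
# the element and the terminal base.
term_dist <- function(a, b, t, beyond_high) {
  if (a <= t && t < b) return(0L)
  if (beyond_high) {
    if (a > t) a - t - 1L else t - b + 1L
  } else {
    if (b <= t) t - b else a - t
  }
}

#' Classify one repeat x transcript pair into a positional category
#'
#' Assigns every positional category whose definition the pair satisfies,
#' then resolves a primary category by precedence (see
#' [POSITIONAL_CATEGORIES]). The definitions:
#'
#' * `UTR3_END` - the element contains, or lies within `proximity_bp` of,
#'   the biological transcript end, and that terminal base is in a 3'UTR
#'   block. An element abutting immediately downstream of the terminus also
#'   qualifies at distance 0 (the transcript end coordinate is exclusive).
#' * `UTR5_START` - same for the biological transcript start in the 5'UTR.
#' * `ORF_START` / `ORF_END` - the element covers the first / last coding
#'   base.
#' * `EXON_SPLICING` - the element spans an internal exon boundary, i.e.
#'   covers at least one base on each side of a splice junction.
#' * `UTR3_INTERNAL` / `UTR5_INTERNAL` - the element overlaps exonic bases
#'   that all lie in the respective UTR, without touching the terminal
#'   position.
#' * `INSIDE_EXON` - fully within one exon and overlapping no boundary;
#'   also the fallback for any other exonic overlap (e.g. on noncoding
#'   transcripts, which have no UTRs or ORF).
#' * `NO_EXONIC_OVERLAP` - no exonic overlap and no terminal proximity
#'   (e.g. purely intronic).
#'
#' Orientation is `SENSE` when the repeat strand equals the transcript
#' strand, `ANTISENSE` otherwise.
#'
#' @param rep A single rmsk record (one-row data frame from [read_rmsk()]
#'   or a named list with `genoName`/`chrom`, `genoStart`, `genoEnd`,
#'   `strand`, optionally `repName`).
#' @param model A [transcript_model][build_transcript_model].
#' @param proximity_bp Window (bp) around the biological terminus within
#'   which a non-overlapping element still counts as a terminal event.
#'   Default 0: strict overlap/abutment, so a near-miss element a few bases
#'   short of the terminus is classed internal.
#' @return An object of class `positional_call`: list with `repeat_id`,
#'   `transcript_id`, `gene`, `category`, `all_categories`, `orientation`,
#'   `overlap_bp` (exonic overlap), `distance_to_terminal` (signed bp to
#'   the 3' terminus: negative upstream within the transcript, positive
#'   beyond the end, 0 when covering it).
#' @export
classify_pair <- function(rep, model, proximity_bp = 0L) {
  rep <- as_rep_record(rep)
  stopifnot(inherits(model, "transcript_model"))
  if (!identical(as.character(rep$chrom), model$chrom)) {
    stop(sprintf("chromosome mismatch: repeat on %s, transcript on %s",
                 rep$chrom, model$chrom), call. = FALSE)
  }
  if (proximity_bp < 0L) stop("proximity_bp must be >= 0", call. = FALSE)
  a <- as.integer(rep$genoStart); b <- as.integer(rep$genoEnd)
  ex <- model$exons
  ov <- function(blocks) {
    if (!nrow(blocks)) return(0L)
    as.integer(sum(pmax(0L, pmin(blocks[, "end"], b) - pmax(blocks[, "start"], a))))
  }
  ov_ex <- ov(ex)
  tb <- terminal_bases(model)
  ob <- orf_bases(model)
  plus <- model$strand == "+"
  d3 <- term_dist(a, b, tb$t3, beyond_high = plus)
  d5 <- term_dist(a, b, tb$t5, beyond_high = !plus)
  utr3_ok <- !model$noncoding && nrow(model$utr3_blocks) > 0L &&
    base_in_blocks(tb$t3, model$utr3_blocks)
  utr5_ok <- !model$noncoding && nrow(model$utr5_blocks) > 0L &&
    base_in_blocks(tb$t5, model$utr5_blocks)
  covers <- function(p) !is.na(p) && a <= p && p < b
  junc <- model$internal_junctions
  spans_junction <- length(junc) > 0L && any(a < junc & junc < b)

  cats <- character()
  if (utr3_ok && d3 <= proximity_bp) cats <- c(cats, "UTR3_END")
  if (utr5_ok && d5 <= proximity_bp) cats <- c(cats, "UTR5_START")
  if (covers(ob$end)) cats <- c(cats, "ORF_END")
  if (covers(ob$start)) cats <- c(cats, "ORF_START")
  if (spans_junction) cats <- c(cats, "EXON_SPLICING")
  if (ov_ex > 0L && ov(model$utr3_blocks) == ov_ex && d3 > 0L)
    cats <- c(cats, "UTR3_INTERNAL")
  if (ov_ex > 0L && ov(model$utr5_blocks) == ov_ex && d5 > 0L)
    cats <- c(cats, "UTR5_INTERNAL")
  boundary_hit <- (utr3_ok && d3 == 0L) || (utr5_ok && d5 == 0L) ||
    covers(ob$start) || covers(ob$end) || spans_junction
  inside_one_exon <- any(ex[, "start"] <= a & b <= ex[, "end"])
  if (ov_ex > 0L && inside_one_exon && !boundary_hit) cats <- c(cats, "INSIDE_EXON")
  if (ov_ex > 0L && !length(cats)) cats <- "INSIDE_EXON"
  if (!length(cats)) cats <- "NO_EXONIC_OVERLAP"
  cats <- POSITIONAL_CATEGORIES[POSITIONAL_CATEGORIES %in% cats]

  beyond3 <- if (plus) a > tb$t3 else b <= tb$t3
  structure(list(
    repeat_id = rep$repName %||% sprintf("%s:%d-%d", rep$chrom, a, b),
    transcript_id = model$name,
    gene = model$name2,
    category = cats[[1L]],
    all_categories = cats,
    orientation = if (identical(rep$strand, model$strand)) "SENSE" else "ANTISENSE",
    overlap_bp = ov_ex,
    distance_to_terminal = if (beyond3) d3 else -d3
  ), class = "positional_call")
}

#' @export
print.positional_call <- function(x, ...) {
  cat(sprintf("<positional_call> %s x %s (%s): %s [%s], overlap %d bp, dist %d\n",
              x$repeat_id, x$transcript_id, x$gene, x$category, x$orientation,
              x$overlap_bp, x$distance_to_terminal))
  if (length(x$all_categories) > 1L)
    cat("  all:", paste(x$all_categories, collapse = ", "), "\n")
  invisible(x)
}

#' Locate all repeats against all transcripts
#'
#' Classifies every repeat x transcript pair with exonic overlap or within
#' terminal proximity, using an interval index for candidate pairing. One
#' call is produced per pair, so a repeat overlapping two isoforms of one
#' gene yields two rows (collapse with [gene_inventory()]).
#'
#' @param reps An rmsk data frame from [read_rmsk()].
#' @param models A list of transcript models ([transcript_models()]).
#' @param rep_name Optional repeat subfamily filter (e.g. `"AluYRa1"`).
#' @param proximity_bp Passed to [classify_pair()].
#' @param emit_nonoverlapping Keep `NO_EXONIC_OVERLAP` calls (e.g. purely
#'   intronic repeats)? Default `FALSE` to bound output size.
#' @return A data frame of class `positional_calls`, one row per call,
#'   deterministically ordered by chromosome, `genoStart` and transcript
#'   accession. Columns: `chrom`, `genoStart`, `genoEnd`, `repName`,
#'   `repClass`, `repFamily`, `repStrand`, `rep_row` (row index into
#'   `reps`), `transcript`, `gene`, `txStrand`, `category`,
#'   `all_categories` (comma-joined), `orientation`, `overlap_bp`,
#'   `distance_to_terminal`.
#' @export
locate_all <- function(reps, models, rep_name = NULL, proximity_bp = 0L,
                       emit_nonoverlapping = FALSE) {
  keep <- if (is.null(rep_name)) seq_len(nrow(reps)) else which(reps$repName %in% rep_name)
  empty <- data.frame(
    chrom = character(), genoStart = integer(), genoEnd = integer(),
    repName = character(), repClass = character(), repFamily = character(),
    repStrand = character(), rep_row = integer(), transcript = character(),
    gene = character(), txStrand = character(), category = character(),
    all_categories = character(), orientation = character(),
    overlap_bp = integer(), distance_to_terminal = integer(),
    stringsAsFactors = FALSE)
  class(empty) <- c("positional_calls", "data.frame")
  if (!length(keep) || !length(models)) return(empty)

  pad <- proximity_bp + 1L  # +1 catches elements abutting the exclusive end
  rg <- GenomicRanges::GRanges(
    seqnames = reps$genoName[keep],
    ranges = IRanges::IRanges(start = pmax(1L, reps$genoStart[keep] + 1L - pad),
                              end = reps$genoEnd[keep] + pad))
  tg <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, character(1L), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(models, `[[`, integer(1L), "txStart") + 1L,
      end = vapply(models, `[[`, integer(1L), "txEnd")))
  hits <- GenomicRanges::findOverlaps(rg, tg)
  if (!length(hits)) return(empty)

  rows <- lapply(seq_along(hits), function(k) {
    i <- keep[S4Vectors::queryHits(hits)[k]]
    m <- models[[S4Vectors::subjectHits(hits)[k]]]
    pc <- classify_pair(reps[i, , drop = FALSE], m, proximity_bp = proximity_bp)
    if (pc$category == "NO_EXONIC_OVERLAP" && !emit_nonoverlapping) return(NULL)
    data.frame(
      chrom = reps$genoName[i], genoStart = reps$genoStart[i],
      genoEnd = reps$genoEnd[i], repName = reps$repName[i],
      repClass = reps$repClass[i], repFamily = reps$repFamily[i],
      repStrand = reps$strand[i], rep_row = i,
      transcript = pc$transcript_id, gene = pc$gene, txStrand = m$strand,
      category = pc$category,
      all_categories = paste(pc$all_categories, collapse = ","),
      orientation = pc$orientation, overlap_bp = pc$overlap_bp,
      distance_to_terminal = pc$distance_to_terminal,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$genoStart, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("positional_calls", "data.frame")
  out
}

#' Count positional calls by repeat group, category and orientation
#'
#' @param calls A data frame from [locate_all()].
#' @param group_by `"repName"`, `"repFamily"` or `"repClass"`.
#' @return A data frame keyed by (group, category, orientation) including
#'   zero rows for empty cells of the groups present, with counts summing
#'   to `nrow(calls)`.
#' @export
summarize_positions <- function(calls, group_by = c("repName", "repFamily", "repClass")) {
  group_by <- match.arg(group_by)
  groups <- sort(unique(calls[[group_by]]))
  grid <- expand.grid(group = groups, category = POSITIONAL_CATEGORIES,
                      orientation = c("SENSE", "ANTISENSE"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(g, c, o) paste(g, c, o, sep = "\r")
  tab <- table(key(calls[[group_by]], calls$category, calls$orientation))
  grid$n <- as.integer(tab[key(grid$group, grid$category, grid$orientation)])
  grid$n[is.na(grid$n)] <- 0L
  names(grid)[1L] <- group_by
  grid <- grid[order(grid[[group_by]],
                     match(grid$category, POSITIONAL_CATEGORIES),
                     grid$orientation, decreasing = c(FALSE, FALSE, TRUE),
                     method = "radix"), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

accession_class <- function(acc) {
  ifelse(startsWith(acc, "NM_"), "NM", ifelse(startsWith(acc, "XM_"), "XM", "other"))
}

#' Collapse positional calls to a per-gene inventory
#'
#' Counts distinct gene symbols supported by calls of a given category (and
#' optionally repeat subfamily), reporting whether support comes from
#' registered (`NM_`) or predicted (`XM_`) accessions. A gene is kept when
#' at least one supporting accession belongs to `accession_classes`, so
#' `accession_classes = "NM"` drops genes supported only by predicted
#' transcripts.
#'
#' @param calls A data frame from [locate_all()].
#' @param category Positional category to inventory (default `"UTR3_END"`).
#' @param rep_name Optional repeat subfamily filter.
#' @param accession_classes Subset of `c("NM", "XM", "other")`.
#' @return A data frame with one row per gene: `gene`, `n_transcripts`,
#'   `accessions` (comma-joined), `support` (`"NM"` when any registered
#'   accession supports the call, else `"XM"`, else `"other"`).
#' @export
gene_inventory <- function(calls, category = "UTR3_END", rep_name = NULL,
                           accession_classes = c("NM", "XM")) {
  stopifnot(category %in% POSITIONAL_CATEGORIES)
  accession_classes <- match.arg(accession_classes, c("NM", "XM", "other"),
                                 several.ok = TRUE)
  sel <- calls$category == category
  if (!is.null(rep_name)) sel <- sel & calls$repName %in% rep_name
  calls <- calls[sel, , drop = FALSE]
  if (!nrow(calls)) {
    return(data.frame(gene = character(), n_transcripts = integer(),
                      accessions = character(), support = character(),
                      stringsAsFactors = FALSE))
  }
  by_gene <- split(calls$transcript, calls$gene)
  rows <- lapply(names(by_gene), function(g) {
    acc <- sort(unique(by_gene[[g]]))
    cls <- unique(accession_class(acc))
    if (!any(cls %in% accession_classes)) return(NULL)
    support <- if ("NM" %in% cls) "NM" else if ("XM" %in% cls) "XM" else "other"
    data.frame(gene = g, n_transcripts = length(acc),
               accessions = paste(acc, collapse = ","), support = support,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(gene = character(), n_transcripts = integer(),
                      accessions = character(), support = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
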