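select_gene_model <- function(models, gene, include_predicted = TRUE) {
  cand <- Filter(function(m) identical(m$name2, gene), models)
  if (!length(cand)) return(NULL)
  reg <- Filter(function(m) startsWith(m$name, "NM_"), cand)
  pool <- if (length(reg)) reg else if (include_predicted) cand else return(NULL)
  spans <- vapply(pool, function(m) m$txEnd - m$txStart, integer(1L))
  pool[[which.max(spans)]]
}

#' Join TAPAS polyadenylation sites onto located repeat elements
#'
#' For every gene in the TAPAS output, finds the target-subfamily repeats
#' overlapping that gene's transcript and tests each reported
#' polyadenylation site for containment in an element, extending the
#' element by the anatomy config's poly-A tail window on the element's
#' sense 3' side (cleavage on the tail falls just past the annotated
#' element end). Sites on an element are classified into Alu anatomical
#' regions via [classify_anatomy()].
#'
#' Gene-level exclusions mirror the filtering applied before the published
#' statistics: a gene is excluded (and logged, not errored) when its TAPAS
#' strand conflicts with the annotation strand or when the annotated
#' transcript has no 3'UTR block ("inappropriate gene structure"). Genes
#' absent from the annotation are reported as unjoined.
#'
#' @param apa A data frame from [read_tapas()].
#' @param reps An rmsk data frame from [read_rmsk()].
#' @param models A list of transcript models; one isoform per gene symbol
#'   is selected (registered `NM_` preferred, widest genomic span).
#' @param cfg An [anatomy_config()]; its `polyA_max_extension` defines the
#'   tail window.
#' @param target_rep_name Repeat subfamily to test against (default
#'   `"AluYRa1"`).
#' @param sense_only Only count elements whose strand matches the
#'   transcript strand (default `TRUE`, matching the sense-insertion
#'   hypothesis).
#' @return A data frame of class `apa_overlap_rows`, one row per APA site:
#'   `gene`, `transcript`, `apa_pos`, `abundance`, `on_element`,
#'   `element_orientation` (`NA` off-element), `anatomy` (region, `NA`
#'   off-element), `rep_row`. Excluded genes are recorded in
#'   `attr(x, "excluded")` (gene, reason); unjoined gene symbols in
#'   `attr(x, "unjoined")`.
#' @export
join_apa_to_elements <- function(apa, reps, models, cfg = anatomy_config(),
                                 target_rep_name = "AluYRa1", sense_only = TRUE) {
  stopifnot(inherits(cfg, "anatomy_config"))
  ext <- cfg$polyA_max_extension
  unjoined <- character()
  excluded <- data.frame(gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(apa))) {
    gene <- apa$gene[i]
    m <- select_gene_model(models, gene)
    if (is.null(m)) { unjoined <- c(unjoined, gene); next }
    if (!identical(m$strand, apa$strand[i])) {
      excluded <- rbind(excluded, data.frame(gene = gene, reason = "strand_conflict",
                                             stringsAsFactors = FALSE))
      next
    }
    if (m$noncoding || nrow(m$utr3_blocks) == 0L) {
      excluded <- rbind(excluded, data.frame(gene = gene, reason = "no_utr3",
                                             stringsAsFactors = FALSE))
      next
    }
    cand <- which(reps$repName == target_rep_name &
                    reps$genoName == m$chrom &
                    reps$genoStart < m$txEnd + ext &
                    reps$genoEnd > m$txStart - ext)
    if (sense_only) cand <- cand[reps$strand[cand] == m$strand]
    cand <- cand[order(reps$genoStart[cand])]
    sites <- apa$apa_sites[[i]]
    abund <- apa$abundances[[i]]
    for (k in seq_along(sites)) {
      pos <- sites[k]
      hit <- NA_integer_
      for (j in cand) {
        plus <- reps$strand[j] == "+"
        lo <- if (plus) reps$genoStart[j] else reps$genoStart[j] - ext
        hi <- if (plus) reps$genoEnd[j] + ext else reps$genoEnd[j]
        if (pos >= lo && pos < hi) { hit <- j; break }
      }
      on_el <- !is.na(hit)
      anat <- if (on_el) {
        classify_anatomy(reps[hit, , drop = FALSE], pos, cfg)$region
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, transcript = m$name, apa_pos = pos, abundance = abund[k],
        on_element = on_el,
        element_orientation = if (on_el) {
          if (identical(reps$strand[hit], m$strand)) "SENSE" else "ANTISENSE"
        } else NA_character_,
        anatomy = anat, rep_row = hit, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), transcript = character(), apa_pos = integer(),
               abundance = numeric(), on_element = logical(),
               element_orientation = character(), anatomy = character(),
               rep_row = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "unjoined") <- unique(unjoined)
  class(out) <- c("apa_overlap_rows", "data.frame")
  out
}

#' Summarize APA sites over repeat elements
#'
#' Computes the fraction of polyadenylation sites falling on the target
#' elements and its split across the Alu anatomy (poly-A tail, A-rich
#' linker, remaining arm regions). The default weights each site equally,
#' matching site-count percentages; `weight = "abundance"` weights sites by
#' their reported abundance instead.
#'
#' @param rows A data frame from [join_apa_to_elements()].
#' @param weight `"sites"` (default) or `"abundance"`.
#' @return An object of class `apa_summary`: list with `n_sites`,
#'   `weight`, percentages `pct_on_element`, `pct_polyA_tail`,
#'   `pct_a_rich`, `pct_other_regions` (all relative to the total weight,
#'   so the three region percentages sum to `pct_on_element`), and
#'   `per_gene`, a per-gene breakdown table. Percentages are stored at full
#'   precision; the print method shows the integer (half-up) headline
#'   figures.
#' @export
summarize_apa <- function(rows, weight = c("sites", "abundance")) {
  weight <- match.arg(weight)
  if (!nrow(rows)) stop("no joined APA sites", call. = FALSE)
  w <- if (weight == "abundance") rows$abundance else rep(1, nrow(rows))
  tot <- sum(w)
  pct <- function(sel) 100 * sum(w[sel]) / tot
  on <- rows$on_element
  tail_ <- on & rows$anatomy == "POLY_A_TAIL"
  arich <- on & rows$anatomy == "A_RICH_LINKER"
  other <- on & !tail_ & !arich
  per_gene <- do.call(rbind, lapply(split(seq_len(nrow(rows)), rows$gene), function(ix) {
    data.frame(gene = rows$gene[ix[1L]], n_sites = length(ix),
               n_on_element = sum(on[ix]),
               pct_on_element = 100 * sum(w[ix][on[ix]]) / sum(w[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  structure(list(
    n_sites = nrow(rows), weight = weight,
    pct_on_element = pct(on),
    pct_polyA_tail = pct(tail_),
    pct_a_rich = pct(arich),
    pct_other_regions = pct(other),
    per_gene = per_gene
  ), class = "apa_summary")
}

#' @export
print.apa_summary <- function(x, ...) {
  cat(sprintf("<apa_summary> %d sites (%s-weighted)\n", x$n_sites, x$weight))
  cat(sprintf("  on element: %d%%  (poly-A tail %d%%, A-rich %d%%, arms %d%%)\n",
              round_half_up(x$pct_on_element), round_half_up(x$pct_polyA_tail),
              round_half_up(x$pct_a_rich), round_half_up(x$pct_other_regions)))
  cat(sprintf("  genes: %d\n", nrow(x$per_gene)))
  invisible(x)
}

#' Write an APA summary as TSV
#'
#' One headline row (percentages to one decimal) followed by the per-gene
#' breakdown in a second table is avoided; instead two files are natural,
#' so this writes the headline table and returns the per-gene table
#' invisibly for callers that want it.
#'
#' @param x An `apa_summary`.
#' @param path Output path for the headline TSV.
#' @param per_gene_path Optional path for the per-gene TSV.
#' @return `path`, invisibly.
#' @export
write_apa_summary <- function(x, path, per_gene_path = NULL) {
  head_df <- data.frame(
    n_sites = x$n_sites, weight = x$weight,
    pct_on_element = round_half_up(x$pct_on_element, 1L),
    pct_polyA_tail = round_half_up(x$pct_polyA_tail, 1L),
    pct_a_rich = round_half_up(x$pct_a_rich, 1L),
    pct_other_regions = round_half_up(x$pct_other_regions, 1L))
  write_tsv_atomic(head_df, path)
  if (!is.null(per_gene_path)) {
    pg <- x$per_gene
    pg$pct_on_element <- round_half_up(pg$pct_on_element, 1L)
    write_tsv_atomic(pg, per_gene_path)
  }
  invisible(path)
}
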