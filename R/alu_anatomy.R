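#' Configure the Alu consensus anatomy
#'
#' An Alu element is a dimer of two 7SL-derived monomers (left arm, right
#' arm) joined by an A-rich linker and followed by a poly-A tail. This
#' config carves the consensus into those regions by 1-based inclusive
#' consensus intervals, which must be contiguous and cover
#' `[1, consensus_length]`; anything downstream of the consensus end (up to
#' `polyA_max_extension` bp past the element's genomic 3' end) is treated
#' as poly-A tail, which rmsk does not annotate explicitly.
#'
#' The defaults (left arm 1-131, linker 132-158, right arm 159-311 of a
#' 311 bp consensus, 30 bp tail window) follow the canonical AluY dimeric
#' layout. They are implementation defaults, not measured AluYRa1
#' coordinates; analyses that depend on region boundaries should construct
#' their own config.
#'
#' @param left_arm,a_linker,right_arm Length-2 integer vectors, 1-based
#'   inclusive consensus intervals.
#' @param consensus_length Consensus length in bp.
#' @param polyA_max_extension Bases downstream of the element's genomic 3'
#'   end still counted as poly-A tail.
#' @return An object of class `anatomy_config`.
#' @export
anatomy_config <- function(left_arm = c(1L, 131L), a_linker = c(132L, 158L),
                           right_arm = c(159L, 311L), consensus_length = 311L,
                           polyA_max_extension = 30L) {
  left_arm <- as.integer(left_arm); a_linker <- as.integer(a_linker)
  right_arm <- as.integer(right_arm)
  consensus_length <- as.integer(consensus_length)
  polyA_max_extension <- as.integer(polyA_max_extension)
  ok <- length(left_arm) == 2L && length(a_linker) == 2L && length(right_arm) == 2L &&
    left_arm[1L] == 1L && left_arm[2L] >= left_arm[1L] &&
    a_linker[1L] == left_arm[2L] + 1L && a_linker[2L] >= a_linker[1L] &&
    right_arm[1L] == a_linker[2L] + 1L && right_arm[2L] >= right_arm[1L] &&
    right_arm[2L] == consensus_length
  if (!ok) stop("anatomy regions must be contiguous and cover [1, consensus_length]",
                call. = FALSE)
  if (polyA_max_extension < 0L) stop("polyA_max_extension must be >= 0", call. = FALSE)
  structure(list(left_arm = left_arm, a_linker = a_linker, right_arm = right_arm,
                 consensus_length = consensus_length,
                 polyA_max_extension = polyA_max_extension),
            class = "anatomy_config")
}

#' @export
print.anatomy_config <- function(x, ...) {
  cat(sprintf("<anatomy_config> left arm %d-%d | A-rich %d-%d | right arm %d-%d (consensus %d bp, tail window %d bp)\n",
              x$left_arm[1L], x$left_arm[2L], x$a_linker[1L], x$a_linker[2L],
              x$right_arm[1L], x$right_arm[2L], x$consensus_length,
              x$polyA_max_extension))
  invisible(x)
}

rep_consensus_view <- function(rep) {
  rep <- as_rep_record(rep)
  if (is.null(rep$consensusStart)) {
    plus <- rep$strand == "+"
    rep$consensusStart <- if (plus) rep$repStart else rep$repLeft
    rep$consensusEnd <- rep$repEnd
  }
  rep
}

#' Map a genomic position into repeat consensus coordinates
#'
#' Affine mapping between the element's genomic interval and its consensus
#' interval, respecting the element strand: on `+` consensus coordinates
#' increase with genomic position, on `-` they decrease (the consensus 3'
#' end sits at the genomic start). Positions past the element's 3' end on
#' its own sense side, within `polyA_max_extension`, map to the beyond-end
#' marker (status `"beyond_end"`), as do in-element positions whose mapped
#' coordinate exceeds the consensus end. Everything else is
#' `"off_element"` (a signal, not an error).
#'
#' The map ignores indels between the genomic copy and the consensus; it is
#' exact for equal-length spans (as produced by the fixture generator) and
#' approximate for real diverged copies.
#'
#' @param rep A single rmsk record (with the normalized consensus view from
#'   [read_rmsk()], or raw `repStart`/`repEnd`/`repLeft` fields).
#' @param pos Genomic position, 0-based.
#' @param polyA_max_extension Tail window in bp (default 0).
#' @return A list with `status` (`"in_element"`, `"beyond_end"`,
#'   `"off_element"`) and `consensus` (1-based consensus bp, `NA` unless
#'   in-element).
#' @seealso [consensus_to_genomic()], [classify_anatomy()]
#' @export
genomic_to_consensus <- function(rep, pos, polyA_max_extension = 0L) {
  rep <- rep_consensus_view(rep)
  pos <- as.integer(pos)
  a <- as.integer(rep$genoStart); b <- as.integer(rep$genoEnd)
  ext <- as.integer(polyA_max_extension)
  plus <- rep$strand == "+"
  if (pos >= a && pos < b) {
    cons <- if (plus) rep$consensusStart + (pos - a) else rep$consensusEnd - (pos - a)
    if (cons > rep$consensusEnd) {
      return(list(status = "beyond_end", consensus = NA_integer_))
    }
    return(list(status = "in_element", consensus = as.integer(cons)))
  }
  beyond <- if (plus) pos >= b && pos < b + ext else pos < a && pos >= a - ext
  if (beyond) return(list(status = "beyond_end", consensus = NA_integer_))
  list(status = "off_element", consensus = NA_integer_)
}

#' Map a consensus coordinate back to a genomic position
#'
#' Inverse of [genomic_to_consensus()] for in-element coordinates.
#'
#' @param rep A single rmsk record.
#' @param consensus 1-based consensus position within the element's mapped
#'   consensus span.
#' @return Genomic position, 0-based.
#' @export
consensus_to_genomic <- function(rep, consensus) {
  rep <- rep_consensus_view(rep)
  consensus <- as.integer(consensus)
  if (consensus < rep$consensusStart || consensus > rep$consensusEnd)
    stop("consensus position outside the element's consensus span", call. = FALSE)
  a <- as.integer(rep$genoStart)
  if (rep$strand == "+") a + (consensus - rep$consensusStart)
  else a + (rep$consensusEnd - consensus)
}

#' Classify a genomic position into an Alu anatomical region
#'
#' Resolves a position to `LEFT_ARM`, `A_RICH_LINKER`, `RIGHT_ARM`,
#' `POLY_A_TAIL` or `OFF_ELEMENT` via [genomic_to_consensus()] and the
#' config's consensus intervals. The poly-A tail is defined positionally:
#' past the consensus end or within the tail window downstream of the
#' element's sense 3' end (rmsk does not annotate tails). Anatomy is
#' computed in the element's own orientation; pass transcript-sense
#' positions unchanged.
#'
#' @param rep A single rmsk record.
#' @param pos Genomic position, 0-based.
#' @param cfg An [anatomy_config()].
#' @param family Optional repeat family gate: when non-NULL, `rep$repFamily`
#'   must equal it (default `NULL`, no gate).
#' @return An object of class `anatomy_call`: list with `region`,
#'   `consensus_pos` (`NA` for tail/off-element), `genomic_pos`,
#'   `repeat_id`.
#' @export
classify_anatomy <- function(rep, pos, cfg = anatomy_config(), family = NULL) {
  stopifnot(inherits(cfg, "anatomy_config"))
  rep <- rep_consensus_view(rep)
  if (!is.null(family) && !identical(rep$repFamily, family)) {
    stop(sprintf("repeat family '%s' does not match required '%s'",
                 rep$repFamily %||% "<missing>", family), call. = FALSE)
  }
  mp <- genomic_to_consensus(rep, pos, polyA_max_extension = cfg$polyA_max_extension)
  region <- switch(mp$status,
    off_element = "OFF_ELEMENT",
    beyond_end = "POLY_A_TAIL",
    in_element = {
      cp <- mp$consensus
      if (cp > cfg$consensus_length) "POLY_A_TAIL"
      else if (cp <= cfg$left_arm[2L]) "LEFT_ARM"
      else if (cp <= cfg$a_linker[2L]) "A_RICH_LINKER"
      else "RIGHT_ARM"
    })
  structure(list(region = region, consensus_pos = mp$consensus,
                 genomic_pos = as.integer(pos),
                 repeat_id = rep$repName %||%
                   sprintf("%s:%d-%d", rep$chrom, rep$genoStart, rep$genoEnd)),
            class = "anatomy_call")
}

#' @export
print.anatomy_call <- function(x, ...) {
  cat(sprintf("<anatomy_call> %s @ %d: %s (consensus %s)\n",
              x$repeat_id, x$genomic_pos, x$region,
              ifelse(is.na(x$consensus_pos), "-", x$consensus_pos)))
  invisible(x)
}

#' Scan a sequence for the CA cleavage dinucleotide and PAS hexamers
#'
#' Polyadenylation cleavage typically falls immediately 3' of a CA
#' dinucleotide, directed by an upstream polyadenylation signal hexamer
#' (canonically AATAAA or ATTAAA). Given a sense-strand sequence and the
#' cleavage offset (1-based index of the first base 3' of the cut), this
#' reports whether the two bases immediately 5' of the cut are `CA`, and
#' all hexamer occurrences lying fully 5' of the cut whose start is within
#' `pas_window` bases of it.
#'
#' @param seq Sense-strand nucleotide string (or anything coercible via
#'   `as.character`, e.g. a `Biostrings::DNAString`).
#' @param cleavage_offset 1-based position of the first base 3' of the
#'   cleavage point; must lie in `[1, nchar(seq) + 1]`.
#' @param pas_window Length-2 integer: hexamer starts between
#'   `cleavage_offset - pas_window[2]` and `cleavage_offset - pas_window[1]`
#'   are reported (default `c(1, 40)`).
#' @param hexamers PAS hexamer set (default `c("AATAAA", "ATTAAA")`).
#' @return A list with `ca` (logical; `NA` when fewer than two bases
#'   precede the cut) and `pas`, a data frame of hits with `hexamer`,
#'   `start` (1-based) and `offset_upstream` (`cleavage_offset - start`).
#' @export
scan_cleavage_motifs <- function(seq, cleavage_offset, pas_window = c(1L, 40L),
                                 hexamers = c("AATAAA", "ATTAAA")) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  off <- as.integer(cleavage_offset)
  if (is.na(off) || off < 1L || off > n + 1L)
    stop(sprintf("cleavage_offset %d outside sequence of length %d", off, n),
         call. = FALSE)
  ca <- if (off >= 3L) substr(seq, off - 2L, off - 1L) == "CA" else NA
  hits <- lapply(toupper(hexamers), function(h) {
    m <- gregexpr(h, seq, fixed = TRUE)[[1L]]
    s <- as.integer(m[m > 0L])
    s <- s[s + nchar(h) <= off &
             off - s >= pas_window[1L] & off - s <= pas_window[2L]]
    if (!length(s)) return(NULL)
    data.frame(hexamer = h, start = s, offset_upstream = off - s,
               stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1L))]
  pas <- if (length(hits)) {
    out <- do.call(rbind, hits)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(hexamer = character(), start = integer(),
               offset_upstream = integer(), stringsAsFactors = FALSE)
  }
  list(ca = ca, pas = pas)
}
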