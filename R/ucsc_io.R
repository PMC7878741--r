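#' Read a UCSC genePred-style gene annotation table
#'
#' Parses the tab-separated genePred dialects distributed by UCSC:
#' `refGene.txt` (extended genePred with a leading `bin` column, 16 columns),
#' extended genePred without `bin` (15 columns), basic genePred (10 columns)
#' and `refFlat.txt` (gene symbol followed by basic genePred, 11 columns).
#' Plain or gzip-compressed input is accepted; compression is sniffed from
#' the magic bytes, not the file name.
#'
#' All coordinates are kept in the table-native 0-based half-open convention.
#' Exon lists retain UCSC's trailing-comma formatting on write so that files
#' emitted by [write_genepred()] round-trip byte-for-byte.
#'
#' @param path Path to the table (optionally gzipped).
#' @param has_bin `"auto"` (default), `"yes"` or `"no"`. Under `"auto"` the
#'   leading `bin` column is detected from the column count and whether the
#'   first column is all-integer.
#' @return A `data.frame`, one row per transcript, with columns `name`,
#'   `chrom`, `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`,
#'   `exonCount`, list-columns `exonStarts`/`exonEnds`, `name2`, and (when
#'   present in the dialect) `bin`, `score`, `cdsStartStat`, `cdsEndStat`,
#'   `exonFrames`. The source dialect is recorded in `attr(x, "dialect")`.
#' @seealso [write_genepred()], [read_rmsk()], [read_tapas()]
#' @export
read_genepred <- function(path, has_bin = c("auto", "yes", "no")) {
  has_bin <- match.arg(has_bin)
  lines <- read_table_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(empty_genepred())
  }
  nf <- length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  looks_int <- function(x) grepl("^-?[0-9]+$", x)
  first_col <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1L), 1L)
  bin_present <- switch(has_bin,
    yes = TRUE,
    no = FALSE,
    auto = nf %in% c(11L, 16L) && all(looks_int(first_col))
  )
  dialect <-
    if (nf == 16L && bin_present) "genePredExtBin"
    else if (nf == 15L && !bin_present) "genePredExt"
    else if (nf == 11L && bin_present) "genePredBin"
    else if (nf == 11L && !bin_present) "refFlat"
    else if (nf == 10L && !bin_present) "genePred"
    else stop(sprintf("genePred: unsupported column count %d (has_bin=%s)", nf, has_bin),
              call. = FALSE)

  parts <- split_fields(lines, nf, "genePred")
  col <- function(i) vapply(parts, `[[`, character(1L), i)
  ln <- seq_along(lines)
  off <- as.integer(bin_present)  # shift when bin leads

  if (dialect == "refFlat") {
    geneName <- col(1L); core <- 1L
  } else {
    geneName <- NULL; core <- off
  }
  name     <- col(core + 1L)
  chrom    <- col(core + 2L)
  strand   <- col(core + 3L)
  txStart  <- as_int_field(col(core + 4L), ln, "txStart", "genePred")
  txEnd    <- as_int_field(col(core + 5L), ln, "txEnd", "genePred")
  cdsStart <- as_int_field(col(core + 6L), ln, "cdsStart", "genePred")
  cdsEnd   <- as_int_field(col(core + 7L), ln, "cdsEnd", "genePred")
  exonCount <- as_int_field(col(core + 8L), ln, "exonCount", "genePred")
  exonStarts <- parse_int_list(col(core + 9L))
  exonEnds   <- parse_int_list(col(core + 10L))

  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop(sprintf("genePred: line %d: invalid strand '%s'",
                                bad[1L], strand[bad[1L]]), call. = FALSE)
  bad <- which(!(txStart <= cdsStart & cdsStart <= cdsEnd & cdsEnd <= txEnd))
  if (length(bad)) stop(sprintf(
    "genePred: line %d: coordinates violate txStart <= cdsStart <= cdsEnd <= txEnd", bad[1L]),
    call. = FALSE)
  bad <- which(lengths(exonStarts) != exonCount | lengths(exonEnds) != exonCount)
  if (length(bad)) stop(sprintf("genePred: line %d: exon list length does not match exonCount",
                                bad[1L]), call. = FALSE)
  for (i in ln) {
    s <- exonStarts[[i]]; e <- exonEnds[[i]]
    ok <- all(e > s) && !is.unsorted(s, strictly = TRUE) &&
      (length(s) < 2L || all(s[-1L] >= e[-length(e)])) &&
      s[1L] == txStart[i] && e[length(e)] == txEnd[i]
    if (!ok) stop(sprintf("genePred: line %d: malformed exon structure", i), call. = FALSE)
  }

  df <- data.frame(name = name, chrom = chrom, strand = strand,
                   txStart = txStart, txEnd = txEnd,
                   cdsStart = cdsStart, cdsEnd = cdsEnd,
                   exonCount = exonCount, stringsAsFactors = FALSE)
  df$exonStarts <- exonStarts
  df$exonEnds <- exonEnds
  if (dialect %in% c("genePredExtBin", "genePredExt")) {
    df$score <- as_int_field(col(core + 11L), ln, "score", "genePred")
    df$name2 <- col(core + 12L)
    df$cdsStartStat <- col(core + 13L)
    df$cdsEndStat <- col(core + 14L)
    df$exonFrames <- col(core + 15L)
  } else if (dialect == "refFlat") {
    df$name2 <- geneName
  } else {
    df$name2 <- df$name
  }
  if (bin_present) df$bin <- as_int_field(col(1L), ln, "bin", "genePred")
  attr(df, "dialect") <- dialect
  df
}

empty_genepred <- function(dialect = "genePredExtBin") {
  df <- data.frame(name = character(), chrom = character(), strand = character(),
                   txStart = integer(), txEnd = integer(),
                   cdsStart = integer(), cdsEnd = integer(),
                   exonCount = integer(), stringsAsFactors = FALSE)
  df$exonStarts <- list()
  df$exonEnds <- list()
  df$name2 <- character()
  attr(df, "dialect") <- dialect
  df
}

#' Write a genePred table
#'
#' Emits the same dialect that [read_genepred()] recorded (or any dialect
#' requested explicitly), reproducing UCSC formatting: tab separation and
#' trailing commas on exon lists. Writes are atomic (temp file then rename).
#'
#' @param df A data frame as returned by [read_genepred()].
#' @param path Output path.
#' @param dialect One of `"genePredExtBin"`, `"genePredExt"`, `"refFlat"`,
#'   `"genePred"`, `"genePredBin"`; defaults to the data frame's recorded
#'   dialect.
#' @return The path, invisibly.
#' @export
write_genepred <- function(df, path, dialect = NULL) {
  dialect <- dialect %||% attr(df, "dialect") %||% "genePredExtBin"
  es <- format_int_list(df$exonStarts)
  ee <- format_int_list(df$exonEnds)
  core <- cbind(df$name, df$chrom, df$strand,
                df$txStart, df$txEnd, df$cdsStart, df$cdsEnd,
                df$exonCount, es, ee)
  rows <- switch(dialect,
    genePredExtBin = cbind(df$bin, core, df$score, df$name2,
                           df$cdsStartStat, df$cdsEndStat, df$exonFrames),
    genePredExt = cbind(core, df$score, df$name2,
                        df$cdsStartStat, df$cdsEndStat, df$exonFrames),
    refFlat = cbind(df$name2, core),
    genePredBin = cbind(df$bin, core),
    genePred = core,
    stop("unknown genePred dialect: ", dialect, call. = FALSE)
  )
  lines <- if (nrow(df)) apply(rows, 1L, paste, collapse = "\t") else character()
  write_lines_atomic(lines, path)
}

RMSK_COLS <- c("bin", "swScore", "milliDiv", "milliDel", "milliIns",
               "genoName", "genoStart", "genoEnd", "genoLeft", "strand",
               "repName", "repClass", "repFamily",
               "repStart", "repEnd", "repLeft", "id")

#' Read a UCSC RepeatMasker (rmsk) table
#'
#' Parses the 17-column `rmsk.txt` dialect (plain or gzipped). Consensus
#' coordinates use RepeatMasker's strand-dependent sign convention: on `+`
#' the element occupies consensus `[repStart, repEnd]` with `-repLeft` bases
#' of consensus remaining beyond `repEnd`; on `-` the roles of `repStart`
#' and `repLeft` swap, so the element occupies `[repLeft, repEnd]` with
#' `-repStart` bases remaining. The raw fields are preserved verbatim and a
#' normalized view is added at parse time so that downstream code never
#' branches on the sign trick: `consensusStart`, `consensusEnd` (1-based
#' inclusive) and `consensusLeft` (bases of consensus beyond the element's
#' 3' end).
#'
#' Rows violating the sign convention are flagged (`conventionOK = FALSE`)
#' with a warning but are not dropped; real tables contain edge cases.
#'
#' @param path Path to the rmsk table.
#' @return A `data.frame` with the 17 UCSC columns plus `consensusStart`,
#'   `consensusEnd`, `consensusLeft`, `conventionOK`.
#' @export
read_rmsk <- function(path) {
  lines <- read_table_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    df <- as.data.frame(setNames(rep(list(integer()), 17L), RMSK_COLS))
    for (nm in c("genoName", "strand", "repName", "repClass", "repFamily"))
      df[[nm]] <- character()
    df$consensusStart <- integer(); df$consensusEnd <- integer()
    df$consensusLeft <- integer(); df$conventionOK <- logical()
    return(df)
  }
  parts <- split_fields(lines, 17L, "rmsk")
  col <- function(i) vapply(parts, `[[`, character(1L), i)
  ln <- seq_along(lines)
  df <- data.frame(
    bin = as_int_field(col(1L), ln, "bin", "rmsk"),
    swScore = as_int_field(col(2L), ln, "swScore", "rmsk"),
    milliDiv = as_int_field(col(3L), ln, "milliDiv", "rmsk"),
    milliDel = as_int_field(col(4L), ln, "milliDel", "rmsk"),
    milliIns = as_int_field(col(5L), ln, "milliIns", "rmsk"),
    genoName = col(6L),
    genoStart = as_int_field(col(7L), ln, "genoStart", "rmsk"),
    genoEnd = as_int_field(col(8L), ln, "genoEnd", "rmsk"),
    genoLeft = as_int_field(col(9L), ln, "genoLeft", "rmsk"),
    strand = col(10L),
    repName = col(11L),
    repClass = col(12L),
    repFamily = col(13L),
    repStart = as_int_field(col(14L), ln, "repStart", "rmsk"),
    repEnd = as_int_field(col(15L), ln, "repEnd", "rmsk"),
    repLeft = as_int_field(col(16L), ln, "repLeft", "rmsk"),
    id = as_int_field(col(17L), ln, "id", "rmsk"),
    stringsAsFactors = FALSE
  )
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stop(sprintf("rmsk: line %d: invalid strand '%s'",
                                bad[1L], df$strand[bad[1L]]), call. = FALSE)
  bad <- which(df$genoStart >= df$genoEnd)
  if (length(bad)) stop(sprintf("rmsk: line %d: genoStart >= genoEnd", bad[1L]),
                        call. = FALSE)
  df <- normalize_consensus(df)
  n_bad <- sum(!df$conventionOK)
  if (n_bad > 0L) {
    warning(sprintf("rmsk: %d record(s) violate the consensus sign convention (flagged, kept)",
                    n_bad), call. = FALSE)
  }
  df
}

# Collapse the strand-dependent sign convention into one normalized view.
normalize_consensus <- function(df) {
  plus <- df$strand == "+"
  df$consensusStart <- ifelse(plus, df$repStart, df$repLeft)
  df$consensusEnd <- df$repEnd
  df$consensusLeft <- ifelse(plus, -df$repLeft, -df$repStart)
  df$conventionOK <- ifelse(plus,
    df$repStart >= 1L & df$repEnd >= df$repStart & df$repLeft <= 0L,
    df$repLeft >= 1L & df$repEnd >= df$repLeft & df$repStart <= 0L)
  df
}

#' Write a RepeatMasker table
#'
#' Emits the 17 raw UCSC columns; the normalized consensus view added by
#' [read_rmsk()] is derived data and is not written, so read-then-write
#' reproduces the input byte-for-byte.
#'
#' @param df A data frame with the 17 rmsk columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rmsk <- function(df, path) {
  rows <- as.matrix(as.data.frame(lapply(df[RMSK_COLS], as.character),
                                  stringsAsFactors = FALSE))
  lines <- if (nrow(df)) apply(rows, 1L, paste, collapse = "\t") else character()
  write_lines_atomic(lines, path)
}

#' Read TAPAS six-column output
#'
#' TAPAS reports, per gene: gene name, chromosome, gene strand, the detected
#' polyadenylation sites (including APA sites), their abundances, and a read
#' count. Multi-site fields are delimited lists within one column; both
#' commas and whitespace are accepted as the intra-column delimiter (the
#' writer emits commas). Empty site lists are permitted: a gene with no APA
#' call yields a record with zero sites.
#'
#' @param path Path to the TAPAS output (optionally gzipped).
#' @return A `data.frame` with columns `gene`, `chrom`, `strand`,
#'   list-columns `apa_sites` (integer genomic positions) and `abundances`
#'   (numeric, parallel to `apa_sites`), and `read_count`.
#' @export
read_tapas <- function(path) {
  lines <- read_table_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    df <- data.frame(gene = character(), chrom = character(), strand = character(),
                     read_count = integer(), stringsAsFactors = FALSE)
    df$apa_sites <- list(); df$abundances <- list()
    return(df[c("gene", "chrom", "strand", "apa_sites", "abundances", "read_count")])
  }
  parts <- split_fields(lines, 6L, "tapas")
  col <- function(i) vapply(parts, `[[`, character(1L), i)
  ln <- seq_along(lines)
  split_list <- function(x) {
    lapply(x, function(v) {
      toks <- strsplit(trimws(v), "[,[:space:]]+")[[1L]]
      toks[nzchar(toks)]
    })
  }
  gene <- col(1L)
  strand <- col(3L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop(sprintf("tapas: line %d: invalid strand '%s'",
                                bad[1L], strand[bad[1L]]), call. = FALSE)
  sites <- lapply(split_list(col(4L)), as.integer)
  abund <- lapply(split_list(col(5L)), as.numeric)
  if (any(vapply(sites, anyNA, logical(1L))) || any(vapply(abund, anyNA, logical(1L))))
    stop("tapas: non-numeric entry in sites or abundances", call. = FALSE)
  bad <- which(lengths(sites) != lengths(abund))
  if (length(bad)) {
    stop(sprintf("tapas: gene '%s' (line %d): %d sites but %d abundances",
                 gene[bad[1L]], bad[1L], lengths(sites)[bad[1L]],
                 lengths(abund)[bad[1L]]), call. = FALSE)
  }
  df <- data.frame(gene = gene, chrom = col(2L), strand = strand,
                   read_count = as_int_field(col(6L), ln, "read_count", "tapas"),
                   stringsAsFactors = FALSE)
  df$apa_sites <- sites
  df$abundances <- abund
  df[c("gene", "chrom", "strand", "apa_sites", "abundances", "read_count")]
}

#' Write TAPAS six-column output
#'
#' @param df A data frame as returned by [read_tapas()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tapas <- function(df, path) {
  fmt_num <- function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  lines <- vapply(seq_len(nrow(df)), function(i) {
    paste(df$gene[i], df$chrom[i], df$strand[i],
          if (length(df$apa_sites[[i]])) paste(df$apa_sites[[i]], collapse = ",") else "",
          if (length(df$abundances[[i]])) fmt_num(df$abundances[[i]]) else "",
          df$read_count[i], sep = "\t")
  }, character(1L))
  write_lines_atomic(lines, path)
}

#' Write a BED6 file
#'
#' @param df A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed6 <- function(df, path) {
  lines <- if (nrow(df)) {
    paste(df$chrom, df$start, df$end, df$name, df$score, df$strand, sep = "\t")
  } else character()
  write_lines_atomic(lines, path)
}

#' Read a BED file (3 to 6 columns)
#'
#' @param path Path to the BED file.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- read_table_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(parts))
  if (nf < 3L) stop("bed: fewer than 3 columns", call. = FALSE)
  col <- function(i) vapply(parts, `[[`, character(1L), i)
  ln <- seq_along(lines)
  df <- data.frame(chrom = col(1L),
                   start = as_int_field(col(2L), ln, "start", "bed"),
                   end = as_int_field(col(3L), ln, "end", "bed"),
                   stringsAsFactors = FALSE)
  if (nf >= 4L) df$name <- col(4L)
  if (nf >= 5L) df$score <- col(5L)
  if (nf >= 6L) {
    df$strand <- col(6L)
    bad <- which(!df$strand %in% c("+", "-", "."))
    if (length(bad)) stop(sprintf("bed: line %d: invalid strand", bad[1L]), call. = FALSE)
  }
  df
}
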