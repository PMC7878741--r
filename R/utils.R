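# Internal helpers shared across modules.

# Open a text connection, transparently handling gzip (sniffed by magic bytes,
# not by file extension -- UCSC distributes both .txt and .txt.gz).
open_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  if (length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

read_table_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Split tab-separated lines, enforcing a fixed field count with a located error.
split_fields <- function(lines, n_fields, what) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != n_fields)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields, expected %d",
                 what, bad[1L], lens[bad[1L]], n_fields), call. = FALSE)
  }
  parts
}

as_int_field <- function(x, line, field, what) {
  suppressWarnings(v <- as.integer(x))
  if (anyNA(v)) {
    i <- which(is.na(v))[1L]
    stop(sprintf("%s: line %d: field '%s' is not an integer: '%s'",
                 what, line[i], field, x[i]), call. = FALSE)
  }
  v
}

# Parse a UCSC comma-separated coordinate list ("10,20,30," with trailing comma).
parse_int_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.integer(v)
  })
}

format_int_list <- function(x) {
  vapply(x, function(v) {
    if (!length(v)) "" else paste0(paste(v, collapse = ","), ",")
  }, character(1L))
}

# Atomic text write: temp file in the target directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dir)
  con <- file(tmp, "wb")  # binary: fixed "\n" endings on every platform
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path, col_names = TRUE) {
  fmt <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, , drop = FALSE], function(col) {
      v <- col[[1L]]
      if (is.numeric(v) && !is.integer(v)) format(v, scientific = FALSE, trim = TRUE)
      else as.character(v)
    }, character(1L)), collapse = "\t")
  }, character(1L))
  if (col_names) fmt <- c(paste(names(df), collapse = "\t"), fmt)
  write_lines_atomic(fmt, path)
}

# round() uses banker's rounding; headline percentages follow the common
# half-up convention instead.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
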