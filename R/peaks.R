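#' Read a ChIP-Seq peak file
#'
#' Reads ENCODE narrowPeak (BED6+4), broadPeak (BED6+3) or plain BED into a
#' peak tibble. `track`, `browser` and `#` comment lines are skipped; gzipped
#' input is accepted. For `"bed"`, columns beyond chrom/start/end are optional
#' and missing values are filled with defaults (name `""`, score 0, strand
#' `"."`, statistics -1). narrowPeak and broadPeak must carry their full
#' column count.
#'
#' Peak strand is retained but ignored by overlap logic: TF binding is
#' double-stranded and ENCODE peaks carry `"."`; only the lncRNA's strand
#' matters (it orients the TSS window).
#'
#' @param path Path to the peak file (optionally gzipped).
#' @param format One of `"narrowPeak"`, `"broadPeak"`, `"bed"`.
#' @return A tibble with columns `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`, `score`, `strand`, `signal_value`, `p_value_log`, `q_value_log`
#'   (-1 = missing), `summit_offset` (-1 = missing), in file order.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "broadPeak", "bed")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  line_no <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (length(lines) == 0) return(empty_peaks())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- switch(format, narrowPeak = 10L, broadPeak = 9L, bed = NA_integer_)
  if (!is.na(expected) && any(nf != expected)) {
    bad <- which(nf != expected)[1]
    abort(sprintf("%s parse error at line %d: expected %d columns, found %d.",
                  format, line_no[bad], expected, nf[bad]))
  }
  if (format == "bed" && any(nf < 3)) {
    bad <- which(nf < 3)[1]
    abort(sprintf("bed parse error at line %d: fewer than 3 columns.", line_no[bad]))
  }

  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  num_col <- function(i, default, what) {
    x <- suppressWarnings(as.numeric(col(i, as.character(default))))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      abort(sprintf("%s parse error at line %d: non-numeric %s.",
                    format, line_no[bad], what))
    }
    x
  }

  start <- suppressWarnings(as.integer(col(2, NA_character_)))
  end <- suppressWarnings(as.integer(col(3, NA_character_)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("%s parse error at line %d: non-integer coordinates.",
                  format, line_no[bad]))
  }
  if (any(start < 0) || any(start >= end)) {
    bad <- which(start < 0 | start >= end)[1]
    abort(sprintf("%s parse error at line %d: invalid interval [%d, %d).",
                  format, line_no[bad], start[bad], end[bad]))
  }

  has_stats <- format %in% c("narrowPeak", "broadPeak")
  tibble(
    chrom = col(1, NA_character_),
    start = start,
    end = end,
    name = col(4, ""),
    score = num_col(5, 0, "score"),
    strand = col(6, "."),
    signal_value = if (has_stats) num_col(7, -1, "signalValue") else -1,
    p_value_log = if (has_stats) num_col(8, -1, "pValue") else -1,
    q_value_log = if (has_stats) num_col(9, -1, "qValue") else -1,
    summit_offset = if (format == "narrowPeak") {
      as.integer(num_col(10, -1, "peak summit"))
    } else -1L
  )
}

empty_peaks <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    signal_value = numeric(), p_value_log = numeric(),
    q_value_log = numeric(), summit_offset = integer()
  )
}

# plain-number formatting (no scientific notation, no trailing zeros)
format_plain <- function(x) {
  out <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      drop0trailing = TRUE),
                character(1))
  out
}

# Serialize peaks; inverse of read_peaks() for the matching format.
write_peaks <- function(peaks, path, format = c("narrowPeak", "broadPeak", "bed")) {
  format <- match.arg(format)
  lines <- switch(
    format,
    narrowPeak = sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
      peaks$chrom, peaks$start, peaks$end, peaks$name,
      format_plain(peaks$score), peaks$strand,
      format_plain(peaks$signal_value), format_plain(peaks$p_value_log),
      format_plain(peaks$q_value_log), peaks$summit_offset
    ),
    broadPeak = sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
      peaks$chrom, peaks$start, peaks$end, peaks$name,
      format_plain(peaks$score), peaks$strand,
      format_plain(peaks$signal_value), format_plain(peaks$p_value_log),
      format_plain(peaks$q_value_log)
    ),
    bed = sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                  peaks$chrom, peaks$start, peaks$end, peaks$name,
                  format_plain(peaks$score), peaks$strand)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a peak-dataset manifest
#'
#' The manifest is the multi-dataset entry point, standing in for a database of
#' ChIP-Seq experiments: a TSV with header columns `path`, `dataset_id`, `tf`,
#' `cell_line`, `species`, `format`. Relative `path`s are resolved against the
#' manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with the manifest columns, `path` made absolute.
#' @export
read_peak_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("path", "dataset_id", "tf", "cell_line", "species", "format")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    abort(sprintf("Manifest is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  dup <- unique(man$dataset_id[duplicated(man$dataset_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate dataset_id in manifest: %s.",
                  paste(dup, collapse = ", ")))
  }
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(base, man$path[rel])
  as_tibble(man[required])
}

#' Load peak datasets listed in a manifest
#'
#' @param manifest A manifest tibble from [read_peak_manifest()], or a path to
#'   a manifest TSV.
#' @param quiet Suppress per-dataset peak-count messages.
#' @return A nested tibble with one row per ChIP-Seq experiment: `dataset_id`,
#'   `tf`, `cell_line`, `species`, `n_peaks`, and a `peaks` list-column of peak
#'   tibbles. A dataset that parses to zero peaks is kept with a warning.
#' @export
load_peak_datasets <- function(manifest, quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_peak_manifest(manifest)
  dup <- unique(manifest$dataset_id[duplicated(manifest$dataset_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate dataset_id: %s.", paste(dup, collapse = ", ")))
  }
  peaks <- purrr::pmap(
    list(manifest$path, manifest$format, manifest$dataset_id),
    function(p, fmt, id) {
      pk <- read_peaks(p, fmt)
      if (!quiet) inform(sprintf("Dataset %s: %d peaks.", id, nrow(pk)))
      if (nrow(pk) == 0) warn(sprintf("Dataset %s has no peaks.", id))
      pk
    }
  )
  manifest |>
    select("dataset_id", "tf", "cell_line", "species") |>
    mutate(n_peaks = vapply(peaks, nrow, integer(1)), peaks = peaks)
}
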