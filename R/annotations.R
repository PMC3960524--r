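#' Regulatory-window presets
#'
#' Named upstream/downstream window presets around the TSS, in bp. The default
#' working window is `"2k1k"` (2,000 bp upstream / 1,000 bp downstream); the
#' wider presets (`"10k1k"`, `"20k1k"`, `"30k2k"`, `"50k5k"`) trade promoter
#' specificity for sensitivity to distal binding.
#'
#' @format A named list; each element is a length-2 integer vector
#'   `c(upstream, downstream)`.
#' @export
lnctf_window_presets <- list(
  "2k1k"  = c(upstream = 2000L,  downstream = 1000L),
  "10k1k" = c(upstream = 10000L, downstream = 1000L),
  "20k1k" = c(upstream = 20000L, downstream = 1000L),
  "30k2k" = c(upstream = 30000L, downstream = 2000L),
  "50k5k" = c(upstream = 50000L, downstream = 5000L)
)

#' Define a TSS regulatory window
#'
#' @param upstream Non-negative number of bp upstream of the TSS (5' of the
#'   feature, strand-aware).
#' @param downstream Non-negative number of bp downstream of the TSS.
#' @return An object of class `lnctf_window` (a named list with `upstream` and
#'   `downstream`). The window always includes the TSS base itself, so its
#'   length is `upstream + downstream + 1`.
#' @examples
#' window_spec(2000, 1000)
#' @export
window_spec <- function(upstream, downstream) {
  if (length(upstream) != 1 || length(downstream) != 1 ||
      !is.finite(upstream) || !is.finite(downstream) ||
      upstream < 0 || downstream < 0) {
    abort("`upstream` and `downstream` must be single finite non-negative numbers.")
  }
  structure(
    list(upstream = as.integer(upstream), downstream = as.integer(downstream)),
    class = "lnctf_window"
  )
}

#' @export
print.lnctf_window <- function(x, ...) {
  cat(sprintf("<lnctf_window> -%d bp / +%d bp around the TSS\n",
              x$upstream, x$downstream))
  invisible(x)
}

#' Resolve a window argument
#'
#' Accepts a preset name (see [lnctf_window_presets]), a length-2 numeric
#' `c(upstream, downstream)`, or an `lnctf_window`.
#'
#' @param window Preset name, numeric pair, or `lnctf_window`.
#' @return An `lnctf_window`.
#' @export
resolve_window <- function(window) {
  if (inherits(window, "lnctf_window")) return(window)
  if (is.character(window) && length(window) == 1) {
    if (!window %in% names(lnctf_window_presets)) {
      abort(sprintf(
        "Unknown window preset '%s'. Available presets: %s.",
        window, paste(names(lnctf_window_presets), collapse = ", ")
      ))
    }
    w <- lnctf_window_presets[[window]]
    return(window_spec(w[["upstream"]], w[["downstream"]]))
  }
  if (is.numeric(window) && length(window) == 2) {
    return(window_spec(window[[1]], window[[2]]))
  }
  abort("`window` must be a preset name, a c(upstream, downstream) pair, or a window_spec().")
}

gtf_attr <- function(attrs, key) {
  stringr::str_match(attrs, paste0('(?:^|; ?)', key, ' +"([^"]*)"'))[, 2]
}

empty_annotation <- function() {
  tibble(
    transcript_id = character(), transcript_name = character(),
    gene_id = character(), gene_name = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character(), biotype = character()
  )
}

#' Read lncRNA transcript annotations from a GTF file
#'
#' Parses a GTF (tab-separated, 9 columns, `key "value";` attributes) into one
#' row per transcript. A transcript's coordinates span the minimum start and
#' maximum end of all its features (`transcript`, `exon`, ...). Comment lines
#' (`#...`) are skipped; gzipped input is accepted. The GTF is trusted to
#' contain the intended lncRNA universe unless `biotypes` is given.
#'
#' @param path Path to a GTF file (optionally gzipped).
#' @param biotypes Optional character vector; keep only transcripts whose
#'   biotype (from `transcript_type`/`transcript_biotype`, falling back to
#'   `gene_type`/`gene_biotype`) is in this set. `NULL` (default) keeps all.
#' @return A tibble with columns `transcript_id`, `transcript_name`, `gene_id`,
#'   `gene_name`, `chrom`, `start`, `end` (1-based inclusive), `strand`
#'   (`"+"`/`"-"`), `biotype`. Name columns are `""` when absent from the GTF.
#' @seealso [gene_table()], [regulatory_regions()]
#' @export
read_lncrna_gtf <- function(path, biotypes = NULL) {
  lines <- readr::read_lines(path)
  line_no <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (length(lines) == 0) return(empty_annotation())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- which(nf != 9)[1]
    abort(sprintf("GTF parse error at line %d: expected 9 tab-separated columns, found %d.",
                  line_no[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("GTF parse error at line %d: non-integer coordinates.", line_no[bad]))
  }
  if (any(start > end)) {
    bad <- which(start > end)[1]
    abort(sprintf("GTF parse error at line %d: start (%d) > end (%d).",
                  line_no[bad], start[bad], end[bad]))
  }

  attrs <- m[, 9]
  tx_id <- gtf_attr(attrs, "transcript_id")
  has_tx <- !is.na(tx_id)
  if (!any(has_tx)) return(empty_annotation())

  feat <- tibble(
    line = line_no[has_tx],
    transcript_id = tx_id[has_tx],
    gene_id = gtf_attr(attrs[has_tx], "gene_id"),
    transcript_name = gtf_attr(attrs[has_tx], "transcript_name"),
    gene_name = gtf_attr(attrs[has_tx], "gene_name"),
    biotype = dplyr::coalesce(
      gtf_attr(attrs[has_tx], "transcript_type"),
      gtf_attr(attrs[has_tx], "transcript_biotype"),
      gtf_attr(attrs[has_tx], "gene_type"),
      gtf_attr(attrs[has_tx], "gene_biotype")
    ),
    chrom = m[has_tx, 1],
    start = start[has_tx],
    end = end[has_tx],
    strand = m[has_tx, 7]
  )
  if (anyNA(feat$gene_id)) {
    bad <- which(is.na(feat$gene_id))[1]
    abort(sprintf("GTF parse error at line %d: feature has transcript_id but no gene_id.",
                  feat$line[bad]))
  }
  if (!all(feat$strand %in% c("+", "-"))) {
    bad <- which(!feat$strand %in% c("+", "-"))[1]
    abort(sprintf("GTF parse error at line %d: strand must be '+' or '-', found '%s'.",
                  feat$line[bad], feat$strand[bad]))
  }

  first_nonempty <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x)) x[[1]] else ""
  }
  tx <- feat |>
    mutate(.order = match(.data$transcript_id, unique(.data$transcript_id))) |>
    group_by(.data$transcript_id) |>
    summarise(
      .order = .data$.order[1],
      # distinct-count checks must precede the columns that shadow their inputs
      .n_gene = n_distinct(.data$gene_id),
      .n_chrom = n_distinct(.data$chrom),
      .n_strand = n_distinct(.data$strand),
      transcript_name = first_nonempty(.data$transcript_name),
      gene_id = .data$gene_id[1],
      gene_name = first_nonempty(.data$gene_name),
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      biotype = first_nonempty(.data$biotype),
      .groups = "drop"
    )
  inconsistent <- tx$.n_chrom > 1 | tx$.n_strand > 1 | tx$.n_gene > 1
  if (any(inconsistent)) {
    abort(sprintf(
      "GTF parse error: transcript '%s' has inconsistent chrom/strand/gene_id across its features.",
      tx$transcript_id[which(inconsistent)[1]]
    ))
  }
  tx <- tx |>
    arrange(.data$.order) |>
    select("transcript_id", "transcript_name", "gene_id", "gene_name",
           "chrom", "start", "end", "strand", "biotype")

  # all transcripts of a gene must share chrom and strand
  gbad <- tx |>
    group_by(.data$gene_id) |>
    summarise(nc = n_distinct(.data$chrom), ns = n_distinct(.data$strand),
              .groups = "drop") |>
    filter(.data$nc > 1 | .data$ns > 1)
  if (nrow(gbad) > 0) {
    abort(sprintf(
      "GTF parse error: gene '%s' has transcripts on different chroms or strands.",
      gbad$gene_id[1]
    ))
  }

  if (!is.null(biotypes)) tx <- filter(tx, .data$biotype %in% biotypes)
  tx
}

#' Summarise an annotation at the gene level
#'
#' @param transcripts A transcript tibble as returned by [read_lncrna_gtf()].
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `n_transcripts`, and a `transcript_ids` list-column.
#' @export
gene_table <- function(transcripts) {
  first_nonempty <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x)) x[[1]] else ""
  }
  transcripts |>
    mutate(.order = match(.data$gene_id, unique(.data$gene_id))) |>
    group_by(.data$gene_id) |>
    summarise(
      .order = .data$.order[1],
      gene_name = first_nonempty(.data$gene_name),
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      n_transcripts = n(),
      transcript_ids = list(.data$transcript_id),
      .groups = "drop"
    ) |>
    arrange(.data$.order) |>
    select(-".order")
}

#' Add transcription start site positions
#'
#' The TSS is the 5'-most transcribed base: `start` on the `+` strand, `end` on
#' the `-` strand (1-based).
#'
#' @param transcripts A transcript tibble (needs `start`, `end`, `strand`).
#' @return The input with an added integer `tss` column.
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", chrom = "chr1",
#'                      start = 100L, end = 500L, strand = "-")
#' tss(tx)$tss  # 500
#' @export
tss <- function(transcripts) {
  mutate(transcripts,
         tss = if_else(.data$strand == "+", .data$start, .data$end))
}

#' Compute TSS regulatory regions
#'
#' For each transcript the window covers, in 1-based inclusive terms,
#' `[tss - upstream, tss + downstream]` on the `+` strand and
#' `[tss - downstream, tss + upstream]` on the `-` strand, clamped on the left
#' at position 1. Results are reported in 0-based half-open coordinates, the
#' convention used for all interval work in this package (BED-compatible).
#' The right end is never clamped: chromosome lengths are not carried in GTF,
#' and a window running past the last annotated base is harmless for overlap.
#'
#' At `level = "gene"` one region is emitted per member transcript, each
#' labelled with the gene's `feature_id`; a gene counts as targeted when any
#' of its transcripts' windows is hit (the permissive "any transcript" union
#' rule). Use `level = "transcript"` for per-transcript resolution.
#'
#' @param transcripts A transcript tibble as from [read_lncrna_gtf()].
#' @param window A preset name, `c(upstream, downstream)` pair, or
#'   [window_spec()]. Default `"2k1k"`.
#' @param level `"gene"` or `"transcript"`: what `feature_id` identifies.
#' @return A tibble with columns `feature_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`; attributes `window` and
#'   `level`.
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", transcript_name = "",
#'                      gene_id = "g1", gene_name = "", chrom = "chr1",
#'                      start = 10000L, end = 12000L, strand = "+",
#'                      biotype = "lncRNA")
#' regulatory_regions(tx, "2k1k", level = "transcript")
#' @export
regulatory_regions <- function(transcripts, window = "2k1k",
                               level = c("gene", "transcript")) {
  level <- match.arg(level)
  w <- resolve_window(window)
  tx <- tss(transcripts)
  left1 <- if_else(tx$strand == "+", tx$tss - w$upstream, tx$tss - w$downstream)
  right1 <- if_else(tx$strand == "+", tx$tss + w$downstream, tx$tss + w$upstream)
  left1 <- pmax(left1, 1L)
  out <- tibble(
    feature_id = if (level == "gene") tx$gene_id else tx$transcript_id,
    transcript_id = tx$transcript_id,
    chrom = tx$chrom,
    start = as.integer(left1 - 1L),
    end = as.integer(right1),
    strand = tx$strand
  )
  attr(out, "window") <- w
  attr(out, "level") <- level
  out
}

# Serialize an annotation back to GTF (gene, transcript and single-exon rows).
# Used by the fixture generator and for parse/serialize round-trip checks.
write_lncrna_gtf <- function(transcripts, path) {
  gt <- gene_table(transcripts)
  gene_span <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gt <- left_join(gt, gene_span, by = "gene_id")
  q <- function(x) paste0('"', x, '"')
  gene_lines <- sprintf(
    '%s\tlnctf\tgene\t%d\t%d\t.\t%s\t.\tgene_id %s; gene_name %s; gene_type %s;',
    gt$chrom, gt$start, gt$end, gt$strand,
    q(gt$gene_id), q(gt$gene_name), q("lncRNA")
  )
  tx_attr <- sprintf(
    'gene_id %s; transcript_id %s; gene_name %s; transcript_name %s; gene_type %s; transcript_type %s;',
    q(transcripts$gene_id), q(transcripts$transcript_id),
    q(transcripts$gene_name), q(transcripts$transcript_name),
    q("lncRNA"), q(transcripts$biotype)
  )
  tx_lines <- sprintf(
    "%s\tlnctf\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
    transcripts$chrom, transcripts$start, transcripts$end,
    transcripts$strand, tx_attr
  )
  exon_lines <- sprintf(
    "%s\tlnctf\texon\t%d\t%d\t.\t%s\t.\t%s",
    transcripts$chrom, transcripts$start, transcripts$end,
    transcripts$strand, tx_attr
  )
  # interleave per gene: gene row, then its transcript/exon rows
  ord <- order(match(transcripts$gene_id, gt$gene_id),
               match(transcripts$transcript_id, transcripts$transcript_id))
  body <- unlist(lapply(seq_len(nrow(gt)), function(i) {
    j <- which(transcripts$gene_id == gt$gene_id[i])
    c(gene_lines[i], rbind(tx_lines[j], exon_lines[j]))
  }))
  readr::write_lines(c("##provider: lnctf synthetic fixture", body), path)
  invisible(path)
}
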