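#' Run the full enrichment pipeline from files
#'
#' Convenience wrapper chaining [read_lncrna_gtf()], [load_peak_datasets()],
#' [regulatory_regions()], [build_target_map()], [resolve_input_ids()] and
#' [run_enrichment()]. This is what the `enrich` CLI subcommand calls.
#'
#' @param gtf Path to the lncRNA annotation GTF.
#' @param manifest Path to the peak-dataset manifest TSV (or a manifest
#'   tibble).
#' @param input Character vector of lncRNA IDs/names, or a path to a text file
#'   with one per line.
#' @param window Window preset or `c(upstream, downstream)`; default `"2k1k"`.
#' @param level `"gene"` or `"transcript"`.
#' @param cell_line Optional cell-line filter applied to the manifest.
#' @param reference Optional reference set: character vector or path to a text
#'   file (one ID per line); replaces the full annotation as the background.
#' @param threshold Adjusted-p cutoff for the common-TF flag.
#' @param biotypes Optional biotype filter passed to [read_lncrna_gtf()].
#' @param quiet Suppress progress messages.
#' @return An `lnctf_enrichment` tibble (see [run_enrichment()]).
#' @export
enrich_lncrna_set <- function(gtf, manifest, input, window = "2k1k",
                              level = c("gene", "transcript"),
                              cell_line = NULL, reference = NULL,
                              threshold = 0.05, biotypes = NULL,
                              quiet = FALSE) {
  level <- match.arg(level)
  read_ids <- function(x) {
    if (length(x) == 1 && file.exists(x)) {
      ids <- readr::read_lines(x)
      ids[nzchar(trimws(ids))]
    } else x
  }
  annotation <- read_lncrna_gtf(gtf, biotypes = biotypes)
  if (nrow(annotation) == 0) abort("Annotation contains no transcripts.")
  datasets <- load_peak_datasets(manifest, quiet = quiet)
  if (!is.null(cell_line)) {
    datasets <- filter(datasets, .data$cell_line == !!cell_line)
    if (nrow(datasets) == 0) {
      abort(sprintf("No dataset matches cell line '%s'.", cell_line))
    }
  }
  regions <- regulatory_regions(annotation, window, level = level)
  tm <- build_target_map(datasets, regions)
  input_ids <- resolve_input_ids(read_ids(input), annotation, level = level)
  if (length(input_ids) == 0) {
    abort("None of the input IDs could be resolved against the annotation.")
  }
  ref_ids <- NULL
  if (!is.null(reference)) {
    ref_ids <- resolve_input_ids(read_ids(reference), annotation, level = level)
  }
  if (!quiet) {
    inform(sprintf("Scoring %d dataset(s) against %d validated input ID(s).",
                   nrow(datasets), length(input_ids)))
  }
  run_enrichment(input_ids, tm, reference = ref_ids, threshold = threshold)
}

#' @export
print.lnctf_enrichment <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf(
    "# lnctf enrichment: %d dataset(s), %d input features, %d common TF dataset(s) at BH <= %g\n",
    nrow(x), attr(x, "n_input") %||% NA_integer_, sum(x$is_common_tf), thr
  ))
  NextMethod()
}

#' Tidy an enrichment result
#'
#' @param x An `lnctf_enrichment` object.
#' @param ... Unused.
#' @return A plain tibble (one row per dataset, already sorted by adjusted p).
#' @export
tidy.lnctf_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "lnctf_enrichment")
  out
}

#' One-row summary of an enrichment run
#'
#' @param x An `lnctf_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_datasets`, `n_common_tf`, `n_input` (`FG_S`),
#'   `bg_s`, `threshold`, `min_bh_p_value`.
#' @export
glance.lnctf_enrichment <- function(x, ...) {
  tibble(
    n_datasets = nrow(x),
    n_common_tf = sum(x$is_common_tf),
    n_input = attr(x, "n_input") %||% NA_integer_,
    bg_s = if (nrow(x)) x$bg_s[1] else NA_integer_,
    threshold = attr(x, "threshold"),
    min_bh_p_value = if (nrow(x)) min(x$bh_p_value) else NA_real_
  )
}

#' Plot an enrichment result
#'
#' Dot plot of `-log10` adjusted p-values per dataset, labelled by TF and
#' dataset ID, with the significance threshold drawn as a dashed line.
#'
#' @param object An `lnctf_enrichment` object.
#' @param top_n Show at most this many top datasets (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnctf_enrichment <- function(object, top_n = 25, ...) {
  thr <- attr(object, "threshold")
  df <- as_tibble(object) |>
    mutate(label = paste0(.data$tf, " [", .data$dataset_id, ", ",
                          .data$cell_line, "]")) |>
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$bh_p_value, .Machine$double.xmin)),
    y = stats::reorder(.data$label, -.data$bh_p_value),
    colour = .data$is_common_tf
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey40"),
      name = sprintf("BH p <= %g", thr)
    ) +
    ggplot2::labs(
      x = expression(-log[10] ~ "BH-adjusted p-value"),
      y = NULL,
      title = "TF peak enrichment around input lncRNA TSSs"
    ) +
    ggplot2::theme_minimal()
}
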