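#' lncRNAs targeted by a transcription factor
#'
#' Retrieves, across every dataset of the TF (optionally restricted to one
#' cell line), all lncRNA features whose regulatory regions contain at least
#' one of its peaks.
#'
#' @param tf_name TF name as recorded in the manifest.
#' @param target_map A [build_target_map()] result.
#' @param annotation Optional transcript tibble from [read_lncrna_gtf()]; when
#'   given, feature names are filled in from it.
#' @param cell_line Optional cell-line filter (exact match).
#' @return A tibble with columns `dataset_id`, `cell_line`, `feature_id`,
#'   `feature_name`, sorted by `dataset_id` then `feature_id`. Empty (with a
#'   warning) when the TF has no matching dataset.
#' @export
lncrnas_targeted_by <- function(tf_name, target_map, annotation = NULL,
                                cell_line = NULL) {
  meta <- attr(target_map, "meta")
  sel <- meta[meta$tf == tf_name, ]
  if (!is.null(cell_line)) sel <- sel[sel$cell_line == cell_line, ]
  if (nrow(sel) == 0) {
    if (!any(meta$tf == tf_name)) {
      warn(sprintf("TF '%s' is not present in any loaded dataset.", tf_name))
    }
    return(tibble(dataset_id = character(), cell_line = character(),
                  feature_id = character(), feature_name = character()))
  }
  rows <- as_tibble(target_map) |>
    filter(.data$dataset_id %in% sel$dataset_id) |>
    left_join(select(sel, "dataset_id", "cell_line"), by = "dataset_id") |>
    mutate(feature_name = feature_names(.data$feature_id, annotation,
                                        attr(target_map, "level"))) |>
    select("dataset_id", "cell_line", "feature_id", "feature_name") |>
    arrange(.data$dataset_id, .data$feature_id)
  rows
}

#' Transcription factors targeting a lncRNA
#'
#' Retrieves all datasets (TF / cell line / dataset ID) having at least one
#' peak in the regulatory region of the given feature.
#'
#' @param feature_id A gene or transcript ID from the annotation universe the
#'   target map was built on.
#' @param target_map A [build_target_map()] result.
#' @param cell_line Optional cell-line filter (exact match).
#' @return A tibble with columns `tf`, `cell_line`, `dataset_id`, sorted by
#'   `tf` then `dataset_id`. Empty when no dataset targets the feature.
#' @export
tfs_targeting <- function(feature_id, target_map, cell_line = NULL) {
  universe <- attr(target_map, "universe")
  if (!feature_id %in% universe) {
    abort(sprintf("Feature '%s' is not in the annotation universe.", feature_id))
  }
  meta <- attr(target_map, "meta")
  fid <- feature_id
  rows <- as_tibble(target_map) |>
    filter(.data$feature_id == fid) |>
    left_join(meta, by = "dataset_id") |>
    select("tf", "cell_line", "dataset_id")
  if (!is.null(cell_line)) {
    cl <- cell_line
    rows <- filter(rows, .data$cell_line == cl)
  }
  arrange(rows, .data$tf, .data$dataset_id)
}

feature_names <- function(feature_id, annotation, level) {
  if (is.null(annotation)) return(rep("", length(feature_id)))
  if (identical(level, "transcript")) {
    lut <- distinct(annotation, id = .data$transcript_id, name = .data$transcript_name)
  } else {
    lut <- distinct(annotation, id = .data$gene_id, name = .data$gene_name)
  }
  out <- lut$name[match(feature_id, lut$id)]
  out[is.na(out)] <- ""
  out
}
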