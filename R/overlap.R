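#' Build a searchable index over regulatory regions
#'
#' Wraps the regions in a `GenomicRanges` structure so overlap queries run in
#' sub-linear time per query. All coordinates are 0-based half-open on the way
#' in and out; overlap means at least 1 bp shared, so an abutting interval
#' (`query_start == region_end`) does not hit.
#'
#' @param regions A region tibble from [regulatory_regions()] (columns
#'   `feature_id`, `chrom`, `start`, `end`).
#' @return An object of class `lnctf_region_index`.
#' @export
region_index <- function(regions) {
  if (nrow(regions) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
    )
  }
  structure(
    list(granges = gr, feature_id = regions$feature_id,
         universe = sort(unique(regions$feature_id)),
         window = attr(regions, "window"), level = attr(regions, "level")),
    class = "lnctf_region_index"
  )
}

#' @export
print.lnctf_region_index <- function(x, ...) {
  cat(sprintf("<lnctf_region_index> %d regions over %d features\n",
              length(x$granges), length(x$universe)))
  invisible(x)
}

#' Query a region index with an interval
#'
#' @param index An [region_index()] object.
#' @param chrom Chromosome name (exact string match).
#' @param start,end Query interval, 0-based half-open.
#' @return A tibble of the overlapping regions (`feature_id`, `chrom`,
#'   `start`, `end`), possibly empty.
#' @export
query_region_index <- function(index, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index$granges))
  j <- S4Vectors::subjectHits(hits)
  tibble(
    feature_id = index$feature_id[j],
    chrom = as.character(GenomicRanges::seqnames(index$granges))[j],
    start = GenomicRanges::start(index$granges)[j] - 1L,
    end = GenomicRanges::end(index$granges)[j]
  )
}

#' Features targeted by a peak set
#'
#' A feature is targeted when at least one peak overlaps at least one of its
#' regulatory regions by >= 1 bp (half-open intervals: `max(starts) <
#' min(ends)`). Peaks on chromosomes absent from the annotation contribute
#' nothing. Duplicated peaks cannot change the result: targeting is a
#' ">= 1 peak" predicate, not a count.
#'
#' @param peaks A peak tibble from [read_peaks()] (columns `chrom`, `start`,
#'   `end`), or a dataset row's `peaks` element.
#' @param regions A region tibble from [regulatory_regions()] or a prebuilt
#'   [region_index()].
#' @return A sorted character vector of targeted `feature_id`s.
#' @export
targets_of <- function(peaks, regions) {
  index <- if (inherits(regions, "lnctf_region_index")) regions else region_index(regions)
  if (nrow(peaks) == 0 || length(index$granges) == 0) return(character())
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, index$granges))
  sort(unique(index$feature_id[S4Vectors::subjectHits(hits)]))
}

#' Build the dataset-to-targets map
#'
#' For every ChIP-Seq dataset, records the set of lncRNA features (genes or
#' transcripts, per the regions' level) with at least one overlapping peak.
#' The per-dataset set size is the background hit count `BG_H` used by
#' [run_enrichment()] under the full-annotation universe.
#'
#' @param datasets A nested dataset tibble from [load_peak_datasets()].
#' @param regions A region tibble from [regulatory_regions()].
#' @return A tibble of class `lnctf_target_map` with columns `dataset_id`,
#'   `feature_id` (one row per targeted feature per dataset), carrying the
#'   annotation universe, dataset metadata, window and level as attributes.
#' @export
build_target_map <- function(datasets, regions) {
  index <- region_index(regions)
  rows <- purrr::map2(
    datasets$dataset_id, datasets$peaks,
    function(id, pk) tibble(dataset_id = id, feature_id = targets_of(pk, index))
  )
  out <- bind_rows(rows)
  attr(out, "universe") <- index$universe
  attr(out, "meta") <- select(datasets, "dataset_id", "tf", "cell_line", "species")
  attr(out, "window") <- index$window
  attr(out, "level") <- index$level
  class(out) <- c("lnctf_target_map", class(out))
  out
}

#' Export a target map as TSV
#'
#' Audit export: one `dataset_id`/`feature_id` row per targeting relationship.
#'
#' @param target_map A [build_target_map()] result.
#' @param path Output TSV path.
#' @export
write_target_map_tsv <- function(target_map, path) {
  readr::write_tsv(as_tibble(target_map)[c("dataset_id", "feature_id")], path,
                   progress = FALSE)
  invisible(path)
}
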