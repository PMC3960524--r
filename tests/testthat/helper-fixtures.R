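# Shared in-code fixtures for the test suite.

# A minimal hand-built transcript tibble.
make_transcripts <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      transcript_id = r$transcript_id,
      transcript_name = r$transcript_name %||% "",
      gene_id = r$gene_id,
      gene_name = r$gene_name %||% "",
      chrom = r$chrom %||% "chr1",
      start = as.integer(r$start),
      end = as.integer(r$end),
      strand = r$strand %||% "+",
      biotype = r$biotype %||% "lncRNA"
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# One small on-disk fixture shared across test files (generated once per run).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "lnctf-shared-fixture")
      spec <- fixture_spec(
        seed = 424242, n_genes = 50, transcripts_per_gene = c(1L, 3L),
        n_null_datasets = 4, peaks_per_dataset = 300,
        planted = planted_spec(foreground_size = 12,
                               hit_fraction_foreground = 1.0,
                               hit_fraction_background = 0.05)
      )
      cache <<- suppressWarnings(generate_fixture(spec, out_dir = dir))
    }
    cache
  }
})
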