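#' Describe a planted (signal-carrying) fixture dataset
#'
#' A planted dataset drops one peak inside the regulatory window of each
#' selected gene: foreground genes are selected with probability
#' `hit_fraction_foreground`, background genes with
#' `hit_fraction_background`. The foreground is the known "interesting" gene
#' set an enrichment run should recover.
#'
#' @param dataset_id,tf Identifiers for the planted experiment.
#' @param hit_fraction_foreground,hit_fraction_background Selection
#'   probabilities in `[0, 1]`.
#' @param foreground_size Number of foreground genes.
#' @return A list of class `lnctf_planted_spec`.
#' @export
planted_spec <- function(dataset_id = "DS_PLANT", tf = "TF_PLANT",
                         hit_fraction_foreground = 0.8,
                         hit_fraction_background = 0.1,
                         foreground_size = 50L) {
  stopifnot(
    hit_fraction_foreground >= 0, hit_fraction_foreground <= 1,
    hit_fraction_background >= 0, hit_fraction_background <= 1,
    foreground_size >= 1
  )
  structure(
    list(dataset_id = dataset_id, tf = tf,
         hit_fraction_foreground = hit_fraction_foreground,
         hit_fraction_background = hit_fraction_background,
         foreground_size = as.integer(foreground_size)),
    class = "lnctf_planted_spec"
  )
}

#' Specify a synthetic fixture
#'
#' Describes a toy lncRNA genome plus ChIP-Seq peak datasets with known
#' targeting ground truth. Genes are laid out on non-overlapping slots spaced
#' so that regulatory windows never touch, making every peak's targeting
#' status unambiguous; all transcripts of a gene share its TSS (3' ends vary).
#' Null datasets draw peak starts uniformly over the chromosomes; an optional
#' planted dataset places peaks inside chosen genes' windows (see
#' [planted_spec()]).
#'
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Length-2 integer range, inclusive.
#' @param chrom_sizes Optional named vector of chromosome lengths (bp). By
#'   default two chromosomes just large enough are created. An error is
#'   raised if the requested genes cannot be placed without overlap.
#' @param n_null_datasets Number of uniform-background datasets.
#' @param peaks_per_dataset Peaks per null dataset.
#' @param peak_width Peak width in bp (default 200, fixed per dataset).
#' @param window Window preset/pair the layout and truth are computed under.
#' @param planted Optional [planted_spec()].
#' @param cell_lines Cell-line labels cycled across datasets.
#' @param species Species metadata string.
#' @return A list of class `lnctf_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 50L,
                         transcripts_per_gene = c(1L, 3L),
                         chrom_sizes = NULL, n_null_datasets = 3L,
                         peaks_per_dataset = 500L, peak_width = 200L,
                         window = "2k1k", planted = NULL,
                         cell_lines = c("K562", "HeLa-S3", "GM12878"),
                         species = "Homo sapiens") {
  w <- resolve_window(window)
  stopifnot(
    n_genes >= 1, length(transcripts_per_gene) == 2,
    transcripts_per_gene[1] >= 1,
    transcripts_per_gene[2] >= transcripts_per_gene[1],
    n_null_datasets >= 0, peaks_per_dataset >= 1, peak_width >= 1
  )
  if (!is.null(planted)) {
    if (!inherits(planted, "lnctf_planted_spec")) {
      abort("`planted` must come from planted_spec().")
    }
    if (planted$foreground_size > n_genes) {
      abort("`foreground_size` cannot exceed `n_genes`.")
    }
    if (peak_width > w$upstream + w$downstream + 1) {
      abort("`peak_width` must fit inside the regulatory window for planted peaks.")
    }
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         transcripts_per_gene = as.integer(transcripts_per_gene),
         chrom_sizes = chrom_sizes, n_null_datasets = as.integer(n_null_datasets),
         peaks_per_dataset = as.integer(peaks_per_dataset),
         peak_width = as.integer(peak_width), window = w, planted = planted,
         cell_lines = cell_lines, species = species),
    class = "lnctf_fixture_spec"
  )
}

# Which genes' windows a set of peaks lands in. Generation-side truth:
# windows are disjoint and sorted per chromosome, so a peak (narrower than the
# inter-window gap) overlaps at most one window; locate it with findInterval.
fixture_hits <- function(pk_chrom, pk_start, pk_end, win) {
  out <- character(0)
  for (ch in unique(win$chrom)) {
    sel <- which(win$chrom == ch)
    sel <- sel[order(win$start[sel])]
    ws <- win$start[sel]; we <- win$end[sel]
    p <- which(pk_chrom == ch)
    if (!length(p)) next
    ps <- pk_start[p]; pe <- pk_end[p]
    j <- findInterval(ps, ws)
    in_j <- j >= 1
    in_j[in_j] <- ps[in_j] < we[j[in_j]]
    jn <- j + 1
    in_next <- jn <= length(ws)
    in_next[in_next] <- ws[jn[in_next]] < pe[in_next]
    out <- c(out, win$gene_id[sel][j[in_j]], win$gene_id[sel][jn[in_next]])
  }
  sort(unique(out))
}

#' Generate a synthetic fixture
#'
#' Deterministically materialises the annotation, peak datasets, and targeting
#' ground truth described by a [fixture_spec()]. When `out_dir` is given,
#' standard files are written: `annotation.gtf`, `peaks/<dataset>.narrowPeak`,
#' `manifest.tsv`, `truth.tsv` (columns `dataset_id`, `level`, `feature_id`)
#' and, for planted fixtures, `foreground.txt` (one gene ID per line). Two
#' runs with the same spec produce byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional output directory (created if needed); `NULL` keeps
#'   the fixture in memory only.
#' @return (Invisibly for file output) a list of class `lnctf_fixture` with
#'   elements `transcripts`, `genes`, `datasets` (nested tibble ready for
#'   [build_target_map()]), `truth`, `foreground`, `windows` (the
#'   generation-side window table), `spec`, and `paths`.
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "lnctf_fixture_spec"))
  fx <- withr::with_seed(spec$seed, fixture_build(spec))
  fx$paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
    gtf <- file.path(out_dir, "annotation.gtf")
    write_lncrna_gtf(fx$transcripts, gtf)
    man <- fx$manifest
    for (i in seq_len(nrow(man))) {
      write_peaks(fx$datasets$peaks[[i]], file.path(out_dir, man$path[i]),
                  "narrowPeak")
    }
    man_path <- file.path(out_dir, "manifest.tsv")
    readr::write_tsv(man, man_path, progress = FALSE)
    truth_path <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(fx$truth, truth_path, progress = FALSE)
    fg_path <- NULL
    if (!is.null(fx$foreground)) {
      fg_path <- file.path(out_dir, "foreground.txt")
      readr::write_lines(fx$foreground, fg_path)
    }
    fx$paths <- list(dir = out_dir, gtf = gtf, manifest = man_path,
                     truth = truth_path, foreground = fg_path)
  }
  structure(fx, class = "lnctf_fixture")
}

fixture_build <- function(spec) {
  w <- spec$window
  u <- w$upstream; d <- w$downstream
  wl <- u + d + 1L
  len_min <- 800L; len_max <- 3000L
  pad <- u + d + spec$peak_width
  slot <- len_max + 2L * pad + 1000L
  n <- spec$n_genes

  sizes <- spec$chrom_sizes
  if (is.null(sizes)) {
    per <- ceiling(n / 2)
    sizes <- c(chr1 = (per + 1L) * slot, chr2 = (n - per + 1L) * slot)
  }
  capacity <- floor(sizes / slot)
  if (sum(capacity) < n) {
    abort(sprintf(
      "Cannot fit %d genes into the given chrom_sizes without overlap (capacity %d at %d bp per gene slot).",
      n, sum(capacity), slot
    ))
  }
  chrom <- rep(names(sizes), capacity)[seq_len(n)]
  slot_idx <- unlist(lapply(capacity, seq_len))[seq_len(n)]

  gene_len <- sample(len_min:len_max, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- (slot_idx - 1L) * slot + pad + 1L       # 1-based gene start
  gend <- gstart + gene_len - 1L
  tss1 <- ifelse(strand == "+", gstart, gend)
  ws1 <- ifelse(strand == "+", tss1 - u, tss1 - d)
  we1 <- ifelse(strand == "+", tss1 + d, tss1 + u)
  gene_id <- sprintf("LNCG%05d", seq_len(n))
  gene_name <- sprintf("LINC%05d", seq_len(n))
  windows <- tibble(gene_id = gene_id, chrom = chrom,
                    start = as.integer(ws1 - 1L), end = as.integer(we1))

  tpg <- spec$transcripts_per_gene
  k <- if (tpg[1] == tpg[2]) rep(tpg[1], n) else sample(tpg[1]:tpg[2], n, replace = TRUE)
  gidx <- rep(seq_len(n), k)
  tnum <- sequence(k)
  nt <- length(gidx)
  off <- floor(runif(nt) * (gene_len[gidx] - 200L))
  t_start <- gstart[gidx]
  t_end <- gend[gidx]
  extra <- tnum != 1L
  plus <- strand[gidx] == "+"
  t_end[plus & extra] <- (gstart[gidx] + 200L + off)[plus & extra]
  t_start[!plus & extra] <- (gstart[gidx] + off)[!plus & extra]
  transcripts <- tibble(
    transcript_id = sprintf("LNCT%05d", seq_len(nt)),
    transcript_name = sprintf("%s-2%02d", gene_name[gidx], tnum),
    gene_id = gene_id[gidx],
    gene_name = gene_name[gidx],
    chrom = chrom[gidx],
    start = as.integer(t_start),
    end = as.integer(t_end),
    strand = strand[gidx],
    biotype = "lncRNA"
  )

  width <- spec$peak_width
  datasets <- list(); truth_gene <- list()
  mk_peaks <- function(chr, s0, prefix) {
    np <- length(s0)
    tibble(chrom = chr, start = as.integer(s0), end = as.integer(s0 + width),
           name = sprintf("%s_pk%05d", prefix, seq_len(np)),
           score = 0, strand = ".", signal_value = 0,
           p_value_log = -1, q_value_log = -1,
           summit_offset = as.integer(width %/% 2))
  }
  for (j in seq_len(spec$n_null_datasets)) {
    id <- sprintf("DS%03d", j)
    pchr <- sample(names(sizes), spec$peaks_per_dataset, replace = TRUE,
                   prob = sizes / sum(sizes))
    s0 <- floor(runif(spec$peaks_per_dataset) * (sizes[pchr] - width))
    pk <- mk_peaks(pchr, s0, id)
    datasets[[id]] <- list(
      id = id, tf = sprintf("TF%02d", ceiling(j / 2)),
      cell_line = spec$cell_lines[(j - 1) %% length(spec$cell_lines) + 1],
      peaks = pk
    )
    truth_gene[[id]] <- fixture_hits(pk$chrom, pk$start, pk$end, windows)
  }

  foreground <- NULL
  if (!is.null(spec$planted)) {
    pl <- spec$planted
    foreground <- sort(sample(gene_id, pl$foreground_size))
    p_hit <- ifelse(gene_id %in% foreground,
                    pl$hit_fraction_foreground, pl$hit_fraction_background)
    sel <- which(runif(n) < p_hit)
    s0 <- (ws1[sel] - 1L) + floor(runif(length(sel)) * (wl - width + 1L))
    pk <- mk_peaks(chrom[sel], s0, pl$dataset_id)
    datasets[[pl$dataset_id]] <- list(
      id = pl$dataset_id, tf = pl$tf, cell_line = spec$cell_lines[1], peaks = pk
    )
    truth_gene[[pl$dataset_id]] <- sort(gene_id[sel])
  }

  ds <- tibble(
    dataset_id = vapply(datasets, `[[`, character(1), "id"),
    tf = vapply(datasets, `[[`, character(1), "tf"),
    cell_line = vapply(datasets, `[[`, character(1), "cell_line"),
    species = spec$species,
    n_peaks = vapply(datasets, function(x) nrow(x$peaks), integer(1)),
    peaks = lapply(datasets, `[[`, "peaks")
  )
  manifest <- tibble(
    path = file.path("peaks", paste0(ds$dataset_id, ".narrowPeak")),
    dataset_id = ds$dataset_id, tf = ds$tf, cell_line = ds$cell_line,
    species = ds$species, format = "narrowPeak"
  )
  tx_of_gene <- split(transcripts$transcript_id, transcripts$gene_id)
  truth <- bind_rows(lapply(names(truth_gene), function(id) {
    g <- truth_gene[[id]]
    bind_rows(
      tibble(dataset_id = id, level = "gene", feature_id = g),
      tibble(dataset_id = id, level = "transcript",
             feature_id = sort(as.character(unlist(tx_of_gene[g], use.names = FALSE))))
    )
  }))

  list(transcripts = transcripts, genes = gene_table(transcripts),
       datasets = ds, manifest = manifest, truth = truth,
       foreground = foreground, windows = windows, spec = spec)
}

#' Read a fixture truth table
#'
#' @param path Path to a `truth.tsv` written by [generate_fixture()].
#' @return A tibble with columns `dataset_id`, `level`, `feature_id`.
#' @export
read_fixture_truth <- function(path) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}
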