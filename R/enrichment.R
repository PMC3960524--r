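#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `m` or more targeted features in a size-`n` input
#' set drawn without replacement from a universe of `N` features of which `M`
#' are targeted:
#' \deqn{P = \sum_{i=m}^{\min(n, M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' Computed term-by-term in log space (`lchoose` + log-sum-exp), so it is
#' numerically safe far into the tail. `m = 0` returns exactly 1 (the sum runs
#' over the full support). All arguments are vectorised and recycled.
#'
#' @param N Universe size (all annotated lncRNA genes/transcripts, or the
#'   reference-set size). `BG_S` in the output schema.
#' @param M Universe members targeted by the TF (`BG_H`).
#' @param n Input-set size (`FG_S`).
#' @param m Input members targeted (`FG_H`).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' hypergeom_pvalue(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_pvalue <- function(N, M, n, m) {
  args <- vctrs_recycle(N = N, M = M, n = n, m = m)
  N <- args$N; M <- args$M; n <- args$n; m <- args$m
  check_counts(N, M, n, m)
  vapply(seq_along(N), function(k) {
    if (m[k] == 0) return(1)
    i <- m[k]:min(n[k], M[k])
    lt <- lchoose(M[k], i) + lchoose(N[k] - M[k], n[k] - i) - lchoose(N[k], n[k])
    mx <- max(lt)
    min(1, exp(mx + log(sum(exp(lt - mx)))))
  }, numeric(1))
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, rep_len, length.out = len)
}

check_counts <- function(N, M, n, m) {
  ok <- is.finite(N) & is.finite(M) & is.finite(n) & is.finite(m) &
    N == round(N) & M == round(M) & n == round(n) & m == round(m) &
    N >= 0 & M >= 0 & M <= N & n >= 0 & n <= N & m >= 0 & m <= pmin(n, M)
  if (!all(ok)) {
    abort(paste0(
      "Invalid enrichment counts: need integers with 0 <= m <= min(n, M), ",
      "M <= N, n <= N."
    ))
  }
  invisible(TRUE)
}

#' Odds ratio of targeting, input set vs background
#'
#' The ratio of the odds that an input lncRNA is targeted to the odds that a
#' background lncRNA is targeted:
#' `(FG_H / (FG_S - FG_H)) / (BG_H / (BG_S - BG_H))`.
#' Degenerate cases map to sentinels, never errors: a fully-hit input set
#' (`FG_H = FG_S`) over an informative background gives `Inf`; an unhit input
#' set over a hit background gives 0; a degenerate background (`BG_H = 0` or
#' `BG_H = BG_S`) gives `NA` (not available). Vectorised.
#'
#' @param fg_h,fg_s Input hits and input size.
#' @param bg_h,bg_s Background hits and background (universe) size.
#' @return Numeric vector; may contain `Inf`, 0, `NA`.
#' @examples
#' odds_ratio(8, 10, 20, 100)  # (8/2) / (20/80) = 16
#' @export
odds_ratio <- function(fg_h, fg_s, bg_h, bg_s) {
  args <- vctrs_recycle(fg_h = fg_h, fg_s = fg_s, bg_h = bg_h, bg_s = bg_s)
  with(args, case_when(
    bg_h == 0 | bg_h == bg_s ~ NA_real_,
    fg_h == fg_s ~ Inf,
    fg_h == 0 ~ 0,
    TRUE ~ (fg_h / (fg_s - fg_h)) / (bg_h / (bg_s - bg_h))
  ))
}

#' Expected number of targeted input features under the null
#'
#' `Expected_H = FG_S * (BG_H / BG_S)`: the input hit count expected if the
#' input set were drawn at random from the background.
#'
#' @param fg_s Input-set size.
#' @param bg_h,bg_s Background hits and background size (`bg_s > 0`).
#' @return Numeric vector (not rounded).
#' @export
expected_count <- function(fg_s, bg_h, bg_s) {
  if (any(bg_s == 0)) abort("`bg_s` must be positive.")
  fg_s * bg_h / bg_s
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment across a family of p-values, preserving
#' input order. Adjusted values never fall below the raw ones and are capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must all lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

strip_id_version <- function(x) sub("\\.\\d+$", "", x)

#' Resolve user-supplied lncRNA IDs or names against an annotation
#'
#' Resolution order: exact ID match first, then name match for whatever is
#' left. A name mapping to several IDs is an error listing the candidates.
#' Duplicated inputs are dropped with a message; Ensembl-style version
#' suffixes (a trailing `.7` etc.) are stripped on both sides when
#' `strip_versions = TRUE` (the default). Inputs that match nothing are
#' dropped with a single warning listing them.
#'
#' @param ids Character vector of IDs and/or names, as users supply them.
#' @param annotation Transcript tibble from [read_lncrna_gtf()].
#' @param level `"gene"` or `"transcript"`: which IDs/names to match.
#' @param strip_versions Strip trailing `.N` version suffixes when matching.
#' @return Character vector of matched feature IDs (unique, annotation
#'   spelling).
#' @export
resolve_input_ids <- function(ids, annotation, level = c("gene", "transcript"),
                              strip_versions = TRUE) {
  level <- match.arg(level)
  ids <- ids[!is.na(ids) & nzchar(trimws(ids))]
  ids <- trimws(ids)
  n_dup <- length(ids) - length(unique(ids))
  if (n_dup > 0) {
    inform(sprintf("Dropped %d duplicated input ID(s).", n_dup))
    ids <- unique(ids)
  }
  if (level == "gene") {
    ann <- distinct(annotation, id = .data$gene_id, name = .data$gene_name)
  } else {
    ann <- distinct(annotation, id = .data$transcript_id, name = .data$transcript_name)
  }
  key <- if (strip_versions) strip_id_version(ids) else ids
  ann_key <- if (strip_versions) strip_id_version(ann$id) else ann$id

  hit_id <- match(key, ann_key)
  unresolved <- is.na(hit_id)
  resolved <- ann$id[hit_id[!unresolved]]

  if (any(unresolved)) {
    by_name <- ann[nzchar(ann$name), ]
    for (k in which(unresolved)) {
      cand <- unique(by_name$id[by_name$name == ids[k]])
      if (length(cand) == 1) {
        resolved <- c(resolved, cand)
        unresolved[k] <- FALSE
      } else if (length(cand) > 1) {
        abort(sprintf("Input name '%s' is ambiguous; candidate IDs: %s.",
                      ids[k], paste(cand, collapse = ", ")))
      }
    }
  }
  if (any(unresolved)) {
    warn(sprintf("%d input ID(s) not found in the annotation and dropped: %s.",
                 sum(unresolved), paste(ids[unresolved], collapse = ", ")))
  }
  unique(resolved)
}

#' Score every ChIP-Seq dataset for enrichment in an input lncRNA set
#'
#' For each dataset, counts the targeted members of the input set (`FG_H`) and
#' of the background (`BG_H`), computes the upper-tail hypergeometric p-value,
#' the expected input hit count and the odds ratio, then adjusts p-values by
#' Benjamini-Hochberg across all datasets of the run (the run is the
#' multiple-testing family). A dataset is flagged a common TF of the input set
#' when its adjusted p-value is at or below `threshold`.
#'
#' With a user `reference` set, all counts are taken within it: `BG_S` is the
#' reference size, `BG_H` the reference members targeted, and input IDs
#' outside the reference are intersected away with a warning (the reference
#' defines the measurable universe).
#'
#' @param input_ids Character vector of feature IDs (already resolved, e.g. by
#'   [resolve_input_ids()]); must intersect the universe.
#' @param target_map A [build_target_map()] result.
#' @param reference Optional character vector of feature IDs replacing the
#'   full annotation as the background universe.
#' @param threshold Adjusted-p cutoff for the `is_common_tf` flag (default
#'   0.05).
#' @return A tibble of class `lnctf_enrichment`, one row per dataset, sorted
#'   by `bh_p_value`, then raw `p_value`, then `dataset_id`; columns `species`,
#'   `cell_line`, `tf`, `dataset_id`, `bg_h`, `bg_s`, `fg_h`, `fg_s`,
#'   `expected_h`, `odds_ratio`, `p_value`, `bh_p_value`, `is_common_tf`.
#' @export
run_enrichment <- function(input_ids, target_map, reference = NULL,
                           threshold = 0.05) {
  universe <- attr(target_map, "universe")
  meta <- attr(target_map, "meta")
  if (is.null(universe) || is.null(meta)) {
    abort("`target_map` must come from build_target_map().")
  }

  background <- universe
  if (!is.null(reference)) {
    reference <- unique(reference)
    missing_ref <- setdiff(reference, universe)
    if (length(missing_ref)) {
      warn(sprintf("%d reference ID(s) absent from the annotation were dropped.",
                   length(missing_ref)))
    }
    background <- sort(intersect(reference, universe))
    if (length(background) == 0) abort("Reference set shares no IDs with the annotation.")
  }

  input <- unique(input_ids)
  outside <- setdiff(input, background)
  if (length(outside)) {
    warn(sprintf("%d input ID(s) outside the %s were dropped: %s.",
                 length(outside),
                 if (is.null(reference)) "annotation universe" else "reference set",
                 paste(outside, collapse = ", ")))
    input <- intersect(input, background)
  }
  if (length(input) == 0) abort("No input IDs remain after validation.")

  bg_s <- length(background)
  fg_s <- length(input)
  tm <- as_tibble(target_map)

  counts <- purrr::map(meta$dataset_id, function(id) {
    tset <- tm$feature_id[tm$dataset_id == id]
    if (!is.null(reference)) tset <- intersect(tset, background)
    c(bg_h = length(tset), fg_h = length(intersect(tset, input)))
  })
  bg_h <- vapply(counts, `[[`, integer(1) + 0, "bg_h")
  fg_h <- vapply(counts, `[[`, integer(1) + 0, "fg_h")

  out <- meta |>
    mutate(
      bg_h = as.integer(bg_h), bg_s = bg_s,
      fg_h = as.integer(fg_h), fg_s = fg_s,
      expected_h = expected_count(fg_s, bg_h, bg_s),
      odds_ratio = odds_ratio(fg_h, fg_s, bg_h, bg_s),
      p_value = hypergeom_pvalue(bg_s, bg_h, fg_s, fg_h)
    ) |>
    mutate(
      bh_p_value = bh_adjust(.data$p_value),
      is_common_tf = .data$bh_p_value <= threshold
    ) |>
    arrange(.data$bh_p_value, .data$p_value, .data$dataset_id) |>
    select("species", "cell_line", "tf", "dataset_id", "bg_h", "bg_s",
           "fg_h", "fg_s", "expected_h", "odds_ratio", "p_value",
           "bh_p_value", "is_common_tf")
  attr(out, "threshold") <- threshold
  attr(out, "n_input") <- fg_s
  attr(out, "window") <- attr(target_map, "window")
  attr(out, "level") <- attr(target_map, "level")
  class(out) <- c("lnctf_enrichment", class(out))
  out
}

# 6 significant digits; Inf -> "Inf", NA -> "NA"
format_sig6 <- function(x) {
  out <- rep("NA", length(x))
  out[is.infinite(x) & x > 0] <- "Inf"
  out[is.infinite(x) & x < 0] <- "-Inf"
  fin <- is.finite(x)
  out[fin] <- formatC(x[fin], digits = 6, format = "g")
  out
}

#' Write an enrichment table as TSV
#'
#' Writes the canonical output schema with header
#' `Species, Cell_Line, TF, Dataset_ID, BG_H, BG_S, FG_H, FG_S, Expected_H,
#' Odds_Ratio, P_Value, BH_P_Value, Common_TF`. Floating values are printed
#' with 6 significant digits; infinity as `Inf`; not-available as `NA`. Output
#' is deterministic: identical inputs give byte-identical files.
#'
#' @param x An `lnctf_enrichment` tibble from [run_enrichment()].
#' @param path Output path, or `""` for stdout.
#' @export
write_enrichment_tsv <- function(x, path) {
  header <- paste(c("Species", "Cell_Line", "TF", "Dataset_ID", "BG_H", "BG_S",
                    "FG_H", "FG_S", "Expected_H", "Odds_Ratio", "P_Value",
                    "BH_P_Value", "Common_TF"), collapse = "\t")
  body <- sprintf(
    "%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
    x$species, x$cell_line, x$tf, x$dataset_id,
    x$bg_h, x$bg_s, x$fg_h, x$fg_s,
    format_sig6(x$expected_h), format_sig6(x$odds_ratio),
    format_sig6(x$p_value), format_sig6(x$bh_p_value),
    ifelse(x$is_common_tf, "TRUE", "FALSE")
  )
  if (identical(path, "")) {
    writeLines(c(header, body))
  } else {
    readr::write_lines(c(header, body), path)
  }
  invisible(path)
}
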