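test_that("hypergeometric p-values match hand-derived exact fractions", {
  # N=10, M=4, n=5: P(X >= 3) = (C(4,3)C(6,2) + C(4,4)C(6,1)) / C(10,5) = 66/252
  expect_equal(hypergeom_pvalue(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(oracle_hypergeom(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  # N=20, M=5, n=8, m=5: single term C(5,5)C(15,3)/C(20,8) = 455/125970
  expect_equal(hypergeom_pvalue(20, 5, 8, 5), 455 / 125970, tolerance = 1e-12)
  expect_equal(oracle_hypergeom(20, 5, 8, 5), 455 / 125970, tolerance = 1e-12)
})

test_that("hypergeometric degenerate identities hold exactly", {
  expect_identical(hypergeom_pvalue(100, 30, 10, 0), 1)
  expect_identical(hypergeom_pvalue(7, 0, 3, 0), 1)
  # n = N forces m = M: the sum covers the whole support
  expect_equal(hypergeom_pvalue(12, 5, 12, 5), 1, tolerance = 1e-12)
})

test_that("hypergeometric p agrees with stats::phyper across random cases", {
  withr::local_seed(31)
  for (rep in 1:200) {
    N <- sample(5:500, 1)
    M <- sample(0:N, 1)
    n <- sample(1:N, 1)
    m <- sample(0:min(n, M), 1)
    expect_equal(
      hypergeom_pvalue(N, M, n, m),
      stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE),
      tolerance = 1e-10
    )
  }
})

test_that("p decreases strictly in m and satisfies the complement identity", {
  grid <- expand.grid(N = c(15, 40), M = c(4, 9), n = c(5, 12))
  for (k in seq_len(nrow(grid))) {
    N <- grid$N[k]; M <- grid$M[k]; n <- grid$n[k]
    ms <- 0:min(n, M)
    p <- hypergeom_pvalue(N, M, n, ms)
    # strict decrease holds on the support: below m_min = max(0, n - (N - M))
    # the tail sum covers everything and P is exactly 1
    m_min <- max(0, n - (N - M))
    expect_true(all(abs(p[ms <= m_min] - 1) < 1e-12))
    on_support <- p[ms >= m_min]
    expect_true(all(diff(on_support) < 0))
    # P(>= m) + P(< m) = 1
    for (m in ms) {
      below <- if (m == 0) 0 else sum(stats::dhyper(0:(m - 1), M, N - M, n))
      expect_equal(hypergeom_pvalue(N, M, n, m) + below, 1, tolerance = 1e-10)
    }
  }
})

test_that("invalid enrichment counts are rejected", {
  expect_error(hypergeom_pvalue(10, 11, 5, 3), "Invalid enrichment counts")
  expect_error(hypergeom_pvalue(10, 4, 11, 3), "Invalid enrichment counts")
  expect_error(hypergeom_pvalue(10, 4, 5, 5), "Invalid enrichment counts")
  expect_error(hypergeom_pvalue(10.5, 4, 5, 3), "Invalid enrichment counts")
})

test_that("odds ratio is the ratio of odds with documented sentinels", {
  expect_equal(odds_ratio(5, 10, 50, 100), 1)
  expect_equal(odds_ratio(8, 10, 20, 100), 16)
  expect_identical(odds_ratio(10, 10, 50, 100), Inf)
  expect_identical(odds_ratio(0, 10, 50, 100), 0)
  expect_true(is.na(odds_ratio(3, 10, 0, 100)))     # background never hit
  expect_true(is.na(odds_ratio(3, 10, 100, 100)))   # background always hit
})

test_that("expected count follows FG_S * BG_H / BG_S", {
  expect_equal(expected_count(10, 50, 100), 5)
  expect_equal(expected_count(0, 50, 100), 0)
  expect_equal(expected_count(7, 3, 9), 7 / 3)
  expect_error(expected_count(10, 5, 0), "positive")
})

test_that("BH adjustment matches hand step-up computations", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.1)), c(0.015, 0.1, 0.1))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("BH adjustment matches the step-up oracle on random vectors", {
  withr::local_seed(77)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("input id resolution handles names, versions, duplicates, unknowns", {
  ann <- make_transcripts(
    list(transcript_id = "ENST1.2", transcript_name = "L1-201",
         gene_id = "ENSG1.7", gene_name = "L1", start = 100, end = 200),
    list(transcript_id = "ENST2.1", transcript_name = "L2-201",
         gene_id = "ENSG2.3", gene_name = "L2", start = 700, end = 900),
    list(transcript_id = "ENST3.1", transcript_name = "L2-202",
         gene_id = "ENSG3.1", gene_name = "L2", start = 1500, end = 1700)
  )
  # exact id, version-stripped id, and name resolution
  expect_equal(resolve_input_ids(c("ENSG1.7", "ENSG2"), ann, "gene"),
               c("ENSG1.7", "ENSG2.3"))
  expect_equal(resolve_input_ids("L1", ann, "gene"), "ENSG1.7")
  # ambiguous name lists candidates
  expect_error(resolve_input_ids("L2", ann, "gene"), "ambiguous.*ENSG2.3.*ENSG3.1")
  # duplicates dropped with a message, unknowns warned and dropped
  expect_message(resolve_input_ids(c("ENSG1.7", "ENSG1.7"), ann, "gene"),
                 "duplicated")
  expect_warning(out <- resolve_input_ids(c("ENSG1.7", "NOPE"), ann, "gene"),
                 "NOPE")
  expect_equal(out, "ENSG1.7")
  # transcript level
  expect_equal(resolve_input_ids("ENST2", ann, "transcript"), "ENST2.1")
  # version stripping can be disabled
  expect_warning(out2 <- resolve_input_ids("ENSG2", ann, "gene",
                                           strip_versions = FALSE), "ENSG2")
  expect_equal(length(out2), 0)
})

make_target_map <- function(sets, universe, cell_line = "K562") {
  ds <- tibble::tibble(
    dataset_id = names(sets),
    tf = paste0("TF_", names(sets)),
    cell_line = cell_line,
    species = "Homo sapiens",
    n_peaks = 1L,
    peaks = list(tibble::tibble(chrom = character(), start = integer(),
                                end = integer()))
  )
  tm <- dplyr::bind_rows(lapply(names(sets), function(id) {
    tibble::tibble(dataset_id = id, feature_id = sets[[id]])
  }))
  attr(tm, "universe") <- sort(universe)
  attr(tm, "meta") <- ds[c("dataset_id", "tf", "cell_line", "species")]
  class(tm) <- c("lnctf_target_map", class(tm))
  tm
}

test_that("run_enrichment counts, sorts and flags per the output contract", {
  universe <- sprintf("g%03d", 1:100)
  tm <- make_target_map(
    list(D1 = universe[1:20],          # contains the whole input
         D2 = universe[seq(2, 60, 2)], # random-ish 30
         D3 = character(0)),
    universe
  )
  input <- universe[1:10]
  res <- run_enrichment(input, tm)
  expect_s3_class(res, "lnctf_enrichment")
  expect_equal(nrow(res), 3)
  expect_equal(res$dataset_id[1], "D1")   # perfect containment ranks first
  d1 <- res[res$dataset_id == "D1", ]
  expect_equal(d1$bg_h, 20L)
  expect_equal(d1$fg_h, 10L)
  expect_equal(d1$bg_s, 100L)
  expect_equal(d1$fg_s, 10L)
  expect_equal(d1$expected_h, 10 * 20 / 100)
  expect_identical(d1$odds_ratio, Inf)
  expect_equal(d1$p_value, oracle_hypergeom(100, 20, 10, 10), tolerance = 1e-12)
  expect_equal(res$bh_p_value, oracle_bh(res$p_value), tolerance = 1e-12)
  expect_true(all(res$bh_p_value >= res$p_value - 1e-15))
  # unhit dataset: m = 0 -> p = 1, never flagged
  d3 <- res[res$dataset_id == "D3", ]
  expect_identical(d3$p_value, 1)
  expect_identical(d3$bh_p_value, 1)
  expect_false(d3$is_common_tf)
})

test_that("input equal to the whole universe gives p = 1 everywhere", {
  universe <- sprintf("g%02d", 1:30)
  tm <- make_target_map(list(D1 = universe[1:7], D2 = universe[5:30]), universe)
  res <- run_enrichment(universe, tm)
  expect_true(all(res$fg_h == res$bg_h))
  expect_true(all(abs(res$p_value - 1) < 1e-12))
})

test_that("a user reference set redefines the background counts", {
  universe <- sprintf("g%03d", 1:100)
  tm <- make_target_map(list(D1 = universe[1:40]), universe)
  reference <- universe[21:70]   # 50 features; 20 of them targeted by D1
  expect_warning(
    res <- run_enrichment(universe[21:30], tm, reference = reference),
    NA
  )
  expect_equal(res$bg_s, 50L)
  expect_equal(res$bg_h, 20L)
  expect_equal(res$fg_s, 10L)
  expect_equal(res$fg_h, 10L)
  expect_equal(res$p_value, oracle_hypergeom(50, 20, 10, 10), tolerance = 1e-12)

  # input outside the reference is intersected away with a warning
  expect_warning(
    res2 <- run_enrichment(universe[c(21:30, 90)], tm, reference = reference),
    "outside the reference"
  )
  expect_equal(res2$fg_s, 10L)

  # nothing left after validation aborts
  expect_error(
    suppressWarnings(run_enrichment(universe[90:95], tm, reference = reference)),
    "No input IDs remain"
  )
})

test_that("enrichment output TSV uses the canonical schema and formatting", {
  universe <- sprintf("g%03d", 1:100)
  tm <- make_target_map(list(D1 = universe[1:20], D2 = character(0)), universe)
  res <- run_enrichment(universe[1:10], tm)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, out)
  lines <- readLines(out)
  expect_equal(
    lines[1],
    paste(c("Species", "Cell_Line", "TF", "Dataset_ID", "BG_H", "BG_S", "FG_H",
            "FG_S", "Expected_H", "Odds_Ratio", "P_Value", "BH_P_Value",
            "Common_TF"), collapse = "\t")
  )
  f1 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f1[4], "D1")
  expect_equal(f1[10], "Inf")                   # FG_H = FG_S sentinel
  f2 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(f2[10], "NA")                    # BG_H = 0 sentinel
  expect_equal(f1[11], formatC(res$p_value[1], digits = 6, format = "g"))
})
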