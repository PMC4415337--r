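test_that("combined score formulas match their printed arithmetic", {
  expect_equal(sequest_combined_score(0, 0, 0), 0)
  expect_equal(sequest_combined_score(2.0, 0.1, 0.9), 7.0)
  expect_equal(sequest_combined_score(1, 0.2, 0.5) - sequest_combined_score(1, 0.2, 0.4),
               0.5, tolerance = 1e-12)
  expect_error(sequest_combined_score(NA, 0, 0), "non-finite")
  expect_equal(xtandem_combined_score(10, 16, 0.5), 36)
  expect_equal(xtandem_combined_score(99, 0, 0.7), 0)
  expect_equal(xtandem_combined_score(10, 25, 0), 25)
  expect_error(xtandem_combined_score(1, -4, 0.5), ">= 0")
})

test_that("both combined scores increase strictly with CC", {
  withr::local_seed(131)
  for (rep in 1:20) {
    x <- runif(1, 0, 5); d <- runif(1, 0, 0.4); st <- runif(1, 0.5, 50)
    sp <- sample(1:40, 1)
    cc1 <- runif(1, -1, 0.9); cc2 <- cc1 + runif(1, 0.01, 0.1)
    expect_gt(sequest_combined_score(x, d, cc2), sequest_combined_score(x, d, cc1))
    expect_gt(xtandem_combined_score(sp, st, cc2), xtandem_combined_score(sp, st, cc1))
  }
})

test_that("the FDR curve equals a brute-force threshold sweep", {
  withr::local_seed(137)
  for (n in c(50, 200, 500)) {
    psms <- tibble::tibble(
      spectrum_id = as.character(seq_len(n)),
      is_decoy = runif(n) < 0.4,
      combined_score = round(rnorm(n, 2, 1), 2)  # rounding forces ties
    )
    if (!any(psms$is_decoy)) psms$is_decoy[1] <- TRUE
    if (all(psms$is_decoy)) psms$is_decoy[2] <- FALSE
    curve <- compute_fdr_curve(psms)
    oracle <- oracle_fdr_sweep(psms$combined_score, psms$is_decoy)
    # compare at the end of each tie group, where the full >= threshold set
    # has been accepted
    last <- rev(!duplicated(rev(curve$threshold)))
    got <- curve[last, ]
    expect_equal(got$threshold, oracle$threshold)
    expect_equal(got$targets, oracle$targets)
    expect_equal(got$decoys, oracle$decoys)
    expect_equal(got$fdr, oracle$fdr)
    expect_equal(got$q, oracle$q)
    # monotone after monotonisation
    expect_true(all(diff(curve$q) >= -1e-12))
  }
})

test_that("separable and interleaved score configurations behave as expected", {
  sep <- tibble::tibble(
    is_decoy = rep(c(FALSE, TRUE), each = 10),
    combined_score = c(20:11, 10:1)
  )
  curve <- compute_fdr_curve(sep)
  expect_equal(curve$fdr[10], 0)          # all 10 targets, no decoys yet
  expect_equal(curve$fdr[20], 1.0)        # full acceptance: 10/10
  expect_equal(psms_at_fdr(curve, 0.005), 10L)
  inter <- tibble::tibble(
    is_decoy = rep(c(TRUE, FALSE), 10),
    combined_score = 20:1
  )
  ci <- compute_fdr_curve(inter)
  expect_true(all(ci$fdr[seq(2, 20, 2)] == 1))
  expect_equal(psms_at_fdr(ci, 0.01), 0L)
  expect_error(compute_fdr_curve(tibble::tibble(is_decoy = c(FALSE, FALSE),
                                                combined_score = c(1, 2))),
               "no decoy")
})

test_that("ties put decoys before targets (conservative ordering)", {
  psms <- tibble::tibble(is_decoy = c(FALSE, TRUE, FALSE),
                         combined_score = c(5, 5, 5))
  curve <- compute_fdr_curve(psms)
  expect_equal(curve$decoys[1], 1L)  # the decoy is counted first
})

test_that("rerank fills scores and sorts by the combined score", {
  withr::local_seed(139)
  cfg <- synth_config(n_peptides = 30, seed = 140)
  bench <- generate_psm_benchmark(cfg, cc_signal = 1)
  rr <- rerank_psms(bench$psms, bench$params, bench$spectra)
  expect_equal(nrow(rr), 30)
  expect_true(all(c("cc", "shared_peaks", "engine_score", "combined_score") %in% names(rr)))
  expect_true(all(diff(rr$combined_score) <= 0))
  expect_equal(rr$combined_score,
               sequest_combined_score(rr$xcorr, rr$delta_cn, rr$cc))
  # single PSM
  one <- rerank_psms(bench$psms[1, ], bench$params, bench$spectra)
  expect_equal(nrow(one), 1)
  # unresolvable ids are skipped with a warning
  broken <- bench$psms
  broken$spectrum_id[1:3] <- "nope"
  expect_warning(rr2 <- rerank_psms(broken, bench$params, bench$spectra),
                 "3 PSM")
  expect_equal(nrow(rr2), 27)
})

test_that("a constant CC never changes accepted counts versus the engine score", {
  withr::local_seed(149)
  n <- 400
  psms <- tibble::tibble(
    is_decoy = rep(c(TRUE, FALSE), n / 2),
    xcorr = rnorm(n, ifelse(rep(c(TRUE, FALSE), n / 2), 1.5, 3), 1),
    delta_cn = pmax(0, rnorm(n, 0.15, 0.05))
  )
  psms$engine_score <- psms$xcorr + 5 * psms$delta_cn
  for (const_cc in c(0, 0.5)) {
    psms$combined_score <- sequest_combined_score(psms$xcorr, psms$delta_cn,
                                                  const_cc)
    for (q in c(0.005, 0.01, 0.05)) {
      expect_equal(psms_at_fdr(compute_fdr_curve(psms, "combined_score"), q),
                   psms_at_fdr(compute_fdr_curve(psms, "engine_score"), q))
    }
  }
})

test_that("X!Tandem reranking uses shared peaks and the S_T formula", {
  withr::local_seed(151)
  cfg <- synth_config(n_peptides = 20, seed = 152)
  bench <- generate_psm_benchmark(cfg, cc_signal = 1, engine = "XTANDEM")
  rr <- rerank_psms(bench$psms, bench$params, bench$spectra)
  expect_true(all(!is.na(rr$shared_peaks)))
  expect_equal(rr$combined_score,
               xtandem_combined_score(rr$shared_peaks, rr$s_t, rr$cc))
  expect_equal(rr$engine_score, rr$s_t)
})
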