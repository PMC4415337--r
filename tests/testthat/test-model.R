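test_that("cleavage energy matches the per-residue brute-force oracle", {
  withr::local_seed(23)
  for (rep in 1:60) {
    params <- rand_params()
    pep <- rand_peptide()
    n <- nchar(pep)
    for (i in sample(seq_len(n - 1), min(4, n - 1))) {
      expect_equal(cleavage_energy(pep, i, params),
                   oracle_cleavage_energy(pep, i, params), tolerance = 1e-12)
    }
  }
  expect_error(cleavage_energy("PEPTIDEK", 8, rand_params()), "out of range")
})

test_that("zero parameters give zero energies, zero ratios, a flat spectrum", {
  p0 <- zero_params()
  pep <- "ACDEFGHIKLMNPQRSK"
  n <- nchar(pep)
  expect_equal(cleavage_energy(pep, 1:(n - 1), p0), rep(0, n - 1))
  expect_equal(log_ratio(pep, 1:(n - 2), p0), rep(0, n - 2))
  expect_equal(unname(predict_y_intensities(pep, p0)), rep(100, n - 1))
})

test_that("log ratio equals its recomputation from energies and G", {
  withr::local_seed(29)
  for (rep in 1:25) {
    params <- rand_params()
    pep <- rand_peptide()
    n <- nchar(pep)
    for (i in seq_len(n - 2)) {
      expect_equal(log_ratio(pep, i, params),
                   oracle_log_ratio(pep, i, params), tolerance = 1e-10)
    }
  }
})

test_that("homopolymers with beta = 0 and identity-only G have flat ratios", {
  withr::local_seed(31)
  p <- rand_params()
  p$beta <- 0
  p$G$penultimate <- p$G$interior  # G depends on residue identity only
  expect_equal(log_ratio("AAAAAA", 1:4, p), rep(0, 4))
})

test_that("predicted intensities invert the ratio chain exactly", {
  withr::local_seed(37)
  for (rep in 1:25) {
    params <- rand_params()
    pep <- rand_peptide(5, 20)
    n <- nchar(pep)
    I <- predict_y_intensities(pep, params)
    expect_true(all(I > 0))
    expect_equal(max(I), 100)
    lr <- log_ratio(pep, seq_len(n - 2), params)
    expect_equal(log(I[seq_len(n - 2)] / I[2:(n - 1)]), stats::setNames(lr, names(I)[seq_len(n-2)]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a constant positive log ratio gives a geometric series peaking at y1", {
  # homopolymer kills the residue terms; a linear C-terminus ramp
  # cterm[d] = -c * d makes every energy difference equal c
  c0 <- 0.35
  p0 <- zero_params()
  p0$delta_cterm[] <- -c0 * (0:10)
  pep <- "GGGGGGGGGG"  # n = 10, so every site stays inside the cterm window
  n <- nchar(pep)
  lr <- log_ratio(pep, seq_len(n - 2), p0)
  expect_equal(lr, rep(c0, n - 2), tolerance = 1e-12)
  I <- unname(predict_y_intensities(pep, p0))
  expect_equal(which.max(I), 1L)
  expect_equal(I, 100 * exp(-c0 * (seq_len(n - 1) - 1)), tolerance = 1e-9)
})

test_that("anchor choice is immaterial after max-normalisation", {
  withr::local_seed(41)
  params <- rand_params()
  pep <- rand_peptide(8, 14)
  n <- nchar(pep)
  lr <- log_ratio(pep, seq_len(n - 2), params)
  # anchor at y_1 instead of y_{n-1}
  logI_alt <- cumsum(c(0, -lr))
  I_alt <- exp(logI_alt - max(logI_alt)) * 100
  expect_equal(unname(predict_y_intensities(pep, params)), I_alt, tolerance = 1e-9)
})

test_that("isotope envelope follows the normalised Poisson pmf", {
  expect_equal(isotope_envelope(2000, n_peaks = 3, lambda_per_da = 1 / 2000),
               c(1, 1, 0.5), tolerance = 1e-12)
  env <- isotope_envelope(10, n_peaks = 3, lambda_per_da = 1e-9)
  expect_equal(env[1], 1)
  expect_lt(env[2], 1e-6)
  # non-increasing iff lambda <= 1
  expect_true(all(diff(isotope_envelope(1000, 5, 9e-4)) <= 0))   # lambda 0.9
  expect_false(all(diff(isotope_envelope(3000, 5, 9e-4)) <= 0))  # lambda 2.7
  expect_error(isotope_envelope(-5), "positive")
})

test_that("predicted spectra have the right peak count, order and scale", {
  withr::local_seed(43)
  params <- rand_params()
  sp <- predict_spectrum("EIELEDPLENMGAQMVK", params, n_isotope_peaks = 3)
  expect_equal(nrow(sp), 48)  # 16 ions x 3 isotopes
  expect_true(all(diff(sp$mz) > 0))
  expect_true(all(sp$intensity > 0))
  expect_equal(max(sp$intensity), 100)
  sp1 <- predict_spectrum("EIELEDPLENMGAQMVK", params, n_isotope_peaks = 1)
  expect_equal(nrow(sp1), 16)
  expect_match(attr(sp, "title"), "EIELEDPLENMGAQMVK")
  expect_match(attr(sp, "title"), params$fragmentation)
})

test_that("CID and HCD differ only through parameters", {
  withr::local_seed(47)
  nm <- specsim:::param_names()
  v <- stats::setNames(rnorm(length(nm), 0, 0.3), nm)
  p_cid <- vector_to_params(v, fragmentation = "CID")
  p_hcd <- vector_to_params(v, fragmentation = "HCD")
  pep <- rand_peptide()
  expect_equal(predict_y_intensities(pep, p_cid),
               predict_y_intensities(pep, p_hcd))
})

test_that("delta shifts at a fixed offset cancel away from the termini", {
  withr::local_seed(53)
  params <- rand_params()
  v <- params_to_vector(params)
  v2 <- v
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v2[paste0("delta|", aas, "|1")] <- v2[paste0("delta|", aas, "|1")] + 0.9
  shifted <- vector_to_params(v2)
  pep <- "ACDEFGHILMNPQSTVWYAVK"  # no K/R except terminal; length 21
  n <- nchar(pep)
  # interior ratios: both windows fully inside the peptide
  interior <- 3:(n - 4)
  expect_equal(log_ratio(pep, interior, params),
               log_ratio(pep, interior, shifted), tolerance = 1e-10)
})
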