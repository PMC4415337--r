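test_that("noiseless spectra invert to the model's own log ratios", {
  withr::local_seed(61)
  params <- rand_params()
  for (rep in 1:10) {
    pep <- rand_peptide(6, 16)
    n <- nchar(pep)
    pk <- simulate_spectrum(pep, params, noise_off())
    obs <- extract_observed_ratios(pep, pk, tol = 0.5, floor = 0)
    expect_equal(obs$i, seq_len(n - 2))
    expect_equal(obs$r, log_ratio(pep, obs$i, params), tolerance = 1e-9)
  }
})

test_that("a missing y peak suppresses both ratios touching it", {
  withr::local_seed(67)
  params <- rand_params()
  pep <- "ACDEFGHIK"  # n = 9, ions y1..y8
  pk <- simulate_spectrum(pep, params, noise_off())
  ys <- generate_y_series(pep)
  drop3 <- pk[abs(pk$mz - ys$mz[3]) > 1e-6, , drop = FALSE]
  obs <- extract_observed_ratios(pep, drop3, tol = 0.5, floor = 0)
  expect_false(2 %in% obs$i)
  expect_false(3 %in% obs$i)
  expect_true(all(c(1, 4, 5, 6, 7) %in% obs$i))
})

test_that("nearest peak wins; distance ties go to the higher intensity", {
  pep <- "GK"  # y1 at 147.11280
  y1 <- unname(y_ion_mz("GK", 1))
  # two candidates inside tol, one nearer
  pk <- tibble::tibble(mz = c(y1 - 0.30, y1 + 0.10), intensity = c(50, 80))
  I <- specsim:::match_nearest_intensity(y1, pk$mz, pk$intensity, tol = 0.5)
  expect_equal(I, 80)
  # exact distance tie: higher intensity wins
  pk2 <- tibble::tibble(mz = c(y1 - 0.25, y1 + 0.25), intensity = c(90, 40))
  I2 <- specsim:::match_nearest_intensity(y1, pk2$mz, pk2$intensity, tol = 0.5)
  expect_equal(I2, 90)
  # exhaustive check against a direct loop on small random cases
  withr::local_seed(71)
  for (rep in 1:50) {
    q <- runif(1, 100, 110)
    mz <- sort(runif(5, 99, 111))
    int <- runif(5, 1, 100)
    got <- specsim:::match_nearest_intensity(q, mz, int, tol = 0.8)
    d <- abs(mz - q)
    cand <- which(d <= 0.8)
    want <- if (length(cand) == 0) NA_real_ else {
      dmin <- min(d[cand])
      best <- cand[d[cand] <= dmin + 1e-12]
      max(int[best])  # tie -> higher intensity
    }
    expect_equal(got, want)
  }
})

test_that("the design matrix reproduces noiseless responses exactly", {
  withr::local_seed(73)
  cfg <- synth_config(n_peptides = 40, seed = 74, noise = noise_off())
  gen <- generate_pairs(cfg)
  obs <- specsim:::collect_observations(gen$pairs, tol = 0.5, floor = 0.01)
  dm <- build_design_matrix(obs)
  theta <- params_to_vector(gen$params)[specsim:::free_param_names()]
  expect_equal(as.numeric(dm$X %*% theta), dm$y, tolerance = 1e-9)
})

test_that("G columns cancel on a homopolymer observation", {
  obs <- tibble::tibble(peptide = "AAAA", i = 1L, r = 0)
  dm <- build_design_matrix(obs)
  gcols <- grep("^G\\|", colnames(dm$X))
  expect_true(all(abs(as.numeric(dm$X[1, gcols])) < 1e-12))
})

test_that("empty observation sets are rejected", {
  expect_error(build_design_matrix(tibble::tibble(peptide = character(),
                                                  i = integer(), r = numeric())),
               "no ratio observations")
  expect_error(fit_parameters(tibble::tibble(peptide = character(),
                                             peaks = list())),
               "empty training set")
})

test_that("noiseless training recovers every free parameter", {
  cfg <- synth_config(n_peptides = 150, seed = 79, noise = noise_off())
  gen <- generate_pairs(cfg)
  fit <- fit_parameters(gen$pairs, ridge = 0)
  expect_lt(max(abs(free_params(fit$params) - free_params(gen$params))), 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
})

test_that("noisy training recovers parameters up to high correlation", {
  cfg <- synth_config(n_peptides = 400, seed = 83,
                      noise = noise_model(0.3, 0, 0L, 0, 0))
  gen <- generate_pairs(cfg)
  fit <- fit_parameters(gen$pairs, ridge = 0)
  expect_gt(cor(free_params(fit$params), free_params(gen$params)), 0.95)
  # residual RMS ~ sqrt(2) * sigma (difference of two iid log-normal exponents)
  expect_equal(fit$residual_rms, sqrt(2) * 0.3, tolerance = 0.1)
})

test_that("training is invariant to pair order and intensity scaling", {
  cfg <- synth_config(n_peptides = 60, seed = 89,
                      noise = noise_model(0.2, 0, 0L, 0, 0))
  gen <- generate_pairs(cfg)
  f1 <- fit_parameters(gen$pairs, ridge = 1e-6)
  perm <- withr::with_seed(1, sample(nrow(gen$pairs)))
  f2 <- fit_parameters(gen$pairs[perm, ], ridge = 1e-6)
  expect_equal(free_params(f2$params), free_params(f1$params), tolerance = 1e-8)
  scaled <- gen$pairs
  scaled$peaks <- lapply(scaled$peaks, function(pk) {
    pk$intensity <- pk$intensity * 37.5
    pk
  })
  f3 <- fit_parameters(scaled, ridge = 1e-6)
  expect_equal(free_params(f3$params), free_params(f1$params), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with ridge advice", {
  # two pairs cannot identify 130 free parameters
  cfg <- synth_config(n_peptides = 2, seed = 97, noise = noise_off())
  gen <- generate_pairs(cfg)
  expect_error(fit_parameters(gen$pairs, ridge = 0), "ridge")
  expect_silent(fit <- fit_parameters(gen$pairs, ridge = 1))
  expect_s3_class(fit, "spec_fit")
})

test_that("cross-validation is perfect on noiseless data and sane on noisy", {
  cfg <- synth_config(n_peptides = 200, seed = 101, noise = noise_off())
  gen <- generate_pairs(cfg)
  cv <- cross_validate(gen$pairs, k_folds = 4, ridge = 1e-6, seed = 5)
  expect_equal(cv$median_cc, 1.0, tolerance = 1e-6)
  expect_lt(cv$ratio_rms, 1e-4)
  expect_error(cross_validate(gen$pairs[1:3, ], k_folds = 5), "fewer pairs")
})

test_that("tidy and glance expose the fit in broom style", {
  cfg <- synth_config(n_peptides = 50, seed = 103, noise = noise_off())
  gen <- generate_pairs(cfg)
  fit <- fit_parameters(gen$pairs, ridge = 1e-4)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 156)
  expect_setequal(unique(td$component), c("delta", "nterm", "cterm", "G"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_pairs, 50)
})
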