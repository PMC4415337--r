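# Synthetic annotated spectra and PSM benchmarks from known ground-truth
# parameters. The generator starts from the model's own predictions and then
# injects noise, dropout, m/z jitter and junk peaks after prediction, so
# parameter-recovery tests exercise a genuine inverse problem rather than a
# shared code path.

#' Noise model for simulated spectra
#'
#' @param log_intensity_sigma SD of multiplicative log-normal noise applied to
#'   every y intensity (0 = none).
#' @param dropout_prob Probability that a y peak is absent entirely.
#' @param n_noise_peaks Number of uniform-m/z junk peaks added.
#' @param noise_intensity_scale Junk-peak intensity as a fraction of the base
#'   peak.
#' @param mz_jitter_sigma SD (Da) of Gaussian m/z jitter on y peaks.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(log_intensity_sigma = 0.3, dropout_prob = 0.1,
                        n_noise_peaks = 10L, noise_intensity_scale = 0.05,
                        mz_jitter_sigma = 0.01) {
  stopifnot(log_intensity_sigma >= 0, dropout_prob >= 0, dropout_prob < 1,
            n_noise_peaks >= 0, noise_intensity_scale >= 0, mz_jitter_sigma >= 0)
  structure(list(log_intensity_sigma = log_intensity_sigma,
                 dropout_prob = dropout_prob,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_intensity_scale = noise_intensity_scale,
                 mz_jitter_sigma = mz_jitter_sigma),
            class = "noise_model")
}

#' Noise-free noise model
#' @return A `noise_model` with every component switched off.
#' @export
noise_off <- function() noise_model(0, 0, 0L, 0, 0)

#' Synthetic-dataset configuration
#'
#' @param n_peptides Number of peptides (one spectrum each).
#' @param length_range Peptide length range, default 7..20 (typical tryptic
#'   lengths).
#' @param tryptic_end Force a C-terminal K/R.
#' @param seed RNG seed; the whole generator is byte-reproducible under it.
#' @param fragmentation "CID" or "HCD".
#' @param noise A [noise_model()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_peptides = 200L, length_range = c(7L, 20L),
                         tryptic_end = TRUE, seed = 1L,
                         fragmentation = c("CID", "HCD"),
                         noise = noise_model()) {
  fragmentation <- match.arg(fragmentation)
  stopifnot(n_peptides >= 1L, length(length_range) == 2L,
            length_range[1] >= 2L, length_range[2] >= length_range[1])
  structure(list(n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 tryptic_end = isTRUE(tryptic_end),
                 seed = as.integer(seed),
                 fragmentation = fragmentation, noise = noise),
            class = "synth_config")
}

#' Random tryptic peptide
#'
#' Uniform residues; when `tryptic_end` the last residue is K or R,
#' mimicking tryptic digestion. Uses the current RNG state.
#'
#' @param length_range Integer range of lengths (inclusive).
#' @param tryptic_end Force a C-terminal K/R.
#' @return A peptide sequence string.
#' @export
random_tryptic_peptide <- function(length_range = c(7L, 20L), tryptic_end = TRUE) {
  len <- if (length_range[1] == length_range[2]) length_range[1] else {
    sample(seq(length_range[1], length_range[2]), 1L)
  }
  res <- sample(AMINO_ACIDS, len, replace = TRUE)
  if (tryptic_end) res[len] <- sample(c("K", "R"), 1L)
  paste(res, collapse = "")
}

#' Sample ground-truth model parameters
#'
#' Deltas and terminus terms are drawn iid N(0, 0.5), G terms N(0, 1), then
#' projected onto the canonical gauge so the truth lies in the trainer's
#' identifiable set. Uses the current RNG state.
#'
#' @param fragmentation "CID" or "HCD".
#' @return A `spec_params` object in canonical gauge, beta = 1.
#' @export
sample_true_params <- function(fragmentation = "CID") {
  nm <- param_names()
  v <- stats::setNames(stats::rnorm(length(nm), 0, 0.5), nm)
  gcols <- grep("^G\\|", nm)
  v[gcols] <- stats::rnorm(length(gcols), 0, 1)
  apply_gauge(vector_to_params(v, fragmentation = fragmentation, beta = 1))
}

#' Simulate an experimental spectrum
#'
#' Starts from the model prediction for the peptide, multiplies each y
#' intensity by log-normal noise, drops peaks at `dropout_prob`, jitters m/z,
#' adds uniform-m/z junk peaks at `noise_intensity_scale` times the base
#' peak, and renormalises the base peak to 100. With all noise off the output
#' equals [predict_spectrum()] exactly.
#'
#' @param peptide Peptide sequence.
#' @param params A `spec_params` object.
#' @param noise A [noise_model()].
#' @param n_isotope_peaks Isotope peaks per ion (1 = monoisotopic only, the
#'   default for training data).
#' @return A peak tibble with `mz`, `intensity`, sorted by m/z.
#' @export
simulate_spectrum <- function(peptide, params, noise = noise_model(),
                              n_isotope_peaks = 1L) {
  pk <- predict_spectrum(peptide, params, n_isotope_peaks = n_isotope_peaks)
  mz <- pk$mz
  inten <- pk$intensity
  k <- length(mz)
  if (noise$log_intensity_sigma > 0) {
    inten <- inten * stats::rlnorm(k, 0, noise$log_intensity_sigma)
  }
  if (noise$dropout_prob > 0) {
    keep <- stats::runif(k) >= noise$dropout_prob
    mz <- mz[keep]; inten <- inten[keep]
  }
  if (noise$mz_jitter_sigma > 0 && length(mz) > 0L) {
    mz <- mz + stats::rnorm(length(mz), 0, noise$mz_jitter_sigma)
  }
  if (noise$n_noise_peaks > 0L) {
    base <- if (length(inten)) max(inten) else 100
    lo <- 100
    hi <- max(c(mz, 100)) + 100
    mz <- c(mz, stats::runif(noise$n_noise_peaks, lo, hi))
    inten <- c(inten, rep(noise$noise_intensity_scale * base, noise$n_noise_peaks))
  }
  out <- tibble::tibble(mz = mz, intensity = inten)
  out <- out[order(out$mz), , drop = FALSE]
  if (nrow(out) > 0L) out$intensity <- out$intensity / max(out$intensity) * 100
  out
}

# n unique random peptides (resampling on collision).
unique_peptides <- function(n, length_range, tryptic_end) {
  seen <- character(0)
  while (length(seen) < n) {
    p <- random_tryptic_peptide(length_range, tryptic_end)
    if (!p %in% seen) seen <- c(seen, p)
  }
  seen
}

#' Generate annotated training pairs in memory
#'
#' @param config A [synth_config()].
#' @param params Optional ground-truth `spec_params`; sampled if NULL.
#' @return A list: `pairs` (tibble `title`, `peptide`, `fragmentation`,
#'   `peaks`), `params` (the truth used).
#' @export
generate_pairs <- function(config, params = NULL) {
  withr::with_seed(config$seed, {
    if (is.null(params)) params <- sample_true_params(config$fragmentation)
    peptides <- unique_peptides(config$n_peptides, config$length_range,
                                config$tryptic_end)
    peaks <- purrr::map(peptides, function(p) {
      simulate_spectrum(p, params, noise = config$noise)
    })
    pairs <- tibble::tibble(
      title = sprintf("synth_%05d", seq_along(peptides)),
      peptide = peptides,
      fragmentation = config$fragmentation,
      peaks = peaks
    )
    list(pairs = pairs, params = params)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `spectra.mgf`, `annotations.tsv` (spectrum_title, peptide,
#' fragmentation) and `true_params.json` to `out_dir`; the files are directly
#' reloadable by [load_training_pairs()] and byte-identical across reruns with
#' the same seed.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the three paths plus the in-memory `pairs`
#'   and `params`.
#' @export
generate_dataset <- function(config, out_dir) {
  gen <- generate_pairs(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spectra <- tibble::tibble(
    title = gen$pairs$title,
    precursor_mz = vapply(gen$pairs$peptide, function(p) {
      (neutral_mass(p) + 2 * MASS_PROTON) / 2
    }, numeric(1)),
    precursor_charge = 2L,
    peaks = gen$pairs$peaks
  )
  mgf_path <- file.path(out_dir, "spectra.mgf")
  ann_path <- file.path(out_dir, "annotations.tsv")
  par_path <- file.path(out_dir, "true_params.json")
  write_mgf(spectra, mgf_path)
  readr::write_tsv(tibble::tibble(spectrum_title = gen$pairs$title,
                                  peptide = gen$pairs$peptide,
                                  fragmentation = gen$pairs$fragmentation),
                   ann_path)
  write_params_json(gen$params, par_path)
  invisible(list(mgf = mgf_path, annotations = ann_path, params_json = par_path,
                 pairs = gen$pairs, params = gen$params))
}

# Shuffle all but the C-terminal residue (preserves tryptic character).
shuffle_decoy <- function(peptide) {
  res <- peptide_residues(peptide)
  n <- length(res)
  if (n > 2L) res[seq_len(n - 1L)] <- sample(res[seq_len(n - 1L)])
  paste(res, collapse = "")
}

#' Generate a synthetic PSM re-ranking benchmark
#'
#' Builds a PSM table with an exact decoy allocation plus the matching
#' spectra. Target PSMs carry their own peptide label; decoy PSMs carry a
#' shuffled-peptide label against the original peptide's spectrum, so the
#' label is unrelated to the spectrum. `cc_signal` in [0, 1] is the
#' probability that a target's spectrum really was generated from its own
#' peptide; at 0 every spectrum is unrelated to its label and the predicted-
#' spectrum CC carries no information. Engine scores are drawn from
#' overlapping target/decoy normals (xcorr-like: N(3, 1) vs N(1.5, 1)).
#'
#' @param config A [synth_config()]; `n_peptides` is the number of PSMs.
#' @param decoy_fraction Fraction of PSMs labelled decoy, in (0, 1).
#' @param cc_signal Probability in [0, 1] that a target spectrum matches its
#'   peptide label.
#' @param engine "SEQUEST" or "XTANDEM".
#' @return A list: `psms` (tibble spectrum_id, peptide, is_decoy, engine,
#'   xcorr, delta_cn, s_t), `spectra` (collection tibble), `params` (truth).
#' @export
generate_psm_benchmark <- function(config, decoy_fraction = 0.5, cc_signal = 1,
                                   engine = c("SEQUEST", "XTANDEM")) {
  engine <- match.arg(engine)
  stopifnot(decoy_fraction > 0, decoy_fraction < 1,
            cc_signal >= 0, cc_signal <= 1)
  withr::with_seed(config$seed, {
    params <- sample_true_params(config$fragmentation)
    n <- config$n_peptides
    n_decoy <- round(decoy_fraction * n)
    is_decoy <- sample(rep(c(TRUE, FALSE), c(n_decoy, n - n_decoy)))
    base_pep <- unique_peptides(n, config$length_range, config$tryptic_end)
    label <- character(n)
    carrier <- character(n)
    for (j in seq_len(n)) {
      if (is_decoy[j]) {
        label[j] <- shuffle_decoy(base_pep[j])
        carrier[j] <- base_pep[j]
      } else {
        label[j] <- base_pep[j]
        carrier[j] <- if (stats::runif(1) < cc_signal) base_pep[j] else
          shuffle_decoy(base_pep[j])
      }
    }
    peaks <- purrr::map(carrier, function(p) {
      simulate_spectrum(p, params, noise = config$noise)
    })
    titles <- sprintf("bench_%05d", seq_len(n))
    mu_x <- ifelse(is_decoy, 1.5, 3.0)
    xcorr <- stats::rnorm(n, mu_x, 1.0)
    delta_cn <- pmax(0, stats::rnorm(n, ifelse(is_decoy, 0.08, 0.25), 0.06))
    s_t <- pmax(0, stats::rnorm(n, ifelse(is_decoy, 15, 30), 8))
    psms <- tibble::tibble(
      spectrum_id = titles, peptide = label, is_decoy = is_decoy,
      engine = engine, xcorr = xcorr, delta_cn = delta_cn, s_t = s_t
    )
    spectra <- tibble::tibble(
      title = titles,
      precursor_mz = vapply(carrier, function(p) {
        (neutral_mass(p) + 2 * MASS_PROTON) / 2
      }, numeric(1)),
      precursor_charge = 2L,
      peaks = peaks
    )
    list(psms = psms, spectra = spectra, params = params)
  })
}
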