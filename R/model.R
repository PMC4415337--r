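# The adjacent-y-ion ratio model.
#
# Under the mobile-proton picture, the log intensity ratio of two neighbouring
# y ions is
#
#   ln(y_i / y_{i+1}) = beta * (E_i - E_{i+1}) + G(A_i, class(i))
#                                              - G(A_{i+1}, class(i+1))
#
# where E_i is the cleavage energy at the y_i site, assembled from short-range
# residue-offset terms plus terminus terms, and G(A, class) = ln(F(A) +
# D(A, site)) combines the b/y and diketopiperazine pathway probabilities of
# the residue A immediately N-terminal to the cleavage site. Remote residues
# affect E_i and E_{i+1} almost equally and cancel in the difference, which is
# what makes the ratio model closed-form.

# Names of the parameters contributing to E_i for a residue vector `res`.
# The y_i cleavage site sits between positions p = n - i and p + 1; offsets d
# are counted from the N-terminal flanking residue p. A residue contributes
# exactly one delta term: the K/R window (-8..5) if it is K or R, the core
# window (-2..1) otherwise. Window positions outside the peptide are omitted.
energy_terms <- function(res, n, i) {
  p <- n - i
  terms <- character(0)
  for (d in KR_OFFSETS) {
    pos <- p + d
    if (pos < 1L || pos > n) next
    x <- res[[pos]]
    if (x == "K" || x == "R" || (d >= -2L && d <= 1L)) {
      terms <- c(terms, paste0("delta|", x, "|", d))
    }
  }
  d_C <- i  # distance from the flank residue p to the C terminus, n - p
  if (d_C <= 10L) terms <- c(terms, paste0("cterm|", d_C))
  d_N <- p - 1L
  s <- max(1L, as.integer(ceiling(5 * d_N / n)))
  c(terms, paste0("nterm|", s))
}

# Site class for the G term of y_i: the diketopiperazine pathway only matters
# where the two N-terminal residues can cyclise, i.e. at the y_{n-1} site.
site_class <- function(i, n) {
  ifelse(i == n - 1L, "penultimate", "interior")
}

g_term_name <- function(res, n, i) {
  paste0("G|", res[[n - i]], "|", site_class(i, n))
}

# Vectorised internals working on a pre-flattened parameter vector v.
all_cleavage_energies <- function(res, n, v) {
  vapply(seq_len(n - 1L), function(i) sum(v[energy_terms(res, n, i)]),
         numeric(1))
}

all_log_ratios <- function(res, n, v, beta) {
  E <- all_cleavage_energies(res, n, v)
  g <- v[vapply(seq_len(n - 1L), function(i) g_term_name(res, n, i),
                character(1))]
  idx <- seq_len(n - 2L)
  unname(beta * (E[idx] - E[idx + 1L]) + g[idx] - g[idx + 1L])
}

#' Cleavage energy at a y-ion site
#'
#' Sums the residue-offset terms in the short-range window around the cleavage
#' site of y_i, plus the C- and N-terminus terms. Ordinary residues are felt
#' over offsets -2..1; K and R, which sequester the mobile proton, over
#' -8..5; the C terminus contributes within distance 10 and the N terminus
#' through one of five distance levels s = max(1, ceiling(5 d_N / n)).
#'
#' @param peptide Peptide sequence of length n.
#' @param i Fragment index/indices, 1 <= i <= n - 1 (vectorised).
#' @param params A `spec_params` object.
#' @return Numeric vector of energies (arbitrary units; scale set by beta).
#' @export
cleavage_energy <- function(peptide, i, params) {
  res <- peptide_residues(peptide)
  n <- length(res)
  if (any(i < 1L | i > n - 1L)) {
    stop("fragment index out of range: i must lie in 1..", n - 1L, call. = FALSE)
  }
  v <- params_to_vector(params)
  vapply(i, function(ii) sum(v[energy_terms(res, n, ii)]), numeric(1))
}

#' Predicted log intensity ratio of adjacent y ions
#'
#' Evaluates ln(y_i / y_{i+1}) under the model: the beta-scaled cleavage
#' energy difference plus the pathway log-probability difference of the two
#' cleavage-site residues.
#'
#' @inheritParams cleavage_energy
#' @param i Fragment index/indices with 1 <= i <= n - 2 (both ions must exist).
#' @return Numeric vector of log ratios.
#' @export
log_ratio <- function(peptide, i, params) {
  res <- peptide_residues(peptide)
  n <- length(res)
  if (any(i < 1L | i > n - 2L)) {
    stop("ratio index out of range: i must lie in 1..", n - 2L, call. = FALSE)
  }
  v <- params_to_vector(params)
  all_log_ratios(res, n, v, params$beta)[i]
}

#' Predicted relative y-ion intensities
#'
#' Reconstructs the whole y series from the chain of adjacent ratios:
#' ln I(y_{n-1}) is anchored at 0 and each ln I(y_i) = ln I(y_{i+1}) +
#' log_ratio(i); the result is rescaled so the largest intensity is 100. The
#' anchor choice is immaterial after rescaling.
#'
#' @inheritParams cleavage_energy
#' @return Named numeric vector of length n - 1 (names `1`..`n-1`), all > 0,
#'   maximum 100.
#' @export
predict_y_intensities <- function(peptide, params) {
  res <- peptide_residues(peptide)
  n <- length(res)
  if (n == 2L) return(stats::setNames(100, "1"))
  lr <- all_log_ratios(res, n, params_to_vector(params), params$beta)
  logI <- rev(cumsum(c(0, rev(lr))))  # logI[i] = sum of lr[i..n-2]
  I <- exp(logI - max(logI)) * 100
  stats::setNames(I, as.character(seq_len(n - 1L)))
}

#' Isotope envelope of a fragment
#'
#' Averagine-style Poisson approximation: the chance of carrying k heavy
#' isotopes is Poisson with rate lambda = lambda_per_da * neutral mass, so the
#' envelope relative to the monoisotopic peak is lambda^k / k!.
#'
#' @param neutral_mass Neutral fragment mass in Da (> 0).
#' @param n_peaks Number of isotope peaks, k = 0..n_peaks-1.
#' @param lambda_per_da Poisson rate per Da; default 5.5e-4 approximates the
#'   13C abundance times the average carbon count per Da.
#' @return Numeric vector of n_peaks relative intensities, entry 1 (the
#'   monoisotopic peak) equal to 1.
#' @export
isotope_envelope <- function(neutral_mass, n_peaks = 3L, lambda_per_da = 5.5e-4) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1L || neutral_mass <= 0) {
    stop("neutral_mass must be a positive number", call. = FALSE)
  }
  stopifnot(n_peaks >= 1L, lambda_per_da > 0)
  lambda <- lambda_per_da * neutral_mass
  k <- seq_len(n_peaks) - 1L
  lambda^k / factorial(k)
}

#' Predict a theoretical spectrum
#'
#' Combines the y-ion m/z series, the ratio-chain intensities, and per-ion
#' isotope envelopes into a single peak list. Isotope peak k of ion y_i sits
#' at mz(y_i) + k * 1.00335 / charge. Peaks closer than 1e-4 Da are merged by
#' summing; the final list is strictly sorted by m/z and rescaled so the base
#' peak is 100.
#'
#' @inheritParams cleavage_energy
#' @param n_isotope_peaks Isotope peaks per ion (1 = monoisotopic only).
#' @param lambda_per_da See [isotope_envelope()].
#' @return A tibble of peaks with columns `mz`, `intensity`, `index` (y-ion
#'   index) and `isotope` (0 = monoisotopic), carrying attributes `title`
#'   (peptide and fragmentation type), `precursor_mz` and `precursor_charge`
#'   (doubly charged precursor).
#' @export
predict_spectrum <- function(peptide, params, n_isotope_peaks = 3L,
                             lambda_per_da = 5.5e-4) {
  res <- peptide_residues(peptide)
  n <- length(res)
  ys <- generate_y_series(peptide)
  I <- predict_y_intensities(peptide, params)
  frag_mass <- ys$mz - MASS_PROTON  # neutral y fragment mass (charge 1)
  ks <- seq_len(n_isotope_peaks) - 1L
  # envelope value for ion i, isotope k: lambda_i^k / k!
  lambda <- lambda_per_da * frag_mass
  env <- outer(lambda, ks, function(l, k) l^k / factorial(k))
  idx <- rep(seq_len(n - 1L), each = n_isotope_peaks)
  iso <- rep(ks, times = n - 1L)
  peaks <- tibble::tibble(
    mz = ys$mz[idx] + iso * MASS_ISOTOPE_SPACING,
    intensity = unname(I[idx]) * env[cbind(idx, iso + 1L)],
    index = idx,
    isotope = iso
  )
  peaks <- merge_peaks(peaks)
  peaks$intensity <- peaks$intensity / max(peaks$intensity) * 100
  attr(peaks, "title") <- paste0(peptide, " ", params$fragmentation, " 2+")
  attr(peaks, "precursor_mz") <- (neutral_mass(peptide) + 2 * MASS_PROTON) / 2
  attr(peaks, "precursor_charge") <- 2L
  peaks
}

# Sort by mz and merge peaks closer than `tol` Da by summing intensities;
# annotation columns keep the first contributor's values.
merge_peaks <- function(peaks, tol = 1e-4) {
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  if (nrow(peaks) > 1L) {
    grp <- cumsum(c(TRUE, diff(peaks$mz) > tol))
    if (any(duplicated(grp))) {
      inten <- tapply(peaks$intensity, grp, sum)
      first <- !duplicated(grp)
      peaks <- peaks[first, , drop = FALSE]
      peaks$intensity <- as.numeric(inten)
    }
  }
  peaks
}

#' Predict spectra for many peptides
#'
#' @param peptides Character vector of peptide sequences.
#' @param params A `spec_params` object.
#' @param ... Passed to [predict_spectrum()].
#' @return A spectra collection tibble (one row per peptide) with columns
#'   `title`, `precursor_mz`, `precursor_charge`, `peaks` (list of peak
#'   tibbles), ready for [write_mgf()].
#' @export
predict_spectra <- function(peptides, params, ...) {
  rows <- purrr::map(peptides, function(p) {
    pk <- predict_spectrum(p, params, ...)
    tibble::tibble(
      title = attr(pk, "title"),
      precursor_mz = attr(pk, "precursor_mz"),
      precursor_charge = attr(pk, "precursor_charge"),
      peaks = list(pk[, c("mz", "intensity")])
    )
  })
  dplyr::bind_rows(rows)
}
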