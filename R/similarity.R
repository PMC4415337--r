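# Spectrum comparison: peak matching on the y-ion grid, Pearson CC, the
# square-root spectral similarity, and shared-peak counting.

# Candidate (theoretical, experimental) pairs within tol, ordered by distance
# (ties: higher experimental intensity, then lower theoretical index), then
# assigned greedily one-to-one. Shared by match_peaks and shared_peak_count.
greedy_assignment <- function(mz_t, mz_e, int_e, tol) {
  if (length(mz_t) == 0L || length(mz_e) == 0L) {
    return(tibble::tibble(t = integer(), e = integer()))
  }
  cand <- purrr::map_dfr(seq_along(mz_t), function(j) {
    d <- abs(mz_e - mz_t[j])
    k <- which(d <= tol)
    tibble::tibble(t = rep(j, length(k)), e = k, dist = d[k])
  })
  if (nrow(cand) == 0L) return(tibble::tibble(t = integer(), e = integer()))
  cand <- cand[order(cand$dist, -int_e[cand$e], cand$t), , drop = FALSE]
  used_t <- logical(length(mz_t)); used_e <- logical(length(mz_e))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    tj <- cand$t[r]; ek <- cand$e[r]
    if (!used_t[tj] && !used_e[ek]) {
      used_t[tj] <- TRUE; used_e[ek] <- TRUE; keep[r] <- TRUE
    }
  }
  cand[keep, c("t", "e"), drop = FALSE]
}

#' Match experimental peaks onto the theoretical y-ion grid
#'
#' Each theoretical monoisotopic y peak is paired with at most one
#' experimental peak within `tol` (greedy nearest-first; each experimental
#' peak is used at most once). Unmatched ions carry experimental intensity 0.
#'
#' @param theoretical Peak tibble with `mz`, `intensity`; if an `isotope`
#'   column is present only rows with `isotope == 0` are used.
#' @param experimental Peak tibble with `mz`, `intensity`.
#' @param tol Matching tolerance in Da (> 0).
#' @return A tibble aligned with the theoretical grid: `index`, `mz`, `v_t`,
#'   `v_e`, `matched`.
#' @export
match_peaks <- function(theoretical, experimental, tol = 0.5) {
  stopifnot(tol > 0)
  th <- theoretical
  if ("isotope" %in% names(th)) th <- th[th$isotope == 0L, , drop = FALSE]
  v_e <- numeric(nrow(th))
  asg <- greedy_assignment(th$mz, experimental$mz, experimental$intensity, tol)
  v_e[asg$t] <- experimental$intensity[asg$e]
  tibble::tibble(
    index = if ("index" %in% names(th)) th$index else seq_len(nrow(th)),
    mz = th$mz,
    v_t = th$intensity,
    v_e = v_e,
    matched = seq_len(nrow(th)) %in% asg$t
  )
}

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation between two equal-length intensity vectors.
#' If either vector is constant the correlation is undefined; 0 is returned
#' with attribute `degenerate = TRUE` so downstream score arithmetic stays
#' finite.
#'
#' @param v1,v2 Numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1].
#' @export
pearson_cc <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("length mismatch: ", length(v1), " vs ", length(v2), call. = FALSE)
  }
  if (length(v1) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(v1, v2)
}

#' Square-root spectral similarity
#'
#' Intensities are accumulated into m/z bins of width `bin_width` (bin index
#' floor(mz / bin_width)) and compared by
#' sum(sqrt(I1 * I2)) / sqrt(sum(I1) * sum(I2)), the square-root dot product.
#' By Cauchy-Schwarz the value lies in [0, 1], reaching 1 exactly for
#' proportional binned spectra.
#'
#' @param s1,s2 Peak tibbles with `mz`, `intensity`; must be non-empty.
#' @param bin_width Bin width in Da (default 1.0, ion-trap scale).
#' @return Similarity in [0, 1].
#' @export
spectral_similarity <- function(s1, s2, bin_width = 1.0) {
  stopifnot(bin_width > 0)
  if (nrow(s1) == 0L || nrow(s2) == 0L) {
    stop("cannot compare an empty spectrum", call. = FALSE)
  }
  bin_sums <- function(s) {
    b <- floor(s$mz / bin_width)
    vapply(split(s$intensity, b), sum, numeric(1))
  }
  b1 <- bin_sums(s1); b2 <- bin_sums(s2)
  shared <- intersect(names(b1), names(b2))
  num <- sum(sqrt(b1[shared] * b2[shared]))
  num / sqrt(sum(b1) * sum(b2))
}

#' Shared-peak count
#'
#' Size of the greedy one-to-one matching (nearest pairs first) between two
#' peak lists at tolerance `tol`.
#'
#' @param s1,s2 Peak tibbles with `mz`, `intensity`.
#' @param tol Tolerance in Da (> 0).
#' @return Non-negative integer.
#' @export
shared_peak_count <- function(s1, s2, tol = 0.5) {
  stopifnot(tol > 0)
  nrow(greedy_assignment(s1$mz, s2$mz, s2$intensity, tol))
}
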