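# PSM re-ranking with predicted-spectrum agreement, and decoy-count FDR.

#' SEQUEST combined re-ranking score
#'
#' Xcorr + 5 * deltaCn + 5 * CC: the engine's cross-correlation and runner-up
#' gap combined with the Pearson CC against the predicted spectrum.
#'
#' @param xcorr,delta_cn,cc Numeric vectors (recycled), all finite.
#' @return Numeric vector of scores.
#' @export
sequest_combined_score <- function(xcorr, delta_cn, cc) {
  if (!all(is.finite(xcorr), is.finite(delta_cn), is.finite(cc))) {
    stop("non-finite input to sequest_combined_score", call. = FALSE)
  }
  xcorr + 5 * delta_cn + 5 * cc
}

#' X!Tandem combined re-ranking score
#'
#' #SharedPeaks * sqrt(S_T) * CC + S_T, where S_T is the X!Tandem score.
#'
#' @param shared_peaks Number of peaks shared by experimental and predicted
#'   spectrum.
#' @param s_t X!Tandem score, >= 0.
#' @param cc Pearson CC against the predicted spectrum.
#' @return Numeric vector of scores.
#' @export
xtandem_combined_score <- function(shared_peaks, s_t, cc) {
  if (any(!is.finite(s_t)) || any(s_t < 0)) {
    stop("s_t must be finite and >= 0", call. = FALSE)
  }
  shared_peaks * sqrt(s_t) * cc + s_t
}

# Engine-only baseline used for FDR comparison: the combined score with the
# CC term removed, so a constant CC provably cannot change accepted counts.
engine_baseline_score <- function(psms) {
  ifelse(psms$engine == "SEQUEST",
         psms$xcorr + 5 * psms$delta_cn,
         psms$s_t)
}

#' Decoy-count FDR curve
#'
#' Records are sorted by decreasing score (ties: decoys first, the
#' conservative order) and the threshold swept: at each rank the decoy count
#' proxies the false positives and the accepted-target count plays TP + FP,
#' giving FDR = decoys / targets (0 when no target is accepted yet). A
#' cumulative minimum from the strict end yields the monotone q column.
#'
#' @param psms PSM tibble with at least `is_decoy` (logical or 0/1) and the
#'   score column.
#' @param score_field Name of the score column to sweep (default
#'   `"combined_score"`).
#' @return A tibble of class `fdr_curve`: `threshold`, `targets`, `decoys`,
#'   `fdr` (raw), `q` (monotonised).
#' @export
compute_fdr_curve <- function(psms, score_field = "combined_score") {
  if (!score_field %in% names(psms)) {
    stop("score field ", sQuote(score_field), " not found", call. = FALSE)
  }
  score <- psms[[score_field]]
  dec <- as.logical(psms$is_decoy)
  if (!any(dec)) stop("no decoy records: decoy-count FDR needs is_decoy = 1 rows", call. = FALSE)
  if (all(dec)) stop("no target records", call. = FALSE)
  ord <- order(-score, -as.integer(dec))
  dec <- dec[ord]
  targets <- cumsum(!dec)
  decoys <- cumsum(dec)
  fdr <- ifelse(targets == 0L, 0, decoys / targets)
  curve <- tibble::tibble(
    threshold = score[ord],
    targets = targets,
    decoys = decoys,
    fdr = fdr,
    q = rev(cummin(rev(fdr)))
  )
  class(curve) <- c("fdr_curve", class(curve))
  curve
}

#' Accepted PSMs at an FDR threshold
#'
#' @param curve An `fdr_curve` from [compute_fdr_curve()].
#' @param q FDR threshold in (0, 1).
#' @return Largest accepted-target count whose monotonised FDR is <= q
#'   (0 if none qualifies).
#' @export
psms_at_fdr <- function(curve, q) {
  stopifnot(q > 0, q < 1)
  ok <- curve$targets[curve$q <= q]
  if (length(ok) == 0L) 0L else max(ok)
}

#' Re-rank PSMs with predicted-spectrum agreement
#'
#' For every PSM the peptide's theoretical spectrum is predicted, the Pearson
#' CC against the experimental spectrum computed (plus shared peaks for
#' X!Tandem records), and the engine-specific combined score filled in.
#' PSMs whose `spectrum_id` resolves to no spectrum are dropped with one
#' warning giving the count.
#'
#' @param psms PSM tibble (see [read_psm_table()] for the schema).
#' @param params A `spec_params` object.
#' @param spectra Spectra collection tibble (from [read_mgf()]); `title` must
#'   match `spectrum_id`.
#' @param tol Peak-matching tolerance in Da.
#' @return The PSM tibble with `cc`, `shared_peaks`, `engine_score` and
#'   `combined_score` columns, sorted by decreasing combined score.
#' @export
rerank_psms <- function(psms, params, spectra, tol = 0.5) {
  idx <- match(psms$spectrum_id, spectra$title)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " PSM(s) with unresolvable spectrum_id skipped",
            call. = FALSE)
    psms <- psms[!missing, , drop = FALSE]
    idx <- idx[!missing]
  }
  if (nrow(psms) == 0L) stop("no PSMs with resolvable spectra", call. = FALSE)
  scored <- purrr::map_dfr(seq_len(nrow(psms)), function(r) {
    pep <- psms$peptide[[r]]
    exp_peaks <- spectra$peaks[[idx[r]]]
    theo <- generate_y_series(pep)
    theo$intensity <- unname(predict_y_intensities(pep, params))
    mv <- match_peaks(theo, exp_peaks, tol = tol)
    cc <- as.numeric(pearson_cc(mv$v_t, mv$v_e))
    sp <- if (psms$engine[[r]] == "XTANDEM") {
      shared_peak_count(theo[, c("mz", "intensity")], exp_peaks, tol = tol)
    } else NA_integer_
    tibble::tibble(cc = cc, shared_peaks = sp)
  })
  out <- dplyr::bind_cols(psms[setdiff(names(psms), c("cc", "shared_peaks",
                                                      "engine_score",
                                                      "combined_score"))],
                          scored)
  out$engine_score <- engine_baseline_score(out)
  out$combined_score <- NA_real_
  sq <- out$engine == "SEQUEST"
  if (any(sq)) {
    out$combined_score[sq] <-
      sequest_combined_score(out$xcorr[sq], out$delta_cn[sq], out$cc[sq])
  }
  if (any(!sq)) {
    out$combined_score[!sq] <-
      xtandem_combined_score(out$shared_peaks[!sq], out$s_t[!sq], out$cc[!sq])
  }
  out[order(-out$combined_score), , drop = FALSE]
}
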