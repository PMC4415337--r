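# Parameter training: ridge-regularised least squares on observed adjacent
# y-ion log ratios. The model is linear in the parameter vector once beta is
# absorbed into the deltas, so one sparse design matrix plus a QR solve is the
# whole estimator.

#' Extract observed adjacent-ratio responses from an annotated spectrum
#'
#' For each theoretical monoisotopic y m/z the nearest experimental peak
#' within `tol` is taken (tie on distance: higher intensity wins). The log
#' ratio r = ln(I_i / I_{i+1}) is emitted only where both matched intensities
#' reach `floor` times the base-peak intensity, so near-noise peaks never
#' enter the regression.
#'
#' @param peptide Peptide sequence.
#' @param peaks Experimental peak tibble/data frame with `mz`, `intensity`.
#' @param tol Matching tolerance in Da (> 0).
#' @param floor Detection floor as a fraction of the base peak.
#' @return A tibble with columns `i`, `r`, `weight`; zero rows allowed.
#' @export
extract_observed_ratios <- function(peptide, peaks, tol = 0.5, floor = 0.01) {
  stopifnot(tol > 0, floor >= 0)
  res <- peptide_residues(peptide)
  n <- length(res)
  theo <- y_ion_mz(peptide, seq_len(n - 1L))
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(i = integer(), r = numeric(), weight = numeric()))
  }
  I <- match_nearest_intensity(theo, peaks$mz, peaks$intensity, tol)
  base <- max(peaks$intensity)
  ok <- !is.na(I) & I >= floor * base
  idx <- which(ok[-length(ok)] & ok[-1L])  # i where both y_i and y_{i+1} pass
  tibble::tibble(i = idx, r = log(I[idx] / I[idx + 1L]), weight = rep(1, length(idx)))
}

# Nearest-peak intensity lookup against a sorted peak list; NA when nothing
# lies within tol. Distance ties go to the more intense peak.
match_nearest_intensity <- function(query, mz, intensity, tol) {
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  m <- length(mz)
  j <- findInterval(query, mz)
  jl <- pmax(j, 1L); jr <- pmin(j + 1L, m)
  dl <- abs(query - mz[jl]); dr <- abs(mz[jr] - query)
  dl[j < 1L] <- Inf
  dr[j >= m] <- Inf
  pick <- ifelse(dl < dr, jl,
          ifelse(dr < dl, jr,
                 ifelse(intensity[jl] >= intensity[jr], jl, jr)))
  d <- pmin(dl, dr)
  out <- intensity[pick]
  out[d > tol] <- NA_real_
  out
}

#' Build the gauge-fixed regression design
#'
#' One row per ratio observation; one column per free parameter. The entry
#' for a delta/terminus parameter is its count in E_i minus its count in
#' E_{i+1}; the two G columns of the flanking residues get +1 and -1. The
#' sum-to-zero constraint at each core offset is folded in by expressing the
#' reference residue's delta through the other nineteen.
#'
#' @param observations A tibble with columns `peptide`, `i`, `r` (one row per
#'   ratio observation), as produced by mapping [extract_observed_ratios()]
#'   over training pairs.
#' @return A list with sparse matrix `X` (columns named by free parameters)
#'   and response vector `y`.
#' @export
build_design_matrix <- function(observations) {
  if (nrow(observations) == 0L) {
    stop("no ratio observations: cannot build a design matrix", call. = FALSE)
  }
  full <- param_names()
  lookup <- stats::setNames(seq_along(full), full)
  nr <- nrow(observations)
  rows <- vector("list", nr); cols <- vector("list", nr); vals <- vector("list", nr)
  res_cache <- list()
  for (r in seq_len(nr)) {
    pep <- observations$peptide[[r]]
    res <- res_cache[[pep]]
    if (is.null(res)) {
      res <- peptide_residues(pep)
      res_cache[[pep]] <- res
    }
    n <- length(res)
    i <- observations$i[[r]]
    plus <- c(energy_terms(res, n, i), g_term_name(res, n, i))
    minus <- c(energy_terms(res, n, i + 1L), g_term_name(res, n, i + 1L))
    rows[[r]] <- rep.int(r, length(plus) + length(minus))
    cols[[r]] <- unname(c(lookup[plus], lookup[minus]))
    vals[[r]] <- c(rep.int(1, length(plus)), rep.int(-1, length(minus)))
  }
  X_full <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                                 x = unlist(vals),
                                 dims = c(nr, length(full)),
                                 dimnames = list(NULL, full))
  Tm <- gauge_expansion_matrix()
  list(X = X_full %*% Tm, y = observations$r)
}

collect_observations <- function(pairs, tol, floor) {
  obs <- purrr::map2_dfr(pairs$peptide, pairs$peaks, function(pep, pk) {
    o <- extract_observed_ratios(pep, pk, tol = tol, floor = floor)
    o$peptide <- rep(pep, nrow(o))
    o
  })
  obs
}

#' Fit model parameters from annotated peptide-spectrum pairs
#'
#' Ridge-regularised least squares on the observed log ratios, with the gauge
#' fixed as described in [apply_gauge()]: beta = 1 (the energy scale is
#' absorbed into the deltas), one reference G level pinned, N-terminus level 1
#' pinned, and sum-to-zero deltas at each core offset.
#'
#' @param pairs A tibble of training pairs with columns `peptide`, `peaks`
#'   (list of peak tibbles) and optionally `fragmentation` (must be uniform).
#' @param ridge Ridge penalty lambda >= 0 on the free parameters.
#' @param tol,floor See [extract_observed_ratios()].
#' @return An object of class `spec_fit`: a list with elements `params`
#'   (a [spec_params] object), `residual_rms`, `n_obs`, `n_pairs`, `ridge`,
#'   `tol`, `floor`.
#' @export
fit_parameters <- function(pairs, ridge = 0, tol = 0.5, floor = 0.01) {
  stopifnot(ridge >= 0)
  if (nrow(pairs) == 0L) stop("empty training set", call. = FALSE)
  fragmentation <- if ("fragmentation" %in% names(pairs)) {
    u <- unique(pairs$fragmentation)
    if (length(u) != 1L) stop("training set mixes fragmentation types", call. = FALSE)
    u
  } else "CID"
  obs <- collect_observations(pairs, tol = tol, floor = floor)
  if (nrow(obs) == 0L) stop("no usable ratio observations in training set", call. = FALSE)
  dm <- build_design_matrix(obs)
  X <- as.matrix(dm$X)
  y <- dm$y
  p <- ncol(X)
  if (ridge > 0) {
    X_aug <- rbind(X, sqrt(ridge) * diag(p))
    y_aug <- c(y, numeric(p))
  } else {
    X_aug <- X; y_aug <- y
  }
  qrX <- qr(X_aug)
  if (qrX$rank < p) {
    stop("design matrix is rank deficient (rank ", qrX$rank, " < ", p,
         "); add data or set ridge > 0", call. = FALSE)
  }
  theta <- qr.coef(qrX, y_aug)
  v_full <- as.numeric(gauge_expansion_matrix() %*% theta)
  names(v_full) <- param_names()
  params <- vector_to_params(v_full, fragmentation = fragmentation, beta = 1)
  resid <- y - as.numeric(X %*% theta)
  structure(
    list(params = params, residual_rms = sqrt(mean(resid^2)),
         n_obs = nrow(obs), n_pairs = nrow(pairs),
         ridge = ridge, tol = tol, floor = floor),
    class = "spec_fit"
  )
}

#' @export
print.spec_fit <- function(x, ...) {
  cat("<spec_fit> adjacent-ratio model, ", x$params$fragmentation, "\n", sep = "")
  cat("  pairs: ", x$n_pairs, "   ratio observations: ", x$n_obs, "\n", sep = "")
  cat("  ridge: ", format(x$ridge), "   residual RMS: ",
      format(x$residual_rms, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.spec_params
#' @export
tidy.spec_fit <- function(x, ...) tidy(x$params, ...)

#' One-row fit summary
#' @param x A `spec_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_pairs`, `n_obs`, `n_free_params`,
#'   `ridge`, `residual_rms`.
#' @export
glance.spec_fit <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, n_obs = x$n_obs,
    n_free_params = length(free_param_names()),
    ridge = x$ridge, residual_rms = x$residual_rms
  )
}

#' Pearson CC between a predicted and an experimental spectrum
#'
#' Predicts monoisotopic y intensities for the peptide, matches the
#' experimental peaks on the y-ion grid, and computes the Pearson correlation
#' over the grid (unmatched ions count as intensity 0).
#'
#' @param peptide Peptide sequence.
#' @param params A `spec_params` object.
#' @param peaks Experimental peak tibble.
#' @param tol Matching tolerance in Da.
#' @return Pearson correlation in [-1, 1] (0, flagged, if degenerate).
#' @export
spectrum_cc <- function(peptide, params, peaks, tol = 0.5) {
  theo <- generate_y_series(peptide)
  theo$intensity <- unname(predict_y_intensities(peptide, params))
  mv <- match_peaks(theo, peaks, tol = tol)
  pearson_cc(mv$v_t, mv$v_e)
}

#' k-fold cross-validation of the trainer
#'
#' Pairs are shuffled into folds with a stated seed; each fold is held out in
#' turn, parameters are fitted on the rest, and held-out performance is
#' summarised as the ratio-residual RMS and the median spectrum Pearson CC.
#'
#' @inheritParams fit_parameters
#' @param k_folds Number of folds (>= 2).
#' @param seed Fold-assignment seed.
#' @return A list with `folds` (per-fold tibble: `fold`, `n_pairs`,
#'   `ratio_rms`, `median_cc`), `ratio_rms` and `median_cc` pooled over all
#'   held-out pairs.
#' @export
cross_validate <- function(pairs, k_folds = 5L, ridge = 0, tol = 0.5,
                           floor = 0.01, seed = 1L) {
  stopifnot(k_folds >= 2L)
  if (nrow(pairs) < k_folds) {
    stop("fewer pairs (", nrow(pairs), ") than folds (", k_folds, ")", call. = FALSE)
  }
  fold <- withr::with_seed(seed, sample(rep(seq_len(k_folds), length.out = nrow(pairs))))
  all_resid <- numeric(0)
  all_cc <- numeric(0)
  fold_rows <- purrr::map_dfr(seq_len(k_folds), function(kf) {
    train <- pairs[fold != kf, , drop = FALSE]
    test <- pairs[fold == kf, , drop = FALSE]
    fit <- fit_parameters(train, ridge = ridge, tol = tol, floor = floor)
    obs <- collect_observations(test, tol = tol, floor = floor)
    resid <- numeric(nrow(obs))
    for (pep in unique(obs$peptide)) {
      sel <- obs$peptide == pep
      resid[sel] <- obs$r[sel] - log_ratio(pep, obs$i[sel], fit$params)
    }
    cc <- purrr::map2_dbl(test$peptide, test$peaks, function(pep, pk) {
      as.numeric(spectrum_cc(pep, fit$params, pk, tol = tol))
    })
    all_resid <<- c(all_resid, resid)
    all_cc <<- c(all_cc, cc)
    tibble::tibble(
      fold = kf, n_pairs = nrow(test),
      ratio_rms = sqrt(mean(resid^2)),
      median_cc = stats::median(cc)
    )
  })
  list(folds = fold_rows,
       ratio_rms = sqrt(mean(all_resid^2)),
       median_cc = stats::median(all_cc))
}
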