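# Figures: mirror plots of predicted vs experimental spectra, and FDR curves.

#' Mirror plot of predicted vs experimental spectrum
#'
#' Theoretical peaks point up, experimental peaks down (both normalised to
#' base peak 100); monoisotopic y ions are labelled and the Pearson CC is
#' printed in the title.
#'
#' @param theoretical Peak tibble (ideally from [predict_spectrum()], so ion
#'   annotations are available).
#' @param experimental Peak tibble.
#' @param peptide Peptide sequence, used in the title.
#' @param tol Matching tolerance used for the CC annotation.
#' @return A ggplot object.
#' @export
plot_mirror <- function(theoretical, experimental, peptide = NULL, tol = 0.5) {
  norm <- function(x) x / max(x) * 100
  th <- theoretical; th$intensity <- norm(th$intensity)
  ex <- experimental; ex$intensity <- -norm(ex$intensity)
  cc_txt <- ""
  if (!is.null(peptide)) {
    mono <- if ("isotope" %in% names(th)) th[th$isotope == 0L, ] else th
    mv <- match_peaks(mono, experimental, tol = tol)
    cc_txt <- sprintf(" (Pearson CC = %.3f)", as.numeric(pearson_cc(mv$v_t, mv$v_e)))
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = th,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity),
      colour = "#2166ac") +
    ggplot2::geom_segment(
      data = ex,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity),
      colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "relative intensity (up: predicted, down: experimental)",
                  title = paste0(peptide %||% "", cc_txt)) +
    ggplot2::theme_minimal()
  if ("index" %in% names(th)) {
    lab <- th[!duplicated(th$index), , drop = FALSE]
    if ("isotope" %in% names(lab)) lab <- lab[lab$isotope == 0L, , drop = FALSE]
    lab$label <- paste0("y", lab$index)
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$mz, y = .data$intensity, label = .data$label),
      vjust = -0.4, size = 2.7, colour = "#2166ac")
  }
  p
}

#' Plot one or more FDR curves
#'
#' Accepted-target count against monotonised FDR, one line per curve, so the
#' re-ranking gain over the engine score is visible directly.
#'
#' @param curves A named list of `fdr_curve` objects (names become the
#'   legend), or a single curve.
#' @param q_max Truncate the x axis at this FDR.
#' @return A ggplot object.
#' @export
plot_fdr_curves <- function(curves, q_max = 0.05) {
  if (inherits(curves, "fdr_curve")) curves <- list(score = curves)
  df <- purrr::imap_dfr(curves, function(cv, nm) {
    tibble::tibble(score = nm, q = cv$q, targets = cv$targets)
  })
  df <- df[df$q <= q_max, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$targets,
                                   colour = .data$score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "FDR", y = "accepted target PSMs", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_fdr_curves
#' @param object An `fdr_curve` object.
#' @param ... Passed to [plot_fdr_curves()].
#' @export
autoplot.fdr_curve <- function(object, ...) plot_fdr_curves(object, ...)
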