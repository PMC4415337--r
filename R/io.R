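# Readers and writers: MGF peak lists, annotation TSV, PSM TSV, FDR-curve TSV.

#' Read a Mascot Generic Format (MGF) file
#'
#' Parses BEGIN IONS / END IONS blocks, honouring TITLE, PEPMASS (first
#' token) and CHARGE headers; peak lines are "mz intensity". Blank lines and
#' `#` comment lines are tolerated anywhere. Peaks are sorted by m/z on load.
#'
#' @param path File path.
#' @return A spectra collection tibble: `title`, `precursor_mz`,
#'   `precursor_charge`, `peaks` (list of peak tibbles). Zero rows for an
#'   empty file.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  in_block <- FALSE
  begin_line <- NA_integer_
  title <- NA_character_; pmz <- NA_real_; chg <- NA_integer_
  mz <- numeric(0); inten <- numeric(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    if (raw == "BEGIN IONS") {
      if (in_block) stop("line ", ln, ": nested BEGIN IONS", call. = FALSE)
      in_block <- TRUE; begin_line <- ln
      title <- NA_character_; pmz <- NA_real_; chg <- NA_integer_
      mz <- numeric(0); inten <- numeric(0)
      next
    }
    if (raw == "END IONS") {
      if (!in_block) stop("line ", ln, ": END IONS without BEGIN IONS", call. = FALSE)
      ord <- order(mz)
      out[[length(out) + 1L]] <- tibble::tibble(
        title = title, precursor_mz = pmz, precursor_charge = chg,
        peaks = list(tibble::tibble(mz = mz[ord], intensity = inten[ord]))
      )
      in_block <- FALSE
      next
    }
    if (!in_block) stop("line ", ln, ": content outside BEGIN IONS block", call. = FALSE)
    if (grepl("=", raw, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", raw))
      val <- sub("^[^=]*=", "", raw)
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") pmz <- as.numeric(strsplit(trimws(val), "\\s+")[[1]][1])
      else if (key == "CHARGE") chg <- as.integer(sub("\\+$", "", trimws(val)))
      # other headers ignored
      next
    }
    tok <- strsplit(raw, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[1:2]))
    if (length(tok) < 2L || any(is.na(vals))) {
      stop("line ", ln, ": malformed peak line ", sQuote(raw), call. = FALSE)
    }
    mz <- c(mz, vals[1]); inten <- c(inten, vals[2])
  }
  if (in_block) {
    stop("block starting at line ", begin_line, " missing END IONS", call. = FALSE)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(title = character(), precursor_mz = numeric(),
                          precursor_charge = integer(), peaks = list()))
  }
  dplyr::bind_rows(out)
}

#' Write spectra as MGF
#'
#' @param spectra Spectra collection tibble (`title`, `precursor_mz`,
#'   `precursor_charge`, `peaks`).
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::map(seq_len(nrow(spectra)), function(r) {
    pk <- spectra$peaks[[r]]
    hdr <- c("BEGIN IONS", paste0("TITLE=", spectra$title[[r]]))
    if (!is.na(spectra$precursor_mz[[r]])) {
      hdr <- c(hdr, sprintf("PEPMASS=%.6f", spectra$precursor_mz[[r]]))
    }
    if (!is.na(spectra$precursor_charge[[r]])) {
      hdr <- c(hdr, sprintf("CHARGE=%d+", spectra$precursor_charge[[r]]))
    }
    c(hdr, sprintf("%.6f %.8e", pk$mz, pk$intensity), "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read a spectrum-annotation table
#'
#' Tab-separated with header columns `spectrum_title`, `peptide`,
#' `fragmentation`.
#'
#' @param path File path.
#' @return A tibble with validated peptides.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("spectrum_title", "peptide", "fragmentation")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (p in ann$peptide) check_peptide(p)
  bad <- !ann$fragmentation %in% c("CID", "HCD")
  if (any(bad)) stop("unknown fragmentation type in annotation row(s) ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  ann
}

#' Load training pairs from an MGF file plus annotations
#'
#' @param mgf_path Spectra in MGF.
#' @param annotations_path TSV with `spectrum_title`, `peptide`,
#'   `fragmentation`.
#' @return A pairs tibble (`title`, `peptide`, `fragmentation`, `peaks`)
#'   ready for [fit_parameters()].
#' @export
load_training_pairs <- function(mgf_path, annotations_path) {
  spectra <- read_mgf(mgf_path)
  ann <- read_annotations(annotations_path)
  idx <- match(ann$spectrum_title, spectra$title)
  if (any(is.na(idx))) {
    stop("annotation titles not found in MGF: ",
         paste(utils::head(ann$spectrum_title[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(title = ann$spectrum_title, peptide = ann$peptide,
                 fragmentation = ann$fragmentation, peaks = spectra$peaks[idx])
}

#' Read a PSM table
#'
#' Tab-separated, header required: `spectrum_id`, `peptide`, `is_decoy`
#' (0/1), `engine` (SEQUEST or XTANDEM), `xcorr`, `delta_cn`, `s_t`.
#' SEQUEST rows need finite `xcorr` and `delta_cn`; XTANDEM rows need
#' `s_t >= 0`.
#'
#' @param path File path.
#' @return A PSM tibble with `is_decoy` as logical.
#' @export
read_psm_table <- function(path) {
  psms <- readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    peptide = readr::col_character(),
    is_decoy = readr::col_character(),
    engine = readr::col_character(),
    .default = readr::col_double()
  ))
  need <- c("spectrum_id", "peptide", "is_decoy", "engine")
  miss <- setdiff(need, names(psms))
  if (length(miss)) stop("PSM table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !psms$is_decoy %in% c("0", "1")
  if (any(bad)) stop("bad is_decoy value (must be 0 or 1) in row(s) ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  psms$is_decoy <- psms$is_decoy == "1"
  badeng <- !psms$engine %in% c("SEQUEST", "XTANDEM")
  if (any(badeng)) stop("unknown engine in row(s) ",
                        paste(which(badeng), collapse = ", "), call. = FALSE)
  for (p in psms$peptide) check_peptide(p)
  sq <- psms$engine == "SEQUEST"
  if (any(sq) && (!all(c("xcorr", "delta_cn") %in% names(psms)) ||
                  any(!is.finite(psms$xcorr[sq])) ||
                  any(!is.finite(psms$delta_cn[sq])))) {
    stop("SEQUEST rows require finite xcorr and delta_cn", call. = FALSE)
  }
  if (any(!sq)) {
    if (!"s_t" %in% names(psms) || any(!is.finite(psms$s_t[!sq]))) {
      stop("XTANDEM rows require finite s_t", call. = FALSE)
    }
    neg <- which(!sq & psms$s_t < 0)
    if (length(neg)) stop("negative s_t (sqrt undefined) in row(s) ",
                          paste(neg, collapse = ", "), call. = FALSE)
  }
  psms
}

#' Write a PSM table
#' @param psms PSM tibble.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  out$is_decoy <- as.integer(out$is_decoy)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write an FDR curve as TSV
#' @param curve An `fdr_curve` tibble.
#' @param path Output path.
#' @export
write_fdr_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path)
  invisible(path)
}
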