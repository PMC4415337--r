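# Monoisotopic residue masses (Da). A residue mass is the amino-acid mass
# minus one water; the y ion adds the water and proton back.
RESIDUE_MASS <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

MASS_H2O <- 18.010565
MASS_PROTON <- 1.007276
MASS_ISOTOPE_SPACING <- 1.00335  # 13C - 12C

AMINO_ACIDS <- names(RESIDUE_MASS)

#' Monoisotopic residue mass
#'
#' Looks up the monoisotopic residue mass (amino acid minus water) for one or
#' more standard one-letter codes.
#'
#' @param aa Character vector of single one-letter amino-acid codes.
#' @return Numeric vector of masses in Da, named by residue.
#' @examples
#' residue_mass("G")
#' residue_mass(c("K", "R"))
#' @export
residue_mass <- function(aa) {
  aa <- as.character(aa)
  bad <- !(aa %in% AMINO_ACIDS) | nchar(aa) != 1L
  if (any(bad)) {
    stop("unknown residue: ", paste(sQuote(unique(aa[bad])), collapse = ", "),
         call. = FALSE)
  }
  RESIDUE_MASS[aa]
}

#' Validate a peptide sequence
#'
#' Checks that a sequence uses only the 20 standard uppercase one-letter codes
#' and has at least one cleavage site (length >= 2). Lowercase letters and
#' modification syntax such as brackets are rejected rather than stripped.
#'
#' @param sequence A single character string.
#' @return The sequence, invisibly, if valid; otherwise an error.
#' @export
check_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("peptide must be a single character string", call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(res %in% AMINO_ACIDS)
  if (any(bad)) {
    stop("unknown residue: ", paste(sQuote(unique(res[bad])), collapse = ", "),
         " in peptide ", sQuote(sequence), call. = FALSE)
  }
  if (length(res) < 2L) {
    stop("peptide must have length >= 2 (at least one cleavage site)",
         call. = FALSE)
  }
  invisible(sequence)
}

peptide_residues <- function(sequence) {
  check_peptide(sequence)
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

#' Neutral monoisotopic peptide mass
#'
#' @param peptide Peptide sequence.
#' @return Neutral mass in Da (sum of residue masses plus one water).
#' @export
neutral_mass <- function(peptide) {
  res <- peptide_residues(peptide)
  sum(RESIDUE_MASS[res]) + MASS_H2O
}

#' m/z of a y ion
#'
#' The y_i ion contains the C-terminal i residues plus water plus the charging
#' proton(s).
#'
#' @param peptide Peptide sequence.
#' @param i Fragment index (vectorised), 1 <= i <= n - 1.
#' @param charge Fragment charge; only 1 is supported here.
#' @return m/z in Da per charge.
#' @export
y_ion_mz <- function(peptide, i, charge = 1L) {
  res <- peptide_residues(peptide)
  n <- length(res)
  if (any(i < 1L | i > n - 1L)) {
    stop("fragment index out of range: i must lie in 1..", n - 1L, call. = FALSE)
  }
  suffix_mass <- cumsum(RESIDUE_MASS[rev(res)])  # suffix_mass[i] = last i residues
  (suffix_mass[i] + MASS_H2O + charge * MASS_PROTON) / charge
}

#' Generate the singly charged y-ion series
#'
#' @param peptide Peptide sequence of length n.
#' @return A tibble with one row per ion y_1..y_{n-1}: `index`, `ion`, `mz`
#'   (strictly increasing), and `intensity` initialised to 0.
#' @export
generate_y_series <- function(peptide) {
  res <- peptide_residues(peptide)
  n <- length(res)
  idx <- seq_len(n - 1L)
  tibble::tibble(
    index = idx,
    ion = paste0("y", idx),
    mz = unname(y_ion_mz(peptide, idx)),
    intensity = 0
  )
}

#' Read a peptide list
#'
#' Plain-text list, one sequence per line; blank lines and lines starting with
#' `#` are ignored. Every sequence is validated.
#'
#' @param path File path.
#' @return Character vector of peptide sequences.
#' @export
read_peptide_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (p in lines) check_peptide(p)
  lines
}
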