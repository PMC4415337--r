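# Model parameters for the adjacent-y-ion intensity-ratio model.
#
# The parameter set mirrors the mobile-proton cleavage-energy formulation:
#   * delta[x][d]    : position-offset effect of residue x at offset d from the
#                      N-terminal flank of the cleavage site; d in -2..1 for
#                      ordinary residues, -8..5 for K/R (proton sequestration
#                      acts over a longer range for basic residues).
#   * delta_cterm[d] : C-terminus effect for site-to-C-terminus distances 0..10.
#   * delta_nterm[s] : N-terminus effect bucketed into 5 levels.
#   * G[class][A]    : log of the combined fragmentation-pathway probability
#                      ln(F(A) + D(A, site)); the b/y and diketopiperazine
#                      pathway probabilities F and D are not separately
#                      identifiable from intensity ratios, so only their sum is
#                      stored, split by site class (interior vs penultimate).

CORE_OFFSETS <- -2:1
CORE_SUMZERO_OFFSETS <- c(-2L, -1L, 1L)  # offset 0 is absorbed into G instead
KR_OFFSETS <- -8:5
CTERM_OFFSETS <- 0:10
NTERM_LEVELS <- 1:5
SITE_CLASSES <- c("interior", "penultimate")
DELTA_REFERENCE_RESIDUE <- "Y"   # sum-to-zero reference at core offsets
G_REFERENCE <- c("G", "interior")

delta_offsets <- function(x) {
  if (x %in% c("K", "R")) KR_OFFSETS else CORE_OFFSETS
}

#' Canonical parameter names
#'
#' Full (un-gauged) parameter vector layout used throughout fitting and
#' serialization. Names have the form `delta|x|d`, `nterm|s`, `cterm|d`,
#' `G|A|class`.
#'
#' @return Character vector of parameter names.
#' @keywords internal
param_names <- function() {
  dn <- unlist(lapply(AMINO_ACIDS, function(x) {
    paste0("delta|", x, "|", delta_offsets(x))
  }), use.names = FALSE)
  c(dn,
    paste0("nterm|", NTERM_LEVELS),
    paste0("cterm|", CTERM_OFFSETS),
    paste0("G|", AMINO_ACIDS, "|interior"),
    paste0("G|", AMINO_ACIDS, "|penultimate"))
}

#' Construct a model-parameter object
#'
#' @param fragmentation "CID" or "HCD".
#' @param beta Scale of the cleavage-energy term. Fixed at 1 by the training
#'   gauge (beta multiplies every delta, so it is not separately identifiable).
#' @param delta Named list, one entry per residue, each a numeric vector named
#'   by offset (`-2`..`1`, or `-8`..`5` for K and R).
#' @param delta_nterm Numeric vector of length 5, names `1`..`5`.
#' @param delta_cterm Numeric vector of length 11, names `0`..`10`.
#' @param G Named list with elements `interior` and `penultimate`, each a
#'   numeric vector named by the 20 residues.
#' @return An object of class `spec_params`.
#' @export
spec_params <- function(fragmentation = c("CID", "HCD"), beta = 1,
                        delta, delta_nterm, delta_cterm, G) {
  fragmentation <- match.arg(fragmentation)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (!setequal(names(delta), AMINO_ACIDS)) {
    stop("delta must have one entry per standard residue", call. = FALSE)
  }
  for (x in AMINO_ACIDS) {
    want <- as.character(delta_offsets(x))
    if (!identical(sort(names(delta[[x]])), sort(want))) {
      stop("delta offsets for ", x, " must be exactly {",
           paste(want, collapse = ","), "}", call. = FALSE)
    }
    delta[[x]] <- delta[[x]][want]
  }
  delta <- delta[AMINO_ACIDS]
  if (length(delta_nterm) != 5L) stop("delta_nterm must have 5 levels", call. = FALSE)
  names(delta_nterm) <- as.character(NTERM_LEVELS)
  if (length(delta_cterm) != 11L) stop("delta_cterm must cover offsets 0..10", call. = FALSE)
  names(delta_cterm) <- as.character(CTERM_OFFSETS)
  if (!setequal(names(G), SITE_CLASSES)) {
    stop("G must have 'interior' and 'penultimate' classes", call. = FALSE)
  }
  for (cl in SITE_CLASSES) {
    if (!setequal(names(G[[cl]]), AMINO_ACIDS)) {
      stop("G$", cl, " must cover all 20 residues", call. = FALSE)
    }
    G[[cl]] <- G[[cl]][AMINO_ACIDS]
  }
  structure(
    list(fragmentation = fragmentation, beta = beta, delta = delta,
         delta_nterm = delta_nterm, delta_cterm = delta_cterm,
         G = G[SITE_CLASSES]),
    class = "spec_params"
  )
}

#' All-zero model parameters
#'
#' Convenient neutral element: every predicted ratio is 1 and every predicted
#' spectrum is flat.
#'
#' @inheritParams spec_params
#' @return A `spec_params` object with all entries 0.
#' @export
zero_params <- function(fragmentation = "CID") {
  vector_to_params(stats::setNames(numeric(length(param_names())), param_names()),
                   fragmentation = fragmentation)
}

#' Flatten parameters to a named vector
#' @param params A `spec_params` object.
#' @return Named numeric vector in `param_names()` order (beta excluded).
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "spec_params"))
  v <- c(
    unlist(lapply(AMINO_ACIDS, function(x) {
      stats::setNames(params$delta[[x]],
                      paste0("delta|", x, "|", names(params$delta[[x]])))
    })),
    stats::setNames(params$delta_nterm, paste0("nterm|", names(params$delta_nterm))),
    stats::setNames(params$delta_cterm, paste0("cterm|", names(params$delta_cterm))),
    stats::setNames(params$G$interior, paste0("G|", AMINO_ACIDS, "|interior")),
    stats::setNames(params$G$penultimate, paste0("G|", AMINO_ACIDS, "|penultimate"))
  )
  v[param_names()]
}

#' Rebuild parameters from a named vector
#' @param v Named numeric vector over `param_names()`.
#' @param fragmentation "CID" or "HCD".
#' @param beta Energy scale (default 1).
#' @return A `spec_params` object.
#' @export
vector_to_params <- function(v, fragmentation = "CID", beta = 1) {
  stopifnot(setequal(names(v), param_names()))
  delta <- lapply(stats::setNames(AMINO_ACIDS, AMINO_ACIDS), function(x) {
    off <- delta_offsets(x)
    stats::setNames(unname(v[paste0("delta|", x, "|", off)]), as.character(off))
  })
  spec_params(
    fragmentation = fragmentation, beta = beta, delta = delta,
    delta_nterm = stats::setNames(unname(v[paste0("nterm|", NTERM_LEVELS)]),
                                  as.character(NTERM_LEVELS)),
    delta_cterm = stats::setNames(unname(v[paste0("cterm|", CTERM_OFFSETS)]),
                                  as.character(CTERM_OFFSETS)),
    G = list(
      interior = stats::setNames(unname(v[paste0("G|", AMINO_ACIDS, "|interior")]),
                                 AMINO_ACIDS),
      penultimate = stats::setNames(unname(v[paste0("G|", AMINO_ACIDS, "|penultimate")]),
                                    AMINO_ACIDS)
    )
  )
}

#' Project parameters onto the canonical (identifiable) gauge
#'
#' Intensity ratios leave several parameter directions unconstrained, so the
#' trainer estimates a canonical representative:
#'
#' * `delta(x, 0)` attaches to the same residue as the pathway term
#'   `G(x, class)` in every ratio, so the two are perfectly confounded; the
#'   offset-0 delta is absorbed into both G classes and pinned to 0
#'   (an exact null shift: predictions are unchanged).
#' * A common shift of all five N-terminus levels and a common shift of every
#'   G entry are exact null directions; `delta_nterm[1]` and
#'   `G(G, interior)` are pinned to 0.
#' * `delta_cterm[0]` can never occur (the offset equals the y index, which
#'   is at least 1) and is pinned to 0.
#' * `sum_x delta(x, d) = 0` over all 20 residues at the remaining core
#'   offsets d = -2, -1, 1 fixes the near-null common shifts there.
#'
#' Ground-truth parameters are passed through this projection before any
#' spectra are generated, so exact recovery by the trainer is well defined.
#'
#' @param params A `spec_params` object.
#' @return A `spec_params` object in canonical gauge.
#' @export
apply_gauge <- function(params) {
  v <- params_to_vector(params)
  # absorb delta(x, 0) into G (null shift)
  for (x in AMINO_ACIDS) {
    d0 <- paste0("delta|", x, "|0")
    v[paste0("G|", x, "|", SITE_CLASSES)] <- v[paste0("G|", x, "|", SITE_CLASSES)] + v[d0]
    v[d0] <- 0
  }
  # null shifts
  v[paste0("nterm|", NTERM_LEVELS)] <-
    v[paste0("nterm|", NTERM_LEVELS)] - v["nterm|1"]
  gshift <- v[paste0("G|", G_REFERENCE[1], "|", G_REFERENCE[2])]
  gcols <- grep("^G\\|", names(v))
  v[gcols] <- v[gcols] - gshift
  # conventions
  v["cterm|0"] <- 0
  for (d in CORE_SUMZERO_OFFSETS) {
    cols <- paste0("delta|", AMINO_ACIDS, "|", d)
    v[cols] <- v[cols] - mean(v[cols])
  }
  vector_to_params(v, fragmentation = params$fragmentation, beta = params$beta)
}

#' Free (gauge-fixed) parameter coordinates
#'
#' Drops the pinned coordinates (`nterm|1`, `cterm|0`, `G|G|interior`) and the
#' sum-to-zero reference residue at each core offset, leaving the coordinates
#' that the trainer actually estimates.
#'
#' @param params A `spec_params` object.
#' @return Named numeric vector of free parameters.
#' @export
free_params <- function(params) {
  params_to_vector(params)[free_param_names()]
}

free_param_names <- function() {
  fixed <- c("nterm|1", "cterm|0",
             paste0("G|", G_REFERENCE[1], "|", G_REFERENCE[2]),
             paste0("delta|", AMINO_ACIDS, "|0"),
             paste0("delta|", DELTA_REFERENCE_RESIDUE, "|", CORE_SUMZERO_OFFSETS))
  setdiff(param_names(), fixed)
}

# Sparse map T from free coordinates to the full vector: identity on free
# rows; delta of the reference residue at each core offset is minus the sum of
# the other 19; pinned rows are zero.
gauge_expansion_matrix <- function() {
  full <- param_names()
  free <- free_param_names()
  ii <- match(free, full)
  jj <- seq_along(free)
  xx <- rep(1, length(free))
  for (d in CORE_SUMZERO_OFFSETS) {
    ref_row <- match(paste0("delta|", DELTA_REFERENCE_RESIDUE, "|", d), full)
    others <- paste0("delta|", setdiff(AMINO_ACIDS, DELTA_REFERENCE_RESIDUE), "|", d)
    ii <- c(ii, rep(ref_row, length(others)))
    jj <- c(jj, match(others, free))
    xx <- c(xx, rep(-1, length(others)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(full), length(free)),
                       dimnames = list(full, free))
}

#' @export
print.spec_params <- function(x, ...) {
  v <- params_to_vector(x)
  cat("<spec_params> ", x$fragmentation,
      " adjacent-y-ion ratio model\n", sep = "")
  cat("  beta: ", format(x$beta), "\n", sep = "")
  cat("  ", length(v), " parameters (", length(free_param_names()),
      " free after gauge fixing)\n", sep = "")
  cat("  delta range: [", format(min(unlist(x$delta)), digits = 3), ", ",
      format(max(unlist(x$delta)), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Tidy a parameter object
#'
#' @param x A `spec_params` object.
#' @param ... Unused.
#' @return A tibble with columns `component` (delta/nterm/cterm/G), `residue`,
#'   `position` (offset, level, or site class) and `estimate`.
#' @export
tidy.spec_params <- function(x, ...) {
  v <- params_to_vector(x)
  parts <- strsplit(names(v), "|", fixed = TRUE)
  tibble::tibble(
    component = purrr::map_chr(parts, 1),
    residue = purrr::map_chr(parts, function(p) {
      if (p[[1]] %in% c("delta", "G")) p[[2]] else NA_character_
    }),
    position = purrr::map_chr(parts, function(p) p[[length(p)]]),
    estimate = unname(v)
  )
}

#' Write model parameters as JSON
#'
#' Keys follow the documented dialect: `fragmentation`, `beta`, `delta` (per
#' residue, offsets as signed decimal strings), `delta_nterm`, `delta_cterm`,
#' `G` (per site class). The round trip through [read_params_json()] is
#' lossless.
#'
#' @param params A `spec_params` object.
#' @param path Output path.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "spec_params"))
  obj <- list(
    fragmentation = params$fragmentation,
    beta = params$beta,
    delta = lapply(params$delta, as.list),
    delta_nterm = as.list(params$delta_nterm),
    delta_cterm = as.list(params$delta_cterm),
    G = lapply(params$G, as.list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model parameters from JSON
#' @param path Path to a file written by [write_params_json()].
#' @return A `spec_params` object.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path)
  num <- function(l) vapply(l, as.numeric, numeric(1))
  spec_params(
    fragmentation = obj$fragmentation,
    beta = as.numeric(obj$beta),
    delta = lapply(obj$delta, num),
    delta_nterm = num(obj$delta_nterm),
    delta_cterm = num(obj$delta_cterm),
    G = lapply(obj$G, num)
  )
}
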