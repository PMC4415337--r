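# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: plain loops and first-principles definitions.

# Brute-force y-ion m/z: explicit loop over the C-terminal i residues.
oracle_y_mz <- function(peptide, i, charge = 1) {
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  total <- 0
  for (k in seq(n - i + 1, n)) total <- total + unname(specsim::residue_mass(res[k]))
  unname((total + 18.010565 + charge * 1.007276) / charge)
}

# Brute-force cleavage energy: loop over every residue of the peptide and
# test both window conditions directly against the parameter lists.
oracle_cleavage_energy <- function(peptide, i, params) {
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  p <- n - i
  e <- 0
  for (pos in seq_len(n)) {
    x <- res[pos]
    d <- pos - p
    if (x %in% c("K", "R")) {
      if (d >= -8 && d <= 5) e <- e + params$delta[[x]][[as.character(d)]]
    } else {
      if (d >= -2 && d <= 1) e <- e + params$delta[[x]][[as.character(d)]]
    }
  }
  d_C <- n - p
  if (d_C <= 10) e <- e + params$delta_cterm[[as.character(d_C)]]
  d_N <- p - 1
  s <- max(1, ceiling(5 * d_N / n))
  e + params$delta_nterm[[as.character(s)]]
}

# Direct recomputation of the log ratio from cleavage energies and G lookups.
oracle_log_ratio <- function(peptide, i, params) {
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  cls <- function(j) if (j == n - 1) "penultimate" else "interior"
  params$beta * (oracle_cleavage_energy(peptide, i, params) -
                 oracle_cleavage_energy(peptide, i + 1, params)) +
    params$G[[cls(i)]][[res[n - i]]] - params$G[[cls(i + 1)]][[res[n - i - 1]]]
}

# Brute-force decoy-count FDR sweep: for every distinct score, accept all
# records scoring >= it and count directly.
oracle_fdr_sweep <- function(score, is_decoy) {
  th <- sort(unique(score), decreasing = TRUE)
  targets <- integer(length(th)); decoys <- integer(length(th))
  for (k in seq_along(th)) {
    acc <- score >= th[k]
    targets[k] <- sum(acc & !is_decoy)
    decoys[k] <- sum(acc & is_decoy)
  }
  fdr <- ifelse(targets == 0, 0, decoys / targets)
  q <- fdr
  for (k in rev(seq_along(q))[-1]) q[k] <- min(q[k], q[k + 1])
  data.frame(threshold = th, targets = targets, decoys = decoys,
             fdr = fdr, q = q)
}

# Maximum one-to-one matching size within tol, by exhaustive recursion
# (feasible for <= ~6 peaks a side).
oracle_max_matching <- function(mz1, mz2, tol) {
  best <- 0L
  recurse <- function(j, used2, count) {
    if (count + (length(mz1) - j + 1L) <= best) return()
    if (j > length(mz1)) { best <<- max(best, count); return() }
    recurse(j + 1L, used2, count)  # leave mz1[j] unmatched
    for (k in seq_along(mz2)) {
      if (!used2[k] && abs(mz1[j] - mz2[k]) <= tol) {
        used2[k] <- TRUE
        recurse(j + 1L, used2, count + 1L)
        used2[k] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(mz2)), 0L)
  best
}

# Random gauge-canonical parameters and random peptide under the current RNG.
rand_params <- function(fragmentation = "CID") {
  specsim::sample_true_params(fragmentation)
}

rand_peptide <- function(min_len = 6, max_len = 20) {
  specsim::random_tryptic_peptide(c(min_len, max_len), tryptic_end = TRUE)
}
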