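## In-silico trypsin digestion, monoisotopic mass computation, and
## coverage-based presence calls against the curated AMP/lysozyme protein
## sub-database.

# Monoisotopic residue masses (Da) of the 20 standard amino acids.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- 18.010565
CARBAMIDOMETHYL_MASS <- 57.02146

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water. With
#' `carbamidomethyl = TRUE`, a fixed carbamidomethyl modification
#' (+57.02146 Da) is added per cysteine.
#'
#' @param sequence peptide sequence(s) over the 20 standard residues.
#' @param carbamidomethyl apply fixed Cys modification, default FALSE.
#' @return numeric mass(es) in Da.
#' @export
monoisotopic_mass <- function(sequence, carbamidomethyl = FALSE) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("empty peptide sequence")
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, names(RESIDUE_MASS))
    if (length(bad)) stop("non-standard residue(s): ", paste(bad, collapse = ","))
    m <- sum(RESIDUE_MASS[aa]) + WATER_MASS
    if (carbamidomethyl) m <- m + CARBAMIDOMETHYL_MASS * sum(aa == "C")
    m
  }, numeric(1), USE.NAMES = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R, except when the following residue is P,
#' and enumerates all peptides with up to `max_missed` missed cleavages and
#' at least `min_len` residues. Positions are 1-based inclusive in the
#' parent protein.
#'
#' @param protein protein sequence (character scalar).
#' @param max_missed maximum missed cleavages, default 1.
#' @param min_len minimum peptide length, default 5.
#' @param carbamidomethyl fixed Cys modification for masses, default FALSE.
#' @return data.frame `sequence`, `start`, `end`, `missed_cleavages`,
#'   `mass`.
#' @export
tryptic_digest <- function(protein, max_missed = 1L, min_len = 5L,
                           carbamidomethyl = FALSE) {
  stopifnot(nzchar(protein))
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n else integer(0))
  bounds <- sort(unique(bounds))
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:min(max_missed, nfrag - i)) {
      st <- bounds[i] + 1L
      en <- bounds[i + 1L + m]
      if (en - st + 1L < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(aa[st:en], collapse = ""),
        start = st, end = en, missed_cleavages = m)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0),
                      mass = numeric(0)))
  res <- do.call(rbind, out)
  res$mass <- monoisotopic_mass(res$sequence, carbamidomethyl)
  res
}

theoretical_peptides <- function(db, max_missed = 1L, min_len = 5L,
                                 carbamidomethyl = FALSE) {
  stopifnot(length(db) > 0, !is.null(names(db)), !anyDuplicated(names(db)),
            all(nzchar(db)))
  do.call(rbind, lapply(names(db), function(p) {
    d <- tryptic_digest(db[[p]], max_missed, min_len, carbamidomethyl)
    if (nrow(d)) d$protein <- p
    d
  }))
}

#' Match observed peptide masses and call protein presence by coverage
#'
#' For each sample group, observed monoisotopic masses are matched against
#' the theoretical tryptic peptides of the protein sub-database: a mass
#' matches when the relative error |observed - theoretical| / theoretical
#' is at most `tol_ppm` ppm. Sequence coverage is the fraction of a
#' protein's residues lying under at least one matched peptide, and a
#' protein is called present in a group when coverage strictly exceeds
#' `presence_threshold` (default 0.5: peptides covering more than half of
#' the predicted sequence). A mass matching peptides of several proteins is
#' credited to all of them and flagged ambiguous.
#'
#' Alternatively, observations may carry identified peptide sequences
#' (column `peptide`) instead of masses; these are matched by exact
#' substring lookup and mass matching is skipped.
#'
#' @param observed data.frame with column `group` plus `mass` (Da) or
#'   `peptide`.
#' @param db named character vector: protein id -> sequence (the curated
#'   sub-database).
#' @param tol_ppm mass tolerance in ppm, default 10.
#' @param max_missed,min_len digestion parameters, defaults 1 and 5.
#' @param presence_threshold coverage required for a presence call
#'   (strict), default 0.5.
#' @param carbamidomethyl fixed Cys modification, default FALSE.
#' @return list with `calls` (data.frame: protein, group, n_matched,
#'   coverage, present) and `matches` (per observation detail, including
#'   an `ambiguous` flag).
#' @export
match_and_cover <- function(observed, db, tol_ppm = 10, max_missed = 1L,
                            min_len = 5L, presence_threshold = 0.5,
                            carbamidomethyl = FALSE) {
  stopifnot(is.data.frame(observed), "group" %in% names(observed),
            length(db) > 0, tol_ppm > 0)
  by_sequence <- "peptide" %in% names(observed)
  if (!by_sequence && !"mass" %in% names(observed))
    stop("observations need a 'mass' or 'peptide' column")
  theo <- theoretical_peptides(db, max_missed, min_len, carbamidomethyl)
  groups <- unique(observed$group)
  matches <- list()
  calls <- list()
  for (g in groups) {
    obs <- observed[observed$group == g, , drop = FALSE]
    hit_rows <- lapply(seq_len(nrow(obs)), function(i) {
      if (by_sequence) which(theo$sequence == obs$peptide[i])
      else which(abs(obs$mass[i] - theo$mass) / theo$mass <= tol_ppm * 1e-6)
    })
    for (i in seq_along(hit_rows)) {
      h <- hit_rows[[i]]
      if (!length(h)) next
      ambiguous <- length(unique(theo$protein[h])) > 1L
      matches[[length(matches) + 1L]] <- data.frame(
        group = g,
        observed = if (by_sequence) obs$peptide[i] else as.character(obs$mass[i]),
        protein = theo$protein[h], peptide = theo$sequence[h],
        start = theo$start[h], end = theo$end[h],
        ambiguous = ambiguous)
    }
    hit <- theo[unlist(hit_rows), , drop = FALSE]
    for (p in names(db)) {
      plen <- nchar(db[[p]])
      covered <- logical(plen)
      hp <- hit[hit$protein == p, , drop = FALSE]
      for (r in seq_len(nrow(hp))) covered[hp$start[r]:hp$end[r]] <- TRUE
      cov <- sum(covered) / plen
      calls[[length(calls) + 1L]] <- data.frame(
        protein = p, group = g,
        n_matched = length(unique(hp$sequence)),
        coverage = cov, present = cov > presence_threshold)
    }
  }
  list(calls = do.call(rbind, calls),
       matches = if (length(matches)) do.call(rbind, matches) else
         data.frame(group = character(0), observed = character(0),
                    protein = character(0), peptide = character(0),
                    start = integer(0), end = integer(0),
                    ambiguous = logical(0)))
}
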