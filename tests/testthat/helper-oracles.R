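# Independent oracles used across the suite. These re-derive expected
# values from first principles and deliberately avoid the package's own
# code paths.

# Benjamini-Hochberg step-up, written directly from the definition:
# sort p ascending, q_(i) = min(1, min_{j >= i} n * p_(j) / j).
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# Naive ungapped identity between two equal-length proteins.
positional_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  mean(va == vb)
}

# Two clusterings (named label vectors over the same ids) describe the
# same partition iff their label pairs are in bijection.
partition_equal <- function(a, b) {
  b <- b[names(a)]
  !anyNA(b) &&
    length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Random in-frame coding sequence over codons with degenerate families
# (used to build toy curation inputs without simulate_family).
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    pool <- c("CTT", "GTT", "TCT", "CCT", "ACT", "GCT", "GGT", "CGT",
              "AAA", "GAA", "TTC", "CAC")
    paste(c("ATG", sample(pool, n_codons - 2L, TRUE), "TAA"), collapse = "")
  })
}

# Pooled two-sample t computed longhand (closed form), as a cross-check
# for the vectorized implementation.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Default expression fixture shared by several tests.
sim_expression_fixture <- function(seed, dispersion = 0.05, n_null = 50L) {
  ge <- study_gene_effects(n_null = n_null)
  spec <- expression_sim_spec(ge$gene_effects, ge$gene_lengths,
                              dispersion = dispersion, seed = seed)
  c(simulate_counts(spec), list(classes = ge$classes))
}
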