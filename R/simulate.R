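## Seeded synthetic-data generators with recorded ground truth: transcript
## families containing allelic variants and close paralogs, negative-
## binomial count matrices over the 2x3x3 design, and secretome peptide
## mass lists. All randomness flows from the single seed in each spec
## (withr::with_seed, so the caller's RNG state is untouched).

## ---- transcript families -------------------------------------------------

# Codon pool for background coding sequence: residues with 4-fold
# third-position degeneracy, so every codon has a synonymous single-nt
# neighbour and no single substitution is forced to create a stop.
SAFE_CODONS <- c("CTT", "GTT", "TCT", "CCT", "ACT", "GCT", "GGT", "CGT")

#' Specification for a simulated AMP family
#'
#' Parameterizes exactly the confounders that curation must resolve:
#' multiple genes per family, allelic variants per gene with controlled
#' synonymous and nonsynonymous differences, and truncated fragments.
#' Allele i > 1 of a gene carries `syn_subs_per_allele` synonymous and
#' `nonsyn_subs_per_allele` nonsynonymous single-nucleotide substitutions
#' relative to the gene reference (allele 1), each at a distinct codon.
#' Gene references diverge from the family base by `gene_syn_subs` /
#' `gene_nonsyn_subs` substitutions at gene-private codons (defaults: the
#' per-allele counts).
#'
#' @param n_genes genes in the family.
#' @param alleles_per_gene transcripts per gene (allele 1 = reference).
#' @param base_length_nt coding length in nt including start and stop;
#'   multiple of 3.
#' @param syn_subs_per_allele,nonsyn_subs_per_allele substitutions per
#'   non-reference allele.
#' @param gene_syn_subs,gene_nonsyn_subs substitutions separating each
#'   gene reference from the family base.
#' @param fragment_fraction proportion of emitted transcripts truncated
#'   below half length (5' end kept), in [0, 1].
#' @param family family label used in truth records.
#' @param seed integer seed.
#' @return object of class `family_sim_spec`.
#' @export
family_sim_spec <- function(n_genes = 2L, alleles_per_gene = 2L,
                            base_length_nt = 300L,
                            syn_subs_per_allele = 2L,
                            nonsyn_subs_per_allele = 1L,
                            gene_syn_subs = syn_subs_per_allele,
                            gene_nonsyn_subs = nonsyn_subs_per_allele,
                            fragment_fraction = 0,
                            family = "famA", seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               alleles_per_gene = as.integer(alleles_per_gene),
               base_length_nt = as.integer(base_length_nt),
               syn_subs_per_allele = as.integer(syn_subs_per_allele),
               nonsyn_subs_per_allele = as.integer(nonsyn_subs_per_allele),
               gene_syn_subs = as.integer(gene_syn_subs),
               gene_nonsyn_subs = as.integer(gene_nonsyn_subs),
               fragment_fraction = fragment_fraction,
               family = family, seed = as.integer(seed))
  with(spec, {
    if (base_length_nt %% 3L != 0L) stop("base_length_nt must be a multiple of 3")
    if (any(c(n_genes, alleles_per_gene) < 1L))
      stop("n_genes and alleles_per_gene must be >= 1")
    if (any(c(syn_subs_per_allele, nonsyn_subs_per_allele,
              gene_syn_subs, gene_nonsyn_subs) < 0L))
      stop("substitution counts must be non-negative")
    if (fragment_fraction < 0 || fragment_fraction > 1)
      stop("fragment_fraction must be in [0, 1]")
  })
  structure(spec, class = "family_sim_spec")
}

syn_variant <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  cand <- single_nt_variants(codon)
  cand[gc[cand] == aa]
}

nonsyn_variant <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  cand <- single_nt_variants(codon)
  cand[gc[cand] != aa & gc[cand] != "*"]
}

single_nt_variants <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) for (nt in setdiff(nts, s[pos])) {
    v <- s; v[pos] <- nt
    out <- c(out, paste(v, collapse = ""))
  }
  out
}

pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

apply_subs <- function(codons, sites, type) {
  for (s in sites) {
    codons[s] <- pick1(if (type == "syn") syn_variant(codons[s])
                       else nonsyn_variant(codons[s]))
  }
  codons
}

#' Simulate a transcript family with known gene membership
#'
#' Emits one transcript per (gene, allele), with substitution counts
#' between variants matching the spec by construction (verified post hoc by
#' brute-force codon comparison). Optionally truncates a fraction of
#' transcripts below half length to exercise the coverage filter.
#' Identical seeds give identical output.
#'
#' @param spec a [family_sim_spec()].
#' @return list with `sequences` (named character, coding nucleotide
#'   sequences) and `truth` (data.frame: id, gene, family, allele,
#'   is_fragment).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_sim_spec"))
  withr::with_seed(spec$seed, {
    n_cod <- spec$base_length_nt %/% 3L
    if (n_cod < 3L) stop("base_length_nt too short")
    body <- sample(SAFE_CODONS, n_cod - 2L, replace = TRUE)
    base <- c("ATG", body, "TAA")
    # mutable codon indices (exclude start and stop)
    free <- 2:(n_cod - 1L)
    per_gene_subs <- spec$gene_syn_subs + spec$gene_nonsyn_subs
    per_allele_subs <- spec$syn_subs_per_allele + spec$nonsyn_subs_per_allele
    need <- spec$n_genes * (per_gene_subs +
                              (spec$alleles_per_gene - 1L) * per_allele_subs)
    if (need > length(free))
      stop("base_length_nt too short for the requested substitution counts")
    sites <- sample(free, need)   # distinct codons for every substitution
    take <- local({
      i <- 0L
      function(k) { if (k == 0L) return(integer(0)); out <- sites[(i + 1L):(i + k)]; i <<- i + k; out }
    })
    seqs <- character(0); truth <- list()
    for (g in seq_len(spec$n_genes)) {
      gene_ref <- base
      if (g > 1L) {
        gene_ref <- apply_subs(gene_ref, take(spec$gene_nonsyn_subs), "nonsyn")
        gene_ref <- apply_subs(gene_ref, take(spec$gene_syn_subs), "syn")
      }
      for (a in seq_len(spec$alleles_per_gene)) {
        al <- gene_ref
        if (a > 1L) {
          al <- apply_subs(al, take(spec$nonsyn_subs_per_allele), "nonsyn")
          al <- apply_subs(al, take(spec$syn_subs_per_allele), "syn")
        }
        id <- sprintf("%s_g%da%d", spec$family, g, a)
        seqs[id] <- paste(al, collapse = "")
        truth[[id]] <- data.frame(id = id, gene = sprintf("%s_g%d", spec$family, g),
                                  family = spec$family, allele = a,
                                  is_fragment = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    # post-hoc construction check: brute-force codon comparison of each
    # allele against its gene reference must reproduce the spec counts
    for (g in seq_len(spec$n_genes)) for (a in seq_len(spec$alleles_per_gene)) {
      if (a == 1L) next
      d <- brute_force_diffs(seqs[sprintf("%s_g%da1", spec$family, g)],
                             seqs[sprintf("%s_g%da%d", spec$family, g, a)])
      if (d$nt_total != per_allele_subs ||
          d$aa_diffs != spec$nonsyn_subs_per_allele)
        stop("internal error: constructed substitution counts do not match spec")
    }
    if (spec$fragment_fraction > 0) {
      n_frag <- round(spec$fragment_fraction * length(seqs))
      frag_ids <- sample(names(seqs), n_frag)
      for (id in frag_ids) {
        keep_cod <- max(2L, floor(n_cod * runif(1, 0.25, 0.45)))
        seqs[id] <- substring(seqs[id], 1L, keep_cod * 3L)
        truth$is_fragment[truth$id == id] <- TRUE
      }
    }
    rownames(truth) <- NULL
    list(sequences = seqs, truth = truth)
  })
}

#' Brute-force codon-by-codon difference counts
#'
#' Independent of the alignment machinery: compares two equal-length,
#' in-frame coding sequences codon by codon. Used as the oracle for
#' [count_differences()] and as the post-hoc check inside
#' [simulate_family()].
#'
#' @param cds_a,cds_b equal-length in-frame coding sequences.
#' @return list `nt_total`, `aa_changing`, `aa_diffs`.
#' @export
brute_force_diffs <- function(cds_a, cds_b) {
  stopifnot(nchar(cds_a) == nchar(cds_b))
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  pa <- translate_codons(ca); pb <- translate_codons(cb)
  nt_total <- aa_changing <- aa_diffs <- 0L
  for (i in seq_along(ca)) {
    if (pa[i] == "*" && pb[i] == "*") next
    nd <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    nt_total <- nt_total + nd
    if (pa[i] != pb[i]) {
      aa_diffs <- aa_diffs + 1L
      aa_changing <- aa_changing + nd
    }
  }
  list(nt_total = nt_total, aa_changing = aa_changing, aa_diffs = aa_diffs)
}

## ---- count matrices ------------------------------------------------------

#' Specification for a simulated count matrix
#'
#' Counts are drawn per gene and sample from a negative-binomial model with
#' mean = true RPKM x length_bp x depth / 1e9 and variance
#' mean + dispersion x mean^2 (`dispersion = 0` gives the Poisson limit).
#' The default depth, 30 million mapped reads per sample, matches typical
#' whole-adult RNA-seq library sizes for this design.
#'
#' @param gene_effects numeric matrix of true mean expression on the RPKM
#'   scale: genes x the six groups ([amp_groups()] column order).
#' @param gene_lengths transcript lengths in bp, named by gene or in row
#'   order.
#' @param design sample design data.frame, default the full 18-sample
#'   [default_design()].
#' @param depth_per_sample total mapped reads per sample (scalar or per
#'   sample), default 3e7.
#' @param dispersion negative-binomial overdispersion, default 0.05.
#' @param seed integer seed.
#' @return object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(gene_effects, gene_lengths,
                                design = default_design(),
                                depth_per_sample = 3e7,
                                dispersion = 0.05, seed = 1L) {
  gene_effects <- as.matrix(gene_effects)
  stopifnot(!is.null(rownames(gene_effects)),
            identical(colnames(gene_effects), AMP_GROUPS))
  if (!is.null(names(gene_lengths))) gene_lengths <- gene_lengths[rownames(gene_effects)]
  stopifnot(length(gene_lengths) == nrow(gene_effects), all(gene_lengths > 0))
  design <- validate_design(design)
  if (nrow(design) == 0L) stop("empty design")
  if (any(depth_per_sample <= 0)) stop("depth must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(gene_effects = gene_effects,
                 gene_lengths = setNames(as.numeric(gene_lengths),
                                         rownames(gene_effects)),
                 design = design,
                 depth_per_sample = rep(depth_per_sample,
                                        length.out = nrow(design)),
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' True log2 fold changes implied by a gene-effects matrix
#'
#' @param gene_effects genes x groups matrix of true RPKM means.
#' @param contrasts contrast names, default [amp_contrasts()].
#' @return genes x contrasts matrix of log2(first group / second group).
#' @export
true_log2fc <- function(gene_effects, contrasts = amp_contrasts()) {
  out <- vapply(contrasts, function(cn) {
    gr <- parse_contrast(cn)
    log2(gene_effects[, gr[1L]] / gene_effects[, gr[2L]])
  }, numeric(nrow(gene_effects)))
  rownames(out) <- rownames(gene_effects)
  out
}

#' Simulate a mapped-read count matrix with known effects
#'
#' @param spec an [expression_sim_spec()].
#' @return list with `counts` (an `amp_counts` object whose totals are the
#'   simulated depths), `design`, and `truth` (list: `gene_effects`,
#'   `log2fc` gene x contrast matrix).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  withr::with_seed(spec$seed, {
    des <- spec$design
    ng <- nrow(spec$gene_effects); ns <- nrow(des)
    mu <- matrix(0, ng, ns, dimnames = list(rownames(spec$gene_effects),
                                            des$sample))
    for (j in seq_len(ns)) {
      rpkm <- spec$gene_effects[, des$group[j]]
      mu[, j] <- rpkm * spec$gene_lengths * spec$depth_per_sample[j] / 1e9
    }
    counts <- if (spec$dispersion == 0)
      matrix(rpois(ng * ns, mu), ng, ns, dimnames = dimnames(mu))
    else
      matrix(rnbinom(ng * ns, size = 1 / spec$dispersion, mu = mu),
             ng, ns, dimnames = dimnames(mu))
    cm <- count_matrix(counts, spec$gene_lengths,
                       totals = pmax(setNames(spec$depth_per_sample, des$sample),
                                     colSums(counts)))
    list(counts = cm, design = des,
         truth = list(gene_effects = spec$gene_effects,
                      log2fc = true_log2fc(spec$gene_effects)))
  })
}

#' Study-like gene-effects panel
#'
#' Builds a true-expression matrix emulating the qualitative expression
#' classes reported for burying-beetle immune effectors: carcass-induced
#' (up in C and CL), carcass-repressed, parenting-induced (up in CL in
#' females), female- and male-biased genes, stable housekeeping genes, and
#' null background genes.
#'
#' @param n_null background genes with no effect.
#' @param n_housekeeping stable reference-style genes, default 12 (the
#'   ribosomal-protein / elongation-factor panel size used for the
#'   normalization check).
#' @param base_rpkm expression of unaffected genes, default 10.
#' @param housekeeping_rpkm expression of housekeeping genes, default 200.
#' @param fold effect size for induced/repressed/sex-biased genes,
#'   default 4.
#' @return list `gene_effects` (matrix), `gene_lengths`, `classes` (named
#'   character: gene -> class).
#' @export
study_gene_effects <- function(n_null = 50L, n_housekeeping = 12L,
                               base_rpkm = 10, housekeeping_rpkm = 200,
                               fold = 4) {
  rows <- list()
  cls <- character(0)
  add <- function(name, class, M, C, CL, Mf = M, Cf = C, CLf = CL) {
    rows[[name]] <<- c(Mm = M, Mf = Mf, Cm = C, Cf = Cf, CLm = CL, CLf = CLf)
    cls[name] <<- class
  }
  add("carcass_induced_1", "carcass_induced",
      base_rpkm, base_rpkm * fold, base_rpkm * fold)
  add("carcass_induced_2", "carcass_induced",
      base_rpkm, base_rpkm * fold, base_rpkm * fold)
  add("carcass_repressed_1", "carcass_repressed",
      base_rpkm * fold, base_rpkm, base_rpkm)
  add("parenting_induced_f", "parenting_induced_female",
      base_rpkm, base_rpkm, base_rpkm,
      base_rpkm, base_rpkm, base_rpkm * fold)
  add("female_biased_1", "female_biased",
      base_rpkm, base_rpkm, base_rpkm,
      base_rpkm * fold, base_rpkm * fold, base_rpkm * fold)
  add("male_biased_1", "male_biased",
      base_rpkm * fold, base_rpkm * fold, base_rpkm * fold,
      base_rpkm, base_rpkm, base_rpkm)
  for (i in seq_len(n_housekeeping))
    add(sprintf("housekeeping_%02d", i), "housekeeping",
        housekeeping_rpkm, housekeeping_rpkm, housekeeping_rpkm)
  for (i in seq_len(n_null))
    add(sprintf("null_%03d", i), "null", base_rpkm, base_rpkm, base_rpkm)
  ge <- do.call(rbind, rows)
  list(gene_effects = ge,
       gene_lengths = setNames(rep(1000, nrow(ge)), rownames(ge)),
       classes = cls)
}

## ---- secretome -----------------------------------------------------------

#' Specification for simulated secretome observations
#'
#' @param presence named list: protein id -> character vector of groups
#'   (subset of [amp_groups()]) in which the protein is present.
#' @param peptide_detection_rate probability that a tryptic peptide of a
#'   present protein is observed, in [0, 1]; default 0.9.
#' @param mass_noise_ppm ppm scale of Gaussian mass error, default 2.
#' @param n_decoy_masses decoy masses added per group, default 20.
#' @param max_missed,min_len digestion parameters used for the true
#'   peptides, defaults 1 and 5.
#' @param seed integer seed.
#' @return object of class `secretome_sim_spec`.
#' @export
secretome_sim_spec <- function(presence, peptide_detection_rate = 0.9,
                               mass_noise_ppm = 2, n_decoy_masses = 20L,
                               max_missed = 1L, min_len = 5L, seed = 1L) {
  stopifnot(is.list(presence), length(presence) > 0, !is.null(names(presence)))
  bad <- setdiff(unlist(presence), AMP_GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (peptide_detection_rate < 0 || peptide_detection_rate > 1)
    stop("detection rate must be in [0, 1]")
  if (mass_noise_ppm < 0) stop("mass noise must be >= 0")
  structure(list(presence = presence,
                 peptide_detection_rate = peptide_detection_rate,
                 mass_noise_ppm = mass_noise_ppm,
                 n_decoy_masses = as.integer(n_decoy_masses),
                 max_missed = as.integer(max_missed),
                 min_len = as.integer(min_len),
                 seed = as.integer(seed)),
            class = "secretome_sim_spec")
}

#' Simulate observed peptide masses per sample group
#'
#' For each of the six groups, the observed mass list is a detection-rate
#' subsample of the in-silico tryptic peptide masses of the proteins
#' present in that group, perturbed by Gaussian ppm noise, plus decoy
#' masses. Decoys are sampled uniformly over the observed mass range and
#' rejection-sampled to lie at least 1 Da from every theoretical peptide
#' mass of every protein, so downstream matcher specificity is testable.
#'
#' @param spec a [secretome_sim_spec()].
#' @param proteins named character vector of protein sequences (must cover
#'   every protein named in `spec$presence`).
#' @return list with `observed` (data.frame: group, mass, is_decoy) and
#'   `truth` (data.frame: protein, group, present).
#' @export
simulate_secretome <- function(spec, proteins) {
  stopifnot(inherits(spec, "secretome_sim_spec"), length(proteins) > 0,
            !is.null(names(proteins)))
  missing <- setdiff(names(spec$presence), names(proteins))
  if (length(missing)) stop("no sequence for protein(s): ",
                            paste(missing, collapse = ", "))
  withr::with_seed(spec$seed, {
    theo <- theoretical_peptides(proteins[names(spec$presence)],
                                 spec$max_missed, spec$min_len)
    all_masses <- theo$mass
    lo <- min(all_masses) - 5; hi <- max(all_masses) + 5
    obs <- list()
    for (g in AMP_GROUPS) {
      present <- names(spec$presence)[vapply(spec$presence, function(x)
        g %in% x, logical(1))]
      tp <- theo[theo$protein %in% present, , drop = FALSE]
      keep <- runif(nrow(tp)) < spec$peptide_detection_rate
      m <- tp$mass[keep]
      m <- m * (1 + rnorm(length(m)) * spec$mass_noise_ppm * 1e-6)
      decoys <- numeric(0)
      while (length(decoys) < spec$n_decoy_masses) {
        cand <- runif(spec$n_decoy_masses, lo, hi)
        ok <- vapply(cand, function(x) min(abs(x - all_masses)) >= 1, logical(1))
        decoys <- c(decoys, cand[ok])
      }
      decoys <- decoys[seq_len(spec$n_decoy_masses)]
      if (length(m) + length(decoys) > 0)
        obs[[g]] <- data.frame(group = g, mass = c(m, decoys),
                               is_decoy = rep(c(FALSE, TRUE),
                                              c(length(m), length(decoys))))
    }
    truth <- expand.grid(protein = names(spec$presence), group = AMP_GROUPS,
                         stringsAsFactors = FALSE)
    truth$present <- mapply(function(p, g) g %in% spec$presence[[p]],
                            truth$protein, truth$group)
    list(observed = do.call(rbind, c(obs, list(make.row.names = FALSE))),
         truth = truth)
  })
}
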