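## Candidate curation: translation, family assignment, coverage filtering,
## and the allele-vs-paralog adjudication that collapses transcript variants
## into a conservative set of genes.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

codons_of <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"   # ambiguity codes (N etc.) become X
  aa
}

translate_nt <- function(x) paste(translate_codons(codons_of(x)), collapse = "")

#' Find the longest open reading frame across six frames
#'
#' An ORF starts at ATG and runs to the first in-frame stop codon or, for
#' fragments missing their 3' end, to the end of the frame. Both strands and
#' all three frame offsets are searched.
#'
#' @param nt_seq nucleotide sequence (character scalar, `ACGTN` alphabet).
#' @param min_orf_aa minimum protein length (stop excluded) to accept.
#' @return list with `cds` (coding nucleotide sequence, stop included when
#'   present), `protein` (trailing stop removed), `strand`, `frame`; or
#'   `NULL` when no ORF reaches `min_orf_aa`.
#' @export
find_longest_orf <- function(nt_seq, min_orf_aa = 30L) {
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt_seq else revcomp(nt_seq)
    for (off in 0:2) {
      frame_seq <- substring(s, 1L + off, nchar(s))
      cod <- codons_of(frame_seq)
      if (!length(cod)) next
      aa <- translate_codons(cod)
      starts <- which(aa == "M")
      stops <- which(aa == "*")
      for (st in starts) {
        nx <- stops[stops >= st]
        en <- if (length(nx)) nx[1L] else length(aa)  # open-ended fragment
        prot_len <- if (length(nx)) en - st else en - st + 1L
        if (prot_len < min_orf_aa) next
        if (is.null(best) || prot_len > best$len) {
          cds <- paste(cod[st:en], collapse = "")
          prot <- paste(aa[st:en][aa[st:en] != "*"], collapse = "")
          best <- list(cds = cds, protein = prot, strand = strand,
                       frame = off + 1L, len = prot_len)
        }
      }
    }
  }
  if (is.null(best)) NULL else best[c("cds", "protein", "strand", "frame")]
}

#' Translate candidate transcripts
#'
#' Translates each transcript either from a supplied CDS hint (1-based
#' inclusive coordinates on the forward strand) or from the longest open
#' reading frame across six frames. Trailing stop codons are removed;
#' in-frame ambiguity codes yield `X`. Transcripts with no ORF of at least
#' `min_orf_aa` residues are flagged `untranslatable` and excluded from all
#' downstream steps.
#'
#' @param transcripts data.frame with columns `id`, `nt_seq`, and optionally
#'   `cds_start`, `cds_end`.
#' @param min_orf_aa minimum ORF length in amino acids (default 30).
#' @return the input data.frame with added columns `cds_seq`, `protein`,
#'   and `status` (`translated` or `untranslatable`).
#' @export
translate_candidates <- function(transcripts, min_orf_aa = 30L) {
  stopifnot(is.data.frame(transcripts), all(c("id", "nt_seq") %in% names(transcripts)))
  if (anyDuplicated(transcripts$id))
    stop("duplicate transcript ids: ",
         paste(unique(transcripts$id[duplicated(transcripts$id)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", toupper(transcripts$nt_seq))
  if (any(bad))
    stop("non-nucleotide characters in: ",
         paste(transcripts$id[bad], collapse = ", "))
  n <- nrow(transcripts)
  cds <- prot <- character(n)
  status <- rep("translated", n)
  has_hint <- if (all(c("cds_start", "cds_end") %in% names(transcripts)))
    !is.na(transcripts$cds_start) & !is.na(transcripts$cds_end)
  else rep(FALSE, n)
  for (i in seq_len(n)) {
    s <- toupper(transcripts$nt_seq[i])
    if (has_hint[i]) {
      a <- transcripts$cds_start[i]; b <- transcripts$cds_end[i]
      if (a < 1L || b > nchar(s) || (b - a + 1L) %% 3L != 0L)
        stop("invalid cds hint for ", transcripts$id[i])
      cds[i] <- substring(s, a, b)
      p <- translate_nt(cds[i])
      prot[i] <- sub("\\*$", "", p)
    } else {
      orf <- find_longest_orf(s, min_orf_aa)
      if (is.null(orf)) {
        status[i] <- "untranslatable"
      } else {
        cds[i] <- orf$cds
        prot[i] <- orf$protein
      }
    }
  }
  transcripts$cds_seq <- cds
  transcripts$protein <- prot
  transcripts$status <- status
  transcripts
}

aln_params <- function() {
  list(substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
}

pair_align <- function(pattern, subject, type = "global") {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    type = type, substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
}

aln_identity <- function(aln) {
  # matches over alignment length including gap columns
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / len
}

#' Assign a protein to an AMP/lysozyme family
#'
#' Aligns the protein globally against every entry of a reference family
#' panel and returns the family of the best-scoring alignment, provided the
#' alignment identity (matches over alignment length) reaches
#' `min_identity`. Score ties are broken by higher identity, then by
#' lexicographic family label.
#'
#' @param protein amino-acid sequence (character scalar).
#' @param panel data.frame with columns `family` and `protein` (one row per
#'   reference sequence), as returned by [read_panel()].
#' @param min_identity minimum alignment identity, default 0.40.
#' @return family label, or `NA_character_` when unassigned.
#' @export
assign_family <- function(protein, panel, min_identity = 0.40) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0,
            all(c("family", "protein") %in% names(panel)))
  if (!nzchar(protein)) stop("empty protein sequence")
  score <- ident <- numeric(nrow(panel))
  for (j in seq_len(nrow(panel))) {
    aln <- pair_align(protein, panel$protein[j])
    score[j] <- Biostrings::score(aln)
    ident[j] <- aln_identity(aln)
  }
  ok <- ident >= min_identity
  if (!any(ok)) return(NA_character_)
  ord <- order(-score, -ident, panel$family)
  ord <- ord[ok[ord]][1L]
  panel$family[ord]
}

#' Remove family members covering less than half the coding region
#'
#' Within one family, each member protein is aligned to the family
#' reference (the longest member) and its coverage is the fraction of
#' reference residues aligned to a member residue. Members with coverage
#' strictly below `min_coverage` are removed; exactly at the threshold they
#' are retained.
#'
#' @param proteins named character vector of member protein sequences.
#' @param min_coverage removal threshold, default 0.5.
#' @return data.frame with `id`, `coverage`, `retained`.
#' @export
coverage_filter <- function(proteins, min_coverage = 0.5) {
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  if (length(proteins) == 1L)
    return(data.frame(id = names(proteins), coverage = 1, retained = TRUE))
  ref_i <- order(-nchar(proteins), names(proteins))[1L]
  ref <- proteins[[ref_i]]
  cov <- vapply(seq_along(proteins), function(i) {
    if (i == ref_i || nchar(proteins[[i]]) >= nchar(ref)) return(1)
    aln <- pair_align(proteins[[i]], ref, type = "global-local")
    (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) / nchar(ref)
  }, numeric(1))
  data.frame(id = names(proteins), coverage = cov,
             retained = cov >= min_coverage)
}

#' Count nucleotide and amino-acid differences between two coding sequences
#'
#' The two proteins are aligned globally and the alignment is back-projected
#' onto the coding nucleotide sequences, so that comparisons are codon-aware.
#' Over aligned, non-gap codon columns it reports the total number of
#' nucleotide differences (`nt_total`), the number of nucleotide differences
#' falling in codons whose encoded amino acid differs (`aa_changing`), and
#' the number of differing amino-acid positions (`aa_diffs`). Gap columns
#' are excluded from all three counts and reported as `gap_columns`.
#'
#' @param cds_a,cds_b coding nucleotide sequences (in-frame, from
#'   [translate_candidates()]).
#' @return list with `nt_total`, `aa_changing`, `aa_diffs`, `gap_columns`.
#' @export
count_differences <- function(cds_a, cds_b) {
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  # drop stop codons from comparison
  pa <- translate_codons(ca); pb <- translate_codons(cb)
  ca <- ca[pa != "*"]; cb <- cb[pb != "*"]
  pa <- pa[pa != "*"]; pb <- pb[pb != "*"]
  # fast path: equal-length in-frame sequences with low mismatch density
  # are compared positionally (no indels to resolve); dense mismatch
  # patterns fall back to the alignment, which would recover e.g.
  # compensating indels
  if (length(pa) == length(pb) && length(pa) > 0L) {
    mism <- pa != pb
    if (mean(mism) <= 0.2) {
      nt_total <- aa_changing <- 0L
      for (i in seq_along(ca)) {
        nd <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
        nt_total <- nt_total + nd
        if (mism[i]) aa_changing <- aa_changing + nd
      }
      return(list(nt_total = nt_total, aa_changing = aa_changing,
                  aa_diffs = sum(mism), gap_columns = 0L))
    }
  }
  aln <- pair_align(paste(pa, collapse = ""), paste(pb, collapse = ""))
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  nt_total <- aa_changing <- aa_diffs <- gap_cols <- 0L
  any_aligned <- FALSE
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (ga && gb) next
    if (ga || gb) {
      gap_cols <- gap_cols + 1L
      if (!ga) ia <- ia + 1L
      if (!gb) ib <- ib + 1L
      next
    }
    ia <- ia + 1L; ib <- ib + 1L
    any_aligned <- TRUE
    nd <- sum(strsplit(ca[ia], "")[[1]] != strsplit(cb[ib], "")[[1]])
    nt_total <- nt_total + nd
    if (sa[k] != sb[k]) {
      aa_diffs <- aa_diffs + 1L
      aa_changing <- aa_changing + nd
    }
  }
  if (!any_aligned) stop("sequences share no aligned codon columns")
  list(nt_total = nt_total, aa_changing = aa_changing,
       aa_diffs = aa_diffs, gap_columns = gap_cols)
}

#' Decide whether two transcript variants are alleles or distinct genes
#'
#' Variants showing zero or a single amino-acid difference are collapsed as
#' redundant (allelic). Variants with few amino-acid differences (up to
#' `few_aa_threshold`) are assigned to different genes only when the total
#' number of nucleotide differences exceeds the number of nucleotide changes
#' responsible for the amino-acid differences, i.e. when synonymous
#' differences exist; otherwise they are treated as alleles. Larger
#' amino-acid divergence always separates genes.
#'
#' @param d difference counts from [count_differences()].
#' @param few_aa_threshold largest amino-acid difference count still
#'   subjected to the nucleotide-level rule (default 5).
#' @return `"same_gene"` or `"distinct_genes"`.
#' @export
adjudicate_pair <- function(d, few_aa_threshold = 5L) {
  stopifnot(d$nt_total >= 0, d$aa_changing <= d$nt_total,
            d$aa_diffs <= d$aa_changing)
  if (d$aa_diffs <= 1L) return("same_gene")
  if (d$aa_diffs <= few_aa_threshold) {
    if (d$nt_total > d$aa_changing) "distinct_genes" else "same_gene"
  } else "distinct_genes"
}

#' Cluster transcripts of one family into genes
#'
#' Connected components (single linkage) of the `same_gene` relation over
#' all retained pairs. Conflicting verdicts inside a component (a pair
#' judged distinct whose members are nevertheless linked through others)
#' are kept in one cluster, conservatively, and reported as conflicts. The
#' representative is the longest member, ties broken by lexicographically
#' smallest id.
#'
#' @param ids transcript ids.
#' @param lengths member lengths (same order as `ids`), used to pick
#'   representatives.
#' @param verdicts data.frame with columns `a`, `b`, `verdict` covering all
#'   unordered pairs of `ids`.
#' @return list with `clusters` (data.frame `gene_id`, `family` absent here,
#'   `representative`, `members` semicolon-joined), `membership` (named
#'   vector id -> gene_id), `conflicts` (data.frame of conflicting pairs).
#' @export
cluster_candidates <- function(ids, lengths, verdicts) {
  stopifnot(length(ids) == length(lengths))
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(verdicts)) {
    for (r in seq_len(nrow(verdicts))) {
      if (verdicts$verdict[r] == "same_gene") {
        ra <- find(match(verdicts$a[r], ids)); rb <- find(match(verdicts$b[r], ids))
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  conflicts <- if (nrow(verdicts)) {
    dd <- verdicts[verdicts$verdict == "distinct_genes", , drop = FALSE]
    same_comp <- comp[match(dd$a, ids)] == comp[match(dd$b, ids)]
    dd[same_comp, c("a", "b"), drop = FALSE]
  } else data.frame(a = character(0), b = character(0))
  out <- lapply(split(seq_along(ids), comp), function(ix) {
    mem <- ids[ix]
    rep_id <- mem[order(-lengths[ix], mem)][1L]
    list(representative = rep_id, members = mem)
  })
  # deterministic cluster order: by representative id
  out <- out[order(vapply(out, `[[`, "", "representative"))]
  clusters <- data.frame(
    gene_id = sprintf("gene_%03d", seq_along(out)),
    representative = vapply(out, `[[`, "", "representative"),
    n_members = vapply(out, function(o) length(o$members), integer(1)),
    members = vapply(out, function(o) paste(sort(o$members), collapse = ";"), "")
  )
  membership <- setNames(
    rep(clusters$gene_id, clusters$n_members),
    unlist(lapply(out, function(o) o$members)))
  list(clusters = clusters, membership = membership[ids], conflicts = conflicts)
}

#' Curate candidate transcripts into AMP/lysozyme genes
#'
#' Full curation pipeline: six-frame translation, family assignment against
#' a reference panel, removal of members covering less than half of the
#' family coding region, and collapse of allelic/redundant variants into
#' genes by the nucleotide-versus-amino-acid adjudication rule. Every input
#' transcript ends in exactly one terminal status (`untranslatable`,
#' `unassigned`, `removed_low_coverage`, `collapsed`, or `retained`).
#'
#' @param transcripts data.frame with `id`, `nt_seq` and optional
#'   `cds_start`/`cds_end` columns.
#' @param panel family panel data.frame (`family`, `protein`).
#' @param min_orf_aa,min_identity,few_aa_threshold,min_coverage tuning
#'   parameters; see the individual stage functions.
#' @return list with `genes` (data.frame: gene_id, family, representative,
#'   n_members, members), `transcripts` (input plus `family`, `gene_id`,
#'   `status`), `log` (one record per filter decision), `conflicts`.
#' @export
curate_candidates <- function(transcripts, panel, min_orf_aa = 30L,
                              min_identity = 0.40, few_aa_threshold = 5L,
                              min_coverage = 0.5) {
  tr <- translate_candidates(transcripts, min_orf_aa)
  tr$family <- NA_character_
  tr$gene_id <- NA_character_
  log <- list()
  note <- function(stage, id, action, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, id = id,
                                           action = action, detail = detail)
  }
  for (i in which(tr$status == "untranslatable"))
    note("translate", tr$id[i], "untranslatable", "no ORF >= min_orf_aa")
  ok <- tr$status == "translated"
  for (i in which(ok)) {
    fam <- assign_family(tr$protein[i], panel, min_identity)
    if (is.na(fam)) {
      tr$status[i] <- "unassigned"
      note("assign", tr$id[i], "unassigned", "below min_identity to all families")
    } else tr$family[i] <- fam
  }
  conflicts <- list()
  genes <- list()
  for (fam in sort(unique(stats::na.omit(tr$family)))) {
    ix <- which(!is.na(tr$family) & tr$family == fam & tr$status == "translated")
    prots <- setNames(tr$protein[ix], tr$id[ix])
    covr <- coverage_filter(prots, min_coverage)
    for (r in seq_len(nrow(covr))) if (!covr$retained[r]) {
      j <- ix[match(covr$id[r], tr$id[ix])]
      tr$status[j] <- "removed_low_coverage"
      note("coverage", covr$id[r], "removed_low_coverage",
           sprintf("coverage=%.3f", covr$coverage[r]))
    }
    keep <- ix[tr$status[ix] == "translated"]
    if (!length(keep)) next
    kid <- tr$id[keep]
    verdicts <- data.frame(a = character(0), b = character(0), verdict = character(0))
    if (length(keep) > 1L) {
      pairs <- utils::combn(seq_along(keep), 2L)
      verdicts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
        i1 <- keep[pairs[1L, c2]]; i2 <- keep[pairs[2L, c2]]
        d <- count_differences(tr$cds_seq[i1], tr$cds_seq[i2])
        data.frame(a = tr$id[i1], b = tr$id[i2],
                   verdict = adjudicate_pair(d, few_aa_threshold))
      }))
    }
    cl <- cluster_candidates(kid, nchar(tr$cds_seq[keep]), verdicts)
    membership <- setNames(paste0(fam, "_", cl$membership), names(cl$membership))
    cl$clusters$gene_id <- paste0(fam, "_", cl$clusters$gene_id)
    cl$clusters$family <- fam
    for (id in kid) {
      gid <- membership[[id]]
      tr$gene_id[match(id, tr$id)] <- gid
      is_rep <- id %in% cl$clusters$representative
      tr$status[match(id, tr$id)] <- if (is_rep) "retained" else "collapsed"
      note("cluster", id, if (is_rep) "retained" else "collapsed",
           paste0("gene=", gid))
    }
    if (nrow(cl$conflicts)) {
      cl$conflicts$family <- fam
      conflicts[[fam]] <- cl$conflicts
      for (r in seq_len(nrow(cl$conflicts)))
        note("cluster", cl$conflicts$a[r], "conflict",
             paste0("linked to ", cl$conflicts$b[r],
                    " despite distinct_genes verdict"))
    }
    genes[[fam]] <- cl$clusters
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), representative = character(0),
               n_members = integer(0), members = character(0),
               family = character(0))
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "family", "representative", "n_members", "members")]
  list(genes = genes, transcripts = tr,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(stage = character(0), id = character(0),
                    action = character(0), detail = character(0)),
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(a = character(0), b = character(0), family = character(0)))
}

#' Per-family gene counts from a curation result
#'
#' @param curated result of [curate_candidates()].
#' @return data.frame `family`, `n_genes`, plus a `total` attribute.
#' @export
family_gene_counts <- function(curated) {
  tab <- table(curated$genes$family)
  out <- data.frame(family = names(tab), n_genes = as.integer(tab))
  attr(out, "total") <- sum(out$n_genes)
  out
}
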