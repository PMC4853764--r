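## RPKM quantification and differential expression over the 2-sex x
## 3-context design: pooled-variance t-tests per contrast with
## Benjamini-Hochberg correction and star annotation.

#' Construct a count matrix object
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns (both dimnames required).
#' @param lengths gene lengths in bp, named by gene or in row order.
#' @param totals per-sample total mapped reads. Defaults to column sums;
#'   totals may exceed column sums when the matrix holds a gene subset.
#' @return object of class `amp_counts`.
#' @export
count_matrix <- function(counts, lengths, totals = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts) || any(is.na(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive and cover every gene")
  if (is.null(totals)) totals <- colSums(counts)
  if (!is.null(names(totals))) totals <- totals[colnames(counts)]
  totals <- as.numeric(totals)
  if (length(totals) != ncol(counts) || any(is.na(totals)))
    stop("totals must cover every sample")
  if (any(totals < colSums(counts)))
    stop("per-sample totals below the column sums of included genes")
  structure(list(counts = counts,
                 lengths = setNames(lengths, rownames(counts)),
                 totals = setNames(totals, colnames(counts))),
            class = "amp_counts")
}

#' @export
print.amp_counts <- function(x, ...) {
  cat("amp_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("sample", "sex", "context", "replicate") %in% names(design)))
  if (!all(design$sex %in% AMP_SEXES)) stop("sex must be one of m, f")
  if (!all(design$context %in% AMP_CONTEXTS)) stop("context must be one of M, C, CL")
  key <- paste(design$sex, design$context, design$replicate)
  if (anyDuplicated(key)) stop("duplicate (sex, context, replicate) in design")
  if (anyDuplicated(design$sample)) stop("duplicate sample ids in design")
  design$group <- group_of(design$sex, design$context)
  design
}

#' The full 18-sample study design
#'
#' Two sexes by three contexts by `n_rep` biological replicates.
#'
#' @param n_rep replicates per (sex, context) cell, default 3.
#' @return design data.frame (`sample`, `sex`, `context`, `replicate`).
#' @export
default_design <- function(n_rep = 3L) {
  d <- expand.grid(replicate = seq_len(n_rep), sex = AMP_SEXES,
                   context = AMP_CONTEXTS, stringsAsFactors = FALSE)
  d <- d[, c("sex", "context", "replicate")]
  d$sample <- paste0(d$context, d$sex, "_r", d$replicate)
  d[, c("sample", "sex", "context", "replicate")]
}

#' RPKM quantification
#'
#' RPKM = count x 10^9 / (length_bp x total mapped reads). log2 values are
#' floored (`rpkm_floor`) so that zeros stay finite and below the
#' expression filter. Group means are geometric means over biological
#' replicates, i.e. arithmetic means of log2 RPKM.
#'
#' @param cm an `amp_counts` object from [count_matrix()].
#' @param design sample design data.frame.
#' @param rpkm_floor floor applied to RPKM before log2, default 2^-4.
#' @return object of class `amp_rpkm` with elements `rpkm`, `log2_rpkm`,
#'   `group_means` (gene x group mean log2 RPKM), `design`, `n_per_group`.
#' @export
compute_rpkm <- function(cm, design, rpkm_floor = 2^-4) {
  stopifnot(inherits(cm, "amp_counts"))
  design <- validate_design(design)
  missing <- setdiff(design$sample, colnames(cm$counts))
  if (length(missing)) stop("design samples absent from counts: ",
                            paste(missing, collapse = ", "))
  if (any(cm$totals <= 0)) stop("zero total mapped reads")
  counts <- cm$counts[, design$sample, drop = FALSE]
  totals <- cm$totals[design$sample]
  rpkm <- sweep(counts, 2L, totals, function(c, n) c * 1e9 / n) / cm$lengths
  log2_rpkm <- log2(pmax(rpkm, rpkm_floor))
  groups <- intersect(AMP_GROUPS, unique(design$group))
  gm <- vapply(groups, function(g) {
    rowMeans(log2_rpkm[, design$sample[design$group == g], drop = FALSE])
  }, numeric(nrow(counts)))
  structure(list(rpkm = rpkm, log2_rpkm = log2_rpkm,
                 group_means = gm, design = design,
                 rpkm_floor = rpkm_floor,
                 lengths = cm$lengths, totals = totals),
            class = "amp_rpkm")
}

#' @export
print.amp_rpkm <- function(x, ...) {
  cat("amp_rpkm:", nrow(x$rpkm), "genes,", ncol(x$rpkm), "samples,",
      ncol(x$group_means), "groups\n")
  invisible(x)
}

#' Filter weakly expressed genes
#'
#' RNA-seq data are noisier at low expression, so genes whose group-mean
#' log2 RPKM stays below `threshold_log2` are excluded. In the default
#' `"all"` mode a gene is excluded only when below threshold in every
#' group; `"any"` mode excludes a gene below threshold in any group.
#' Equality with the threshold retains the gene (the rule is strict).
#'
#' @param rk an `amp_rpkm` object.
#' @param threshold_log2 log2 RPKM threshold, default 1.
#' @param mode `"all"` (default) or `"any"`.
#' @return character vector of retained gene ids.
#' @export
filter_low_expression <- function(rk, threshold_log2 = 1, mode = c("all", "any")) {
  mode <- match.arg(mode)
  below <- rk$group_means < threshold_log2
  excl <- if (mode == "all") apply(below, 1L, all) else apply(below, 1L, any)
  rownames(rk$group_means)[!excl]
}

#' Housekeeping stability check
#'
#' Expression fold range of each gene across the six group means:
#' `2^(max - min)` of group-mean log2 RPKM. A gene passes when its fold is
#' strictly below `fold_limit` (default 1.3), the stability criterion for
#' housekeeping genes used to validate RPKM normalization.
#'
#' @param rk an `amp_rpkm` object.
#' @param genes gene ids to check.
#' @param fold_limit stability bound, default 1.3.
#' @return data.frame `gene`, `fold`, `pass`.
#' @export
housekeeping_stability <- function(rk, genes, fold_limit = 1.3) {
  missing <- setdiff(genes, rownames(rk$group_means))
  if (length(missing)) stop("unknown gene ids: ", paste(missing, collapse = ", "))
  gm <- rk$group_means[genes, , drop = FALSE]
  fold <- 2^(apply(gm, 1L, max) - apply(gm, 1L, min))
  data.frame(gene = genes, fold = unname(fold), pass = unname(fold < fold_limit))
}

star_code <- function(p_adj) {
  ifelse(p_adj < 0.001, "***",
         ifelse(p_adj < 0.01, "**",
                ifelse(p_adj < 0.05, "*", "")))
}

#' Per-gene t-test with Benjamini-Hochberg correction for one contrast
#'
#' Two-sided two-sample t-test on log2 RPKM per gene between the two groups
#' named in the contrast (e.g. `"Mm-vs-Cm"`), pooled-variance Student by
#' default (`var_equal = FALSE` gives Welch). The log2 fold change is the
#' difference of group-mean log2 RPKM (first group minus second),
#' equivalently the log2 ratio of geometric means. BH step-up correction is
#' applied across all tested genes within the contrast; stars mark adjusted
#' p below 0.05 / 0.01 / 0.001.
#'
#' Degenerate genes (zero variance in both groups) get p = 1 when the
#' means are equal, and p = 0 with `degenerate = TRUE` when they differ.
#'
#' @param rk an `amp_rpkm` object.
#' @param contrast one of [amp_contrasts()].
#' @param genes genes to test (default: all rows).
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return data.frame `gene`, `log2fc`, `t`, `df`, `p`, `p_adj`, `star`,
#'   `degenerate`.
#' @export
t_test_bh <- function(rk, contrast, genes = NULL, var_equal = TRUE) {
  gr <- parse_contrast(contrast)
  if (is.null(genes)) genes <- rownames(rk$log2_rpkm)
  d <- rk$design
  s1 <- d$sample[d$group == gr[1L]]; s2 <- d$sample[d$group == gr[2L]]
  if (length(s1) < 2L || length(s2) < 2L)
    stop("both groups need >= 2 replicates for ", contrast)
  x <- rk$log2_rpkm[genes, s1, drop = FALSE]
  y <- rk$log2_rpkm[genes, s2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- diff / se
  degen <- se == 0
  tstat[degen & diff == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degen & diff == 0] <- 1
  p[degen & diff != 0] <- 0   # limit convention, flagged
  df[degen] <- NA_real_
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, log2fc = unname(diff), t = unname(tstat),
             df = unname(df), p = unname(p), p_adj = unname(p_adj),
             star = star_code(unname(p_adj)), degenerate = unname(degen))
}

#' Run the seven study contrasts and build the heat-map matrix
#'
#' Computes the named contrasts (carcass use M-vs-C per sex, parental care
#' C-vs-CL per sex, sex within each context) over the expression-filtered
#' gene set, and a heat-map export of group-mean log2 RPKM with star
#' annotations. User-designated reference genes (e.g. ribosomal protein
#' genes shown to confirm uniform expression) are always included in the
#' output even when they fail the expression filter.
#'
#' @param rk an `amp_rpkm` object over the full design.
#' @param genes genes to test (default: [filter_low_expression()] retained
#'   set).
#' @param reference_genes gene ids always carried into the heat-map.
#' @param contrasts contrast names, default [amp_contrasts()].
#' @param var_equal pooled (default) or Welch t-test.
#' @return list with `results` (named list of per-contrast data.frames) and
#'   `heatmap` (data.frame: gene, six group-mean columns, one star column
#'   per contrast).
#' @export
run_contrasts <- function(rk, genes = NULL, reference_genes = character(0),
                          contrasts = amp_contrasts(), var_equal = TRUE) {
  have <- unique(rk$design$group)
  need <- unique(unlist(lapply(contrasts, parse_contrast)))
  absent <- setdiff(need, have)
  if (length(absent)) stop("design lacks groups: ", paste(absent, collapse = ", "))
  if (is.null(genes)) genes <- filter_low_expression(rk)
  genes <- setdiff(genes, reference_genes)
  results <- lapply(contrasts, function(cn) t_test_bh(rk, cn, genes, var_equal))
  names(results) <- contrasts
  hm_genes <- c(genes, intersect(reference_genes, rownames(rk$group_means)))
  hm <- data.frame(gene = hm_genes,
                   rk$group_means[hm_genes, , drop = FALSE],
                   check.names = FALSE)
  for (cn in contrasts) {
    st <- setNames(results[[cn]]$star, results[[cn]]$gene)
    hm[[paste0("star_", cn)]] <- ifelse(hm_genes %in% names(st),
                                        st[hm_genes], "")
  }
  rownames(hm) <- NULL
  list(results = results, heatmap = hm)
}
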