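## End-to-end pipeline: curate -> quantify -> contrasts -> secretome, with a
## resolved-config + run-log reproducibility contract.

default_config <- function() {
  list(min_orf_aa = 30L, min_identity = 0.40, few_aa_threshold = 5L,
       min_coverage = 0.5,
       rpkm_floor = 2^-4, expression_threshold_log2 = 1,
       expression_filter_mode = "all", housekeeping_fold_limit = 1.3,
       var_equal = TRUE,
       max_missed = 1L, min_len = 5L, tol_ppm = 10,
       presence_threshold = 0.5, carbamidomethyl = FALSE,
       reference_genes = character(0), housekeeping_genes = character(0),
       seed = 1L)
}

resolve_config <- function(config = list()) {
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains candidate curation, RPKM quantification, the seven
#' differential-expression contrasts, and (optionally) secretome presence
#' calls against the curated protein sub-database. All outputs are written
#' as TSV/FASTA under `outdir`, together with the fully resolved
#' configuration (`config.yaml`) and a structured run log, so a run is
#' reproducible from its output directory alone. Given identical inputs,
#' config, and seed, outputs are byte-identical.
#'
#' @param transcripts_fasta path to candidate transcript nucleotide FASTA.
#' @param panel_fasta path to family panel protein FASTA (`family=` token
#'   in headers).
#' @param counts_tsv,design_tsv count matrix and design TSVs (see
#'   [read_counts_and_design()]); counts are keyed by curated gene id or by
#'   transcript id.
#' @param secretome_tsv optional observed-peptide TSV (`group` + `mass` or
#'   `peptide`).
#' @param outdir output directory, created if needed.
#' @param config named list overriding [pipeline defaults][run_pipeline]
#'   (thresholds, modes, reference/housekeeping gene ids, seed).
#' @return (invisibly) list with `curated`, `rpkm`, `contrasts`,
#'   `housekeeping`, `secretome` (or NULL), and `config`.
#' @export
run_pipeline <- function(transcripts_fasta, panel_fasta, counts_tsv,
                         design_tsv, secretome_tsv = NULL, outdir,
                         config = list()) {
  cfg <- resolve_config(config)
  # validate all inputs before writing anything (no partial outputs)
  inputs <- c(transcripts_fasta, panel_fasta, counts_tsv, design_tsv,
              secretome_tsv)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) stop("missing input file(s): ",
                           paste(absent, collapse = ", "))
  seqs <- read_fasta(transcripts_fasta, type = "dna")
  panel <- read_panel(panel_fasta)
  cd <- read_counts_and_design(counts_tsv, design_tsv)
  secretome_obs <- if (!is.null(secretome_tsv)) read_secretome_tsv(secretome_tsv)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run_log.tsv")

  curated <- curate_candidates(
    data.frame(id = names(seqs), nt_seq = unname(seqs)),
    panel, min_orf_aa = cfg$min_orf_aa, min_identity = cfg$min_identity,
    few_aa_threshold = cfg$few_aa_threshold, min_coverage = cfg$min_coverage)
  write_tsv(curated$genes, file.path(outdir, "curated_genes.tsv"))
  reps <- curated$transcripts[curated$transcripts$status == "retained", ]
  if (nrow(reps))
    write_fasta(setNames(reps$protein, reps$gene_id),
                file.path(outdir, "curated_proteins.fasta"), type = "protein")

  rk <- compute_rpkm(cd$counts, cd$design, rpkm_floor = cfg$rpkm_floor)
  retained <- filter_low_expression(rk, cfg$expression_threshold_log2,
                                    cfg$expression_filter_mode)
  hk <- if (length(cfg$housekeeping_genes))
    housekeeping_stability(rk, cfg$housekeeping_genes,
                           cfg$housekeeping_fold_limit)
  ctr <- run_contrasts(rk, genes = retained,
                       reference_genes = cfg$reference_genes,
                       var_equal = cfg$var_equal)
  for (cn in names(ctr$results))
    write_tsv(ctr$results[[cn]],
              file.path(outdir, paste0("contrast_", gsub("-", "_", cn), ".tsv")))
  write_tsv(ctr$heatmap, file.path(outdir, "heatmap_matrix.tsv"))
  if (!is.null(hk)) write_tsv(hk, file.path(outdir, "housekeeping.tsv"))

  secr <- NULL
  if (!is.null(secretome_obs)) {
    db <- if (nrow(reps)) setNames(reps$protein, reps$gene_id) else
      setNames(panel$protein, panel$id)
    secr <- match_and_cover(secretome_obs, db, tol_ppm = cfg$tol_ppm,
                            max_missed = cfg$max_missed,
                            min_len = cfg$min_len,
                            presence_threshold = cfg$presence_threshold,
                            carbamidomethyl = cfg$carbamidomethyl)
    write_tsv(secr$calls, file.path(outdir, "secretome_calls.tsv"))
    write_tsv(secr$matches, file.path(outdir, "secretome_matches.tsv"))
  }

  # run log: every curation decision plus stage in/out counts
  log <- curated$log
  log <- rbind(log, data.frame(
    stage = "expression", id = rownames(rk$rpkm),
    action = ifelse(rownames(rk$rpkm) %in% retained, "retained",
                    "excluded_low_expression"),
    detail = ""))
  write_tsv(log, logf)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))

  invisible(list(curated = curated, rpkm = rk,
                 contrasts = ctr, housekeeping = hk,
                 secretome = secr, config = cfg))
}
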