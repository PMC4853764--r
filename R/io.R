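## File I/O: FASTA via Biostrings, TSV tables with validation, the family
## panel format (family= token in headers), and the run log.

#' Read a FASTA file
#'
#' @param path file path.
#' @param type `"dna"` or `"protein"`.
#' @return named character vector of sequences, ids and order preserved.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  full <- names(set)
  out <- setNames(as.character(set), ids)
  attr(out, "descriptions") <- setNames(full, ids)
  out
}

#' Write sequences to FASTA
#'
#' Round-trip contract: `read_fasta(write_fasta(x))` recovers `x` up to
#' line wrapping.
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(sequences, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  stopifnot(!is.null(names(sequences)))
  set <- if (type == "dna") Biostrings::DNAStringSet(sequences)
  else Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a family panel protein FASTA
#'
#' The family of each reference protein is encoded in the header after a
#' `family=` token, e.g. `>defA_1 family=defensin`.
#'
#' @param path protein FASTA path.
#' @return data.frame with `id`, `family`, `protein`.
#' @export
read_panel <- function(path) {
  seqs <- read_fasta(path, type = "protein")
  desc <- attr(seqs, "descriptions")
  fam <- sub(".*family=([^ ]+).*", "\\1", desc)
  no_tag <- !grepl("family=", desc)
  if (any(no_tag))
    stop("panel entries without family= token: ",
         paste(names(seqs)[no_tag], collapse = ", "))
  data.frame(id = names(seqs), family = unname(fam),
             protein = unname(seqs))
}

#' Read a count matrix and sample design from TSV
#'
#' The counts file has columns `gene`, `length_bp`, then one column per
#' sample; the design file has columns `sample`, `sex`, `context`,
#' `replicate`. Sample columns are matched to design rows; missing or
#' extra samples raise an error naming them. A design that does not fill
#' the full 2-sex x 3-context x 3-replicate layout loads with a warning
#' listing the missing cells.
#'
#' @param counts_path,design_path TSV paths.
#' @param totals optional named per-sample total mapped reads; defaults to
#'   column sums.
#' @return list with `counts` (`amp_counts`) and `design`.
#' @export
read_counts_and_design <- function(counts_path, design_path, totals = NULL) {
  for (p in c(counts_path, design_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ct <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene", "length_bp") %in% names(ct)))
    stop("counts file needs 'gene' and 'length_bp' columns")
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  design <- validate_design(design)
  sample_cols <- setdiff(names(ct), c("gene", "length_bp"))
  missing <- setdiff(design$sample, sample_cols)
  if (length(missing))
    stop("design sample(s) absent from counts: ", paste(missing, collapse = ", "))
  extra <- setdiff(sample_cols, design$sample)
  if (length(extra))
    stop("counts column(s) absent from design: ", paste(extra, collapse = ", "))
  mat <- as.matrix(ct[, design$sample, drop = FALSE])
  rownames(mat) <- ct$gene
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene %s, sample %s",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  if (any(ct$length_bp <= 0))
    stop("non-positive length for gene ",
         ct$gene[which(ct$length_bp <= 0)[1]])
  full <- default_design()
  absent <- setdiff(paste(full$sex, full$context, full$replicate),
                    paste(design$sex, design$context, design$replicate))
  if (length(absent))
    warning("design does not fill the full 2x3x3 layout; missing cells: ",
            paste(absent, collapse = "; "))
  list(counts = count_matrix(mat, setNames(ct$length_bp, ct$gene), totals),
       design = design)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read observed secretome peptides from TSV
#'
#' Expects columns `group` plus `mass` (Da) or `peptide`.
#'
#' @param path TSV path.
#' @return data.frame of observations.
#' @export
read_secretome_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(x) || !any(c("mass", "peptide") %in% names(x)))
    stop("secretome file needs 'group' and 'mass' or 'peptide' columns")
  bad <- setdiff(x$group, AMP_GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  x
}
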