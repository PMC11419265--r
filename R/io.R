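# Readers/writers for external formats and the shared in-memory data model.
#
# Conventions: expression is TPM (non-negative) in genes x subjects matrices;
# all genomic intervals are 0-based half-open (BED convention) internally.

#' Expression panel for one tissue
#'
#' An `ExpressionPanel` holds the TPM matrix of one tissue: genes in rows,
#' subjects (donors) in columns.  Values must be non-negative and gene and
#' subject identifiers unique.
#'
#' @param tissue_id single string naming the tissue.
#' @param values numeric matrix of TPM, genes x subjects, with rownames
#'   (gene ids) and colnames (subject ids).
#' @return An object of class `ExpressionPanel` (a list with elements
#'   `tissue_id` and `values`).
#' @examples
#' m <- matrix(c(0, 1, 5, 10, 2, 3), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_panel("lung", m)
#' @export
expression_panel <- function(tissue_id, values) {
  if (!is_string(tissue_id)) stopf("'tissue_id' must be a single string")
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stopf("'values' needs rownames (genes) and colnames (subjects)")
  if (anyDuplicated(gid))
    stopf("duplicate gene id(s): %s",
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stopf("duplicate subject id(s): %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stopf("panel '%s': TPM values must be non-negative and non-missing",
          tissue_id)
  structure(list(tissue_id = tissue_id, values = values),
            class = "ExpressionPanel")
}

#' @export
print.ExpressionPanel <- function(x, ...) {
  cat(sprintf("ExpressionPanel '%s': %d genes x %d subjects\n",
              x$tissue_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_panel
#' @param x object to query.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_panel
#' @export
subject_ids <- function(x) colnames(x$values)

#' Named gene set
#'
#' @param name set label.
#' @param members character vector of gene ids; duplicates removed, must be
#'   non-empty.
#' @return object of class `GeneSet`.
#' @export
gene_set <- function(name, members) {
  if (!is_string(name)) stopf("'name' must be a single string")
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) == 0L) stopf("gene set '%s' is empty", name)
  structure(list(name = name, members = members), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Expression matrices: GCT v1.2 or wide TSV (auto-detected by header)

#' Read an expression matrix (GCT v1.2 or wide TSV)
#'
#' GCT v1.2 is GTEx's native text format: a `#1.2` header line, a dimensions
#' line, then `Name`/`Description` columns followed by one column per sample.
#' A headerless dialect -- a wide TSV whose first column is the gene id -- is
#' accepted too and detected by the absence of the `#1.2` magic.
#'
#' @param path file path.
#' @param tissue_id tissue label for the resulting panel.
#' @return [expression_panel()] object.
#' @export
read_expression_gct <- function(path, tissue_id) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stopf("%s: empty file", path)
  if (startsWith(first, "#1.2")) {
    lines <- readLines(path)
    if (length(lines) < 3L)
      stopf("%s: truncated GCT (need header, dims and a data line)", path)
    dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
      stopf("%s: malformed GCT dimensions at line 2: '%s'", path, lines[2L])
    nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
    tab <- read.delim(text = lines[-(1:2)], header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) != nc + 2L)
      stopf("%s: GCT header declares %d samples but found %d columns",
            path, nc, ncol(tab) - 2L)
    if (nrow(tab) != nr)
      stopf("%s: GCT header declares %d genes but found %d rows",
            path, nr, nrow(tab))
    ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stopf("%s: expected gene-id column plus samples", path)
    ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
  }
  if (!is.numeric(vals)) stopf("%s: non-numeric expression values", path)
  if (anyDuplicated(ids))
    stopf("%s: duplicate gene id(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(vals) || any(vals < 0))
    stopf("%s: negative or missing TPM values", path)
  rownames(vals) <- ids
  expression_panel(tissue_id, vals)
}

#' Write an expression panel as GCT v1.2
#'
#' @param panel [expression_panel()] object.
#' @param path output path.
#' @export
write_expression_gct <- function(panel, path) {
  stopifnot(inherits(panel, "ExpressionPanel"))
  v <- panel$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(v)), collapse = "\t")
  writeLines(header, con)
  body <- cbind(rownames(v), "na",
                format(v, trim = TRUE, scientific = FALSE, digits = 15))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample metadata

.sex_levels <- c("male", "female")

#' Read the sample-attributes table
#'
#' One row per subject-tissue combination.  Mandatory columns:
#' `subject_id`, `sex` (`male`/`female`), `tissue_id`, `organ`,
#' `ischemic_time` (minutes, >= 0) and `fixative_time` (hours, >= 0).
#'
#' @param path TSV path (header row required).
#' @return data.frame with the typed columns above.
#' @export
read_sample_metadata <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "tissue_id", "organ",
            "ischemic_time", "fixative_time")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("%s: missing mandatory column(s): %s", path,
          paste(miss, collapse = ", "))
  validate_sample_metadata(tab[need])
}

validate_sample_metadata <- function(tab) {
  bad_sex <- setdiff(unique(tab$sex), .sex_levels)
  if (length(bad_sex))
    stopf("unknown sex value(s): %s", paste(bad_sex, collapse = ", "))
  if (anyNA(tab$ischemic_time) || any(tab$ischemic_time < 0))
    stopf("ischemic_time must be non-negative")
  if (anyNA(tab$fixative_time) || any(tab$fixative_time < 0))
    stopf("fixative_time must be non-negative")
  if (anyDuplicated(tab[c("subject_id", "tissue_id")]))
    stopf("duplicated subject-tissue record(s)")
  tab
}

# ---------------------------------------------------------------------------
# Intervals (BED 0-based half-open), gene lists, eQTL tables

#' Read a BED3+ interval file
#'
#' Columns: chrom, start, end, then optionally name, variant type
#' (`deletion`/`insertion`) and allele frequency.  Coordinates are 0-based
#' half-open and preserved as such.
#'
#' @param path BED path (no header line).
#' @param assembly optional assembly tag (e.g. "hg38") attached as an
#'   attribute and checked when interval sets are combined.
#' @return data.frame `chrom,start,end,name,variant_type,allele_frequency`
#'   with attribute `assembly`.
#' @export
read_bed <- function(path, assembly = NA_character_) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stopf("%s: BED needs at least 3 columns", path)
  out <- data.frame(
    chrom = as.character(tab[[1L]]),
    start = as.integer(tab[[2L]]),
    end = as.integer(tab[[3L]]),
    name = if (ncol(tab) >= 4L) as.character(tab[[4L]])
           else sprintf("iv%d", seq_len(nrow(tab))),
    variant_type = if (ncol(tab) >= 5L) as.character(tab[[5L]])
                   else NA_character_,
    allele_frequency = if (ncol(tab) >= 6L) as.numeric(tab[[6L]]) else NA_real_,
    stringsAsFactors = FALSE)
  bad <- which(!(out$start < out$end))
  if (length(bad))
    stopf("%s: start >= end at line %d", path, bad[1L])
  known <- c("deletion", "insertion")
  odd <- setdiff(stats::na.omit(unique(out$variant_type)), known)
  if (length(odd))
    stopf("%s: unknown variant type(s): %s", path, paste(odd, collapse = ", "))
  if (any(!is.na(out$allele_frequency) &
          (out$allele_frequency < 0 | out$allele_frequency > 1)))
    stopf("%s: allele frequency outside [0, 1]", path)
  attr(out, "assembly") <- assembly
  out
}

#' Read gene annotations from a BED-like file
#'
#' Columns: chrom, start, end, gene_id, optional strand, optional 0/1 flag
#' marking the male-specific region of chromosome Y.
#'
#' @inheritParams read_bed
#' @return data.frame `gene_id,chrom,start,end,strand,chry_msr` with
#'   attribute `assembly`.
#' @export
read_gene_annotation <- function(path, assembly = NA_character_) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stopf("%s: need chrom,start,end,gene_id", path)
  out <- data.frame(
    gene_id = as.character(tab[[4L]]),
    chrom = as.character(tab[[1L]]),
    start = as.integer(tab[[2L]]),
    end = as.integer(tab[[3L]]),
    strand = if (ncol(tab) >= 5L) as.character(tab[[5L]]) else "*",
    chry_msr = if (ncol(tab) >= 6L) as.logical(as.integer(tab[[6L]]))
               else FALSE,
    stringsAsFactors = FALSE)
  bad <- which(!(out$start < out$end))
  if (length(bad)) stopf("%s: start >= end at line %d", path, bad[1L])
  if (anyDuplicated(out$gene_id)) stopf("%s: duplicate gene ids", path)
  attr(out, "assembly") <- assembly
  out
}

#' Read a plain gene list (one id per line)
#'
#' @param path text file path.
#' @param name optional set name (defaults to the file name).
#' @return [gene_set()] object; an empty file is an error.
#' @export
read_gene_list <- function(path, name = NULL) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stopf("%s: empty gene list", path)
  gene_set(name %||% basename(path), ids)
}

#' Read an eQTL association table
#'
#' TSV with columns `variant_id`, `gene_id`, `tissue_id`, `effect_sign`
#' (+1 or -1).  The table is assumed pre-filtered to significant
#' associations, as GTEx eQTL releases are.
#'
#' @param path TSV path.
#' @return data.frame of typed records.
#' @export
read_eqtl_table <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene_id", "tissue_id", "effect_sign")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  sign <- suppressWarnings(as.integer(tab$effect_sign))
  if (anyNA(sign) || !all(sign %in% c(-1L, 1L)))
    stopf("%s: effect_sign must be +1 or -1", path)
  tab$effect_sign <- sign
  tab[need]
}

#' Write a result table as TSV
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_results_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
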