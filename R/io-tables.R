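# Readers/writers for the pipeline's tabular formats.  All internal
# coordinates are 1-based inclusive; BED input is converted at the boundary.
# Chromosome names are normalized by stripping a leading "chr" so that mixed
# conventions ("chr1" vs "1") cannot split one chromosome in two.

#' Construct a replicated expression time-course matrix
#'
#' Container for a genes x samples RPKM matrix for one species and condition,
#' with `length(timepoints) * n_replicates` sample columns ordered
#' timepoint-major (all replicates of the first time point, then the second,
#' ...).  Column names encode `<condition>_<time>h_r<replicate>`.
#'
#' @param values numeric matrix (genes x samples) of non-negative finite RPKM
#'   values with unique rownames (gene ids).
#' @param timepoints strictly increasing numeric vector of hours.
#' @param n_replicates replicates per time point.
#' @param species species label.
#' @param condition condition label (e.g. "Th17" or "Th0").
#' @return an object of class `TimeCourseMatrix`: a list with elements
#'   `values`, `timepoints`, `n_replicates`, `species`, `condition`,
#'   `col_time` (hours per column) and `col_rep` (replicate per column).
#' @export
time_course_matrix <- function(values, timepoints, n_replicates,
                               species = "", condition = "Th17") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) == 0L) stop("`timepoints` must be non-empty")
  if (any(diff(timepoints) <= 0)) stop("`timepoints` must be strictly increasing")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  if (ncol(values) != length(timepoints) * n_replicates)
    stop(sprintf("expected %d sample columns (%d timepoints x %d replicates), got %d",
                 length(timepoints) * n_replicates, length(timepoints),
                 n_replicates, ncol(values)))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (gene ids)")
  if (any(!is.finite(values)) || any(values < 0))
    stop("RPKM values must be non-negative and finite")
  col_time <- rep(timepoints, each = n_replicates)
  col_rep <- rep(seq_len(n_replicates), times = length(timepoints))
  colnames(values) <- sprintf("%s_%sh_r%d", condition,
                              format(col_time, trim = TRUE, scientific = FALSE),
                              col_rep)
  structure(
    list(values = values, timepoints = timepoints, n_replicates = n_replicates,
         species = species, condition = condition,
         col_time = col_time, col_rep = col_rep),
    class = "TimeCourseMatrix")
}

#' @export
print.TimeCourseMatrix <- function(x, ...) {
  cat(sprintf("TimeCourseMatrix: %d genes x %d samples (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$species, x$condition))
  cat("timepoints (h):", paste(x$timepoints, collapse = ", "),
      sprintf(" x %d replicates\n", x$n_replicates))
  invisible(x)
}

#' Subset a TimeCourseMatrix to selected time points
#'
#' @param tc a `TimeCourseMatrix`.
#' @param timepoints hours to keep (must be present in `tc$timepoints`).
#' @return a `TimeCourseMatrix` restricted to those time points.
#' @export
subset_timepoints <- function(tc, timepoints) {
  stopifnot(inherits(tc, "TimeCourseMatrix"))
  if (!all(timepoints %in% tc$timepoints))
    stop("requested timepoints not all present in the matrix")
  keep <- tc$col_time %in% timepoints
  time_course_matrix(tc$values[, keep, drop = FALSE],
                     timepoints = sort(unique(tc$col_time[keep])),
                     n_replicates = tc$n_replicates,
                     species = tc$species, condition = tc$condition)
}

#' Write / read an expression matrix as TSV
#'
#' Format: a header of `gene_id` followed by `<condition>_<time>h_r<rep>`
#' sample columns, one row per gene.  `read_expression_tsv` reconstructs the
#' time-point/replicate design from the header and rejects files with ragged
#' rows, duplicate gene ids or negative values, naming the offending line.
#'
#' @param tc a `TimeCourseMatrix`.
#' @param path file path.
#' @param species species label attached on reading (the file stores the
#'   condition in its header, not the species).
#' @return `read_expression_tsv` returns a `TimeCourseMatrix`;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "TimeCourseMatrix"))
  df <- data.frame(gene_id = rownames(tc$values), tc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, species = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2L) stop(sprintf("%s: no data rows", path))
  if (any(nf != nf[1L]))
    stop(sprintf("%s: ragged rows at line(s) %s", path,
                 paste(which(nf != nf[1L]), collapse = ", ")))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("%s: no data rows", path))
  if (colnames(df)[1L] != "gene_id")
    stop(sprintf("%s: first column must be 'gene_id'", path))
  sample_cols <- colnames(df)[-1L]
  m <- regmatches(sample_cols,
                  regexec("^(.+)_([0-9.]+)h_r([0-9]+)$", sample_cols))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop(sprintf("%s: malformed sample column name(s): %s", path,
                 paste(sample_cols[bad], collapse = ", ")))
  condition <- unique(vapply(m, `[`, "", 2L))
  if (length(condition) != 1L)
    stop(sprintf("%s: mixed conditions in header: %s", path,
                 paste(condition, collapse = ", ")))
  col_time <- as.numeric(vapply(m, `[`, "", 3L))
  col_rep <- as.integer(vapply(m, `[`, "", 4L))
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop(sprintf("%s: duplicate gene id(s) at line(s) %s", path,
                 paste(which(dup) + 1L, collapse = ", ")))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop(sprintf("%s: non-numeric expression values", path))
  neg <- which(apply(vals, 1L, function(r) any(r < 0, na.rm = TRUE)))
  if (length(neg))
    stop(sprintf("%s: negative RPKM value(s) at line(s) %s", path,
                 paste(neg + 1L, collapse = ", ")))
  rownames(vals) <- df$gene_id
  timepoints <- sort(unique(col_time))
  n_rep <- length(col_rep) / length(timepoints)
  if (n_rep != round(n_rep) ||
      !all(table(col_time) == n_rep))
    stop(sprintf("%s: unbalanced design (unequal replicates per time point)", path))
  ord <- order(col_time, col_rep)
  time_course_matrix(vals[, ord, drop = FALSE], timepoints,
                     as.integer(n_rep), species = species,
                     condition = condition)
}

normalize_chrom <- function(chrom, context = "annotation") {
  chrom <- as.character(chrom)
  has_prefix <- grepl("^chr", chrom)
  if (any(has_prefix) && !all(has_prefix))
    warning(sprintf("%s mixes 'chr'-prefixed and bare chromosome names; normalizing to bare names",
                    context))
  sub("^chr", "", chrom)
}

validate_annotation <- function(ann, src) {
  if (anyDuplicated(ann$gene_id))
    stop(sprintf("%s: duplicate gene ids: %s", src,
                 paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", ")))
  if (any(ann$start <= 0) || any(ann$end <= 0))
    stop(sprintf("%s: non-positive coordinates", src))
  bad <- ann$start > ann$end
  if (any(bad))
    stop(sprintf("%s: start > end for gene(s) %s", src,
                 paste(ann$gene_id[bad], collapse = ", ")))
  ann$chrom <- normalize_chrom(ann$chrom, src)
  ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
}

#' Read a gene annotation
#'
#' Accepts a BED file (0-based half-open, converted to 1-based inclusive), a
#' GTF (parsed with [rtracklayer::import()], keeping `gene` features), or a
#' TSV with columns `gene_id`, `chrom`, `start`, `end` and optional `strand`
#' and `biotype` (1-based inclusive).  Chromosome names mixing "chr1"/"1"
#' conventions trigger a warning and are normalized to bare names.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"gtf"`, `"bed"`.
#' @return a data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, sorted by (chrom, start).
#' @export
read_annotation <- function(path, format = c("tsv", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
    ann <- data.frame(gene_id = as.character(df$gene_id),
                      chrom = as.character(df$chrom),
                      start = as.integer(df$start), end = as.integer(df$end),
                      strand = if ("strand" %in% colnames(df)) df$strand else "+",
                      biotype = if ("biotype" %in% colnames(df)) df$biotype else "coding",
                      stringsAsFactors = FALSE)
  } else if (format == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop(sprintf("%s: BED needs at least 4 columns (chrom, start, end, name)", path))
    ann <- data.frame(gene_id = as.character(df[[4L]]),
                      chrom = as.character(df[[1L]]),
                      start = as.integer(df[[2L]]) + 1L,  # 0-based half-open -> 1-based inclusive
                      end = as.integer(df[[3L]]),
                      strand = if (ncol(df) >= 6L) df[[6L]] else "+",
                      biotype = "coding", stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- as.data.frame(gr)
    if ("type" %in% colnames(md) && any(md$type == "gene"))
      md <- md[md$type == "gene", , drop = FALSE]
    biotype <- md$gene_biotype %||% md$biotype %||% md$gene_type %||% "coding"
    ann <- data.frame(gene_id = as.character(md$gene_id),
                      chrom = as.character(md$seqnames),
                      start = as.integer(md$start), end = as.integer(md$end),
                      strand = as.character(md$strand),
                      biotype = as.character(biotype), stringsAsFactors = FALSE)
  }
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  validate_annotation(ann, path)
}

#' Write a gene annotation as the package's TSV dialect
#' @param ann annotation data.frame as returned by [read_annotation()].
#' @param path file path.
#' @export
write_annotation_tsv <- function(ann, path) {
  write.table(ann[, c("gene_id", "chrom", "start", "end", "strand", "biotype")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a one-to-one ortholog map
#'
#' Two-column TSV (`human_gene`, `mouse_gene`; header optional).  Any gene
#' appearing in more than one pair violates the one-to-one requirement and is
#' rejected with the offending gene ids.
#'
#' @param path file path.
#' @return a data.frame with columns `human_gene`, `mouse_gene`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  header <- identical(first, c("human_gene", "mouse_gene"))
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop(sprintf("%s: ortholog map must have exactly 2 columns", path))
  colnames(df) <- c("human_gene", "mouse_gene")
  df$human_gene <- as.character(df$human_gene)
  df$mouse_gene <- as.character(df$mouse_gene)
  offenders <- c(df$human_gene[duplicated(df$human_gene)],
                 df$mouse_gene[duplicated(df$mouse_gene)])
  if (length(offenders))
    stop(sprintf("%s: not one-to-one; genes in multiple pairs: %s", path,
                 paste(unique(offenders), collapse = ", ")))
  df
}

#' @rdname read_ortholog_map
#' @param ortho ortholog map data.frame.
#' @export
write_ortholog_map <- function(ortho, path) {
  write.table(ortho[, c("human_gene", "mouse_gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a disease lead-SNP catalog
#'
#' TSV with columns `snp_id`, `trait`, `chrom`, `pos`, `pvalue`.  P-values
#' must lie in (0, 1]; positions must be positive.  Chromosome names are
#' normalized as for annotations.
#'
#' @param path file path.
#' @return data.frame with the five columns above.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "trait", "chrom", "pos", "pvalue")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  if (any(df$pos <= 0)) stop(sprintf("%s: non-positive SNP position(s)", path))
  bad_p <- df$pvalue <= 0 | df$pvalue > 1
  if (any(bad_p))
    stop(sprintf("%s: p-value(s) outside (0, 1] at line(s) %s", path,
                 paste(which(bad_p) + 1L, collapse = ", ")))
  df$chrom <- normalize_chrom(df$chrom, path)
  df[, req]
}

#' @rdname read_snp_table
#' @param snps SNP catalog data.frame.
#' @export
write_snp_table <- function(snps, path) {
  write.table(snps[, c("snp_id", "trait", "chrom", "pos", "pvalue")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-time-point differential-expression table
#'
#' TSV with columns `gene_id`, `timepoint`, `log2_fc`, `fdr`; exactly one row
#' per (gene, timepoint); FDR in \[0, 1\].
#'
#' @param path file path.
#' @return data.frame with the four columns above.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "timepoint", "log2_fc", "fdr")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  key <- paste(df$gene_id, df$timepoint)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (gene, timepoint) row(s): %s", path,
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  if (any(df$fdr < 0 | df$fdr > 1)) stop(sprintf("%s: FDR outside [0, 1]", path))
  df[, req]
}

#' @rdname read_de_table
#' @param de DE table data.frame.
#' @export
write_de_table <- function(de, path) {
  write.table(de[, c("gene_id", "timepoint", "log2_fc", "fdr")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a functional term-to-gene map
#'
#' Long-format TSV with columns `term`, `gene`; returned as a named list of
#' character vectors (one element per term).
#'
#' @param path file path.
#' @return named list: term -> character vector of gene ids.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "gene") %in% colnames(df)))
    stop(sprintf("%s: term map needs columns 'term' and 'gene'", path))
  lapply(split(as.character(df$gene), df$term), unique)
}

#' @rdname read_term_map
#' @param terms named list term -> gene vector.
#' @export
write_term_map <- function(terms, path) {
  df <- data.frame(term = rep(names(terms), lengths(terms)),
                   gene = unlist(terms, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
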