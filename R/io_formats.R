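## Readers and writers for the external formats the pipeline touches:
## gene annotation (BED / GFF3 / TSV), SEG-like binned copy-number TSV,
## rectangular expression matrices, GMT gene sets, cohort metadata.
## Internal coordinates are uniformly 0-based half-open; all conversions
## happen here at the boundary.

.ann_cols <- c("gene_id", "symbol", "chromosome", "start", "end",
               "strand", "biotype", "arm")

.assign_arm <- function(chromosome, start, centromeres) {
  arm <- rep("unknown", length(chromosome))
  if (is.null(centromeres)) return(arm)
  stopifnot(all(c("chromosome", "position") %in% names(centromeres)))
  pos <- centromeres$position[match(chromosome, centromeres$chromosome)]
  known <- !is.na(pos)
  if (any(!known))
    warning(sprintf("%d gene(s) on chromosomes absent from the centromere table; arm set to 'unknown'",
                    sum(!known)), call. = FALSE)
  arm[known] <- ifelse(start[known] < pos[known], "p", "q")
  arm
}

.validate_annotation <- function(df) {
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("annotation record %d: end <= start", bad[1L]), call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in annotation", call. = FALSE)
  structure(df[, .ann_cols], class = c("gene_annotation", "data.frame"))
}

#' Read a gene annotation
#'
#' BED input is taken as 0-based half-open (native); GFF3 is converted from
#' 1-based inclusive; TSV is the package's own dialect with columns
#' gene_id, symbol, chromosome, start, end, strand, biotype already in
#' 0-based half-open coordinates. When a centromere table
#' (columns `chromosome`, `position`) is given, each gene is assigned to
#' arm "p" or "q" by comparing its start with the centromere position;
#' genes on chromosomes missing from the table get arm "unknown" with a
#' warning.
#'
#' @param path File path.
#' @param format One of "TSV", "BED", "GFF3".
#' @param centromeres Optional data.frame with `chromosome`, `position`.
#' @return A `gene_annotation` data.frame.
#' @export
read_gene_annotation <- function(path, format = c("TSV", "BED", "GFF3"),
                                 centromeres = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "TSV") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- setdiff(.ann_cols, "arm")
    if (!all(need %in% names(df)))
      stop(sprintf("annotation TSV must have columns: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = format)
    if (format == "GFF3") {
      type <- as.character(gr$type)
      if ("gene" %in% type) gr <- gr[type == "gene"]
    }
    mc <- S4Vectors::mcols(gr)
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% names(mc)) return(as.character(mc[[nm]]))
      NULL
    }
    ids <- pick("gene_id", "ID", "name")
    if (is.null(ids)) ids <- sprintf("GENE%04d", seq_along(gr))
    sym <- pick("Name", "gene_name", "name")
    if (is.null(sym)) sym <- ids
    bty <- pick("biotype", "gene_biotype")
    if (is.null(bty)) bty <- rep("unknown", length(gr))
    df <- data.frame(gene_id = ids, symbol = sym,
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,  # to 0-based
                     end = GenomicRanges::end(gr),           # half-open
                     strand = as.character(GenomicRanges::strand(gr)),
                     biotype = bty, stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "."
  }
  df$arm <- .assign_arm(df$chromosome, df$start, centromeres)
  .validate_annotation(df)
}

#' Write a gene annotation as TSV
#'
#' @param annotation A `gene_annotation` data.frame.
#' @param path Output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation[, setdiff(.ann_cols, "arm")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binned copy-number profiles from a SEG-like TSV
#'
#' Required columns: `sample`, `chrom`, `start`, `end`, and at least one of
#' `log2_ratio`, `cn`. Bins are grouped by sample and stably sorted by
#' (chrom, start); overlapping bins within a sample are a validation error.
#' With only a `cn` column, the log2 ratio is derived as `log2(cn / 2)`
#' (diploid baseline), requiring cn > 0.
#'
#' @param path File path.
#' @return Named list of [cn_profile()] objects, in order of first
#'   appearance of each sample.
#' @export
read_cn_bins <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("SEG-like TSV needs columns sample, chrom, start, end", call. = FALSE)
  has_l2 <- "log2_ratio" %in% names(df)
  has_cn <- "cn" %in% names(df)
  if (!has_l2 && !has_cn)
    stop("need a log2_ratio and/or cn column", call. = FALSE)
  if (!has_l2) {
    if (any(df$cn <= 0))
      stop("cn must be > 0 to derive log2 ratios", call. = FALSE)
    df$log2_ratio <- log2(df$cn / 2)
  }
  keep <- c("chrom", "start", "end", "log2_ratio", if (has_cn) "cn")
  samples <- unique(df$sample)
  out <- lapply(samples, function(s)
    cn_profile(s, df[df$sample == s, keep, drop = FALSE]))
  stats::setNames(out, samples)
}

#' Write copy-number profiles as a SEG-like TSV
#'
#' @param profiles List of [cn_profile()] objects.
#' @param path Output path.
#' @export
write_cn_bins <- function(profiles, path) {
  rows <- lapply(profiles, function(p) cbind(sample = p$sample_id, p$bins))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rectangular expression matrix
#'
#' First column gene ids, header line sample ids. Duplicated gene ids,
#' missing cells and ragged rows are rejected. The declared scale travels
#' with the matrix as an attribute and gates scale-sensitive operations
#' downstream.
#'
#' @param path File path.
#' @param scale One of "log2TPM", "FPKM", "TMM", "log2FPKM".
#' @return Numeric matrix (genes x samples) with attribute `scale`.
#' @export
read_matrix <- function(path, scale = c("log2TPM", "FPKM", "TMM", "log2FPKM")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]),
         call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop(sprintf("duplicated gene id '%s'", df[[1L]][duplicated(df[[1L]])][1L]),
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric or missing cells in expression matrix", call. = FALSE)
  rownames(m) <- df[[1L]]
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample id in header", call. = FALSE)
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Duplicate set names are an error; duplicate genes within a set are
#' deduplicated with a warning; empty sets are kept with a warning. Set
#' order is preserved.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 2 fields", short[1L]), call. = FALSE)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop(sprintf("duplicate gene-set name '%s'", nms[duplicated(nms)][1L]),
         call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning(sprintf("duplicate genes within set(s) %s; deduplicated",
                    paste(nms[dup], collapse = ", ")), call. = FALSE)
    sets <- lapply(sets, unique)
  }
  if (any(lengths(sets) == 0L))
    warning("empty gene set(s) present", call. = FALSE)
  stats::setNames(sets, nms)
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read cohort metadata
#'
#' TSV with columns sample_id, inss_stage, mna_status, balance_17q,
#' os_time (days), os_event (0 censored / 1 event).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_cohort_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(df)))
    stop("metadata needs columns sample_id, os_time, os_event", call. = FALSE)
  if (any(df$os_time < 0)) stop("os_time must be >= 0", call. = FALSE)
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0 or 1", call. = FALSE)
  df
}

#' Write cohort metadata as TSV
#'
#' @param meta data.frame of cohort metadata.
#' @param path Output path.
#' @export
write_cohort_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
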