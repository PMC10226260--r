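#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Genomic interval in 0-based half-open coordinates
#'
#' All internal coordinates are 0-based half-open; readers convert at the
#' boundary (BED is native, GFF3 is 1-based inclusive on disk).
#'
#' @param chrom Chromosome name.
#' @param start 0-based start.
#' @param end Exclusive end; must satisfy `end > start`.
#' @return A `genomic_region` list with fields `chrom`, `start`, `end`.
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || end <= start || start < 0)
    stop("invalid genomic region: need 0 <= start < end", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("%s:%d-%d\n", x$chrom, as.integer(x$start), as.integer(x$end)))
  invisible(x)
}

# fraction in [0,1] check
.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  x
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# stable per-component sub-seeds derived from one master seed, so that adding
# a component never perturbs the streams of the others
.sub_seeds <- function(seed, components) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(components)),
                  components)
}
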