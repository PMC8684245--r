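#' Define the panel of populations being scored
#'
#' A panel is the ordered set of population labels whose alternate-allele
#' frequency columns appear, in this order, in the variant table. Order is
#' significant: frequency column `i` belongs to `names[i]`.
#'
#' @param names Character vector of distinct, non-empty population labels.
#' @return An object of class `finemav_panel` with elements `names` and `n`.
#' @examples
#' population_panel(c("90HC", "SSIP", "SSMP"))
#' @export
population_panel <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L)
    stop("a panel needs at least 2 populations, got ", length(names))
  if (anyDuplicated(names))
    stop("population names must be distinct")
  if (any(!nzchar(names)) || anyNA(names))
    stop("population names must be non-empty")
  structure(list(names = names, n = length(names)), class = "finemav_panel")
}

#' @export
print.finemav_panel <- function(x, ...) {
  cat("<finemav_panel> ", x$n, " populations: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assemble and validate a pipeline run configuration
#'
#' Collects everything [run_pipeline()] needs: input/output paths, the
#' population panel, the purity penalty exponent, the streaming chunk size
#' and the filter-policy flags. When `penalty` is `NULL` the recommended
#' default for `length(populations)` populations is used (see
#' [default_penalty()]).
#'
#' @param variants Path to the tab-delimited variant extract. Columns, in
#'   order: `CHROM:POS`, `ID`, `REF`, `ALT`, then `AA` (if `has_aa`), then
#'   `CADD_PHRED` (if `has_cadd`), then one alternate-allele-frequency
#'   column per population.
#' @param populations Character vector of population labels (column order),
#'   or a [population_panel()].
#' @param out_prefix Output path prefix; the pipeline writes
#'   `<prefix>_finemav.tsv`, `<prefix>_<population>.bw` and `<prefix>.log`.
#' @param chrom_sizes Path to a two-column chromosome-sizes table
#'   (name, length); required for bigWig emission.
#' @param annotations Optional path to a VEP-style annotation table
#'   supplying `AA` and/or `CADD_PHRED` where the variant table lacks them.
#' @param penalty Purity penalty exponent x (> 1). `NULL` selects the
#'   recommended default for the panel size.
#' @param chunk_size Lines streamed per chunk (default 200000).
#' @param strict_ancestral Reject lowercase (low-confidence) ancestral
#'   calls instead of accepting them.
#' @param has_aa,has_cadd Whether the variant table carries the `AA` /
#'   `CADD_PHRED` columns.
#' @param header Whether the variant table has a header line to skip.
#' @param max_annotation_entries Entry budget for the annotation lookup
#'   table, which is held in memory across chunks; exceeding it is fatal.
#' @param seed Optional integer seed (used only by fixture generation).
#' @return An object of class `finemav_config`.
#' @export
finemav_config <- function(variants, populations, out_prefix,
                           chrom_sizes = NULL, annotations = NULL,
                           penalty = NULL, chunk_size = 200000L,
                           strict_ancestral = FALSE,
                           has_aa = TRUE, has_cadd = TRUE, header = FALSE,
                           max_annotation_entries = 5e6, seed = NULL) {
  panel <- if (inherits(populations, "finemav_panel")) populations
           else population_panel(populations)
  if (is.null(penalty)) penalty <- default_penalty(panel$n)
  penalty <- as.numeric(penalty)
  if (!is.finite(penalty) || penalty <= 1)
    stop("penalty x must exceed 1 (got ", penalty,
         "): x <= 1 would not penalise derived-allele sharing")
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    stop("chunk_size must be a positive integer")
  structure(list(
    variants = variants, annotations = annotations,
    chrom_sizes = chrom_sizes, out_prefix = out_prefix,
    panel = panel, penalty = penalty, chunk_size = chunk_size,
    strict_ancestral = isTRUE(strict_ancestral),
    has_aa = isTRUE(has_aa), has_cadd = isTRUE(has_cadd),
    header = isTRUE(header),
    max_annotation_entries = max_annotation_entries,
    seed = seed), class = "finemav_config")
}

#' @export
print.finemav_config <- function(x, ...) {
  cat("<finemav_config>\n")
  cat("  variants:    ", x$variants, "\n", sep = "")
  cat("  annotations: ", if (is.null(x$annotations)) "-" else x$annotations,
      "\n", sep = "")
  cat("  chrom sizes: ", if (is.null(x$chrom_sizes)) "-" else x$chrom_sizes,
      "\n", sep = "")
  cat("  out prefix:  ", x$out_prefix, "\n", sep = "")
  cat("  populations: ", paste(x$panel$names, collapse = ","), "\n", sep = "")
  cat("  penalty x:   ", x$penalty, "\n", sep = "")
  cat("  chunk size:  ", x$chunk_size, "\n", sep = "")
  invisible(x)
}
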