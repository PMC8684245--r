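## Output writers: the score TSV (precision-bearing artifact), one bigWig
## track per population (float32, for genome browsers), and the run log.

# column order of the score table for a panel: 9 + 2n columns
score_header <- function(panel) {
  c("chrom", "pos", "id", "ref", "alt", "aa", "derived_allele",
    "cadd_phred", paste0("daf_", panel$names), "dap",
    paste0("finemav_", panel$names))
}

# 6 significant digits, locale-independent; "." for missing
.fmt_real <- function(x) {
  out <- formatC(x, digits = 6, format = "g", flag = "")
  out[is.na(x)] <- "."
  trimws(out)
}

# render score rows as TSV lines (no header) from parallel vectors;
# daf/fm are site-by-population matrices
.format_lines_raw <- function(chrom, pos, id, ref, alt, aa, derived,
                              cadd, daf, dap, fm) {
  aa[is.na(aa)] <- "."
  parts <- c(list(chrom, pos, id, ref, alt, aa, derived, .fmt_real(cadd)),
             lapply(seq_len(ncol(daf)), function(j) .fmt_real(daf[, j])),
             list(.fmt_real(dap)),
             lapply(seq_len(ncol(fm)), function(j) .fmt_real(fm[, j])))
  do.call(paste, c(parts, sep = "\t"))
}

# render ScoreRow data.table rows as TSV lines (no header)
format_score_rows <- function(scores, panel) {
  cols <- score_header(panel)
  stopifnot(all(cols %in% names(scores)))
  .format_lines_raw(
    scores$chrom, scores$pos, scores$id, scores$ref, scores$alt,
    scores$aa, scores$derived_allele, scores$cadd_phred,
    as.matrix(scores[, paste0("daf_", panel$names), with = FALSE]),
    scores$dap,
    as.matrix(scores[, paste0("finemav_", panel$names), with = FALSE]))
}

#' Write the score table
#'
#' One header line plus one row per scored site, tab-delimited. Reals are
#' rendered with 6 significant digits; re-parsing reproduces values to
#' that precision. This TSV is the precision-bearing output (bigWig
#' stores float32).
#'
#' @param scores A `data.table` of score rows from [score_sites()].
#' @param panel The [population_panel()] naming the per-population columns.
#' @param path Output path.
#' @return Invisibly, the number of rows written.
#' @export
write_scores_tsv <- function(scores, panel, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste(score_header(panel), collapse = "\t"), con)
  if (nrow(scores) > 0L)
    writeLines(format_score_rows(scores, panel), con)
  invisible(nrow(scores))
}

#' Read back a score table written by [write_scores_tsv()]
#'
#' @param path Path to the score TSV.
#' @return A `data.table` with the same columns ("." read as `NA`).
#' @export
read_scores_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                    colClasses = list(character = "chrom"))
}

# shared bigWig emitter over parallel chrom/pos/value vectors
.write_bigwig_intervals <- function(chrom, pos, values, chrom_sizes, path) {
  miss <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(miss) > 0L)
    stop("chromosome(s) absent from the chromosome-sizes file: ",
         paste(miss, collapse = ", "))
  if (length(chrom) > 0L) {
    over <- pos > chrom_sizes[chrom]
    if (any(over)) {
      i <- which(over)[1L]
      stop("position ", pos[i], " beyond the end of chromosome ",
           chrom[i], " (", chrom_sizes[[chrom[i]]], ")")
    }
    if (anyDuplicated(paste0(chrom, ":", pos)) > 0L)
      stop("duplicate chrom:pos among scored sites; per-base bigWig values ",
           "are ill-defined for overlapping sites (upstream filtering bug?)")
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                              seqlengths = as.integer(chrom_sizes))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(chrom_sizes)),
    ranges = IRanges::IRanges(start = pos, width = 1L),
    score = as.numeric(values),
    seqinfo = si)
  gr <- BiocGenerics::sort(gr)   # format requires sorted intervals
  rtracklayer::export.bw(gr, path)
  invisible(length(gr))
}

#' Write one population's scores as a bigWig track
#'
#' Each scored site contributes a single-base interval (0-based half-open
#' `[pos - 1, pos)` in bigWig coordinates; 1-based `pos` in the score
#' table) valued with that population's FineMAV score. Intervals are
#' sorted per chromosome as the format requires; input row order is not
#' otherwise used. Every chromosome seen must appear in `chrom_sizes` and
#' every position must fit inside it.
#'
#' @param scores A `data.table` of score rows from [score_sites()].
#' @param population Population name (matching the panel) or index.
#' @param chrom_sizes Named numeric vector of chromosome lengths, as from
#'   [read_chrom_sizes()], or a path to a chromosome-sizes file.
#' @param path Output `.bw` path.
#' @param panel The [population_panel()] (needed when `population` is an
#'   index).
#' @return Invisibly, the number of intervals written.
#' @export
write_bigwig <- function(scores, population, chrom_sizes, path,
                         panel = NULL) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      is.null(names(chrom_sizes)))
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (is.numeric(population)) {
    stopifnot(!is.null(panel))
    population <- panel$names[[population]]
  }
  col <- paste0("finemav_", population)
  if (!col %in% names(scores))
    stop("no score column for population '", population, "'")
  .write_bigwig_intervals(scores$chrom, scores$pos, scores[[col]],
                          chrom_sizes, path)
}

# "3.5" -> "3.50" for the log echo; free-form values pass through
.fmt_penalty <- function(x) {
  if (grepl("^[0-9]+(\\.[0-9]{1,2})?$", format(x, trim = TRUE)))
    sprintf("%.2f", x)
  else format(x, trim = TRUE)
}

#' Write the run log
#'
#' Machine-parseable `key: value` lines: the configuration echo, totals,
#' per-reason rejection counts and wall-clock timestamps.
#'
#' @param summary A `finemav_run` from [run_pipeline()].
#' @param path Output path. I/O failure here warns rather than fails:
#'   the score outputs are already on disk.
#' @return Invisibly, `NULL`.
#' @export
write_log <- function(summary, path) {
  stopifnot(inherits(summary, "finemav_run"))
  cfg <- summary$config
  ct <- summary$counters
  lines <- c(
    "tool: finemav",
    paste0("started: ", format(summary$started, "%Y-%m-%d %H:%M:%S %Z")),
    paste0("finished: ", format(summary$finished, "%Y-%m-%d %H:%M:%S %Z")),
    paste0("variants: ", cfg$variants),
    paste0("annotations: ",
           if (is.null(cfg$annotations)) "-" else cfg$annotations),
    paste0("chrom_sizes: ",
           if (is.null(cfg$chrom_sizes)) "-" else cfg$chrom_sizes),
    paste0("out_prefix: ", cfg$out_prefix),
    paste0("populations: ", paste(cfg$panel$names, collapse = ",")),
    paste0("n_populations: ", cfg$panel$n),
    paste0("penalty_x: ", .fmt_penalty(cfg$penalty)),
    paste0("chunk_size: ", cfg$chunk_size),
    paste0("strict_ancestral: ", cfg$strict_ancestral),
    paste0("chunks_processed: ", ct$chunks),
    paste0("sites_read: ", ct$sites_read),
    paste0("sites_scored: ", ct$sites_scored),
    paste0("sites_rejected: ", sum(ct$rejected)))
  if (length(ct$rejected))
    lines <- c(lines, paste0("rejected_", names(ct$rejected), ": ",
                             ct$rejected))
  tryCatch(writeLines(lines, path),
           error = function(e)
             warning("could not write run log: ", conditionMessage(e)))
  invisible(NULL)
}

#' Per-population score percentiles
#'
#' Convenience for choosing a genome-browser threshold line (e.g. the
#' 99th percentile): computes quantiles of each population's scores from
#' a score table.
#'
#' @param scores A score `data.table` or a path to a score TSV.
#' @param probs Quantile probabilities (default 0.99).
#' @return A `data.table`: `population`, one column per probability.
#' @export
score_percentiles <- function(scores, probs = 0.99) {
  if (is.character(scores)) scores <- read_scores_tsv(scores)
  cols <- grep("^finemav_", names(scores), value = TRUE)
  if (length(cols) == 0L) stop("no finemav_* columns found")
  out <- data.table::rbindlist(lapply(cols, function(cn) {
    q <- stats::quantile(scores[[cn]], probs = probs, na.rm = TRUE,
                         names = FALSE)
    c(list(population = sub("^finemav_", "", cn)),
      stats::setNames(as.list(q), paste0("p", probs * 100)))
  }))
  out[]
}
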