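## Streaming engine: iterate the variant table in fixed-size line chunks,
## score each chunk, and merge results into the final outputs.

#' Iterate a text file in fixed-size line chunks
#'
#' Returns a reader function that yields successive blocks of at most
#' `chunk_size` lines and `NULL` at end of input. The concatenation of all
#' blocks equals the file's data lines exactly; every block except
#' possibly the last has exactly `chunk_size` lines. Memory use is bounded
#' by the chunk size, not the file size.
#'
#' @param path Path to a text file.
#' @param chunk_size Lines per chunk (positive integer).
#' @param header Skip one header line before the first chunk.
#' @return A function; each call returns a character vector of lines, or
#'   `NULL` when the input is exhausted (the connection is then closed).
#' @examples
#' f <- tempfile(); writeLines(as.character(1:5), f)
#' nxt <- iterate_chunks(f, 2)
#' nxt(); nxt(); nxt(); nxt()  # 2, 2, 1 lines, then NULL
#' @export
iterate_chunks <- function(path, chunk_size, header = FALSE) {
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    stop("chunk_size must be a positive integer")
  con <- file(path, open = "r")
  if (header) readLines(con, n = 1L)
  done <- FALSE
  offset <- if (header) 1L else 0L
  function() {
    if (done) return(NULL)
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) {
      close(con)
      done <<- TRUE
      return(NULL)
    }
    attr(lines, "line_offset") <- offset
    offset <<- offset + length(lines)
    lines
  }
}

#' Run the full scoring pipeline
#'
#' Streams the variant table in chunks of `config$chunk_size` lines;
#' each chunk is parsed, supplemented from the annotation lookup (loaded
#' once and held across chunks), polarised and scored, and its score rows
#' are appended to the output table. After the last chunk the
#' per-population bigWig tracks and the run log are written. Outputs are
#' identical for any chunk size. On failure, partial outputs are removed.
#'
#' Outputs, for `out_prefix` "P" and populations pop1..popn:
#' `P_finemav.tsv` (score table with intermediate quantities),
#' `P_<pop>.bw` (one bigWig per population, value = that population's
#' FineMAV score at each scored site), and `P.log` (machine-parseable
#' `key: value` run log).
#'
#' @param config A [finemav_config()].
#' @return An object of class `finemav_run`: counters (`sites_read`,
#'   `sites_scored`, `rejected` by reason, `chunks`), output paths, the
#'   config, and timestamps.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "finemav_config"))
  started <- Sys.time()
  panel <- config$panel

  if (!file.exists(config$variants))
    stop("variant table not found: ", config$variants)
  if (is.null(config$chrom_sizes))
    stop("a chromosome-sizes file is required for bigWig emission")
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)

  out_dir <- dirname(config$out_prefix)
  if (!dir.exists(out_dir))
    stop("output directory does not exist: ", out_dir)
  tsv_path <- paste0(config$out_prefix, "_finemav.tsv")
  bw_paths <- stats::setNames(
    paste0(config$out_prefix, "_", panel$names, ".bw"), panel$names)
  log_path <- paste0(config$out_prefix, ".log")
  # fail before processing if the output location is unwritable
  ok <- tryCatch({ file.create(tsv_path) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("cannot write to output path: ", tsv_path)

  ann <- NULL
  ann_keys <- NULL; ann_aa <- NULL; ann_cadd <- NULL
  if (!is.null(config$annotations)) {
    ann <- parse_vep_annotation(config$annotations)
    if (ann$n_entries > config$max_annotation_entries)
      stop("annotation table has ", ann$n_entries, " entries, over the ",
           config$max_annotation_entries, " in-memory budget; pre-join it ",
           "onto the variant table or raise max_annotation_entries")
    # plain-vector view of the lookup for cheap per-chunk match()
    ann_keys <- ann$table$location_key
    ann_aa <- ann$table$aa
    ann_cadd <- ann$table$cadd_phred
  }

  counters <- new.env(parent = emptyenv())
  counters$read <- 0L
  counters$scored <- 0L
  counters$chunks <- 0L
  counters$rejected <- integer(0)
  bump <- function(reasons) {
    if (length(reasons) == 0L) return(invisible())
    for (r in unique(reasons)) {
      counters$rejected[r] <- sum(counters$rejected[r],
                                  sum(reasons == r), na.rm = TRUE)
    }
  }

  # bigWig interval buffers: minimal columns, accumulated across chunks
  bw_chrom <- list(); bw_pos <- list(); bw_fm <- list()

  run <- function() {
    con_out <- file(tsv_path, open = "w")
    on.exit(close(con_out), add = TRUE)
    writeLines(paste(score_header(panel), collapse = "\t"), con_out)
    nxt <- iterate_chunks(config$variants, config$chunk_size,
                          header = config$header)
    repeat {
      lines <- nxt()
      if (is.null(lines)) break
      counters$chunks <- counters$chunks + 1L
      counters$read <- counters$read + length(lines)
      p <- .parse_block_raw(lines, panel, has_aa = config$has_aa,
                            has_cadd = config$has_cadd)
      ok <- is.na(p$reason)
      bump(p$reason[!ok])
      chrom <- p$chrom[ok]; pos <- p$pos[ok]; id <- p$id[ok]
      ref <- p$ref[ok]; alt <- p$alt[ok]; aa <- p$aa[ok]
      cadd <- p$cadd_phred[ok]; af <- p$af[ok, , drop = FALSE]
      if (!is.null(ann_keys) && length(chrom) > 0L) {
        hit <- match(paste0(chrom, ":", pos), ann_keys)
        fill_aa <- which(is.na(aa) & !is.na(hit))
        if (length(fill_aa)) {
          v <- ann_aa[hit[fill_aa]]
          aa[fill_aa[!is.na(v)]] <- v[!is.na(v)]
        }
        fill_cadd <- which(is.na(cadd) & !is.na(hit))
        if (length(fill_cadd)) {
          v <- ann_cadd[hit[fill_cadd]]
          cadd[fill_cadd[!is.na(v)]] <- v[!is.na(v)]
        }
      }
      sc <- .score_block_raw(ref, alt, aa, cadd, af, config$penalty,
                             strict_ancestral = config$strict_ancestral)
      keep <- is.na(sc$reason)
      bump(sc$reason[!keep])
      ns <- sum(keep)
      counters$scored <- counters$scored + ns
      if (ns > 0L) {
        writeLines(.format_lines_raw(
          chrom[keep], pos[keep], id[keep], ref[keep], alt[keep], aa[keep],
          sc$derived_allele, cadd[keep], sc$daf, sc$dap, sc$finemav),
          con_out)
        k <- length(bw_chrom) + 1L
        bw_chrom[[k]] <<- chrom[keep]
        bw_pos[[k]] <<- pos[keep]
        bw_fm[[k]] <<- sc$finemav
      }
    }
  }

  finished <- tryCatch({
    run()
    all_chrom <- unlist(bw_chrom, use.names = FALSE)
    all_pos <- unlist(bw_pos, use.names = FALSE)
    all_fm <- if (length(bw_fm)) do.call(rbind, bw_fm)
              else matrix(numeric(0), 0L, panel$n)
    if (length(all_chrom) == 0L) all_chrom <- character(0)
    for (j in seq_len(panel$n)) {
      .write_bigwig_intervals(all_chrom, all_pos, all_fm[, j],
                              chrom_sizes, bw_paths[[panel$names[j]]])
    }
    Sys.time()
  }, error = function(e) {
    unlink(c(tsv_path, bw_paths, log_path))
    stop("pipeline aborted (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })

  summary <- structure(list(
    counters = list(
      sites_read = counters$read, sites_scored = counters$scored,
      rejected = if (length(counters$rejected))
        counters$rejected[order(names(counters$rejected))] else integer(0),
      chunks = counters$chunks),
    paths = c(scores = tsv_path, bw_paths, log = log_path),
    config = config, started = started, finished = finished),
    class = "finemav_run")
  write_log(summary, log_path)
  summary
}

#' @export
print.finemav_run <- function(x, ...) {
  ct <- x$counters
  cat("<finemav_run> ", ct$sites_read, " sites read, ", ct$sites_scored,
      " scored, ", sum(ct$rejected), " rejected (", ct$chunks,
      " chunks)\n", sep = "")
  if (length(ct$rejected))
    for (r in names(ct$rejected))
      cat("  rejected ", r, ": ", ct$rejected[[r]], "\n", sep = "")
  cat("  scores: ", x$paths[["scores"]], "\n", sep = "")
  invisible(x)
}
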