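## Reading and validating the tab-delimited variant extract and the
## VEP-style annotation table, and joining the two.

.BASES <- c("A", "C", "G", "T")

# Vector-level parser used by both the data.table API and the streaming
# engine (which avoids data.table construction in its per-chunk hot path).
# Returns full-length parallel vectors plus a per-row rejection reason
# (NA when the row is well-formed). Reasons: MALFORMED_ROW (wrong field
# count), BAD_LOCATION, BAD_ALLELE, AF_OUT_OF_RANGE, CADD_INVALID.
.parse_block_raw <- function(lines, panel, has_aa = TRUE, has_cadd = TRUE) {
  n <- panel$n
  n_fields <- 4L + has_aa + has_cadd + n
  m <- length(lines)
  if (m == 0L)
    return(list(chrom = character(0), pos = integer(0), id = character(0),
                ref = character(0), alt = character(0), aa = character(0),
                cadd_phred = numeric(0),
                af = matrix(numeric(0), nrow = 0L, ncol = n),
                reason = character(0)))

  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  reason <- rep(NA_character_, m)
  if (length(fields) != n_fields) {
    # ragged rows: fall back to per-row field counts
    counts <- lengths(strsplit(lines, "\t", fixed = TRUE))
    reason[counts != n_fields] <- "MALFORMED_ROW"
    # tstrsplit pads short rows with NA; overlong rows lose tail fields.
    # Both are already flagged; pad the column list if the file is narrow.
    if (length(fields) < n_fields)
      fields <- c(fields, rep(list(rep(NA_character_, m)),
                              n_fields - length(fields)))
  } else {
    short <- Reduce(`|`, lapply(fields, is.na))
    # NA from tstrsplit padding means the row had too few fields; a literal
    # empty field parses as "" not NA, so this is unambiguous
    reason[short] <- "MALFORMED_ROW"
  }

  loc <- fields[[1L]]
  colon <- regexpr(":", loc, fixed = TRUE)
  chrom <- ifelse(colon > 0L, substr(loc, 1L, colon - 1L), NA_character_)
  pos <- suppressWarnings(as.integer(substr(loc, colon + 1L, nchar(loc))))
  bad_loc <- is.na(reason) & (colon <= 1L | is.na(pos) | pos < 1L |
                                !nzchar(chrom))
  reason[bad_loc] <- "BAD_LOCATION"

  ref <- toupper(fields[[3L]])
  alt <- toupper(fields[[4L]])
  bad_allele <- is.na(reason) &
    (!(ref %in% .BASES) | !(alt %in% .BASES) | ref == alt)
  reason[bad_allele] <- "BAD_ALLELE"

  i <- 5L
  aa <- rep(NA_character_, m)
  if (has_aa) {
    aa <- fields[[i]]
    aa[!is.na(aa) & aa %in% c("", ".", "-")] <- NA_character_
    i <- i + 1L
  }
  cadd <- rep(NA_real_, m)
  if (has_cadd) {
    raw <- fields[[i]]
    blank <- is.na(raw) | raw %in% c("", ".")
    cadd <- suppressWarnings(as.numeric(raw))
    bad_cadd <- is.na(reason) & !blank & (is.na(cadd) | cadd < 0)
    reason[bad_cadd] <- "CADD_INVALID"
    cadd[blank] <- NA_real_
    i <- i + 1L
  }

  af <- matrix(NA_real_, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    af[, j] <- suppressWarnings(as.numeric(fields[[i + j - 1L]]))
  }
  bad_af <- is.na(reason) &
    (rowSums(is.na(af)) > 0L | rowSums(af < 0 | af > 1, na.rm = TRUE) > 0L)
  reason[bad_af] <- "AF_OUT_OF_RANGE"

  list(chrom = chrom, pos = pos, id = fields[[2L]], ref = ref, alt = alt,
       aa = aa, cadd_phred = cadd, af = af, reason = reason)
}

# Parse a block of raw variant-table lines into validated records.
# Returns list(records = data.table, rejects = data.table(line, reason)).
# Line numbers are 1-based in the original file; `line_offset` is the
# number of lines already consumed.
parse_variant_block <- function(lines, panel, has_aa = TRUE,
                                has_cadd = TRUE, line_offset = 0L) {
  raw <- .parse_block_raw(lines, panel, has_aa = has_aa, has_cadd = has_cadd)
  ok <- is.na(raw$reason)
  records <- data.table::data.table(
    chrom = raw$chrom[ok], pos = raw$pos[ok], id = raw$id[ok],
    ref = raw$ref[ok], alt = raw$alt[ok], aa = raw$aa[ok],
    cadd_phred = raw$cadd_phred[ok])
  af_dt <- data.table::as.data.table(raw$af[ok, , drop = FALSE])
  data.table::setnames(af_dt, paste0("af_", seq_len(panel$n)))
  records <- cbind(records, af_dt)
  rejects <- data.table::data.table(
    line = which(!ok) + as.integer(line_offset), reason = raw$reason[!ok])
  list(records = records, rejects = rejects)
}

#' Read and validate a tab-delimited variant extract
#'
#' Reads the whole table into memory; [run_pipeline()] uses the same parser
#' chunk-wise for large files. Each well-formed row becomes one record;
#' malformed rows (wrong field count, unparsable location, non-ACGT or
#' identical alleles, frequencies outside `[0, 1]`, negative or unparsable
#' CADD) are counted and skipped with a reason code, never silently
#' altered. File order is preserved.
#'
#' @param path Path to the tab-delimited file (no header unless `header`).
#' @param panel A [population_panel()]; the table must have one frequency
#'   column per population, in panel order, after the fixed columns.
#' @param has_aa,has_cadd Whether the `AA` / `CADD_PHRED` columns are
#'   present between `ALT` and the frequency columns.
#' @param header Skip one header line.
#' @return A list: `records` (a `data.table`: `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `aa`, `cadd_phred`, `af_1..af_n`), `rejects` (a `data.table`
#'   of 1-based `line` and `reason`), and `n_read` (data lines seen).
#' @examples
#' f <- tempfile()
#' writeLines("2:109513601\trs3827760\tA\tG\tA\t21.75\t0.922\t0.029\t0.490", f)
#' parse_variant_table(f, population_panel(c("90HC", "SSIP", "SSMP")))$records
#' @export
parse_variant_table <- function(path, panel, has_aa = TRUE, has_cadd = TRUE,
                                header = FALSE) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  lines <- readLines(path)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  out <- parse_variant_block(lines, panel, has_aa = has_aa,
                             has_cadd = has_cadd,
                             line_offset = if (header) 1L else 0L)
  out$n_read <- length(lines)
  out
}

#' Parse a VEP-style annotation table into a location-keyed lookup
#'
#' The table must be tab-delimited with a header; the first column is the
#' location in `chromosome:start` (or `chromosome:start-end`) form, and
#' columns named `AA` and/or `CADD_PHRED` (case-insensitive) supply the
#' ancestral allele and CADD score. Single-base ranges `c:s-s` normalise
#' to `c:s`; multi-base ranges are skipped (the statistic is defined for
#' SNPs only). On duplicate keys the first occurrence wins and a warning
#' is counted.
#'
#' @param path Path to the annotation file.
#' @return An object of class `finemav_annotation`: a list with `table`
#'   (a keyed `data.table`: `location_key`, `aa`, `cadd_phred`),
#'   `n_entries`, `n_duplicates` and `skipped` (a `data.table` of `line`,
#'   `reason`).
#' @export
parse_vep_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = TRUE)
  if (ncol(dt) < 2L)
    stop("annotation table needs a Location column plus AA and/or ",
         "CADD_PHRED columns")
  cn <- toupper(names(dt))
  aa_col <- which(cn == "AA")[1L]
  cadd_col <- which(cn == "CADD_PHRED")[1L]
  if (is.na(aa_col) && is.na(cadd_col))
    stop("annotation header has neither an AA nor a CADD_PHRED column")

  loc <- dt[[1L]]
  m <- length(loc)
  # chrom:start or chrom:start-end
  ok_form <- grepl("^[^:[:space:]]+:[0-9]+(-[0-9]+)?$", loc)
  reason <- rep(NA_character_, m)
  reason[!ok_form] <- "BAD_LOCATION"
  rng <- grepl("-", loc, fixed = TRUE) & ok_form
  if (any(rng)) {
    parts <- data.table::tstrsplit(sub("^[^:]+:", "", loc[rng]), "-",
                                   fixed = TRUE)
    s <- as.numeric(parts[[1L]]); e <- as.numeric(parts[[2L]])
    bad_rng <- s != e
    idx <- which(rng)
    reason[idx[bad_rng]] <- "RANGE_NOT_SNP"
    loc[idx[!bad_rng]] <- paste0(sub(":[0-9]+-[0-9]+$", "", loc[idx[!bad_rng]]),
                                 ":", format(s[!bad_rng], scientific = FALSE,
                                             trim = TRUE))
  }
  ok <- is.na(reason)
  skipped <- data.table::data.table(line = which(!ok) + 1L,
                                    reason = reason[!ok])

  aa <- if (!is.na(aa_col)) dt[[aa_col]][ok] else rep(NA_character_, sum(ok))
  aa[!is.na(aa) & aa %in% c("", ".", "-")] <- NA_character_
  cadd <- if (!is.na(cadd_col))
    suppressWarnings(as.numeric(dt[[cadd_col]][ok])) else
    rep(NA_real_, sum(ok))
  cadd[!is.na(cadd) & cadd < 0] <- NA_real_

  tab <- data.table::data.table(location_key = loc[ok], aa = aa,
                                cadd_phred = cadd)
  dup <- duplicated(tab$location_key)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning(n_dup, " duplicate annotation key(s); first occurrence kept")
    tab <- tab[!dup]
  }
  data.table::setkey(tab, location_key)
  structure(list(table = tab, n_entries = nrow(tab),
                 n_duplicates = n_dup, skipped = skipped),
            class = "finemav_annotation")
}

#' @export
print.finemav_annotation <- function(x, ...) {
  cat("<finemav_annotation> ", x$n_entries, " entries (",
      x$n_duplicates, " duplicates dropped, ", nrow(x$skipped),
      " rows skipped)\n", sep = "")
  invisible(x)
}

#' Fill missing AA / CADD_PHRED fields from an annotation lookup
#'
#' For each record lacking an ancestral allele or CADD score, fills the
#' missing field from the annotation entry at the record's `chrom:pos`
#' key, when one exists. Fields already present in the variant table are
#' never overwritten, so merging is idempotent. Records still lacking
#' required fields pass through; the downstream filter policy rejects
#' them with a counted reason.
#'
#' @param records A `data.table` of variant records
#'   (see [parse_variant_table()]).
#' @param ann A `finemav_annotation` from [parse_vep_annotation()], or
#'   `NULL` (no-op).
#' @return The records with `aa` / `cadd_phred` gaps filled where possible.
#' @export
merge_annotations <- function(records, ann) {
  if (is.null(ann)) return(records)
  stopifnot(inherits(ann, "finemav_annotation"))
  records <- data.table::copy(records)
  key <- paste0(records$chrom, ":", records$pos)
  hit <- ann$table[data.table::data.table(location_key = key),
                   on = "location_key"]
  fill_aa <- is.na(records$aa) & !is.na(hit$aa)
  if (any(fill_aa)) records[fill_aa, aa := hit$aa[fill_aa]]
  fill_cadd <- is.na(records$cadd_phred) & !is.na(hit$cadd_phred)
  if (any(fill_cadd))
    records[fill_cadd, cadd_phred := hit$cadd_phred[fill_cadd]]
  records[]
}

#' Read a chromosome-sizes table
#'
#' Two tab-delimited columns (chromosome name, length in bases), as used
#' by the standard bigWig toolchain. Names are taken verbatim; no "chr"
#' prefix normalisation is applied.
#'
#' @param path Path to the chromosome-sizes file.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chromosome-sizes file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) stop("chromosome-sizes file is empty: ", path)
  if (anyDuplicated(dt$chrom)) stop("duplicate chromosome names in ", path)
  sizes <- as.numeric(dt$size)
  if (any(is.na(sizes) | sizes < 1)) stop("invalid chromosome length in ", path)
  stats::setNames(sizes, dt$chrom)
}
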