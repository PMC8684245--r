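## Core statistic: ancestral polarisation, derived allele purity (DAP),
## and the per-population FineMAV score DAP * DAF_i * CADD_PHRED.

.PENALTY_DEFAULTS <- c(`2` = 4.96, `3` = 3.50, `4` = 2.98,
                       `5` = 2.71, `6` = 2.53, `7` = 2.41)

#' Recommended purity penalty exponent for a panel size
#'
#' Returns the recommended minimal penalty parameter x for `n` populations.
#' These constants were derived empirically for panels of 2 to 7
#' populations; larger panels require an explicit user-chosen x.
#'
#' @param n Number of populations (integer, 2..7 for defaults).
#' @return The penalty exponent x.
#' @examples
#' default_penalty(3) # 3.50
#' @export
default_penalty <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop("the statistic needs at least 2 populations (got n = ", n, ")")
  if (n > 7L)
    stop("no recommended penalty for n = ", n,
         ": defaults cover 2-7 populations; supply the penalty x explicitly",
         " (e.g. --penalty) for larger panels")
  unname(.PENALTY_DEFAULTS[as.character(n)])
}

# ancestral-allele codes that mean "unknown"
.AA_MISSING_CODES <- c(".", "-", "N", "n")

#' Polarise one site to derived allele frequencies
#'
#' Orients a biallelic SNP against its ancestral allele: if the ancestral
#' allele equals REF the derived allele is ALT and the DAF vector is the
#' alternate-allele frequencies as given; if it equals ALT the derived
#' allele is REF and the DAF vector is their complement. A lowercase
#' ancestral call marks a low-confidence inference (Ensembl convention);
#' it is accepted by default and rejected under `strict_ancestral`.
#'
#' @param ref,alt Reference and alternate alleles (single bases).
#' @param aa Ancestral allele, or `NA`/`"."`/`"-"`/`"N"` when unknown.
#' @param af_alt Numeric vector of per-population alternate-allele
#'   frequencies in `[0, 1]`.
#' @param strict_ancestral Reject low-confidence (lowercase) calls.
#' @return A list: `status` (`"ok"` or `"rejected"`), and on success
#'   `daf` (per-population derived allele frequency), `derived_allele` and
#'   `low_confidence`; on rejection `reason` (`"AA_MISSING"`,
#'   `"AA_LOW_CONFIDENCE"` or `"AA_MISMATCH"`).
#' @examples
#' polarize("A", "G", "G", c(0.3, 0.9))  # derived = A, daf = (0.7, 0.1)
#' @export
polarize <- function(ref, alt, aa, af_alt, strict_ancestral = FALSE) {
  stopifnot(length(ref) == 1L, length(alt) == 1L, length(aa) == 1L)
  if (ref == alt) stop("ref and alt must differ (biallelic SNP contract)")
  if (any(!is.finite(af_alt)) || any(af_alt < 0) || any(af_alt > 1))
    stop("af_alt must lie in [0, 1]")
  if (is.na(aa) || aa %in% .AA_MISSING_CODES)
    return(list(status = "rejected", reason = "AA_MISSING"))
  low_conf <- aa != toupper(aa)
  if (low_conf && strict_ancestral)
    return(list(status = "rejected", reason = "AA_LOW_CONFIDENCE"))
  aa_up <- toupper(aa)
  if (aa_up == toupper(ref)) {
    list(status = "ok", daf = af_alt, derived_allele = alt,
         low_confidence = low_conf)
  } else if (aa_up == toupper(alt)) {
    list(status = "ok", daf = 1 - af_alt, derived_allele = ref,
         low_confidence = low_conf)
  } else {
    list(status = "rejected", reason = "AA_MISMATCH")
  }
}

#' Derived allele purity
#'
#' DAP measures how confined the derived allele is to a single population.
#' With per-population derived allele frequencies d_1..d_n, the total is
#' d_N = sum(d_i), each population's share is f_i = d_i / d_N, and
#' DAP = sum(f_i ^ x). Frequencies (not counts) feed the shares, so
#' unequal population sizes need no correction. DAP is 1 when exactly one
#' population carries the derived allele and falls to n^(1 - x) when all
#' share it equally. When the derived allele is absent everywhere
#' (d_N = 0) DAP is defined as 0, which keeps every downstream score 0.
#'
#' @param daf Numeric vector of per-population derived allele frequencies
#'   (one site), or a matrix with one site per row.
#' @param x Penalty exponent, > 1.
#' @return A single DAP in `[0, 1]`, or a vector of one per matrix row.
#' @examples
#' compute_dap(c(1, 0, 0), 3.5)            # 1: fully population-specific
#' compute_dap(c(0.5, 0.5), 4.96)          # 2^(1 - 4.96): equal sharing
#' @export
compute_dap <- function(daf, x) {
  x <- as.numeric(x)
  if (!is.finite(x) || x <= 1) stop("penalty x must exceed 1")
  if (is.matrix(daf)) {
    if (any(!is.finite(daf)) || any(daf < 0) || any(daf > 1))
      stop("daf values must lie in [0, 1]")
    d_n <- rowSums(daf)
    dap <- numeric(nrow(daf))
    nz <- d_n > 0
    if (any(nz)) dap[nz] <- rowSums((daf[nz, , drop = FALSE] / d_n[nz])^x)
    dap
  } else {
    daf <- as.numeric(daf)
    if (any(!is.finite(daf)) || any(daf < 0) || any(daf > 1))
      stop("daf values must lie in [0, 1]")
    d_n <- sum(daf)
    if (d_n == 0) 0 else sum((daf / d_n)^x)
  }
}

#' Score one polarised site
#'
#' The per-population FineMAV score is DAP x DAF_i x CADD_PHRED: high when
#' a derived allele is frequent, population-specific, and predicted
#' functional.
#'
#' @param daf Per-population derived allele frequencies of one site.
#' @param cadd_phred Phred-scaled CADD score of the site (>= 0).
#' @param x Penalty exponent, > 1.
#' @return A list with `dap` and `finemav` (vector, one score per
#'   population).
#' @examples
#' compute_scores(c(0.922, 0.029, 0.490), cadd_phred = 20, x = 3.5)
#' @export
compute_scores <- function(daf, cadd_phred, x) {
  if (is.na(cadd_phred)) stop("cadd_phred is required to score a site")
  if (cadd_phred < 0) stop("cadd_phred must be non-negative")
  dap <- compute_dap(daf, x)
  list(dap = dap, finemav = dap * daf * cadd_phred)
}

#' Score a table of annotated variant records
#'
#' The vectorised production path: polarises every record, applies the
#' filter policy (missing/mismatching ancestral alleles and missing CADD
#' scores are rejected with a reason, never scored as 0), and computes DAP
#' and the per-population FineMAV scores.
#'
#' @param records A `data.table` of parsed variant records as returned by
#'   [parse_variant_table()] (columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `aa`, `cadd_phred`, `af_1..af_n`).
#' @param panel A [population_panel()]; its order names the `daf_*` and
#'   `finemav_*` output columns.
#' @param x Penalty exponent, > 1.
#' @param strict_ancestral Reject lowercase (low-confidence) ancestral
#'   calls.
#' @return A list with `scores` (a `data.table`, one row per scored site:
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `aa`, `derived_allele`,
#'   `cadd_phred`, `daf_<pop>` per population, `dap`, `finemav_<pop>` per
#'   population) and `rejects` (a `data.table` of `id`, `pos`, `reason`).
#' @export
score_sites <- function(records, panel, x, strict_ancestral = FALSE) {
  stopifnot(inherits(panel, "finemav_panel"))
  n <- panel$n
  af_cols <- paste0("af_", seq_len(n))
  if (!all(af_cols %in% names(records)))
    stop("records lack the expected frequency columns ",
         paste(af_cols, collapse = ", "))
  af <- as.matrix(records[, af_cols, with = FALSE])
  sc <- .score_block_raw(records$ref, records$alt, records$aa,
                         records$cadd_phred, af, x, strict_ancestral)
  keep <- is.na(sc$reason)
  rejects <- data.table::data.table(
    id = records$id[!keep], pos = records$pos[!keep],
    reason = sc$reason[!keep])
  if (!any(keep))
    return(list(scores = .empty_scores(panel), rejects = rejects))

  scores <- data.table::data.table(
    chrom = records$chrom[keep], pos = records$pos[keep],
    id = records$id[keep], ref = records$ref[keep],
    alt = records$alt[keep], aa = records$aa[keep],
    derived_allele = sc$derived_allele, cadd_phred = records$cadd_phred[keep])
  daf_dt <- data.table::as.data.table(sc$daf)
  data.table::setnames(daf_dt, paste0("daf_", panel$names))
  fm_dt <- data.table::as.data.table(sc$finemav)
  data.table::setnames(fm_dt, paste0("finemav_", panel$names))
  scores <- cbind(scores, daf_dt, dap = sc$dap, fm_dt)
  list(scores = scores, rejects = rejects)
}

# Vectorised polarise+score on parallel vectors; the engine's hot path.
# Returns full-length `reason` (NA where scored) and, for scored rows
# only, `derived_allele`, `daf`/`finemav` (matrices) and `dap`.
.score_block_raw <- function(ref, alt, aa, cadd_phred, af, x,
                             strict_ancestral = FALSE) {
  m <- length(ref)
  reason <- rep(NA_character_, m)
  missing_aa <- is.na(aa) | aa %in% .AA_MISSING_CODES
  reason[missing_aa] <- "AA_MISSING"
  if (strict_ancestral) {
    low_conf <- !missing_aa & aa != toupper(aa)
    reason[is.na(reason) & low_conf] <- "AA_LOW_CONFIDENCE"
  }
  aa_up <- toupper(aa)
  anc_ref <- is.na(reason) & aa_up == toupper(ref)
  anc_alt <- is.na(reason) & !anc_ref & aa_up == toupper(alt)
  reason[is.na(reason) & !anc_ref & !anc_alt] <- "AA_MISMATCH"
  reason[is.na(reason) & is.na(cadd_phred)] <- "CADD_MISSING"

  keep <- is.na(reason)
  if (!any(keep))
    return(list(reason = reason, derived_allele = character(0),
                daf = af[0L, , drop = FALSE], dap = numeric(0),
                finemav = af[0L, , drop = FALSE]))
  flip <- anc_alt[keep]
  daf <- af[keep, , drop = FALSE]
  daf[flip, ] <- 1 - daf[flip, , drop = FALSE]
  dap <- compute_dap(daf, x)
  fm <- daf * (dap * cadd_phred[keep])
  list(reason = reason,
       derived_allele = ifelse(flip, ref[keep], alt[keep]),
       daf = daf, dap = dap, finemav = fm)
}

# empty ScoreRow table with the right columns for a panel
.empty_scores <- function(panel) {
  cols <- c("chrom", "pos", "id", "ref", "alt", "aa", "derived_allele",
            "cadd_phred", paste0("daf_", panel$names), "dap",
            paste0("finemav_", panel$names))
  out <- data.table::as.data.table(
    stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out[, c("chrom", "id", "ref", "alt", "aa", "derived_allele") :=
        list(character(0), character(0), character(0), character(0),
             character(0), character(0))]
  out[, pos := integer(0)]
  data.table::setcolorder(out, cols)
  out[]
}
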