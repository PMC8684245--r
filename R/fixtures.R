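## Synthetic, schema-conformant inputs with known ground truth, plus a
## deliberately naive scoring oracle. The generator targets schema and
## statistic coverage (site classes, defect classes), not population
## genetics realism: no linkage, demography or selection is simulated.

#' Describe a synthetic input fixture
#'
#' Sites are drawn independently. A `frac_specific` fraction carries a
#' derived allele confined to one (random) population (truth DAP = 1);
#' defect fractions inject one defect class each (ancestral allele
#' missing, ancestral allele matching neither observed allele, CADD score
#' absent everywhere, one allele frequency out of range); everything else
#' is a clean shared polymorphism with per-population DAF drawn uniformly
#' on `daf_range` and CADD_PHRED uniformly on `cadd_range`. A
#' `frac_annotated` fraction of non-defective sites has its AA and CADD
#' blanked in the variant table and supplied through the annotation file
#' instead, exercising the join.
#'
#' @param n_sites Number of variant rows to generate.
#' @param populations Population labels (>= 2).
#' @param frac_specific Fraction of population-specific sites.
#' @param frac_aa_missing,frac_aa_mismatch,frac_cadd_missing,frac_malformed_af
#'   Defect fractions; all fractions must sum to <= 1.
#' @param frac_annotated Fraction of rows whose AA/CADD arrive via the
#'   annotation file rather than the variant table.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param daf_range,cadd_range Uniform sampling ranges for derived allele
#'   frequencies and CADD_PHRED scores.
#' @return An object of class `finemav_fixture_spec`.
#' @export
fixture_spec <- function(n_sites = 1000L,
                         populations = c("POP1", "POP2", "POP3"),
                         frac_specific = 0.2,
                         frac_aa_missing = 0, frac_aa_mismatch = 0,
                         frac_cadd_missing = 0, frac_malformed_af = 0,
                         frac_annotated = 0.3, seed = 1L,
                         daf_range = c(0, 1), cadd_range = c(0, 40)) {
  panel <- population_panel(populations)
  fracs <- c(specific = frac_specific, aa_missing = frac_aa_missing,
             aa_mismatch = frac_aa_mismatch, cadd_missing = frac_cadd_missing,
             malformed_af = frac_malformed_af)
  if (any(fracs < 0) || sum(fracs) > 1)
    stop("site-class fractions must be non-negative and sum to <= 1")
  structure(list(n_sites = as.integer(n_sites), panel = panel,
                 fracs = fracs, frac_annotated = frac_annotated,
                 seed = as.integer(seed), daf_range = daf_range,
                 cadd_range = cadd_range),
            class = "finemav_fixture_spec")
}

#' Generate a synthetic fixture on disk
#'
#' Writes a conforming variant table (headerless, with AA and CADD_PHRED
#' columns), a VEP-style annotation table, a chromosome-sizes file and a
#' ground-truth table. Truth DAP and scores are computed with
#' [oracle_score()], the naive reference implementation, so the fixture
#' is independent of the production scoring path. Byte-identical given
#' the same spec (including seed).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @param x Penalty exponent used for the truth scores; default is
#'   [default_penalty()] of the panel size.
#' @return A list of paths (`variants`, `annotations`, `chrom_sizes`,
#'   `truth`) plus the `truth` `data.table` itself: per site, the class,
#'   the expected rejection reason (`"."` for clean sites) and the
#'   oracle-computed `dap` and `finemav_*` values.
#' @export
generate_fixture <- function(spec, dir = tempfile("finemav_fixture_"),
                             x = NULL) {
  stopifnot(inherits(spec, "finemav_fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- spec$panel
  n <- panel$n
  m <- spec$n_sites
  if (is.null(x)) x <- default_penalty(n)
  set.seed(spec$seed)

  # site classes, exact counts, shuffled deterministically
  counts <- round(spec$fracs * m)
  while (sum(counts) > m) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  classes <- sample(rep(c(names(counts), "shared"),
                        c(counts, m - sum(counts))))

  chroms <- c("1", "2")
  chrom_len <- 2e6
  chrom <- sample(chroms, m, replace = TRUE)
  pos <- integer(m)
  for (cc in chroms) {
    idx <- chrom == cc
    pos[idx] <- sample.int(chrom_len - 1L, sum(idx))  # unique per chrom
  }
  id <- sprintf("fx%06d", seq_len(m))
  ref <- sample(.BASES, m, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), ""))
  cadd <- round(runif(m, spec$cadd_range[1], spec$cadd_range[2]), 3)

  daf <- matrix(round(runif(m * n, spec$daf_range[1], spec$daf_range[2]), 3),
                nrow = m)
  specific <- classes == "specific"
  if (any(specific)) {
    daf[specific, ] <- 0
    owner <- sample.int(n, sum(specific), replace = TRUE)
    daf[cbind(which(specific), owner)] <-
      round(runif(sum(specific), 0.2, 1), 3)
  }

  # ancestral allele: ref or alt at random; af_alt follows from the daf
  anc_is_ref <- sample(c(TRUE, FALSE), m, replace = TRUE)
  aa <- ifelse(anc_is_ref, ref, alt)
  af <- daf
  af[!anc_is_ref, ] <- 1 - af[!anc_is_ref, , drop = FALSE]

  # defects
  aa[classes == "aa_missing"] <- sample(c(".", "N", "-"),
                                        sum(classes == "aa_missing"),
                                        replace = TRUE)
  mm <- classes == "aa_mismatch"
  if (any(mm))
    aa[mm] <- mapply(function(r, a) sample(setdiff(.BASES, c(r, a)), 1L),
                     ref[mm], alt[mm])
  cadd_chr <- formatC(cadd, format = "fg", digits = 8)
  cadd_chr[classes == "cadd_missing"] <- "."
  af_chr <- matrix(formatC(af, format = "fg", digits = 8), nrow = m)
  bad_af <- classes == "malformed_af"
  if (any(bad_af))
    af_chr[cbind(which(bad_af), sample.int(n, sum(bad_af), replace = TRUE))] <-
      "1.5"

  # route a fraction of non-defective rows' AA/CADD through the VEP file
  eligible <- classes %in% c("shared", "specific")
  via_ann <- eligible & runif(m) < spec$frac_annotated
  aa_tab <- aa; cadd_tab <- cadd_chr
  aa_tab[via_ann] <- "."
  cadd_tab[via_ann] <- "."

  variants_path <- file.path(dir, "variants.tsv")
  rows <- paste(paste0(chrom, ":", pos), id, ref, alt, aa_tab, cadd_tab,
                sep = "\t")
  for (j in seq_len(n)) rows <- paste(rows, af_chr[, j], sep = "\t")
  writeLines(rows, variants_path)

  ann_path <- file.path(dir, "annotations.tsv")
  ann_rows <- paste(paste0(chrom[via_ann], ":", pos[via_ann]),
                    aa[via_ann], cadd_chr[via_ann], sep = "\t")
  writeLines(c("Location\tAA\tCADD_PHRED", ann_rows), ann_path)

  sizes_path <- file.path(dir, "chrom.sizes")
  writeLines(paste(chroms, format(chrom_len, scientific = FALSE),
                   sep = "\t"), sizes_path)

  # ground truth via the naive oracle
  expected_reason <- rep(".", m)
  expected_reason[classes == "aa_missing"] <- "AA_MISSING"
  expected_reason[classes == "aa_mismatch"] <- "AA_MISMATCH"
  expected_reason[classes == "cadd_missing"] <- "CADD_MISSING"
  expected_reason[classes == "malformed_af"] <- "AF_OUT_OF_RANGE"
  truth <- data.table::data.table(
    chrom = chrom, pos = pos, id = id, class = classes,
    expected_reason = expected_reason)
  dap_t <- rep(NA_real_, m)
  fm_t <- matrix(NA_real_, nrow = m, ncol = n)
  for (k in which(expected_reason == ".")) {
    o <- oracle_score(ref[k], alt[k], aa[k], af[k, ], cadd[k], x)
    stopifnot(o$status == "ok")
    dap_t[k] <- o$dap
    fm_t[k, ] <- o$finemav
  }
  truth[, dap := dap_t]
  for (j in seq_len(n))
    truth[, paste0("finemav_", panel$names[j]) := fm_t[, j]]
  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t", na = ".")

  list(variants = variants_path, annotations = ann_path,
       chrom_sizes = sizes_path, truth_path = truth_path, truth = truth,
       panel = panel, x = x, dir = dir)
}

#' Naive reference scorer (test oracle)
#'
#' A deliberately unvectorised, loop-based re-implementation of
#' polarisation, derived allele purity and the per-population score,
#' sharing no code with the production path. It exists so that tests can
#' check the two independently-written routes agree; it is not meant to
#' be fast.
#'
#' @param ref,alt,aa Alleles for one site.
#' @param af_alt Per-population alternate-allele frequencies.
#' @param cadd_phred CADD score (`NA` if absent).
#' @param x Penalty exponent.
#' @param strict_ancestral Reject lowercase ancestral calls.
#' @return A list: `status` (`"ok"`/`"rejected"`), `reason` on rejection;
#'   on success `daf`, `derived_allele`, `dap`, `finemav`.
#' @export
oracle_score <- function(ref, alt, aa, af_alt, cadd_phred, x,
                         strict_ancestral = FALSE) {
  upper <- function(ch) {
    from <- c("a", "c", "g", "t"); to <- c("A", "C", "G", "T")
    for (k in seq_along(from)) if (identical(ch, from[k])) return(to[k])
    ch
  }
  if (is.na(aa) || identical(aa, ".") || identical(aa, "-") ||
      identical(aa, "N") || identical(aa, "n"))
    return(list(status = "rejected", reason = "AA_MISSING"))
  is_lower <- aa %in% c("a", "c", "g", "t")
  if (is_lower && strict_ancestral)
    return(list(status = "rejected", reason = "AA_LOW_CONFIDENCE"))
  aa_u <- upper(aa)
  daf <- numeric(length(af_alt))
  if (identical(aa_u, upper(ref))) {
    for (i in seq_along(af_alt)) daf[i] <- af_alt[i]
    derived <- alt
  } else if (identical(aa_u, upper(alt))) {
    for (i in seq_along(af_alt)) daf[i] <- 1 - af_alt[i]
    derived <- ref
  } else {
    return(list(status = "rejected", reason = "AA_MISMATCH"))
  }
  if (is.na(cadd_phred))
    return(list(status = "rejected", reason = "CADD_MISSING"))
  d_n <- 0
  for (i in seq_along(daf)) d_n <- d_n + daf[i]
  if (d_n == 0) {
    dap <- 0
  } else {
    dap <- 0
    for (i in seq_along(daf)) dap <- dap + (daf[i] / d_n)^x
  }
  fm <- numeric(length(daf))
  for (i in seq_along(daf)) fm[i] <- dap * daf[i] * cadd_phred
  list(status = "ok", daf = daf, derived_allele = derived,
       dap = dap, finemav = fm)
}
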