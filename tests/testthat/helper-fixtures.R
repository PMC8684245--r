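# Shared test helpers: small on-the-fly inputs, never stored fixtures.

trio_panel <- function() population_panel(c("90HC", "SSIP", "SSMP"))

# write a headerless variant table (AA + CADD columns) from row strings
write_variants <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path)
  path
}

# render one variant row in the input dialect
variant_row <- function(chrom, pos, id, ref, alt, aa, cadd, af) {
  paste(c(paste0(chrom, ":", pos), id, ref, alt, aa, cadd,
          format(af, trim = TRUE, scientific = FALSE)), collapse = "\t")
}

# a fixture with every defect class, shared across tests
defect_spec <- function(n_sites = 1000L, seed = 42L) {
  fixture_spec(n_sites = n_sites, populations = c("POP1", "POP2", "POP3"),
               frac_specific = 0.15, frac_aa_missing = 0.05,
               frac_aa_mismatch = 0.05, frac_cadd_missing = 0.05,
               frac_malformed_af = 0.05, frac_annotated = 0.3, seed = seed)
}

# run the pipeline on a generated fixture, returning the summary
run_fixture <- function(fx, tag, chunk_size = 200000L, ...) {
  dir <- file.path(tempdir(), paste0("fmrun_", tag))
  dir.create(dir, showWarnings = FALSE)
  cfg <- finemav_config(fx$variants, fx$panel,
                        out_prefix = file.path(dir, "out"),
                        chrom_sizes = fx$chrom_sizes,
                        annotations = fx$annotations,
                        chunk_size = chunk_size, ...)
  run_pipeline(cfg)
}

# random clean polarisable records table for oracle-vs-production checks
random_records <- function(m, n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1L), ""))
  aa <- ifelse(runif(m) < 0.5, ref, alt)
  # some lowercase (low-confidence) ancestral calls
  low <- runif(m) < 0.1
  aa[low] <- tolower(aa[low])
  dt <- data.table::data.table(
    chrom = sample(c("1", "2"), m, replace = TRUE),
    pos = sample.int(1e6, m), id = sprintf("s%06d", seq_len(m)),
    ref = ref, alt = alt, aa = aa,
    cadd_phred = runif(m, 0, 40))
  for (j in seq_len(n)) dt[, paste0("af_", j) := runif(m)]
  dt
}
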