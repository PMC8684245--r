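panel3 <- population_panel(c("90HC", "SSIP", "SSMP"))

test_that("well-formed rows parse to records preserving file order", {
  rows <- c(
    "2:109513601\trs3827760\tA\tG\tA\t21.75\t0.922\t0.029\t0.490",
    "7:100371358\trs2293766\tG\tA\tg\t.\t0.528\t0.257\t0.557")
  p <- parse_variant_table(write_variants(rows), panel3)
  expect_equal(nrow(p$records), 2L)
  expect_equal(nrow(p$rejects), 0L)
  r <- p$records[1]
  expect_equal(r$chrom, "2")
  expect_equal(r$pos, 109513601L)
  expect_equal(r$id, "rs3827760")
  expect_equal(r$ref, "A")
  expect_equal(r$alt, "G")
  expect_equal(unlist(r[, .(af_1, af_2, af_3)], use.names = FALSE),
               c(0.922, 0.029, 0.490))
  # lowercase ancestral call and missing CADD survive parsing as-is
  expect_equal(p$records$aa[2], "g")
  expect_true(is.na(p$records$cadd_phred[2]))
})

test_that("malformed rows are rejected with reasons, never altered", {
  rows <- c(
    "1:100\ts1\tA\tG\tA\t10\t0.1\t0.2\t0.3",      # clean
    "1:101\ts2\tA\tG\tA\t10\t1.5\t0.2\t0.3",      # AF out of range
    "1:102\ts3\tA\tG\tA\t10\t0.1\tx\t0.3",        # AF unparsable
    "1:103\ts4\tA\tG\tA\t10\t0.1\t0.2",           # too few fields
    "1:104\ts5\tA\tA\tA\t10\t0.1\t0.2\t0.3",      # ref == alt
    "1:105\ts6\tA\tZ\tA\t10\t0.1\t0.2\t0.3",      # non-ACGT allele
    "banana\ts7\tA\tG\tA\t10\t0.1\t0.2\t0.3",     # unparsable location
    "1:106\ts8\tA\tG\tA\t-3\t0.1\t0.2\t0.3")      # negative CADD
  p <- parse_variant_table(write_variants(rows), panel3)
  expect_equal(nrow(p$records), 1L)
  expect_equal(p$rejects$reason,
               c("AF_OUT_OF_RANGE", "AF_OUT_OF_RANGE", "MALFORMED_ROW",
                 "BAD_ALLELE", "BAD_ALLELE", "BAD_LOCATION", "CADD_INVALID"))
  expect_equal(p$rejects$line, 2:8)
  # conservation: every input line is either yielded or rejected
  expect_equal(p$n_read, nrow(p$records) + nrow(p$rejects))
})

test_that("empty file yields an empty stream without error", {
  path <- tempfile()
  file.create(path)
  p <- parse_variant_table(path, panel3)
  expect_equal(nrow(p$records), 0L)
  expect_equal(nrow(p$rejects), 0L)
  expect_equal(p$n_read, 0L)
})

test_that("missing variant table is fatal", {
  expect_error(parse_variant_table(tempfile(), panel3), "not found")
})

test_that("column layout is configurable and round-trips", {
  # no AA / no CADD layout: 4 + n fields
  rows <- c("1:10\tv1\tC\tT\t0.5\t0.25",
            "1:20\tv2\tG\tA\t0\t1")
  p <- parse_variant_table(write_variants(rows),
                           population_panel(c("P1", "P2")),
                           has_aa = FALSE, has_cadd = FALSE)
  expect_equal(nrow(p$records), 2L)
  expect_true(all(is.na(p$records$aa)))

  # round-trip: re-rendering parsed records and re-parsing is lossless
  set.seed(11)
  recs <- random_records(50, 3, seed = 11)
  rows <- vapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i]
    variant_row(r$chrom, r$pos, r$id, r$ref, r$alt, r$aa,
                format(r$cadd_phred, digits = 15),
                format(c(r$af_1, r$af_2, r$af_3), digits = 15))
  }, "")
  p2 <- parse_variant_table(write_variants(rows), panel3)
  expect_equal(nrow(p2$rejects), 0L)
  expect_equal(as.data.frame(p2$records), as.data.frame(recs),
               tolerance = 1e-12)
})

test_that("variant tables honour the optional header flag", {
  rows <- c("location\tid\tref\talt\taa\tcadd\taf1\taf2\taf3",
            "1:100\ts1\tA\tG\tA\t10\t0.1\t0.2\t0.3")
  p <- parse_variant_table(write_variants(rows), panel3, header = TRUE)
  expect_equal(nrow(p$records), 1L)
  expect_equal(p$n_read, 1L)
})

test_that("VEP annotation parsing normalises keys and keeps first duplicate", {
  path <- tempfile()
  writeLines(c("Location\tAA\tCADD_PHRED",
               "16:31099000\tA\t23.1",
               "2:109513601-109513601\tG\t12.5",
               "3:500-600\tC\t4.0",
               "not_a_key\tT\t1.0",
               "16:31099000\tC\t99.0"), path)
  expect_warning(parse_vep_annotation(path), "duplicate")
  ann <- suppressWarnings(parse_vep_annotation(path))
  expect_equal(ann$n_entries, 2L)
  expect_equal(ann$n_duplicates, 1L)
  expect_equal(sort(ann$skipped$reason), c("BAD_LOCATION", "RANGE_NOT_SNP"))
  tab <- ann$table
  expect_equal(tab[location_key == "16:31099000", aa], "A")  # first wins
  expect_equal(tab[location_key == "16:31099000", cadd_phred], 23.1)
  expect_equal(tab[location_key == "2:109513601", aa], "G")
})

test_that("annotation merge fills gaps, never overwrites, and is idempotent", {
  rows <- c("1:100\ts1\tA\tG\t.\t.\t0.1\t0.2\t0.3",
            "1:200\ts2\tA\tG\tG\t7.5\t0.1\t0.2\t0.3",
            "1:300\ts3\tA\tG\t.\t.\t0.1\t0.2\t0.3")
  p <- parse_variant_table(write_variants(rows), panel3)
  ann_path <- tempfile()
  writeLines(c("Location\tAA\tCADD_PHRED",
               "1:100\tA\t23.1",
               "1:200\tA\t1.0"), ann_path)
  ann <- parse_vep_annotation(ann_path)
  merged <- merge_annotations(p$records, ann)
  expect_equal(merged$aa, c("A", "G", NA))          # fill, keep, no key
  expect_equal(merged$cadd_phred, c(23.1, 7.5, NA)) # fill, keep, no key
  # idempotent: a second pass changes nothing
  expect_equal(merge_annotations(merged, ann), merged)
  # NULL annotation is the identity
  expect_identical(merge_annotations(p$records, NULL), p$records)
})

test_that("chromosome-sizes reader validates its input", {
  path <- tempfile()
  writeLines(c("1\t248956422", "X\t156040895"), path)
  sizes <- read_chrom_sizes(path)
  expect_equal(sizes, c(`1` = 248956422, X = 156040895))
  writeLines(c("1\t10", "1\t20"), path)
  expect_error(read_chrom_sizes(path), "duplicate")
  writeLines("1\t-5", path)
  expect_error(read_chrom_sizes(path), "invalid")
})
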