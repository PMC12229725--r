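panel <- fixture_panel()

test_that("all three reporting dialects parse, including messy variants", {
  p1 <- parse_site_report("chr1:45,634,495(+) - 45,634,499(−)")
  expect_equal(p1$dialect, "junction_pair")
  expect_equal(p1$coord_a, 45634495)
  expect_equal(p1$coord_b, 45634499)
  expect_equal(c(p1$strand_a, p1$strand_b), c("+", "-"))

  p2 <- parse_site_report("chr1:45,634,499-45,634,495")
  expect_equal(p2$dialect, "bare_range")
  expect_equal(c(p2$coord_a, p2$coord_b), c(45634499, 45634495))

  p3 <- parse_site_report("chr1:160,440,780(−)")
  expect_equal(p3$dialect, "single_junction")
  expect_equal(p3$strand_a, "-")

  # capitalization and stray spaces, as printed in one lab's submission
  p4 <- parse_site_report("Chr22: 40,844,216-40,844,212")
  expect_equal(p4$chrom, "chr22")
  expect_equal(p4$dialect, "bare_range")

  nd <- parse_site_report("not detected", sample = "C", lab_id = "lab9")
  expect_false(nd$detected)

  expect_error(parse_site_report("chrX;12345"), class = "vcnref_format_error")
  expect_error(parse_site_report("banana"), "banana")
})

test_that("canonicalization maps every dialect onto the duplication interval", {
  # plus junction marks the interval start
  c1 <- parse_site_report("chr1:45,634,495(+)") |> canonicalize_sites()
  expect_equal(c(c1$tsd_start, c1$tsd_end), c(45634495, 45634499))
  # minus junction marks the interval end
  c2 <- parse_site_report("chr1:160,440,780(−)") |> canonicalize_sites()
  expect_equal(c(c2$tsd_start, c2$tsd_end), c(160440776, 160440780))
  # reversed bare range is sorted
  c3 <- parse_site_report("chr16:2,259,702-2,259,698") |> canonicalize_sites()
  expect_equal(c(c3$tsd_start, c3$tsd_end), c(2259698, 2259702))
  # non-default duplication length
  c4 <- parse_site_report("chr5:1,000(+)") |> canonicalize_sites(tsd_length = 3)
  expect_equal(c(c4$tsd_start, c4$tsd_end), c(1000, 1002))
  # a two-coordinate report implying the wrong length is flagged, not fatal
  expect_warning(
    c5 <- parse_site_report("chr5:1,000-1,010") |> canonicalize_sites(),
    "duplication"
  )
  expect_true(c5$length_mismatch)
})

test_that("canonicalization is idempotent and dialect-invariant on the panel", {
  can <- parse_site_report(panel$reports$site_string, panel$reports$sample,
                           panel$reports$lab_id) |>
    canonicalize_sites()
  # every lab's rendering of a site collapses to one identical interval
  distinct_sites <- dplyr::distinct(can[c("sample", "chrom", "tsd_start",
                                          "tsd_end")])
  expect_equal(nrow(distinct_sites), 10)
  per_lab <- dplyr::count(can, lab_id)
  expect_true(all(per_lab$n == 10))
  # every canonical interval has the 5-bp duplication length
  expect_true(all(can$tsd_end - can$tsd_start + 1 == 5))
  expect_false(any(can$length_mismatch))
})

test_that("consensus building recovers the panel and handles empty input", {
  can <- parse_site_report(panel$reports$site_string, panel$reports$sample,
                           panel$reports$lab_id) |>
    canonicalize_sites()
  cons <- build_site_consensus(can)
  expect_equal(sum(cons$consensus), 10)
  expect_equal(sum(cons$consensus & cons$sample == "A"), 4)
  expect_true(all(cons$support == 3))
  expect_true(all(cons$spread_bp == 0))
  # the single-site sample matches its printed consensus interval
  e <- cons[cons$sample == "E", ]
  expect_equal(e$chrom, "chr3")
  expect_equal(e$tsd_start, 35632785)
  expect_equal(e$tsd_end, 35632789)
  # all "not detected" gives an empty consensus
  nd <- parse_site_report(rep("not detected", 3), sample = "C",
                          lab_id = c("lab9", "lab10", "lab11")) |>
    canonicalize_sites() |>
    build_site_consensus()
  expect_equal(nrow(nd), 0)
})

test_that("discrepant reports carry per-lab offsets and tolerance groups them", {
  reports <- tibble::tibble(
    sample = "X",
    lab_id = c("a", "b", "c"),
    site_string = c("chr7:1,000(+)", "chr7:1,002(+)", "chr7:1,000(+)")
  )
  can <- parse_site_report(reports$site_string, reports$sample,
                           reports$lab_id) |> canonicalize_sites()
  strict <- build_site_consensus(can, tolerance_bp = 0)
  expect_equal(nrow(strict), 2)
  expect_false(any(strict$consensus))
  loose <- build_site_consensus(can, tolerance_bp = 2)
  expect_equal(nrow(loose), 1)
  expect_true(loose$consensus)
  expect_equal(loose$spread_bp, 4)  # 2 bp at each end
  d <- loose$discrepancies[[1]]
  expect_equal(sort(unique(d$start_offset)), c(0, 2))
})

test_that("comparison against the prior reference reproduces the tally", {
  cons <- parse_site_report(panel$reports$site_string, panel$reports$sample,
                            panel$reports$lab_id) |>
    canonicalize_sites() |>
    build_site_consensus()
  cmp <- compare_to_reference(cons, panel$reference)
  expect_equal(nrow(cmp), 10)
  expect_equal(sum(cmp$category == "exact"), 4)
  expect_equal(sum(cmp$category == "offset"), 5)
  expect_equal(sum(cmp$category == "chrom_mismatch"), 1)
  expect_equal(sum(cmp$category == "unmatched"), 0)
  # the mismapped site pairs the old chr4 coordinate with the chr16 interval
  mm <- cmp[cmp$category == "chrom_mismatch", ]
  expect_equal(mm$ref_chrom, "chr4")
  expect_equal(mm$match_chrom, "chr16")
  # 1-bp junction-convention offsets
  expect_equal(cmp$offset_bp[cmp$ref_position == 130934986], 1)
  expect_equal(cmp$offset_bp[cmp$ref_position == 35632784], 1)
  # exact matches hit either junction
  expect_equal(cmp$category[cmp$ref_position == 42082676], "exact")
  expect_equal(sort(cmp$offset_bp[cmp$category == "offset"]),
               c(1, 1, 28, 77, 100))
})

test_that("insertion-length model combines provirus, extra bases, and TSD", {
  expect_equal(expected_insertion_length(4154, 1, include_tsd = TRUE), 4160)
  expect_equal(expected_insertion_length(4154, 1, include_tsd = FALSE), 4155)
  expect_equal(expected_insertion_length(5000), 5000)
  expect_equal(expected_insertion_length(5000, -2, tsd_length = 4,
                                         include_tsd = TRUE), 5002)
  expect_error(expected_insertion_length(0), class = "vcnref_schema_error")
  # the packaged long-read calls all equal the TSD-inclusive model value
  expect_true(all(panel$pacbio$insertion_length_bp ==
                    expected_insertion_length(4154, 1, include_tsd = TRUE)))
})

test_that("annotation labels sites by containing interval with precedence", {
  cons <- parse_site_report(panel$reports$site_string, panel$reports$sample,
                            panel$reports$lab_id) |>
    canonicalize_sites() |>
    build_site_consensus()
  ann <- annotate_sites(cons, panel$annotation)
  expect_equal(sum(ann$region == "intron"), 6)
  expect_equal(sum(ann$region == "intergenic"), 3)
  expect_equal(sum(ann$region == "3'UTR"), 1)
  expect_equal(ann$gene[ann$chrom == "chr22" & ann$tsd_start == 42082672],
               "SMDT1")
  # overlapping labels resolve exon > UTR > intron
  overlap <- tibble::tibble(chrom = "chr9", start = c(1, 50), end = c(200, 150),
                            gene = c("G1", "G1"),
                            region = c("intron", "exon"))
  site <- tibble::tibble(sample = "X", chrom = "chr9", tsd_start = 100,
                         tsd_end = 104)
  expect_message(res <- annotate_sites(site, overlap), "precedence")
  expect_equal(res$region, "exon")
})

test_that("BED output uses 0-based half-open intervals and round-trips", {
  sites <- tibble::tibble(sample = c("A", "A"), chrom = c("chr1", "chr22"),
                          tsd_start = c(45634495, 42082672),
                          tsd_end = c(45634499, 42082676))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  lines <- readLines(path)
  expect_match(lines[2], "^chr1\t45634494\t45634499\tA:1\t0\t\\+$")
  back <- read_sites_bed(path)
  expect_equal(back$tsd_start, sites$tsd_start)
  expect_equal(back$tsd_end, sites$tsd_end)

  # cross-check the coordinate convention with an independent BED reader
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    expect_equal(BiocGenerics::start(gr), sites$tsd_start)
    expect_equal(BiocGenerics::end(gr), sites$tsd_end)
  }

  # empty site list: header-only file
  empty_path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites[0, ], empty_path)
  expect_equal(length(readLines(empty_path)), 1)
  expect_equal(nrow(read_sites_bed(empty_path)), 0)
})
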