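test_that("window tiling follows the 50 kbp / 10 kbp overlap scheme", {
  cfg <- sv_config()
  ref <- sv_reference(c(c1 = strrep("A", 16)))
  ref$lengths[["c1"]] <- 100000L  # lengths drive tiling; sequence unused here
  segs <- tile_segments(ref, cfg)
  expect_equal(segs$start, c(0L, 40000L, 80000L))
  expect_equal(segs$end, c(50000L, 90000L, 100000L))

  ref$lengths[["c1"]] <- 30000L
  expect_equal(tile_segments(ref, cfg)[, c("start", "end")],
               data.frame(start = 0L, end = 30000L))
  ref$lengths[["c1"]] <- 50000L
  expect_equal(tile_segments(ref, cfg)[, c("start", "end")],
               data.frame(start = 0L, end = 50000L))
})

test_that("tiling covers every base; interior boundary bases covered twice", {
  set.seed(20)
  cfg <- sv_config()
  for (len in sample(20000:400000, 100L)) {
    ref <- sv_reference(c(x = "ACGT"))
    ref$lengths[["x"]] <- len
    segs <- tile_segments(ref, cfg)
    expect_true(all(segs$end - segs$start <= cfg$segment_length))
    expect_equal(segs$start[1L], 0L)
    expect_equal(segs$end[nrow(segs)], len)
    if (nrow(segs) > 1L) {
      # consecutive windows overlap by exactly the configured amount
      # (the final, truncated window may overlap more)
      ov <- segs$end[-nrow(segs)] - segs$start[-1L]
      expect_true(all(ov[-length(ov)] == cfg$segment_overlap))
      expect_true(ov[length(ov)] >= cfg$segment_overlap ||
                    segs$end[nrow(segs)] - segs$start[nrow(segs)] < cfg$segment_length)
      expect_true(all(segs$start[-1L] <= segs$end[-nrow(segs)]))
    }
  }
})

test_that("barcode selection enforces >= 3 pairs and span > 5 kbp, strictly", {
  fx <- make_barcode_fixture()
  bam <- fixture_bam(fx$recs, fx$ref)
  seg <- list(chrom = "chr1", start = 0L, end = 50000L)
  got <- select_barcodes(seg, bam, sv_config())
  expect_equal(got, c("BCA", "BCE"))
  # span measured leftmost start to rightmost end within the window
  df <- svweave:::.annotate_records(read_bam_records(bam))
  bca <- df[df$barcode == "BCA" & df$is_mapped, ]
  expect_equal(max(bca$ref_end) - min(bca$pos), 6100)
})

test_that("pair counting counts a pair once even with both mates in-window", {
  fx <- make_barcode_fixture()
  # BCB has 2 pairs = 4 reads in window; must still count 2
  seg <- list(chrom = "chr1", start = 0L, end = 50000L)
  got <- select_barcodes(seg, fixture_bam(fx$recs, fx$ref),
                         sv_config(min_barcode_pairs = 2L))
  expect_true("BCB" %in% got)
  got3 <- select_barcodes(seg, fixture_bam(fx$recs, fx$ref), sv_config())
  expect_false("BCB" %in% got3)
})

test_that("gathering recruits local pairs, read-map pairs, and fetches mates", {
  set.seed(22)
  ref <- fixture_reference(60000L)
  recs <- rbind(
    pair_recs("in1", pos1 = 1000L, pos2 = 1300L, barcode = "BX1"),
    pair_recs("in2", pos1 = 4000L, pos2 = 4300L, barcode = "BX1"),
    pair_recs("in3", pos1 = 9000L, pos2 = 9300L, barcode = "BX1"),
    # only mate2 in window; mate1 far left outside
    pair_recs("half", pos1 = 52000L, pos2 = 9500L, barcode = "BX1"),
    # badly aligned pair under BX1 anywhere in the genome -> via read map
    pair_recs("bad", pos1 = 55000L, barcode = "BX1", mapped2 = FALSE),
    # different barcode: ignored
    pair_recs("oth", pos1 = 5000L, pos2 = 5300L, barcode = "BX9")
  )
  bam <- fixture_bam(recs, ref)
  cfg <- sv_config(primary_chroms = "chr1", min_barcode_span = 5000L)
  m <- build_read_map(bam, cfg)
  seg <- list(chrom = "chr1", start = 0L, end = 10000L, segment_id = "s1")
  gs <- gather_segment_reads(seg, bam, m, config = cfg)
  expect_equal(gs$barcodes, "BX1")
  expect_true(all(c("in1", "in2", "in3", "half") %in% gs$local$qname))
  # the out-of-window mate of "half" was fetched by name
  expect_equal(sum(gs$local$qname == "half"), 2L)
  expect_true("bad" %in% gs$recruited$qname)
  expect_false("oth" %in% gs$local$qname)
})

test_that("empty barcode set gathers nothing", {
  ref <- fixture_reference(20000L)
  recs <- pair_recs("a", pos1 = 100L, pos2 = 400L, barcode = "Z1")
  bam <- fixture_bam(recs, ref)
  m <- build_read_map(bam, sv_config(primary_chroms = "chr1"))
  seg <- list(chrom = "chr1", start = 0L, end = 20000L, segment_id = "s")
  gs <- gather_segment_reads(seg, bam, m, barcodes = character(),
                             config = sv_config())
  expect_equal(nrow(gs$local), 0L)
  expect_equal(nrow(gs$recruited), 0L)
})

test_that("long reads overlapping the window are capped in coordinate order", {
  set.seed(23)
  ref <- fixture_reference(30000L)
  n <- 150L
  lrecs <- do.call(rbind, lapply(seq_len(n), function(i)
    rec(sprintf("lr%03d", i), 0L, pos = 10L * i, cigar = "1000M",
        seq = strrep("A", 1000L), qual = strrep("I", 1000L))))
  lbam <- fixture_bam(lrecs, ref)
  ref2 <- ref
  recs <- pair_recs("p", pos1 = 100L, pos2 = 400L, barcode = "B")
  bam <- fixture_bam(recs, ref2, tempfile("slr"))
  m <- build_read_map(bam, sv_config(primary_chroms = "chr1"))
  seg <- list(chrom = "chr1", start = 0L, end = 30000L, segment_id = "s")
  gs <- gather_segment_reads(seg, bam, m, long_bam = lbam,
                             barcodes = "B", config = sv_config())
  expect_length(gs$long_reads, 100L)
})

test_that("gathering is deterministic for identical inputs", {
  fx <- make_barcode_fixture()
  bam <- fixture_bam(fx$recs, fx$ref)
  cfg <- sv_config(primary_chroms = "chr1")
  m <- build_read_map(bam, cfg)
  seg <- list(chrom = "chr1", start = 0L, end = 50000L, segment_id = "s")
  g1 <- gather_segment_reads(seg, bam, m, config = cfg)
  g2 <- gather_segment_reads(seg, bam, m, config = cfg)
  expect_identical(g1$barcodes, g2$barcodes)
  expect_identical(g1$local$qname, g2$local$qname)
})

test_that("a spanning fragment's barcode is selected, a spurious one never", {
  set.seed(24)
  ref <- fixture_reference(60000L)
  s <- ref$sequences[["chr1"]]
  # fragment truly spanning 0-30000: pairs sampled along it
  npairs <- 25L
  p1 <- as.integer(runif(npairs, 0, 29500))
  frag <- do.call(rbind, lapply(seq_len(npairs), function(i)
    pair_recs(sprintf("f%02d", i), pos1 = p1[i], pos2 = p1[i] + 250L,
              barcode = "SPAN")))
  spur <- pair_recs("s1", pos1 = 15000L, pos2 = 15300L, barcode = "SPUR")
  bam <- fixture_bam(rbind(frag, spur), ref)
  seg <- list(chrom = "chr1", start = 0L, end = 50000L)
  sel <- select_barcodes(seg, bam, sv_config())
  expect_true("SPAN" %in% sel)
  expect_false("SPUR" %in% sel)
})
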