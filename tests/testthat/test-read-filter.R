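# The badly-aligned predicate: (a) all-bases Phred > 20 on both mates AND
# ((b) unmapped / unplaced / >20% soft-clipped OR (c) AM:i:0).

lowq <- function(n, q = 15L) strrep(intToUtf8(q + 33L), n)

test_that("quality gate (a) is necessary: one low-quality base vetoes", {
  cfg <- sv_config()
  p <- pair_recs("p", qual1 = paste0(strrep("I", 99), lowq(1)), mapped2 = FALSE)
  r <- badly_aligned(p[1, ], p[2, ], cfg)
  expect_false(r$bad)  # mate unmapped, but (a) fails
  expect_true(is.na(r$reason))
  # boundary: exactly Phred 20 fails the strict inequality
  p20 <- pair_recs("p", qual1 = lowq(100, 20L), mapped2 = FALSE)
  expect_false(badly_aligned(p20[1, ], p20[2, ], cfg)$bad)
  p21 <- pair_recs("p", qual1 = lowq(100, 21L), mapped2 = FALSE)
  expect_true(badly_aligned(p21[1, ], p21[2, ], cfg)$bad)
})

test_that("condition (b): unmapped mate, unplaced contig, soft-clip fraction", {
  cfg <- sv_config()
  p <- pair_recs("p", mapped2 = FALSE)
  expect_equal(badly_aligned(p[1, ], p[2, ], cfg)$reason, "align")

  up <- pair_recs("p", chrom = "chrUn_KI270302v1")
  expect_true(badly_aligned(up[1, ], up[2, ], cfg)$bad)

  # 40 of 150 bases soft-clipped = 26.7% > 20%
  cl <- pair_recs("p", cigar1 = "110M40S", qual1 = strrep("I", 150))
  cl$seq[1] <- strrep("A", 150)
  expect_true(badly_aligned(cl[1, ], cl[2, ], cfg)$bad)
  # exactly 20% does not trigger (strict >)
  cl2 <- pair_recs("p", cigar1 = "120M30S", qual1 = strrep("I", 150))
  cl2$seq[1] <- strrep("A", 150)
  expect_false(badly_aligned(cl2[1, ], cl2[2, ], cfg)$bad)
})

test_that("condition (c): AM zero recruits a cleanly mapped pair", {
  cfg <- sv_config()
  p <- pair_recs("p", am1 = 0L)
  r <- badly_aligned(p[1, ], p[2, ], cfg)
  expect_true(r$bad)
  expect_equal(r$reason, "am0")
  # AM absent and cleanly mapped: nothing fires
  cln <- pair_recs("p")
  expect_false(badly_aligned(cln[1, ], cln[2, ], cfg)$bad)
  # AM = 1 does not fire either
  am1 <- pair_recs("p", am1 = 1L)
  expect_false(badly_aligned(am1[1, ], am1[2, ], cfg)$bad)
})

test_that("orphans are evaluated with the absent mate treated as unmapped", {
  cfg <- sv_config()
  solo <- rec("solo", flag = 1L + 64L, qual = strrep("I", 100))
  expect_true(badly_aligned(solo, NULL, cfg)$bad)
})

test_that("build_read_map stores exactly the qualifying barcoded pairs", {
  set.seed(10)
  ref <- fixture_reference(3000L)
  recs <- rbind(
    pair_recs("good_unmapped", pos1 = 100L, barcode = "BC1-1", mapped2 = FALSE),
    pair_recs("good_am", pos1 = 300L, pos2 = 600L, barcode = "BC2-1", am2 = 0L),
    pair_recs("clean", pos1 = 800L, pos2 = 1100L, barcode = "BC3-1"),
    pair_recs("lowqual", pos1 = 1200L, barcode = "BC4-1", mapped2 = FALSE,
              qual2 = lowq(100)),
    pair_recs("no_bx", pos1 = 1500L, mapped2 = FALSE)
  )
  bam <- fixture_bam(recs, ref)
  m <- build_read_map(bam, sv_config(primary_chroms = "chr1"))
  expect_equal(m$total_pairs, 2L)
  expect_setequal(names(m$by_barcode), c("BC1-1", "BC2-1"))
  expect_equal(m$n_dropped_no_barcode, 1L)

  # empty input
  m0 <- build_read_map(rec("x", 0L)[0, ], sv_config())
  expect_equal(m0$total_pairs, 0L)
})

test_that("read-map queries return M(B), idempotent under duplicates", {
  set.seed(11)
  ref <- fixture_reference(3000L)
  recs <- do.call(rbind, lapply(1:6, function(i)
    pair_recs(paste0("p", i), pos1 = i * 100L,
              barcode = paste0("BC", (i - 1L) %/% 2L + 1L, "-1"),
              mapped2 = FALSE)))
  m <- build_read_map(fixture_bam(recs, ref), sv_config(primary_chroms = "chr1"))
  expect_equal(m$total_pairs, 6L)
  q1 <- query_read_map(m, "BC1-1")
  expect_equal(length(unique(q1$qname)), 2L)
  expect_equal(nrow(query_read_map(m, character())), 0L)
  expect_identical(query_read_map(m, c("BC1-1", "BC1-1", "BC2-1")),
                   query_read_map(m, c("BC1-1", "BC2-1")))
})

test_that("map contents equal a brute-force filter on random pairs", {
  set.seed(12)
  n <- 1000L
  cfg <- sv_config(primary_chroms = "chr1")
  mk_qual <- function() {
    q <- sample(c(30L, 25L, 22L), 1L)
    bad <- sample(c(TRUE, FALSE), 1L, prob = c(0.3, 0.7))
    s <- rep(q, 50L)
    if (bad) s[sample(50L, 1L)] <- sample(10:20, 1L)
    intToUtf8(s + 33L, multiple = FALSE)
  }
  rows <- vector("list", n)
  truth <- logical(n)
  for (i in seq_len(n)) {
    un2 <- runif(1) < 0.2
    clip1 <- sample(c(0L, 5L, 11L, 20L), 1L)   # of 50 bp: 22% and 40% trigger
    am <- sample(c(NA_integer_, 0L, 1L), 1L, prob = c(0.6, 0.2, 0.2))
    q1 <- mk_qual(); q2 <- mk_qual()
    chrom <- sample(c("chr1", "chrUn_x"), 1L, prob = c(0.9, 0.1))
    cigar1 <- if (clip1 > 0L) sprintf("%dM%dS", 50L - clip1, clip1) else "50M"
    p <- pair_recs(sprintf("r%04d", i), chrom = chrom, pos1 = 100L, pos2 = 400L,
                   barcode = sprintf("B%03d", i %% 50L), qual1 = q1, qual2 = q2,
                   cigar1 = cigar1, cigar2 = "50M", am1 = am, mapped2 = !un2)
    p$seq <- strrep("A", 50L)
    rows[[i]] <- p
    # independent re-derivation of the predicate
    minq <- function(qq) min(utf8ToInt(qq)) - 33L
    a <- minq(q1) > 20L && minq(q2) > 20L
    b <- un2 || chrom == "chrUn_x" || clip1 / 50 > 0.2
    cc <- !is.na(am) && am == 0L
    truth[i] <- a && (b || cc)
  }
  df <- do.call(rbind, rows)
  m <- build_read_map(df, cfg)
  expect_equal(m$total_pairs, sum(truth))
  got <- sort(unique(m$reads$qname))
  expect_equal(got, sort(sprintf("r%04d", which(truth))))
})

test_that("recruitment is monotone in the quality and clip thresholds", {
  set.seed(13)
  rows <- do.call(rbind, lapply(1:200, function(i) {
    q <- intToUtf8(sample(15:35, 60L, TRUE) + 33L)
    clip <- sample(0:30, 1L)
    cigar <- if (clip > 0) sprintf("%dM%dS", 60L - clip, clip) else "60M"
    p <- pair_recs(sprintf("m%03d", i), pos1 = 10L, pos2 = 200L,
                   barcode = "B1", qual1 = q, qual2 = strrep("I", 60),
                   cigar1 = cigar, cigar2 = "60M",
                   mapped2 = runif(1) < 0.5)
    p$seq <- strrep("A", 60L)
    p
  }))
  sizes_q <- vapply(c(10L, 20L, 30L), function(thr)
    build_read_map(rows, sv_config(min_base_phred = thr))$total_pairs, integer(1L))
  expect_true(all(diff(sizes_q) <= 0L))
  sizes_c <- vapply(c(0.05, 0.2, 0.4), function(thr)
    build_read_map(rows, sv_config(max_softclip_fraction = thr))$total_pairs,
    integer(1L))
  expect_true(all(diff(sizes_c) <= 0L))
})
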