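# Diploid genome simulation, truth consistency, linked-read and long-read
# generation.

# independent application of a truth set to the reference
apply_truth <- function(refseq, truth) {
  out <- refseq
  for (i in rev(seq_len(nrow(truth)))) {  # right to left keeps coordinates valid
    p <- truth$pos[i]
    if (truth$svtype[i] == "DEL") {
      out <- paste0(substr(out, 1, p), substr(out, p + truth$svlen[i] + 1L, nchar(out)))
    } else {
      out <- paste0(substr(out, 1, p), truth$seq[i], substr(out, p + 1L, nchar(out)))
    }
  }
  out
}

test_that("zero SVs yield haplotypes equal to the reference", {
  gen <- simulate_svs(sim_config(genome_length = 20000L, n_svs = 0L, seed = 70L))
  expect_identical(gen$haplotypes[[1L]], gen$reference$sequences[[1L]])
  expect_identical(gen$haplotypes[[2L]], gen$reference$sequences[[1L]])
  expect_equal(nrow(gen$truth), 0L)
})

test_that("a homozygous deletion shortens both haplotypes and hits the truth VCF", {
  tv <- tempfile(fileext = ".vcf")
  gen <- simulate_svs(sim_config(genome_length = 60000L, n_svs = 1L,
                                 zygosity = "hom", seed = 71L,
                                 sv_size_sampler = function(n) rep(500L, n)),
                      truth_vcf = tv)
  tr <- gen$truth
  expect_equal(nrow(tr), 1L)
  if (tr$svtype == "DEL") {
    expect_equal(nchar(gen$haplotypes[[1L]]), 60000L - 500L)
    expect_equal(nchar(gen$haplotypes[[2L]]), 60000L - 500L)
  } else {
    expect_equal(nchar(gen$haplotypes[[1L]]), 60000L + 500L)
  }
  v <- readLines(tv)
  body <- grep("^[^#]", v, value = TRUE)
  expect_length(body, 1L)
  expect_match(body, if (tr$svtype == "DEL") "SVLEN=-500" else "SVLEN=500")
  expect_match(body, if (tr$zygosity == "hom") "1/1" else "0/1")
})

test_that("truth set and haplotypes are mutually consistent", {
  for (seed in 72:74) {
    gen <- simulate_svs(sim_config(genome_length = 80000L, n_svs = 4L,
                                   zygosity = "mixed", seed = seed))
    for (h in 1:2) {
      on_h <- gen$truth[gen$truth$haps %in% c("both", as.character(h)), ]
      expect_identical(apply_truth(gen$reference$sequences[[1L]], on_h),
                       gen$haplotypes[[h]],
                       info = sprintf("seed %d hap %d", seed, h))
    }
  }
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_svs(sim_config(genome_length = 80000L, n_svs = 2L, seed = 75L))
  s2 <- simulate_svs(sim_config(genome_length = 80000L, n_svs = 2L, seed = 75L))
  expect_identical(s1$haplotypes, s2$haplotypes)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- simulate_linked_reads(s1, d1)
  r2 <- simulate_linked_reads(s2, d2)
  expect_identical(read_bam_records(r1$bam)$seq, read_bam_records(r2$bam)$seq)
})

test_that("linked reads respect fragment structure and coverage accounting", {
  gen <- simulate_svs(sim_config(genome_length = 200000L, n_svs = 0L,
                                 slr_coverage = 30, seed = 76L))
  res <- simulate_linked_reads(gen, tempfile("slr"))
  expect_lt(abs(res$n_bases - 30 * 200000) / (30 * 200000), 0.05)
  df <- read_bam_records(res$bam)
  expect_true(all(!is.na(df$barcode)))
  # reads sharing a barcode derive from one fragment: span within max length
  mapped <- df[df$is_mapped, ]
  span <- tapply(mapped$pos, mapped$barcode, function(p) diff(range(p)))
  expect_true(all(span <= 100000L))
  # barcodes look LongRanger-style
  expect_true(all(grepl("-1$", df$barcode)))
})

test_that("coverage accounting holds across seeds", {
  devs <- vapply(101:110, function(seed) {
    gen <- simulate_svs(sim_config(genome_length = 100000L, n_svs = 0L,
                                   slr_coverage = 35, seed = seed))
    res <- simulate_linked_reads(gen, tempfile("cov"))
    abs(res$n_bases - 35 * 100000) / (35 * 100000)
  }, numeric(1L))
  expect_true(all(devs < 0.05))
})

test_that("reads crossing an SV junction are soft-clipped with AM 0; inserted-only reads unmapped", {
  gen <- simulate_svs(sim_config(genome_length = 80000L, n_svs = 1L,
                                 zygosity = "hom", seed = 77L,
                                 sv_size_sampler = function(n) rep(5000L, n)))
  res <- simulate_linked_reads(gen, tempfile("jx"))
  df <- read_bam_records(res$bam)
  clipped <- grepl("S", df$cigar)
  expect_gt(sum(clipped), 0L)
  expect_true(all(df$am[clipped] == 0L, na.rm = TRUE))
  if (gen$truth$svtype[1L] == "INS") {
    expect_gt(sum(!df$is_mapped), 0L)  # reads from inside the 5 kb insertion
  }
})

test_that("long reads have the configured length and error profile", {
  gen <- simulate_svs(sim_config(genome_length = 120000L, n_svs = 0L,
                                 long_coverage = 4, seed = 78L))
  res <- simulate_long_reads(gen, tempfile("lr"))
  df <- read_bam_records(res$bam)
  lens <- nchar(df$seq)
  # error indels can shift lengths by a handful of bases
  expect_true(all(lens >= 8950L & lens <= 12050L))

  # error 0: exact substrings of the reference
  gen0 <- simulate_svs(sim_config(genome_length = 40000L, n_svs = 0L,
                                  long_coverage = 2,
                                  long_error_range = c(0, 0), seed = 79L))
  r0 <- simulate_long_reads(gen0, tempfile("lr0"))
  d0 <- read_bam_records(r0$bam)
  hit <- vapply(d0$seq[1:5], function(x)
    grepl(x, gen0$reference$sequences[[1L]], fixed = TRUE), logical(1L))
  expect_true(all(hit))

  # mean identity within the configured band
  ref <- gen$reference$sequences[[1L]]
  ids <- vapply(head(seq_len(nrow(df)), 12L), function(i) {
    r <- df[i, ]
    if (!r$is_mapped) return(NA_real_)
    region <- substr(ref, max(1L, r$pos - 50L), min(nchar(ref), r$pos + nchar(r$seq) + 50L))
    al <- Biostrings::pairwiseAlignment(r$seq, region, type = "global-local")
    1 - Biostrings::nedit(al) / nchar(r$seq)
  }, numeric(1L))
  expect_gt(mean(ids, na.rm = TRUE), 0.99)
  expect_lt(mean(ids, na.rm = TRUE), 0.9995)
})

test_that("a configured coverage gap removes all reads touching it", {
  gen <- simulate_svs(sim_config(genome_length = 60000L, n_svs = 0L,
                                 coverage_gap = c(30000L, 31000L), seed = 80L))
  res <- simulate_linked_reads(gen, tempfile("gap"))
  df <- read_bam_records(res$bam)
  mapped <- df[df$is_mapped, ]
  st <- svweave:::.cpp_cigar_stats(mapped$cigar)
  rend <- mapped$pos + st[, "ref_width"]
  expect_false(any(mapped$pos < 31000 & rend > 30000))
})

test_that("infeasible SV spacing raises a helpful error", {
  expect_error(simulate_svs(sim_config(genome_length = 30000L, n_svs = 8L,
                                       sv_size_sampler = function(n) rep(2000L, n),
                                       seed = 81L)),
               "reduce|too short")
})
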