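# De Bruijn graph construction against a brute-force k-mer oracle, the
# diploid-aware simplification rules, tip-aware path extension, and
# long-read gap closing.

cover_reads <- function(hap, n = NULL, rl = 150L, cov = 30) {
  if (is.null(n)) n <- ceiling(cov * nchar(hap) / rl)
  st <- sample(seq_len(nchar(hap) - rl + 1L), n, TRUE)
  substring(hap, st, st + rl - 1L)
}

test_that("graph nodes and edges equal brute-force k-mer enumeration", {
  set.seed(30)
  cfg <- sv_config(short_solid_min = 1L)
  for (len in c(500L, 2000L, 8000L)) {
    s <- rand_dna(len)
    reads <- cover_reads(s, cov = 20)
    g <- build_assembly_graph(reads, config = cfg)
    expect_setequal(graph_kmers(g),
                    oracle_solid_kmers(reads, character(), cfg$kmer_size,
                                       short_min = 1L))
    expect_setequal(graph_edge_kmers(g),
                    sort(unique(names(oracle_kmer_counts(reads, cfg$kmer_size + 1L)))))
  }
})

test_that("solid threshold drops singleton error k-mers but keeps corroborated long-read k-mers", {
  set.seed(31)
  s <- rand_dna(2000)
  reads <- cover_reads(s, cov = 20)
  err_read <- paste0(substr(s, 500, 560), "TTTTACGTTTTA", substr(s, 561, 640))
  g <- build_assembly_graph(c(reads, err_read), config = sv_config())
  oracle <- oracle_solid_kmers(c(reads, err_read), character(), 55L, short_min = 2L)
  expect_setequal(graph_kmers(g), oracle)

  # long-read-only k-mers: one long read alone is dropped, two are kept
  lr <- substr(s, 100, 1900)
  g1 <- build_assembly_graph(character(), lr, config = sv_config())
  expect_length(g1$unitigs, 0L)
  g2 <- build_assembly_graph(character(), c(lr, lr), config = sv_config())
  expect_gt(length(g2$unitigs), 0L)
})

test_that("a single read spells one unitig; tiled error-free reads reassemble the source", {
  set.seed(32)
  cfg <- sv_config(short_solid_min = 1L)
  s <- rand_dna(1000)
  g <- build_assembly_graph(s, config = cfg)
  expect_length(g$unitigs, 1L)
  expect_true(g$unitigs[1L] %in% c(s, rc(s)))

  s2 <- rand_dna(5000)
  g2 <- build_assembly_graph(cover_reads(s2, cov = 30), config = sv_config())
  expect_length(g2$unitigs, 1L)
  # interior reconstructed exactly (coverage thins at the extreme ends)
  expect_true(grepl(substr(s2, 100, 4900), g2$unitigs[1L], fixed = TRUE) ||
                grepl(rc(substr(s2, 100, 4900)), g2$unitigs[1L], fixed = TRUE))
})

test_that("an SNV between haplotypes forms a bulge with shared flanks", {
  set.seed(33)
  s <- rand_dna(3000)
  h2 <- s
  substr(h2, 1500, 1500) <- if (substr(s, 1500, 1500) == "A") "C" else "A"
  g <- build_assembly_graph(c(cover_reads(s, cov = 30), cover_reads(h2, cov = 30)),
                            config = sv_config())
  expect_equal(length(g$unitigs), 4L)  # two flanks + two parallel branches
  expect_equal(nrow(g$links), 4L)
})

test_that("graph export is identical under read reordering", {
  set.seed(34)
  s <- rand_dna(3000)
  reads <- cover_reads(s, cov = 25)
  g1 <- build_assembly_graph(reads, config = sv_config())
  g2 <- build_assembly_graph(rev(reads), config = sv_config())
  expect_identical(g1, g2)
})

test_that("simplification removes error tips but keeps long tips and het bulges", {
  set.seed(35)
  cfg <- sv_config(short_solid_min = 1L)
  s <- rand_dna(3000)
  reads <- cover_reads(s, cov = 30)
  # one chimeric read tail creates a coverage-1 short dead-end branch
  # (a handful of foreign bases -> a tip of a few k-mers, length < k + 10)
  err <- paste0(substr(s, 1000, 1144), rand_dna(5))
  g <- build_assembly_graph(c(reads, err), config = cfg)
  gs <- simplify_assembly_graph(g, cfg)
  expect_lt(length(gs$unitigs), length(g$unitigs))
  expect_length(gs$unitigs, 1L)  # error tip removed, graph recompacted

  # heterozygous bulge: both branches ~ balanced coverage -> retained
  h2 <- paste0(substr(s, 1, 1500), substr(s, 1801, 3000))  # 300 bp del
  gh <- build_assembly_graph(c(cover_reads(s, cov = 30), cover_reads(h2, cov = 29)),
                             config = sv_config())
  ghs <- simplify_assembly_graph(gh, sv_config())
  expect_equal(length(ghs$unitigs), 4L)  # flanks + both alleles survive

  # long coverage-drop tip at 20x: retained regardless
  gap_reads <- {
    st <- sample(c(seq_len(1200L), seq(2000L, 2850L)), 600L, TRUE)
    substring(s, st, st + 149L)
  }
  gg <- simplify_assembly_graph(build_assembly_graph(gap_reads, config = sv_config()),
                                sv_config())
  expect_equal(length(gg$unitigs), 2L)  # both sides kept as separate unitigs
})

test_that("error-branch bulges below the coverage floor are removed", {
  set.seed(36)
  s <- rand_dna(3000)
  reads <- cover_reads(s, cov = 40)
  mut <- s
  substr(mut, 1500, 1500) <- if (substr(s, 1500, 1500) == "A") "G" else "A"
  err_reads <- cover_reads(mut, n = 3L)  # ~3% of coverage: error branch
  keep <- vapply(err_reads, function(r) {
    st <- regexpr(substr(r, 1, 20), mut, fixed = TRUE)
    st <= 1500L & st + 149L >= 1500L
  }, logical(1L))
  g <- build_assembly_graph(c(reads, err_reads), config = sv_config(short_solid_min = 1L))
  gs <- simplify_assembly_graph(g, sv_config(short_solid_min = 1L))
  if (any(keep)) expect_lte(length(gs$unitigs), length(g$unitigs))
  expect_length(extend_contig_paths(gs, sv_config())$seq, 1L)
})

test_that("path extension spells a linear graph into one contig", {
  set.seed(37)
  cfg <- sv_config()
  s <- rand_dna(4000)
  g <- simplify_assembly_graph(build_assembly_graph(cover_reads(s, cov = 30),
                                                    config = cfg), cfg)
  ctg <- extend_contig_paths(g, cfg)
  expect_equal(nrow(ctg), 1L)
  expect_false(ctg$terminated_by_tip_rule[1L])
})

test_that("both alleles of a heterozygous deletion bulge are spelled", {
  set.seed(38)
  cfg <- sv_config()
  s <- rand_dna(5000)
  h2 <- paste0(substr(s, 1, 2500), substr(s, 2701, 5000))  # 200 bp het DEL
  g <- simplify_assembly_graph(
    build_assembly_graph(c(cover_reads(s, cov = 30), cover_reads(h2, cov = 30)),
                         config = cfg), cfg)
  ctg <- extend_contig_paths(g, cfg)
  expect_equal(nrow(ctg), 2L)
  jref <- substr(s, 2450, 2750)
  jalt <- substr(h2, 2450, 2550)
  expect_true(any(grepl(jref, ctg$seq) | grepl(rc(jref), ctg$seq)))
  expect_true(any(grepl(jalt, ctg$seq) | grepl(rc(jalt), ctg$seq)))
})

gap_scenario <- function(seed) {
  # repeat-flanked interior coverage gap: the repeat bridges the graph and
  # the gap-adjacent unique stubs become long facing tips
  set.seed(seed)
  bg <- rand_dna(20000)
  rep300 <- rand_dna(300)
  substr(bg, 8001, 8300) <- rep300
  substr(bg, 11501, 11800) <- rep300
  st <- sample(seq_len(20000L - 150L), 8000L, TRUE)
  keep <- (st + 149L) <= 8800L | st >= 11201L
  list(bg = bg, reads = substring(bg, st[keep], st[keep] + 149L))
}

test_that("facing long tips around a coverage drop stop extension (no chimera)", {
  sc <- gap_scenario(39)
  cfg <- sv_config()
  g <- simplify_assembly_graph(build_assembly_graph(sc$reads, config = cfg), cfg)
  ctg_on <- extend_contig_paths(g, cfg)
  ctg_off <- extend_contig_paths(g, sv_config(tip_rule = FALSE))
  chim <- paste0(substr(sc$bg, 7901, 8300), substr(sc$bg, 11801, 12200))
  has_chim <- function(ct) any(grepl(chim, ct$seq) | grepl(rc(chim), ct$seq))
  expect_false(has_chim(ctg_on))
  expect_true(any(ctg_on$terminated_by_tip_rule))
  expect_true(has_chim(ctg_off))  # the rule, not luck, prevents the join
})

test_that("long reads close an assembly gap, tolerating read error", {
  set.seed(40)
  cfg <- sv_config()
  truth <- rand_dna(15000)
  ctgs <- c(substr(truth, 1, 6000), substr(truth, 9001, 15000))
  lr <- vapply(1:5, function(i) substr(truth, 5000 + i * 7L, 11000 + i * 7L), "")
  res <- close_gaps_with_long_reads(ctgs, lr, cfg)
  expect_equal(attr(res, "n_joins"), 1L)
  expect_true(any(res$seq == truth | res$seq == rc(truth)))

  # zero long reads: identity
  res0 <- close_gaps_with_long_reads(ctgs, character(), cfg)
  expect_equal(res0$seq, ctgs)

  # 1% error: join still succeeds, gap within 1% edit distance of truth
  noisy <- vapply(lr, function(r) {
    s <- strsplit(r, "")[[1L]]
    pos <- sample(length(s), round(0.01 * length(s)))
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    paste(s, collapse = "")
  }, "")
  resn <- close_gaps_with_long_reads(ctgs, noisy, cfg)
  expect_equal(attr(resn, "n_joins"), 1L)
  joined <- resn$seq[which.max(nchar(resn$seq))]
  al <- Biostrings::pairwiseAlignment(joined, truth, type = "global")
  dist <- Biostrings::nedit(al)
  expect_lt(dist / nchar(truth), 0.01)
})

test_that("segment assembly recovers a homozygous deletion junction exactly", {
  set.seed(41)
  cfg <- sv_config()
  ref <- rand_dna(20000)
  alt <- paste0(substr(ref, 1, 10000), substr(ref, 10501, 20000))  # 500 bp hom DEL
  reads <- cover_reads(alt, cov = 40)
  seg <- list(segment_id = "s", local = data.frame(seq = reads),
              recruited = data.frame(seq = character()), long_reads = character())
  ctg <- assemble_segment(seg, cfg)
  expect_gte(nrow(ctg), 1L)
  junction <- substr(alt, 9900, 10100)
  expect_true(any(grepl(junction, ctg$seq) | grepl(rc(junction), ctg$seq)))
})

test_that("contigs are byte-identical across repeated runs", {
  set.seed(42)
  cfg <- sv_config()
  s <- rand_dna(4000)
  reads <- cover_reads(s, cov = 25)
  run <- function() {
    g <- simplify_assembly_graph(build_assembly_graph(reads, config = cfg), cfg)
    extend_contig_paths(g, cfg)$seq
  }
  expect_identical(run(), run())
})

test_that("all reads shorter than k give an empty graph with a warning", {
  cfg <- sv_config()
  expect_warning(g <- build_assembly_graph(c("ACGT", "GGGG"), config = cfg),
                 "shorter than k")
  expect_length(g$unitigs, 0L)
  expect_equal(nrow(extend_contig_paths(g, cfg)), 0L)
})
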