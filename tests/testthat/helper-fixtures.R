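# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles deliberately re-derive quantities by brute force, independent of
# the implementation paths they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# one aligned-record row in the shape read_bam_records() returns
rec <- function(qname, flag = 0L, chrom = "chr1", pos = 100L, mapq = 60L,
                cigar = "100M", seq = strrep("A", 100L), qual = strrep("I", 100L),
                barcode = NA_character_, am = NA_integer_,
                mchrom = NA_character_, mpos = NA_integer_) {
  data.frame(qname = qname, flag = as.integer(flag), chrom = chrom,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             seq = seq, qual = qual, barcode = barcode, am = am,
             mchrom = mchrom, mpos = as.integer(mpos),
             is_mapped = !bitwAnd(as.integer(flag), 4L) > 0L,
             mate_mapped = !bitwAnd(as.integer(flag), 8L) > 0L,
             first_in_pair = bitwAnd(as.integer(flag), 64L) > 0L,
             stringsAsFactors = FALSE)
}

# a mapped read pair; flags get pairing bits
pair_recs <- function(qname, chrom = "chr1", pos1 = 100L, pos2 = 400L,
                      barcode = NA_character_, qual1 = strrep("I", 100L),
                      qual2 = strrep("I", 100L), cigar1 = "100M",
                      cigar2 = "100M", am1 = NA_integer_, am2 = NA_integer_,
                      mapped1 = TRUE, mapped2 = TRUE) {
  f1 <- 1L + 64L + (!mapped1) * 4L + (!mapped2) * 8L + 32L * mapped2
  f2 <- 1L + 128L + (!mapped2) * 4L + (!mapped1) * 8L + 16L * mapped2
  rbind(
    rec(qname, f1, chrom = if (mapped1) chrom else ifelse(mapped2, chrom, NA),
        pos = if (mapped1) pos1 else ifelse(mapped2, pos2, NA),
        cigar = if (mapped1) cigar1 else NA_character_, qual = qual1,
        barcode = barcode, am = am1,
        mchrom = if (mapped2) chrom else NA, mpos = if (mapped2) pos2 else NA),
    rec(qname, f2, chrom = if (mapped2) chrom else ifelse(mapped1, chrom, NA),
        pos = if (mapped2) pos2 else ifelse(mapped1, pos1, NA),
        cigar = if (mapped2) cigar2 else NA_character_, qual = qual2,
        barcode = barcode, am = am2,
        mchrom = if (mapped1) chrom else NA, mpos = if (mapped1) pos1 else NA)
  )
}

fixture_reference <- function(len = 2000L, name = "chr1", seed = 99L) {
  withr_seed <- .Random.seed
  set.seed(seed)
  out <- sv_reference(setNames(rand_dna(len), name))
  .Random.seed <<- withr_seed
  out
}

fixture_bam <- function(records, reference, prefix = tempfile("fix")) {
  write_reads_bam(records, reference, prefix)
}

# ---- oracle: brute-force k-mer / (k+1)-mer enumeration --------------------
canon <- function(kmers) pmin(kmers, rc(kmers))

enumerate_kmers <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    s <- toupper(s)
    for (piece in strsplit(gsub("[^ACGT]", " ", s), " +")[[1L]]) {
      if (nchar(piece) < k) next
      st <- seq_len(nchar(piece) - k + 1L)
      out <- c(out, substring(piece, st, st + k - 1L))
    }
  }
  out
}

oracle_kmer_counts <- function(seqs, k) {
  km <- enumerate_kmers(seqs, k)
  if (!length(km)) return(integer())
  table(canon(km))
}

oracle_solid_kmers <- function(short, long, k, short_min = 2L, long_min = 2L) {
  cs <- oracle_kmer_counts(short, k)
  cl <- oracle_kmer_counts(long, k)
  all_k <- union(names(cs), names(cl))
  s <- ifelse(all_k %in% names(cs), as.integer(cs[all_k]), 0L)
  l <- ifelse(all_k %in% names(cl), as.integer(cl[all_k]), 0L)
  all_k[s >= short_min | (l >= 1L & s >= 1L) | l >= long_min]
}

# k-mers actually present in a graph's unitigs
graph_kmers <- function(graph) {
  km <- enumerate_kmers(graph$unitigs, graph$k)
  sort(unique(canon(km)))
}

graph_edge_kmers <- function(graph) {
  within <- enumerate_kmers(graph$unitigs, graph$k + 1L)
  junction <- character()
  if (nrow(graph$links) > 0L) {
    for (i in seq_len(nrow(graph$links))) {
      u <- graph$links[i, 1L]; ue <- graph$links[i, 2L]
      v <- graph$links[i, 3L]; ve <- graph$links[i, 4L]
      us <- graph$unitigs[u]; if (ue == 0L) us <- rc(us)
      vs <- graph$unitigs[v]; if (ve == 1L) vs <- rc(vs)
      junction <- c(junction,
                    paste0(substr(us, nchar(us) - graph$k + 1L, nchar(us)),
                           substr(vs, graph$k, graph$k)))
    }
  }
  sort(unique(canon(c(within, junction))))
}

# ---- oracle: full affine-gap glocal DP (score only), row-vectorized -------
# query-global, reference-local; match +1, mismatch -mm, gap -(open+len*ext)
oracle_glocal_score <- function(q, r, mm = 4, open = 6, ext = 1) {
  qv <- utf8ToInt(q); rv <- utf8ToInt(r)
  n <- length(qv); m <- length(rv)
  NEG <- -1e9
  Hprev <- numeric(m + 1)            # free ref start: row 0 all zero
  Fcol <- rep(NEG, m + 1)
  cvec <- 0:m
  for (i in seq_len(n)) {
    Fcol <- pmax(Fcol - ext, Hprev - open - ext)
    sub <- ifelse(rv == qv[i], 1, -mm)
    # candidate without in-row gaps (E): diagonal or vertical
    H0 <- c(Fcol[1L], pmax(Hprev[1:m] + sub, Fcol[2:(m + 1L)]))
    # E[c] = max_{c'<c} H0[c'] - open - (c-c')*ext, via running-max identity
    E <- c(NEG, cummax(H0[1:m] + cvec[1:m] * ext - ext) - open - cvec[2:(m + 1L)] * ext + ext)
    Hprev <- pmax(H0, E)
    # second pass not needed: gap-into-gap within a row never beats one gap
  }
  max(Hprev)
}

# ---- oracle: maximum bipartite matching by exhaustive search --------------
oracle_max_matching <- function(eligible) {
  # eligible: logical matrix calls x truth
  nc <- nrow(eligible); nt <- ncol(eligible)
  if (nc == 0L || nt == 0L) return(0L)
  best <- 0L
  recurse <- function(ci, used_t, count) {
    if (count + (nc - ci + 1L) <= best) return()
    if (ci > nc) { best <<- max(best, count); return() }
    recurse(ci + 1L, used_t, count)  # leave call unmatched
    for (ti in which(eligible[ci, ] & !used_t)) {
      used_t[ti] <- TRUE
      recurse(ci + 1L, used_t, count + 1L)
      used_t[ti] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

# ---- barcode-selection fixture (shared by segmenter + acceptance) ---------
make_barcode_fixture <- function() {
  set.seed(21)
  ref <- fixture_reference(60000L)
  mk <- function(bc, positions) {
    do.call(rbind, lapply(seq_along(positions), function(i)
      pair_recs(sprintf("%s_p%d", bc, i), pos1 = positions[i],
                pos2 = positions[i] + 250L, barcode = bc)))
  }
  # included: 3 pairs, leftmost start 1000, rightmost end 7100 (span 6100)
  a <- mk("BCA", c(1000L, 3000L, 6750L))
  # excluded: only 2 pairs despite 20 kbp span
  b <- mk("BCB", c(2000L, 21650L))
  # excluded: 5 pairs spanning 4000 bp
  c_ <- mk("BCC", c(10000L, 11000L, 12000L, 13000L, 13650L))
  # excluded: 3 pairs spanning exactly 5000 bp (strict >)
  d <- mk("BCD", c(30000L, 32000L, 34650L))
  # included: 3 pairs spanning 5001 bp
  e <- mk("BCE", c(40000L, 42000L, 44651L))
  list(ref = ref, recs = rbind(a, b, c_, d, e))
}

# ---- small diploid simulation helper used across suites -------------------
quick_sim <- function(seed, genome_length = 150000L, n_svs = 3L,
                      zygosity = "hom", slr_coverage = 40,
                      sv_lens = NULL, ...) {
  sampler <- if (is.null(sv_lens)) NULL else function(n) sample(sv_lens, n, TRUE)
  sim_config(genome_length = genome_length, n_svs = n_svs,
             zygosity = zygosity, slr_coverage = slr_coverage,
             sv_size_sampler = sampler, seed = seed, ...)
}
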