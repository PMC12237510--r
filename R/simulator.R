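# Synthetic data: diploid genomes with implanted indels, barcoded
# linked-read pairs sampled from long fragments, and HiFi-like long reads.
# Reads are emitted as a truth-aligned BAM: each read is placed at its known
# reference-projected coordinate, reads crossing an SV junction carry
# soft-clips (with AM:i:0, emulating an aligner's failure to cluster them),
# and reads sourced entirely from inserted sequence are unmapped. This
# emulates a barcode-aware aligner's output so the whole pipeline is
# testable without an external aligner.

#' Simulation configuration
#'
#' @param genome_length Reference length in bp.
#' @param chrom_name Name of the simulated chromosome.
#' @param n_svs Number of implanted SVs.
#' @param sv_size_sampler Function(n) returning n SV lengths; default is a
#'   mixture of Alu-like (~300 bp), L1-like (~6 kbp), STR-like (small,
#'   motif-multiple) and log-uniform components clamped to [50, 9500].
#' @param zygosity `"hom"`, `"het"`, or `"mixed"` (half/half).
#' @param min_sv_gap Minimum distance between implanted SVs (bp).
#' @param slr_coverage Total linked-read coverage over the diploid sample
#'   (x of the reference length).
#' @param fragment_length_range Long-fragment lengths (bp), sampled uniform.
#' @param fragment_coverage Read coverage of each fragment by its own read
#'   pairs (x); linked-read chemistry covers each fragment only shallowly.
#' @param fragments_per_barcode Fragments sharing one barcode (1 =
#'   TELL-Seq-like; >1 emulates 10x-style barcode collisions).
#' @param read_length,insert_mean,insert_sd Short-read pair geometry (bp).
#' @param short_error Per-base substitution rate of short reads.
#' @param long_coverage Long-read coverage (x); 0 disables.
#' @param long_length_range Long-read lengths (bp), uniform.
#' @param long_error_range Per-read error rate, uniform in this range;
#'   errors are 90% substitutions, 10% 1-bp indels.
#' @param coverage_gap Optional `c(start, end)` (0-based, half-open
#'   reference interval): read pairs touching it are dropped, emulating a
#'   sequencing-bias coverage hole.
#' @param planted_repeat Optional `list(length =, positions =)`: identical
#'   repeat copies written into the reference background at the given
#'   0-based positions (used to study repeat-bridged coverage drops).
#' @param seed Integer seed; all three generators derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1000000L,
                       chrom_name = "sim1",
                       n_svs = 10L,
                       sv_size_sampler = NULL,
                       zygosity = "hom",
                       min_sv_gap = 2000L,
                       slr_coverage = 40,
                       fragment_length_range = c(5000L, 100000L),
                       fragment_coverage = 0.2,
                       fragments_per_barcode = 1L,
                       read_length = 150L,
                       insert_mean = 350,
                       insert_sd = 50,
                       short_error = 0,
                       long_coverage = 0,
                       long_length_range = c(9000L, 12000L),
                       long_error_range = c(0.001, 0.01),
                       coverage_gap = NULL,
                       planted_repeat = NULL,
                       seed = 1L) {
  stopifnot(fragment_length_range[1L] <= fragment_length_range[2L],
            long_length_range[1L] <= long_length_range[2L],
            long_error_range[1L] <= long_error_range[2L],
            short_error >= 0, short_error <= 1,
            fragment_length_range[1L] >= 2L * read_length + 20L)
  if (is.null(sv_size_sampler)) sv_size_sampler <- .default_sv_sizes
  out <- list(genome_length = as.integer(genome_length),
              chrom_name = chrom_name, n_svs = as.integer(n_svs),
              sv_size_sampler = sv_size_sampler, zygosity = zygosity,
              min_sv_gap = as.integer(min_sv_gap),
              slr_coverage = slr_coverage,
              fragment_length_range = as.integer(fragment_length_range),
              fragment_coverage = fragment_coverage,
              fragments_per_barcode = as.integer(fragments_per_barcode),
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              short_error = short_error,
              long_coverage = long_coverage,
              long_length_range = as.integer(long_length_range),
              long_error_range = long_error_range,
              coverage_gap = coverage_gap,
              planted_repeat = planted_repeat,
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

# mixture over the indel size classes seen in human data
.default_sv_sizes <- function(n) {
  comp <- sample.int(4L, n, replace = TRUE, prob = c(0.40, 0.15, 0.20, 0.25))
  len <- integer(n)
  len[comp == 1L] <- as.integer(round(rnorm(sum(comp == 1L), 300, 30)))
  len[comp == 2L] <- as.integer(round(rnorm(sum(comp == 2L), 6000, 300)))
  len[comp == 3L] <- 4L * as.integer(round(runif(sum(comp == 3L), 15, 80)))
  len[comp == 4L] <- as.integer(round(exp(runif(sum(comp == 4L),
                                                log(50), log(9500)))))
  pmin(pmax(len, 50L), 9500L)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a diploid genome with implanted indels
#'
#' Generates a random reference, places non-overlapping insertions and
#' deletions (>= `min_sv_gap` apart, away from the chromosome ends), and
#' applies them to one or both haplotypes according to zygosity.
#'
#' @param sim A [sim_config()].
#' @param truth_vcf Optional path; when given, the truth set is written as
#'   VCF (GT 1/1 or 0/1).
#' @return List of class `sv_simulation`: `reference` (an `sv_reference`),
#'   `haplotypes` (list of two sequences), `truth` (data.frame with `chrom`,
#'   `pos` 1-based anchor, `svtype`, `svlen`, `seq`, `zygosity`, `haps`),
#'   `blocks` (per-haplotype projection tables), `truth_vcf`.
#' @export
simulate_svs <- function(sim = sim_config(), truth_vcf = NULL) {
  set.seed(sim$seed)
  L <- sim$genome_length
  bg <- .random_dna(L)
  if (!is.null(sim$planted_repeat)) {
    rep_seq <- .random_dna(sim$planted_repeat$length)
    for (p in sim$planted_repeat$positions)
      substr(bg, p + 1L, p + sim$planted_repeat$length) <- rep_seq
  }
  nsv <- sim$n_svs
  truth <- data.frame(chrom = character(), pos = integer(), svtype = character(),
                      svlen = integer(), seq = character(), zygosity = character(),
                      haps = character(), stringsAsFactors = FALSE)
  if (nsv > 0L) {
    lens <- sim$sv_size_sampler(nsv)
    if (L < 10L * max(lens)) stop("genome too short for requested SV sizes")
    margin <- 5000L
    gap <- sim$min_sv_gap + max(lens)
    ok <- FALSE
    for (try in 1:50) {
      pos <- sort(sample.int(L - 2L * margin, nsv) + margin)
      if (nsv == 1L || min(diff(pos)) >= gap) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place ", nsv, " SVs >= ", gap,
                  " bp apart; reduce n_svs or SV sizes")
    type <- sample(c("DEL", "INS"), nsv, replace = TRUE)
    zyg <- switch(sim$zygosity,
                  hom = rep("hom", nsv),
                  het = rep("het", nsv),
                  mixed = sample(c("hom", "het"), nsv, replace = TRUE),
                  stop("zygosity must be hom/het/mixed"))
    hap_of <- ifelse(zyg == "hom", "both",
                     as.character(sample.int(2L, nsv, replace = TRUE)))
    seqs <- character(nsv)
    for (i in seq_len(nsv)) {
      seqs[i] <- if (type[i] == "INS") .random_dna(lens[i])
                 else substr(bg, pos[i] + 1L, pos[i] + lens[i])
    }
    truth <- data.frame(chrom = sim$chrom_name, pos = pos, svtype = type,
                        svlen = lens, seq = seqs, zygosity = zyg,
                        haps = hap_of, stringsAsFactors = FALSE)
  }
  reference <- sv_reference(setNames(bg, sim$chrom_name))
  haps <- list(); blocks <- list()
  for (h in 1:2) {
    on_h <- truth[truth$haps %in% c("both", as.character(h)), , drop = FALSE]
    ap <- .apply_svs(bg, on_h)
    haps[[h]] <- ap$seq
    blocks[[h]] <- ap$blocks
  }
  out <- list(reference = reference, haplotypes = haps, truth = truth,
              blocks = blocks, truth_vcf = NULL, sim = sim)
  class(out) <- "sv_simulation"
  if (!is.null(truth_vcf)) {
    tv <- truth
    if (nrow(tv) > 0L) {
      tv$gt <- ifelse(tv$zygosity == "hom", "1/1", "0/1")
      anchor <- substr(rep(bg, nrow(tv)), tv$pos, tv$pos)
      tv$ref <- ifelse(tv$svtype == "DEL", paste0(anchor, tv$seq), anchor)
      tv$alt <- ifelse(tv$svtype == "DEL", anchor, paste0(anchor, tv$seq))
    }
    write_sv_vcf(tv, reference, truth_vcf)
    out$truth_vcf <- truth_vcf
  }
  out
}

# apply SVs (truth rows, ascending pos) to a background; returns the
# haplotype sequence and the block projection table
.apply_svs <- function(bg, svs) {
  L <- nchar(bg)
  parts <- character(); rows <- list()
  cur <- 0L; hap_at <- 0L
  add_block <- function(rs, re, ins_seq = NULL) {
    if (!is.null(ins_seq)) {
      n <- nchar(ins_seq)
      rows[[length(rows) + 1L]] <<- data.frame(ref_start = NA_integer_,
                                               ref_end = NA_integer_,
                                               hap_start = hap_at,
                                               hap_end = hap_at + n, ins = TRUE)
      parts[[length(parts) + 1L]] <<- ins_seq
      hap_at <<- hap_at + n
    } else if (re > rs) {
      rows[[length(rows) + 1L]] <<- data.frame(ref_start = rs, ref_end = re,
                                               hap_start = hap_at,
                                               hap_end = hap_at + (re - rs),
                                               ins = FALSE)
      parts[[length(parts) + 1L]] <<- substr(bg, rs + 1L, re)
      hap_at <<- hap_at + (re - rs)
    }
  }
  if (nrow(svs) > 0L) {
    for (i in seq_len(nrow(svs))) {
      p <- svs$pos[i]  # 1-based anchor; event begins at 0-based position p
      if (svs$svtype[i] == "DEL") {
        add_block(cur, p)
        cur <- p + svs$svlen[i]
      } else {
        add_block(cur, p)
        add_block(NA, NA, ins_seq = svs$seq[i])
        cur <- p
      }
    }
  }
  add_block(cur, L)
  list(seq = paste(parts, collapse = ""), blocks = do.call(rbind, rows))
}

# project hap-coordinate reads onto the reference.
# reads: data.frame(start, end) 0-based half-open in hap coordinates.
# returns data.frame(mapped, pos, cigar, junction)
.project_reads <- function(reads, blocks, min_anchor = 25L) {
  n <- nrow(reads)
  out <- data.frame(mapped = logical(n), pos = rep(NA_integer_, n),
                    cigar = rep(NA_character_, n), junction = logical(n))
  bs <- blocks$hap_start
  idx <- findInterval(reads$start, bs)
  within <- reads$end <= blocks$hap_end[idx]
  simple <- within & !blocks$ins[idx]
  out$mapped[simple] <- TRUE
  out$pos[simple] <- blocks$ref_start[idx[simple]] +
    (reads$start[simple] - blocks$hap_start[idx[simple]])
  out$cigar[simple] <- paste0(reads$end[simple] - reads$start[simple], "M")
  # reads fully inside an inserted block stay unmapped;
  # the rest cross one or more block boundaries
  for (i in which(!within)) {
    s <- reads$start[i]; e <- reads$end[i]
    j <- idx[i]
    best_len <- 0L; best_pos <- NA_integer_; best_off <- 0L
    while (j <= nrow(blocks) && blocks$hap_start[j] < e) {
      os <- max(s, blocks$hap_start[j]); oe <- min(e, blocks$hap_end[j])
      if (!blocks$ins[j] && oe - os > best_len) {
        best_len <- oe - os
        best_pos <- blocks$ref_start[j] + (os - blocks$hap_start[j])
        best_off <- os - s
      }
      j <- j + 1L
    }
    if (best_len >= min_anchor) {
      out$mapped[i] <- TRUE
      out$pos[i] <- best_pos
      left <- best_off; right <- (e - s) - best_off - best_len
      out$cigar[i] <- paste0(if (left > 0L) paste0(left, "S") else "",
                             best_len, "M",
                             if (right > 0L) paste0(right, "S") else "")
      out$junction[i] <- TRUE
    }
  }
  out
}

.apply_subs <- function(seqs, n_err) {
  todo <- which(n_err > 0L)
  for (i in todo) {
    s <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(length(s), min(n_err[i], length(s)))
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate barcoded linked-read pairs
#'
#' Long fragments (uniform lengths in `fragment_length_range`) are sampled
#' from both haplotypes until the target coverage is met; each fragment
#' receives a barcode and is shallowly covered by read pairs
#' (`fragment_coverage`). Reads are placed at their reference-projected
#' coordinates (see module header) and written as an indexed BAM.
#'
#' @param genome An `sv_simulation` from [simulate_svs()].
#' @param out_prefix Output prefix; `<prefix>.bam` (+ index) is created.
#' @param sim Overrides `genome$sim` when given.
#' @return List: `bam`, `n_pairs`, `n_bases`, `n_fragments`.
#' @export
simulate_linked_reads <- function(genome, out_prefix, sim = NULL) {
  sim <- if (is.null(sim)) genome$sim else sim
  set.seed(sim$seed + 1L)
  rl <- sim$read_length
  target_bases_hap <- sim$slr_coverage / 2 * sim$genome_length
  frag_counter <- 0L
  all_recs <- list()
  total_bases <- 0
  for (h in 1:2) {
    hap <- genome$haplotypes[[h]]
    hL <- nchar(hap)
    blocks <- genome$blocks[[h]]
    mean_frag <- mean(pmin(sim$fragment_length_range, hL))
    # overhanging fragments are truncated, so the expected effective length
    # is shorter than the drawn length, especially on short chromosomes
    mean_eff <- mean_frag * hL / (hL + mean_frag)
    n_frag <- ceiling(1.25 * target_bases_hap / (mean_eff * sim$fragment_coverage)) + 4L
    flen0 <- pmin(as.integer(runif(n_frag, sim$fragment_length_range[1L],
                                   sim$fragment_length_range[2L] + 1)), hL)
    # fragments may overhang the chromosome ends and are truncated there, so
    # coverage is uniform right up to the ends (no edge ramp-down)
    s0 <- as.integer(floor(runif(n_frag, -(flen0 - 1), hL - 1)))
    fstart <- pmax(0L, s0)
    fend <- pmin(hL, s0 + flen0)
    flen <- fend - fstart
    ok <- flen >= 2L * rl + 20L
    flen <- flen[ok]; fstart <- fstart[ok]
    npairs <- pmax(1L, as.integer(round(flen * sim$fragment_coverage / (2 * rl))))
    cumb <- cumsum(npairs * 2L * rl)
    cross <- which(cumb >= target_bases_hap)
    keep <- seq_len(if (length(cross)) cross[1L] else length(cumb))
    flen <- flen[keep]; fstart <- fstart[keep]; npairs <- npairs[keep]
    nf <- length(keep)
    bcid <- frag_counter + seq_len(nf)
    frag_counter <- frag_counter + nf
    # expand to pairs
    fi <- rep(seq_len(nf), npairs)
    np <- length(fi)
    ins <- pmax(2L * rl + 20L, pmin(as.integer(rnorm(np, sim$insert_mean, sim$insert_sd)),
                                    flen[fi]))
    ps <- as.integer(floor(runif(np, fstart[fi], fstart[fi] + flen[fi] - ins + 1)))
    s1 <- ps; e1 <- ps + rl
    s2 <- ps + ins - rl; e2 <- ps + ins
    bar <- sprintf("BX%07d-1",
                   (bcid[fi] - 1L) %/% sim$fragments_per_barcode + 1L)
    qn <- sprintf("sim_h%d_p%07d", h, seq_len(np))
    p1 <- .project_reads(data.frame(start = s1, end = e1), blocks)
    p2 <- .project_reads(data.frame(start = s2, end = e2), blocks)
    seq1 <- substring(hap, s1 + 1L, e1)
    seq2 <- substring(hap, s2 + 1L, e2)
    if (sim$short_error > 0) {
      seq1 <- .apply_subs(seq1, stats::rbinom(np, rl, sim$short_error))
      seq2 <- .apply_subs(seq2, stats::rbinom(np, rl, sim$short_error))
    }
    recs <- .pair_to_records(qn, sim$chrom_name, p1, p2, seq1, seq2, rl, bar)
    if (!is.null(sim$coverage_gap)) {
      g0 <- sim$coverage_gap[1L]; g1 <- sim$coverage_gap[2L]
      st <- .cpp_cigar_stats(recs$cigar)
      rend <- ifelse(is.na(recs$pos), NA_real_, recs$pos + st[, "ref_width"])
      hit <- !is.na(recs$pos) & recs$pos < g1 & rend > g0
      bad_q <- unique(recs$qname[hit])
      recs <- recs[!(recs$qname %in% bad_q), , drop = FALSE]
    }
    all_recs[[h]] <- recs
    total_bases <- total_bases + sum(nchar(recs$seq))
  }
  recs <- do.call(rbind, all_recs)
  bam <- write_reads_bam(recs, genome$reference, out_prefix)
  list(bam = bam, n_pairs = nrow(recs) / 2, n_bases = total_bases,
       n_fragments = frag_counter)
}

# build paired SAM-style records from two projection tables
.pair_to_records <- function(qn, chrom, p1, p2, seq1, seq2, rl, bar) {
  np <- length(qn)
  qual <- strrep("I", rl)
  flag1 <- 1L + 64L + ifelse(p1$mapped, 0L, 4L) + ifelse(p2$mapped, 32L, 8L)
  flag2 <- 1L + 128L + 16L * p2$mapped + ifelse(p2$mapped, 0L, 4L) +
    ifelse(p1$mapped, 0L, 8L)
  proper <- p1$mapped & p2$mapped
  flag1 <- flag1 + 2L * proper
  flag2 <- flag2 + 2L * proper
  # unmapped mate placed at its partner's coordinate
  pos1 <- ifelse(p1$mapped, p1$pos, p2$pos)
  pos2 <- ifelse(p2$mapped, p2$pos, p1$pos)
  ch1 <- ifelse(is.na(pos1), NA_character_, chrom)
  ch2 <- ifelse(is.na(pos2), NA_character_, chrom)
  am1 <- ifelse(p1$mapped, ifelse(p1$junction, 0L, 1L), NA_integer_)
  am2 <- ifelse(p2$mapped, ifelse(p2$junction, 0L, 1L), NA_integer_)
  r1 <- data.frame(qname = qn, flag = flag1, chrom = ch1, pos = pos1,
                   mapq = ifelse(p1$mapped, 60L, 0L), cigar = p1$cigar,
                   mchrom = ch2, mpos = pos2, seq = seq1, qual = qual,
                   barcode = bar, am = am1, stringsAsFactors = FALSE)
  r2 <- data.frame(qname = qn, flag = flag2, chrom = ch2, pos = pos2,
                   mapq = ifelse(p2$mapped, 60L, 0L), cigar = p2$cigar,
                   mchrom = ch1, mpos = pos1, seq = seq2, qual = qual,
                   barcode = bar, am = am2, stringsAsFactors = FALSE)
  rbind(r1, r2)
}

#' Simulate HiFi-like long reads
#'
#' Read lengths uniform in `long_length_range`, per-read error uniform in
#' `long_error_range` (90% substitutions, 10% 1-bp indels), sampled from
#' both haplotypes to the configured coverage and written as a truth-aligned
#' indexed BAM.
#'
#' @param genome An `sv_simulation`.
#' @param out_prefix Output prefix for `<prefix>.bam`.
#' @param sim Overrides `genome$sim` when given.
#' @return List: `bam`, `n_reads`, `n_bases`.
#' @export
simulate_long_reads <- function(genome, out_prefix, sim = NULL) {
  sim <- if (is.null(sim)) genome$sim else sim
  set.seed(sim$seed + 2L)
  if (sim$long_coverage <= 0) stop("long_coverage must be > 0")
  target_hap <- sim$long_coverage / 2 * sim$genome_length
  all_recs <- list()
  nb <- 0
  for (h in 1:2) {
    hap <- genome$haplotypes[[h]]
    hL <- nchar(hap)
    blocks <- genome$blocks[[h]]
    mean_len <- mean(sim$long_length_range)
    n <- ceiling(target_hap / mean_len)
    len <- pmin(as.integer(runif(n, sim$long_length_range[1L],
                                 sim$long_length_range[2L] + 1)), hL)
    st <- as.integer(floor(runif(n, 0, hL - len + 1)))
    seqs <- substring(hap, st + 1L, st + len)
    err <- runif(n, sim$long_error_range[1L], sim$long_error_range[2L])
    if (any(err > 0)) seqs <- .apply_long_errors(seqs, err)
    pr <- .project_reads(data.frame(start = st, end = st + len), blocks,
                         min_anchor = 100L)
    # sequence length may differ from the hap interval after indel errors:
    # pad/truncate the CIGAR's clip so SEQ and CIGAR agree
    cig <- .fix_cigar_len(pr$cigar, nchar(seqs), pr$mapped)
    recs <- data.frame(qname = sprintf("lr_h%d_%06d", h, seq_len(n)),
                       flag = ifelse(pr$mapped, 0L, 4L),
                       chrom = ifelse(pr$mapped, sim$chrom_name, NA_character_),
                       pos = pr$pos,
                       mapq = ifelse(pr$mapped, 60L, 0L), cigar = cig,
                       mchrom = NA_character_, mpos = NA_integer_,
                       seq = seqs, qual = strrep("I", nchar(seqs)),
                       stringsAsFactors = FALSE)
    if (!is.null(sim$coverage_gap)) {
      g0 <- sim$coverage_gap[1L]; g1 <- sim$coverage_gap[2L]
      cst <- .cpp_cigar_stats(recs$cigar)
      rend <- ifelse(is.na(recs$pos), NA_real_, recs$pos + cst[, "ref_width"])
      hit <- !is.na(recs$pos) & recs$pos < g1 & rend > g0
      recs <- recs[!hit, , drop = FALSE]
    }
    all_recs[[h]] <- recs
    nb <- nb + sum(nchar(recs$seq))
  }
  recs <- do.call(rbind, all_recs)
  bam <- write_reads_bam(recs, genome$reference, out_prefix)
  list(bam = bam, n_reads = nrow(recs), n_bases = nb)
}

.apply_long_errors <- function(seqs, err) {
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    n_err <- stats::rbinom(1L, nchar(seqs[i]), err[i])
    if (n_err == 0L) next
    s <- strsplit(seqs[i], "")[[1L]]
    pos <- sort(sample.int(length(s), min(n_err, length(s))), decreasing = TRUE)
    kind <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE,
                   prob = c(0.9, 0.05, 0.05))
    for (j in seq_along(pos)) {
      p <- pos[j]
      if (kind[j] == "sub") s[p] <- sample(setdiff(bases, s[p]), 1L)
      else if (kind[j] == "ins") s <- append(s, sample(bases, 1L), after = p)
      else s <- s[-p]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# rebuild each mapped CIGAR as [lS] mM [rS] so the query length it implies
# matches the (error-perturbed) sequence length exactly
.fix_cigar_len <- function(cig, seqlen, mapped) {
  fix <- which(mapped)
  if (!length(fix)) return(cig)
  for (i in fix) {
    ops <- .parse_cigar(cig[i])
    l <- if (ops$op[1L] == "S") ops$len[1L] else 0L
    m <- seqlen[i] - l
    if (m < 1L) { l <- max(0L, seqlen[i] - 1L); m <- seqlen[i] - l }
    # any trailing clip is absorbed into a recomputed one
    mlen <- sum(ops$len[ops$op == "M"])
    newm <- min(m, mlen)
    r <- seqlen[i] - l - newm
    cig[i] <- paste0(if (l > 0L) paste0(l, "S") else "", newm, "M",
                     if (r > 0L) paste0(r, "S") else "")
  }
  cig
}

#' @export
print.sv_simulation <- function(x, ...) {
  cat(sprintf("sv_simulation: %s (%s bp), %d SV(s)\n", x$sim$chrom_name,
              format(x$sim$genome_length, big.mark = ","), nrow(x$truth)))
  if (nrow(x$truth) > 0L)
    print(table(x$truth$svtype, x$truth$zygosity))
  invisible(x)
}
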