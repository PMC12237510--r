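# Local assembly of one window: de Bruijn graph over the gathered reads
# (plus long reads in hybrid mode), diploid-aware simplification, tip-aware
# greedy path extension, and long-read gap closing.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the k-mer assembly graph for one window
#'
#' Nodes are canonical k-mers, edges observed (k+1)-mer adjacencies, both
#' compacted into unitigs. K-mers below the solid threshold are dropped:
#' short-read k-mers need `short_solid_min` occurrences; long-read k-mers
#' are kept when seen in at least one short read or `long_solid_min` long
#' reads (long-read errors would otherwise flood the k-mer spectrum).
#'
#' @param short_reads Character vector of read sequences (non-ACGT bases
#'   split reads).
#' @param long_reads Optional character vector of long-read sequences.
#' @param config An [sv_config()].
#' @return List of class `sv_graph`: `k`, `unitigs`, `cov`, `n_kmers`,
#'   `links` (matrix u/ue/v/ve, ends 0 = unitig start, 1 = end), `link_cov`.
#' @export
build_assembly_graph <- function(short_reads, long_reads = character(),
                                 config = sv_config()) {
  k <- config$kmer_size
  if (length(short_reads) + length(long_reads) == 0L ||
      all(nchar(c(short_reads, long_reads)) < k)) {
    if (length(short_reads) + length(long_reads) > 0L)
      warning("all reads shorter than k = ", k, "; empty graph")
    g <- list(k = k, unitigs = character(), cov = numeric(),
              n_kmers = integer(), links = matrix(integer(), 0, 4),
              link_cov = numeric())
    class(g) <- "sv_graph"
    return(g)
  }
  # case handled in C++ (non-ACGT bases split reads there as well)
  g <- .cpp_dbg_build(short_reads, long_reads, k,
                      config$short_solid_min, config$long_solid_min)
  class(g) <- "sv_graph"
  g
}

#' @export
print.sv_graph <- function(x, ...) {
  cat(sprintf("sv_graph: k=%d, %d unitig(s), %d link(s), total %s bp\n",
              x$k, length(x$unitigs), nrow(x$links),
              format(sum(nchar(x$unitigs)), big.mark = ",")))
  invisible(x)
}

#' Simplify an assembly graph while retaining diploid structure
#'
#' Removes only sequencing-error artifacts: short low-coverage dead-end tips
#' (length < k+10, coverage <= `tip_max_cov`), exact-duplicate parallel
#' unitigs, and bulge branches below the heterozygous-coverage floor
#' (`bulge_floor_frac` of the length-weighted median coverage) when their
#' partner branch is above it. Long tips (>= 2k) and balanced bulges --
#' heterozygous alleles -- are retained regardless of similarity.
#'
#' @param graph An `sv_graph`.
#' @param config An [sv_config()].
#' @return A simplified, recompacted `sv_graph`.
#' @export
simplify_assembly_graph <- function(graph, config = sv_config()) {
  if (length(graph$unitigs) == 0L) return(graph)
  g <- .cpp_dbg_simplify(graph, config$tip_max_cov, config$bulge_floor_frac)
  class(g) <- "sv_graph"
  g
}

#' Extend unitig paths into contigs
#'
#' Greedy extension seeded from the longest unused unitigs. At a junction
#' with a single outgoing edge the path extends only if no long dead-end tip
#' (length >= `tip_vicinity_len`) is incident at the junction or its
#' immediate neighbours -- a long tip signals a coverage drop whose naive
#' traversal would spell a chimeric (false-deletion) contig. At a junction
#' with several outgoing edges every branch is spelled through the shared
#' flanks so both alleles of a bulge appear among the contigs. Each unitig
#' is used at most twice per path.
#'
#' @param graph A simplified `sv_graph`.
#' @param config An [sv_config()].
#' @return Data.frame with `contig_id`, `seq`, `terminated_by_tip_rule`,
#'   `mean_cov`.
#' @export
extend_contig_paths <- function(graph, config = sv_config()) {
  if (length(graph$unitigs) == 0L)
    return(data.frame(contig_id = character(), seq = character(),
                      terminated_by_tip_rule = logical(), mean_cov = numeric(),
                      stringsAsFactors = FALSE))
  res <- .cpp_dbg_extend(graph, config$tip_rule, config$tip_vicinity_len,
                         2L, 64L)
  data.frame(contig_id = sprintf("ctg%03d", seq_along(res$contigs)),
             seq = res$contigs,
             terminated_by_tip_rule = res$terminated_by_tip_rule,
             mean_cov = res$mean_cov, stringsAsFactors = FALSE)
}

# anchor a set of flank sequences inside one long read (read indexed once);
# returns a list (by flank name) of accepted anchors
.anchor_flanks <- function(flanks, read, config) {
  m <- .cpp_anchor_in_read(unlist(flanks), read, config$align_mismatch,
                           config$align_gap_open, config$align_gap_extend,
                           config$align_seed)
  ok <- m[, "found"] == 1 & m[, "aligned"] >= config$gap_anchor_len &
    m[, "identity"] >= config$gap_anchor_identity
  out <- lapply(which(ok), function(i)
    list(start = m[i, "ref_start"], end = m[i, "ref_end"],
         identity = m[i, "identity"]))
  names(out) <- names(flanks)[ok]
  out
}

#' Close inter-contig gaps with long reads
#'
#' For every ordered pair of contig ends, a long read that end-anchors both
#' flanking sequences (>= `gap_anchor_len` aligned bases per side at
#' >= `gap_anchor_identity`) supports a join; joins are applied greedily by
#' descending supporting-read count, the gap spelled by the best-anchored
#' read, and each contig end used at most once.
#'
#' @param contigs Data.frame from [extend_contig_paths()] (or a character
#'   vector of sequences).
#' @param long_reads Character vector of long-read sequences (already capped
#'   per window).
#' @param config An [sv_config()].
#' @return Data.frame in the same shape with joined contigs replacing their
#'   parts; `n_joins` attribute counts applied joins.
#' @export
close_gaps_with_long_reads <- function(contigs, long_reads,
                                       config = sv_config()) {
  if (is.character(contigs))
    contigs <- data.frame(contig_id = sprintf("ctg%03d", seq_along(contigs)),
                          seq = contigs,
                          terminated_by_tip_rule = FALSE,
                          mean_cov = NA_real_, stringsAsFactors = FALSE)
  if (length(long_reads) == 0L || nrow(contigs) < 2L) {
    attr(contigs, "n_joins") <- 0L
    return(contigs)
  }
  fl <- config$gap_anchor_len * 2L
  n <- nrow(contigs)
  seqs <- contigs$seq
  # only contigs long enough to anchor a full flank participate in joins
  join_idx <- which(nchar(seqs) >= fl)
  if (length(join_idx) > 60L)
    join_idx <- join_idx[order(-nchar(seqs[join_idx]))[1:60]]
  # flanks per contig and orientation: tail = junction at the right edge
  tails <- list(); heads <- list()
  for (i in join_idx) {
    s <- seqs[i]; L <- nchar(s)
    tails[[paste0(i, "+")]] <- substr(s, max(1L, L - fl + 1L), L)
    heads[[paste0(i, "+")]] <- substr(s, 1L, min(fl, L))
    rc <- .revcomp(s)
    tails[[paste0(i, "-")]] <- substr(rc, max(1L, L - fl + 1L), L)
    heads[[paste0(i, "-")]] <- substr(rc, 1L, min(fl, L))
  }
  # collect anchors per read (each read's seed index is built once)
  cand <- list()
  for (ri in seq_along(long_reads)) {
    rd <- toupper(long_reads[ri])
    ta <- .anchor_flanks(tails, rd, config)
    ha <- .anchor_flanks(heads, rd, config)
    for (k1 in names(ta)) for (k2 in names(ha)) {
      c1 <- as.integer(sub("[+-]$", "", k1)); c2 <- as.integer(sub("[+-]$", "", k2))
      if (c1 == c2) next
      gap <- ha[[k2]]$start - ta[[k1]]$end
      if (gap < -config$gap_anchor_len || gap > nchar(rd)) next
      cand[[length(cand) + 1L]] <- list(
        k1 = k1, k2 = k2, read = ri, gap = gap,
        gapseq = if (gap > 0) substr(rd, ta[[k1]]$end + 1L, ha[[k2]]$start) else "",
        trim = if (gap < 0) -gap else 0L,
        quality = min(ta[[k1]]$identity, ha[[k2]]$identity))
    }
  }
  if (!length(cand)) { attr(contigs, "n_joins") <- 0L; return(contigs) }
  key <- vapply(cand, function(x) paste(x$k1, x$k2), character(1L))
  support <- table(key)
  grp <- split(cand, key)
  joins <- lapply(names(grp), function(k) {
    g <- grp[[k]]
    best <- g[[which.max(vapply(g, `[[`, numeric(1L), "quality"))]]
    best$support <- length(g)
    best
  })
  ordj <- order(-vapply(joins, `[[`, numeric(1L), "support"),
                -vapply(joins, `[[`, numeric(1L), "quality"))
  joins <- joins[ordj]

  # physical end of contig i used by an oriented tail/head
  phys_tail <- function(key) {
    i <- as.integer(sub("[+-]$", "", key))
    c(i, if (endsWith(key, "+")) 1L else 0L)
  }
  phys_head <- function(key) {
    i <- as.integer(sub("[+-]$", "", key))
    c(i, if (endsWith(key, "+")) 0L else 1L)
  }
  # chains of oriented pieces
  chain_of <- seq_len(n)
  chains <- lapply(seq_len(n), function(i)
    list(pieces = list(list(ctg = i, orient = "+", gap = NULL)),
         left = c(i, 0L), right = c(i, 1L)))
  used_end <- character()
  ekey <- function(e) paste(e[1L], e[2L])
  flip_chain <- function(ch) {
    ch$pieces <- rev(lapply(ch$pieces, function(p) {
      if (!is.null(p$gap)) p$gap <- .revcomp(p$gap)
      else p$orient <- if (p$orient == "+") "-" else "+"
      p
    }))
    tmp <- ch$left; ch$left <- ch$right; ch$right <- tmp
    ch
  }
  n_joins <- 0L
  for (j in joins) {
    e1 <- phys_tail(j$k1); e2 <- phys_head(j$k2)
    if (ekey(e1) %in% used_end || ekey(e2) %in% used_end) next
    c1 <- chain_of[e1[1L]]; c2 <- chain_of[e2[1L]]
    if (c1 == c2) next
    ch1 <- chains[[c1]]; ch2 <- chains[[c2]]
    # e1 must be an extremity of ch1 (right side after possible flip)
    if (ekey(ch1$right) == ekey(e1)) { } else if (ekey(ch1$left) == ekey(e1)) {
      ch1 <- flip_chain(ch1)
    } else next
    if (ekey(ch2$left) == ekey(e2)) { } else if (ekey(ch2$right) == ekey(e2)) {
      ch2 <- flip_chain(ch2)
    } else next
    merged <- list(pieces = c(ch1$pieces, list(list(ctg = NA, orient = NA,
                                                    gap = j$gapseq, trim = j$trim)),
                              ch2$pieces),
                   left = ch1$left, right = ch2$right)
    chains[[c1]] <- merged
    chains[c2] <- list(NULL)  # keep list indices stable
    for (p in merged$pieces) if (!is.null(p$ctg) && !is.na(p$ctg)) chain_of[p$ctg] <- c1
    used_end <- c(used_end, ekey(e1), ekey(e2))
    n_joins <- n_joins + 1L
  }
  # spell chains
  out_seq <- character(); out_tip <- logical(); out_cov <- numeric(); out_id <- character()
  done <- logical(n)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    if (is.null(ch)) next
    s <- ""
    pend_trim <- 0L
    members <- integer()
    for (p in ch$pieces) {
      if (is.null(p$ctg) || is.na(p$ctg)) {  # gap filler piece
        s <- paste0(s, p$gap)
        pend_trim <- p$trim %||% 0L
      } else {
        ps <- seqs[p$ctg]
        if (p$orient == "-") ps <- .revcomp(ps)
        if (pend_trim > 0L) ps <- substr(ps, pend_trim + 1L, nchar(ps))
        pend_trim <- 0L
        s <- paste0(s, ps)
        members <- c(members, p$ctg)
      }
    }
    done[members] <- TRUE
    out_seq <- c(out_seq, s)
    out_tip <- c(out_tip, any(contigs$terminated_by_tip_rule[members]))
    out_cov <- c(out_cov, mean(contigs$mean_cov[members]))
    out_id <- c(out_id, paste(contigs$contig_id[members], collapse = "+"))
  }
  res <- data.frame(contig_id = out_id, seq = out_seq,
                    terminated_by_tip_rule = out_tip, mean_cov = out_cov,
                    stringsAsFactors = FALSE)
  attr(res, "n_joins") <- n_joins
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble one gathered window into contigs
#'
#' Composition of [build_assembly_graph()], [simplify_assembly_graph()],
#' [extend_contig_paths()] and, when long reads are present,
#' [close_gaps_with_long_reads()]. Contigs shorter than `min_contig_len`
#' are dropped.
#'
#' @param segment An `sv_segment` from [gather_segment_reads()].
#' @param config An [sv_config()].
#' @return Contig data.frame as from [extend_contig_paths()].
#' @export
assemble_segment <- function(segment, config = sv_config()) {
  reads <- unique(c(segment$local$seq, segment$recruited$seq))
  reads <- reads[!is.na(reads)]
  if (length(reads) == 0L) {
    message("segment ", segment$segment_id, ": no reads gathered")
    return(data.frame(contig_id = character(), seq = character(),
                      terminated_by_tip_rule = logical(), mean_cov = numeric(),
                      stringsAsFactors = FALSE))
  }
  g <- build_assembly_graph(reads, segment$long_reads, config)
  g <- simplify_assembly_graph(g, config)
  ctg <- extend_contig_paths(g, config)
  if (length(segment$long_reads) > 0L)
    ctg <- close_gaps_with_long_reads(ctg, segment$long_reads, config)
  ctg <- ctg[nchar(ctg$seq) >= config$min_contig_len, , drop = FALSE]
  if (nrow(ctg) > 0L)
    ctg$contig_id <- sprintf("%s|%s", segment$segment_id, ctg$contig_id)
  ctg
}

#' Dump a graph as GFA 1.0 for debugging
#' @param graph An `sv_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\ts%d\t%s\tdp:f:%.2f", seq_along(graph$unitigs),
                     graph$unitigs, graph$cov))
  if (nrow(graph$links) > 0L) {
    lm <- graph$links
    # end 1 = '+' (leaving the stored 3' end); end 0 = '-' orientation
    lines <- c(lines, sprintf("L\ts%d\t%s\ts%d\t%s\t%dM",
                              lm[, 1L], ifelse(lm[, 2L] == 1L, "+", "-"),
                              lm[, 3L], ifelse(lm[, 4L] == 0L, "+", "-"),
                              graph$k - 1L))
  }
  writeLines(lines, path)
  invisible(path)
}
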