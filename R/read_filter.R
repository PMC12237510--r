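# Recruitment of badly aligned read pairs into a barcode-keyed read map.
#
# A pair is recruited iff (a) every base of both mates exceeds the Phred
# gate -- a necessary quality filter so that reads displaced by sequencing
# error are not mistaken for SV evidence -- AND at least one badness signal
# holds: (b) a mate is unmapped, on an unplaced contig, or soft-clipped over
# more than the clip-fraction threshold, or (c) a mate carries AM:i:0
# (aligner could not cluster it with same-barcode reads).

.is_unplaced <- function(chrom, config) {
  if (!is.null(config$primary_chroms))
    return(!is.na(chrom) & !(chrom %in% config$primary_chroms))
  !is.na(chrom) & grepl(config$unplaced_regex, chrom)
}

# vectorized pair predicate over two aligned record frames (r2 rows may be NA)
.badly_aligned_vec <- function(r1, r2, config) {
  has2 <- !is.na(r2$qname)
  qa <- r1$minq > config$min_base_phred &
    (!has2 | (!is.na(r2$minq) & r2$minq > config$min_base_phred))
  b1 <- !r1$is_mapped | .is_unplaced(r1$chrom, config) |
    (!is.na(r1$clip_frac) & r1$clip_frac > config$max_softclip_fraction)
  b2 <- ifelse(has2,
               !r2$is_mapped | .is_unplaced(r2$chrom, config) |
                 (!is.na(r2$clip_frac) & r2$clip_frac > config$max_softclip_fraction),
               TRUE)  # absent mate treated as unmapped
  condb <- b1 | b2
  condc <- (!is.na(r1$am) & r1$am == 0L) | (has2 & !is.na(r2$am) & r2$am == 0L)
  bad <- qa & (condb | condc)
  reason <- rep(NA_character_, length(bad))
  reason[bad & condb & !condc] <- "align"
  reason[bad & !condb & condc] <- "am0"
  reason[bad & condb & condc] <- "align+am0"
  list(bad = bad, reason = reason)
}

#' Decide whether a read pair is badly aligned
#'
#' Returns TRUE iff the all-bases quality gate holds on both mates AND a
#' badness signal fires: a mate unmapped / on an unplaced contig /
#' soft-clipped beyond the threshold fraction, or a mate with `AM:i:0`. An
#' absent mate (orphan) is treated as unmapped.
#'
#' @param read1 One-row record data.frame (see [read_bam_records()]).
#' @param read2 Matching mate record, or `NULL` for an orphan.
#' @param config An [sv_config()].
#' @return List with `bad` (logical) and `reason` (`"align"`, `"am0"`,
#'   `"align+am0"`, or `NA` when not recruited).
#' @export
badly_aligned <- function(read1, read2 = NULL, config = sv_config()) {
  r1 <- .annotate_records(read1)
  r2 <- if (is.null(read2)) {
    r1[0, ][1, ]  # single all-NA row
  } else .annotate_records(read2)
  res <- .badly_aligned_vec(r1, r2, config)
  list(bad = res$bad[1L], reason = res$reason[1L])
}

# group primary records into pairs; returns list(r1, r2, pair_id per record)
.pair_records <- function(df) {
  ord <- order(df$qname, !df$first_in_pair, method = "radix")
  df <- df[ord, , drop = FALSE]
  q <- df$qname
  newrun <- c(TRUE, q[-1L] != q[-length(q)])
  pid <- cumsum(newrun)
  # at most two records per qname expected (primary only); extras dropped
  rank_in_pair <- sequence(rle(pid)$lengths)
  keep <- rank_in_pair <= 2L
  df <- df[keep, , drop = FALSE]
  pid <- pid[keep]
  rank_in_pair <- rank_in_pair[keep]
  i1 <- which(rank_in_pair == 1L)
  i2 <- which(rank_in_pair == 2L)
  r1 <- df[i1, , drop = FALSE]
  r2idx <- rep(NA_integer_, length(i1))
  r2idx[match(pid[i2], pid[i1])] <- i2
  r2 <- df[r2idx, , drop = FALSE]  # NA rows where orphan
  list(df = df, pid = pid, r1 = r1, r2 = r2, i1 = i1, r2idx = r2idx)
}

#' Build the barcode-keyed map of badly aligned read pairs
#'
#' Scans a whole BAM (or an in-memory record frame), applies
#' [badly_aligned()] to every primary pair, and stores qualifying pairs
#' keyed by barcode. Pairs without a barcode on either mate are dropped and
#' counted.
#'
#' @param bam Path to an indexed BAM, or a record data.frame from
#'   [read_bam_records()].
#' @param config An [sv_config()].
#' @return An `sv_read_map`: list with `reads` (record frame with `pair_id`),
#'   `pairs` (pair_id, barcode, reason), `by_barcode` (pair ids split by
#'   barcode), `total_pairs`, `n_dropped_no_barcode`.
#' @export
build_read_map <- function(bam, config = sv_config()) {
  df <- if (is.character(bam)) read_bam_records(bam) else bam
  empty <- list(reads = df[0, , drop = FALSE],
                pairs = data.frame(pair_id = integer(), barcode = character(),
                                   reason = character(), stringsAsFactors = FALSE),
                by_barcode = list(), total_pairs = 0L, n_dropped_no_barcode = 0L)
  class(empty) <- "sv_read_map"
  if (nrow(df) == 0L) return(empty)
  df <- .annotate_records(df)
  df <- df[df$primary, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  pr <- .pair_records(df)
  res <- .badly_aligned_vec(pr$r1, pr$r2, config)
  bc <- ifelse(!is.na(pr$r1$barcode), pr$r1$barcode, pr$r2$barcode)
  keep <- res$bad & !is.na(bc)
  dropped <- sum(res$bad & is.na(bc))
  if (!any(keep)) { empty$n_dropped_no_barcode <- dropped; return(empty) }
  kept_pid <- pr$pid[pr$i1][keep]
  rows <- c(pr$i1[keep], pr$r2idx[keep][!is.na(pr$r2idx[keep])])
  reads <- pr$df[sort(rows), , drop = FALSE]
  reads$pair_id <- pr$pid[sort(rows)]
  pairs <- data.frame(pair_id = kept_pid, barcode = bc[keep],
                      reason = res$reason[keep], stringsAsFactors = FALSE)
  out <- list(reads = reads, pairs = pairs,
              by_barcode = split(pairs$pair_id, pairs$barcode),
              total_pairs = nrow(pairs),
              n_dropped_no_barcode = dropped)
  class(out) <- "sv_read_map"
  out
}

#' @export
print.sv_read_map <- function(x, ...) {
  cat(sprintf("sv_read_map: %d badly aligned pair(s) under %d barcode(s); %d dropped (no barcode)\n",
              x$total_pairs, length(x$by_barcode), x$n_dropped_no_barcode))
  invisible(x)
}

#' Query the read map by a barcode list
#'
#' Returns the union over the given barcodes of their stored pairs (M(B)).
#' Duplicate barcodes in the query do not duplicate pairs.
#'
#' @param map An `sv_read_map`.
#' @param barcodes Character vector of barcodes.
#' @return Record data.frame (with `pair_id`) of the matching pairs' reads.
#' @export
query_read_map <- function(map, barcodes) {
  ids <- unique(unlist(map$by_barcode[unique(barcodes)], use.names = FALSE))
  map$reads[map$reads$pair_id %in% ids, , drop = FALSE]
}

#' Dump the recruited-pair table for debugging
#'
#' @param map An `sv_read_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_read_map_tsv <- function(map, path) {
  qn <- map$reads$qname[match(map$pairs$pair_id, map$reads$pair_id)]
  utils::write.table(data.frame(read = qn, barcode = map$pairs$barcode,
                                reason = map$pairs$reason),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
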