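# Tiling the reference into overlapping windows, per-window barcode
# selection, and read gathering.
#
# A barcode is selected for a window when at least `min_barcode_pairs` read
# pairs with that barcode align inside the window and the extent from the
# leftmost aligned start to the rightmost aligned end exceeds
# `min_barcode_span` (both measured within the window): evidence that a
# long fragment with this barcode truly spans the window rather than a few
# reads mapping there spuriously.

#' Tile a reference into overlapping windows
#'
#' Windows start at 0 and advance by `segment_length - segment_overlap`; the
#' last window on each chromosome is truncated at its end. Coordinates are
#' 0-based half-open.
#'
#' @param reference An `sv_reference`.
#' @param config An [sv_config()].
#' @return Data.frame with `chrom`, `start`, `end`, `segment_id`.
#' @export
tile_segments <- function(reference, config = sv_config()) {
  step <- config$segment_length - config$segment_overlap
  out <- lapply(names(reference$lengths), function(chrom) {
    len <- reference$lengths[[chrom]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    # drop windows fully contained in their predecessor
    starts <- starts[starts == 0L | starts < len - config$segment_overlap]
    ends <- pmin(starts + config$segment_length, len)
    keep <- ends > starts
    data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$segment_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df
}

# core selection over an annotated in-memory record frame
.select_barcodes_core <- function(df, chrom, start, end, config) {
  df <- df[df$primary & df$is_mapped & !is.na(df$barcode) &
             df$chrom == chrom & df$pos < end & df$ref_end > start, , drop = FALSE]
  if (nrow(df) == 0L) return(character())
  key <- paste0(df$barcode, "\r", df$qname)
  npairs <- tapply(key, df$barcode, function(k) length(unique(k)))
  lo <- tapply(df$pos, df$barcode, min)
  hi <- tapply(df$ref_end, df$barcode, max)
  sel <- names(npairs)[npairs >= config$min_barcode_pairs &
                         (hi - lo) > config$min_barcode_span]
  sort(as.character(sel))
}

#' Select barcodes for a window
#'
#' @param segment One row of [tile_segments()] output (or a list with
#'   `chrom`, `start`, `end`).
#' @param bam Indexed BAM path, or an annotated record frame.
#' @param config An [sv_config()].
#' @return Sorted character vector of selected barcodes, B(s).
#' @export
select_barcodes <- function(segment, bam, config = sv_config()) {
  df <- if (is.character(bam)) {
    .annotate_records(read_bam_records(
      bam, sprintf("%s:%d-%d", segment$chrom, segment$start + 1L, segment$end)))
  } else .annotate_records(bam)
  .select_barcodes_core(df, segment$chrom, segment$start, segment$end, config)
}

# gather core: local pairs with a selected barcode, plus mate completion
.gather_local_core <- function(df, full_df, chrom, start, end, barcodes, config,
                               mate_fetch = NULL) {
  inwin <- df$primary & df$is_mapped & !is.na(df$barcode) &
    df$chrom == chrom & df$pos < end & df$ref_end > start &
    df$barcode %in% barcodes
  loc <- df[inwin, , drop = FALSE]
  if (nrow(loc) == 0L) return(loc)
  # complete pairs: fetch mates not already in the window set
  have <- paste0(loc$qname, "\r", loc$first_in_pair)
  want <- paste0(loc$qname, "\r", !loc$first_in_pair)
  missing <- setdiff(want, have)
  mates <- NULL
  if (length(missing)) {
    miss_q <- sub("\r.*$", "", missing)
    if (!is.null(full_df)) {
      cand <- full_df[full_df$qname %in% miss_q & full_df$primary, , drop = FALSE]
      mates <- cand[paste0(cand$qname, "\r", cand$first_in_pair) %in% missing, , drop = FALSE]
    } else if (!is.null(mate_fetch)) {
      mates <- mate_fetch(loc, missing)
    }
  }
  out <- if (is.null(mates) || nrow(mates) == 0L) loc else
    rbind(loc, mates[, names(loc), drop = FALSE])
  out[order(ifelse(is.na(out$pos), .Machine$integer.max, out$pos), out$qname,
            !out$first_in_pair, method = "radix"), , drop = FALSE]
}

# index-backed mate lookup by (mate position, qname), capped
.mate_fetch_bam <- function(bam_path, config) {
  force(bam_path); force(config)
  function(loc, missing) {
    miss_q <- sub("\r.*$", "", missing)
    need <- loc[paste0(loc$qname, "\r", !loc$first_in_pair) %in% missing, , drop = FALSE]
    need <- need[!is.na(need$mchrom) & !is.na(need$mpos), , drop = FALSE]
    if (nrow(need) == 0L) return(NULL)
    if (nrow(need) > config$mate_lookup_cap)
      need <- need[seq_len(config$mate_lookup_cap), , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      need$mchrom, IRanges::IRanges(need$mpos + 1L, need$mpos + 1L)))
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
               "mpos", "seq", "qual"),
      tag = c("BX", "AM"), which = gr)
    res <- Rsamtools::scanBam(bam_path, param = param)
    recs <- lapply(res, .records_from_scan)
    cand <- do.call(rbind, recs)
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand <- .annotate_records(cand)
    cand <- cand[cand$primary & cand$qname %in% need$qname, , drop = FALSE]
    cand[paste0(cand$qname, "\r", cand$first_in_pair) %in% missing, , drop = FALSE]
  }
}

#' Gather a window's read set
#'
#' Local pairs are reads with a selected barcode whose primary alignment
#' overlaps the window (half-in-window pairs are completed by an
#' index-backed mate lookup); recruited pairs are the read map's M(B(s));
#' in hybrid mode up to `max_long_reads_per_segment` primary long-read
#' alignments overlapping the window are added in coordinate order.
#'
#' @param segment One row of [tile_segments()] output.
#' @param bam Indexed BAM path or annotated record frame of linked reads.
#' @param read_map An `sv_read_map` from [build_read_map()].
#' @param long_bam Optional long-read BAM path (or record frame).
#' @param barcodes Barcode list B(s); computed via [select_barcodes()] when
#'   `NULL`.
#' @param full_frame Optional record frame used for in-memory mate lookup
#'   when `bam` is a (possibly windowed) frame; defaults to `bam` itself.
#' @param config An [sv_config()].
#' @return List of class `sv_segment` with `chrom`, `start`, `end`,
#'   `segment_id`, `barcodes`, `local` (record frame), `recruited` (record
#'   frame), `long_reads` (character vector of sequences).
#' @export
gather_segment_reads <- function(segment, bam, read_map, long_bam = NULL,
                                 barcodes = NULL, full_frame = NULL,
                                 config = sv_config()) {
  from_path <- is.character(bam)
  df <- if (from_path) {
    .annotate_records(read_bam_records(
      bam, sprintf("%s:%d-%d", segment$chrom, segment$start + 1L, segment$end)))
  } else .annotate_records(bam)
  if (is.null(barcodes))
    barcodes <- .select_barcodes_core(df, segment$chrom, segment$start,
                                      segment$end, config)
  local <- .gather_local_core(
    df, full_df = if (from_path) NULL else (if (is.null(full_frame)) df else full_frame),
    segment$chrom, segment$start, segment$end, barcodes, config,
    mate_fetch = if (from_path) .mate_fetch_bam(bam, config) else NULL)
  recruited <- query_read_map(read_map, barcodes)
  long_seqs <- character()
  if (!is.null(long_bam)) {
    ldf <- if (is.character(long_bam)) {
      .annotate_records(read_bam_records(
        long_bam, sprintf("%s:%d-%d", segment$chrom, segment$start + 1L, segment$end)))
    } else .annotate_records(long_bam)
    ldf <- ldf[ldf$primary & ldf$is_mapped & ldf$chrom == segment$chrom &
                 ldf$pos < segment$end & ldf$ref_end > segment$start, , drop = FALSE]
    ldf <- ldf[order(ldf$pos, ldf$qname, method = "radix"), , drop = FALSE]
    ldf <- head(ldf, config$max_long_reads_per_segment)
    long_seqs <- ldf$seq
  }
  out <- list(chrom = segment$chrom, start = segment$start, end = segment$end,
              segment_id = if (!is.null(segment$segment_id)) segment$segment_id
                           else sprintf("%s:%d-%d", segment$chrom, segment$start, segment$end),
              barcodes = barcodes, local = local, recruited = recruited,
              long_reads = long_seqs)
  class(out) <- "sv_segment"
  out
}

#' Write the window manifest as BED
#' @param segments Output of [tile_segments()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  utils::write.table(segments[, c("chrom", "start", "end", "segment_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
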