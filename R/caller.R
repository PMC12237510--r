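# Calling indels from contig-to-window realignments. Contigs are aligned
# glocally (global in the contig, local in the padded window), indels are
# read off the CIGAR, left-aligned against the reference, size-filtered to
# the reporting window, deduplicated on (chrom, pos, type, length), and
# sorted.

#' Align a contig back to its window
#'
#' Glocal alignment of the contig against the window sequence padded by
#' `align_pad` on both sides: exact-match seeding on window-unique k-mers,
#' collinear chaining, and banded affine-gap alignment between adjacent
#' anchors (small problems are solved by full dynamic programming). Both
#' strands are tried; alignments under `min_align_identity` (gap-compressed)
#' are discarded.
#'
#' @param contig Contig sequence (character scalar).
#' @param segment An `sv_segment` or any list with `chrom`, `start`, `end`.
#' @param reference An `sv_reference`.
#' @param config An [sv_config()].
#' @return List of alignments; each has `contig_seq` (as aligned), `chrom`,
#'   `ref_start` (0-based, genomic), `cigar`, `strand`, `identity`, `score`.
#'   Empty list when no placement is found.
#' @export
align_contig <- function(contig, segment, reference, config = sv_config()) {
  chromseq <- reference$sequences[[segment$chrom]]
  wstart <- max(0L, segment$start - config$align_pad)
  wend <- min(nchar(chromseq), segment$end + config$align_pad)
  window <- substr(chromseq, wstart + 1L, wend)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") toupper(contig) else .revcomp(toupper(contig))
    a <- .cpp_align(q, window, config$align_mismatch, config$align_gap_open,
                    config$align_gap_extend, config$align_seed, 4e6)
    if (isTRUE(a$found) && (is.null(best) || a$score > best$score)) {
      best <- a
      best$strand <- strand
      best$contig_seq <- q
    }
    # a near-perfect placement cannot be beaten by the other strand
    if (!is.null(best) && strand == "+" &&
        best$identity_gc > 0.995 && best$score > 0.5 * nchar(q)) break
  }
  if (is.null(best)) return(list())
  if (best$identity_gc < config$min_align_identity) return(list())
  list(list(contig_seq = best$contig_seq, chrom = segment$chrom,
            ref_start = wstart + best$ref_start, cigar = best$cigar,
            strand = best$strand, identity = best$identity_gc,
            score = best$score))
}

.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' Extract size-filtered indels from a contig alignment CIGAR
#'
#' One call per internal I or D operation whose length falls inside
#' `[min_sv_len, max_sv_len]`. Deletion alleles are read from the reference,
#' insertion alleles from the contig; `pos` is the 1-based reference
#' position of the base before the event. Leading/trailing indel operations
#' (unanchored contig ends) are ignored.
#'
#' @param alignment One element of [align_contig()] output.
#' @param reference An `sv_reference`.
#' @param config An [sv_config()].
#' @param contig_id Identifier recorded in the calls.
#' @param segment_id Identifier of the source window.
#' @return SV call data.frame (`chrom`, `pos`, `svtype`, `svlen`, `ref`,
#'   `alt`, `segment_id`, `contig_id`).
#' @export
cigar_indels <- function(alignment, reference, config = sv_config(),
                         contig_id = "contig", segment_id = "segment") {
  empty <- data.frame(chrom = character(), pos = integer(), svtype = character(),
                      svlen = integer(), ref = character(), alt = character(),
                      segment_id = character(), contig_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(alignment) || length(alignment) == 0L) return(empty)
  ops <- .parse_cigar(alignment$cigar)
  if (nrow(ops) == 0L) return(empty)
  # internal ops only: ignore leading/trailing non-M blocks
  mpos <- which(ops$op %in% c("M", "=", "X"))
  if (length(mpos) == 0L) return(empty)
  interior <- seq(min(mpos), max(mpos))
  chromseq <- reference$sequences[[alignment$chrom]]
  rpos <- alignment$ref_start  # 0-based
  qpos <- 0L
  # query offset consumed by ops before the interior
  for (i in seq_len(nrow(ops))) {
    if (i >= min(mpos)) break
    if (ops$op[i] %in% c("I", "S")) qpos <- qpos + ops$len[i]
    if (ops$op[i] %in% c("D", "N")) rpos <- rpos + ops$len[i]
  }
  calls <- list()
  for (i in interior) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (len >= config$min_sv_len && len <= config$max_sv_len) {
        anchor1 <- rpos  # 1-based position of base before event == 0-based first deleted
        ref_allele <- substr(chromseq, anchor1, anchor1 + len)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = alignment$chrom, pos = anchor1, svtype = "DEL",
          svlen = len, ref = ref_allele, alt = substr(ref_allele, 1L, 1L),
          segment_id = segment_id, contig_id = contig_id,
          stringsAsFactors = FALSE)
      }
      rpos <- rpos + len
    } else if (op == "I") {
      if (len >= config$min_sv_len && len <= config$max_sv_len) {
        anchor1 <- rpos
        anchor_base <- substr(chromseq, anchor1, anchor1)
        ins <- substr(alignment$contig_seq, qpos + 1L, qpos + len)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = alignment$chrom, pos = anchor1, svtype = "INS",
          svlen = len, ref = anchor_base, alt = paste0(anchor_base, ins),
          segment_id = segment_id, contig_id = contig_id,
          stringsAsFactors = FALSE)
      }
      qpos <- qpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }
  if (length(calls) == 0L) return(empty)
  do.call(rbind, calls)
}

#' Left-align indel calls against the reference
#'
#' Shifts each event to its leftmost equivalent placement (standard VCF
#' normalization) so the same event discovered in overlapping windows or on
#' both haplotype contigs deduplicates on its exact key.
#'
#' @param calls SV call data.frame.
#' @param reference An `sv_reference`.
#' @return The calls with normalized `pos`, `ref`, `alt`.
#' @export
left_align_calls <- function(calls, reference) {
  if (is.null(calls) || nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    chromseq <- reference$sequences[[calls$chrom[i]]]
    pos <- calls$pos[i]  # 1-based anchor
    len <- calls$svlen[i]
    if (calls$svtype[i] == "DEL") {
      # deleted interval is (pos, pos+len]; shift while the base entering the
      # interval from the left equals the base leaving it on the right
      while (pos > 1L &&
             substr(chromseq, pos + len, pos + len) == substr(chromseq, pos, pos)) {
        pos <- pos - 1L
      }
      calls$pos[i] <- pos
      calls$ref[i] <- substr(chromseq, pos, pos + len)
      calls$alt[i] <- substr(chromseq, pos, pos)
    } else if (calls$svtype[i] == "INS") {
      ins <- substr(calls$alt[i], 2L, nchar(calls$alt[i]))
      while (pos > 1L && substr(ins, len, len) == substr(chromseq, pos, pos)) {
        ins <- paste0(substr(chromseq, pos, pos), substr(ins, 1L, len - 1L))
        pos <- pos - 1L
      }
      calls$pos[i] <- pos
      anchor <- substr(chromseq, pos, pos)
      calls$ref[i] <- anchor
      calls$alt[i] <- paste0(anchor, ins)
    }
  }
  calls
}

#' Deduplicate calls on their exact key
#'
#' Among calls sharing (chrom, pos, svtype, svlen) exactly one survives --
#' the first in (segment, contig) order -- so events seen in overlapping
#' windows or from both allele contigs are reported once. Calls differing
#' in any key field all survive. Idempotent.
#'
#' @param calls SV call data.frame.
#' @return Deduplicated calls.
#' @export
dedup_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) return(calls)
  ord <- order(calls$chrom, calls$pos, calls$svtype, calls$svlen,
               calls$segment_id, calls$contig_id, method = "radix")
  calls <- calls[ord, , drop = FALSE]
  key <- paste(calls$chrom, calls$pos, calls$svtype, calls$svlen)
  calls[!duplicated(key), , drop = FALSE]
}

#' Merge per-window calls into a genome-wide callset
#'
#' Concatenates per-window extractions, left-aligns, deduplicates, and
#' sorts by (chrom, pos, svtype, svlen).
#'
#' @param call_list List of SV call data.frames.
#' @param reference An `sv_reference`.
#' @return Sorted, deduplicated call data.frame.
#' @export
call_genome <- function(call_list, reference) {
  call_list <- Filter(function(x) !is.null(x) && nrow(x) > 0L, call_list)
  empty <- data.frame(chrom = character(), pos = integer(), svtype = character(),
                      svlen = integer(), ref = character(), alt = character(),
                      segment_id = character(), contig_id = character(),
                      stringsAsFactors = FALSE)
  if (length(call_list) == 0L) return(empty)
  calls <- do.call(rbind, call_list)
  calls <- left_align_calls(calls, reference)
  calls <- dedup_calls(calls)
  ord <- order(match(calls$chrom, names(reference$sequences)), calls$pos,
               calls$svtype, calls$svlen, method = "radix")
  calls[ord, , drop = FALSE]
}
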