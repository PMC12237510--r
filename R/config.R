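#' Pipeline configuration
#'
#' Bundles every tunable of the caller. Defaults reflect the intended
#' operating point for ~150 bp linked reads at 30-40x coverage: 50 kbp
#' windows overlapping by 10 kbp (the overlap bounds the largest detectable
#' deletion), barcode selection at >= 3 read pairs spanning > 5 kbp, a
#' strict all-bases Phred > 20 quality gate on recruited read pairs, and a
#' 55-mer assembly graph.
#'
#' @param segment_length Window length in bp.
#' @param segment_overlap Overlap of consecutive windows in bp; must be
#'   smaller than `segment_length`.
#' @param min_barcode_pairs Minimum read pairs a barcode must have aligned in
#'   a window to be selected for it.
#' @param min_barcode_span Minimum distance (bp, strict) between the leftmost
#'   aligned start and rightmost aligned end of a barcode's reads in the
#'   window.
#' @param min_base_phred All bases of both mates must exceed this Phred score
#'   (strict) for a pair to enter the recruited-read map.
#' @param max_softclip_fraction A read with more than this fraction of its
#'   bases soft-clipped counts as badly aligned.
#' @param min_sv_len,max_sv_len Reported SV size window in bp.
#' @param max_long_reads_per_segment Cap on long reads fed to one window's
#'   assembly (hybrid mode).
#' @param kmer_size Odd k for the de Bruijn graph, >= 15.
#' @param short_solid_min Minimum short-read count for a k-mer to be kept.
#'   Long-read k-mers are kept when corroborated by >= 1 short-read
#'   occurrence or >= `long_solid_min` long reads.
#' @param long_solid_min See `short_solid_min`.
#' @param tip_max_cov Dead-end unitigs shorter than `kmer_size + 10` with
#'   mean coverage at or below this are removed as sequencing-error tips.
#' @param bulge_floor_frac Parallel bulge branches below this fraction of the
#'   length-weighted median unitig coverage are removed; branches above it
#'   are retained regardless of similarity (heterozygous alleles).
#' @param tip_rule Refuse single-edge path extension when a long dead-end tip
#'   (length >= `tip_vicinity_len`) is incident near the junction; guards
#'   against chimeric joins over coverage drops.
#' @param tip_vicinity_len Minimum tip length (bp) that triggers the rule;
#'   default `2 * kmer_size`.
#' @param min_contig_len Contigs shorter than this are dropped; default
#'   `2 * kmer_size`.
#' @param align_match,align_mismatch,align_gap_open,align_gap_extend Scoring
#'   for contig-to-window alignment (mismatch and gaps as positive costs).
#' @param align_seed Seed length for window-unique exact-match anchoring.
#' @param min_align_identity Gap-compressed identity below which a contig
#'   alignment is discarded.
#' @param align_pad Reference padding (bp) added around a window before
#'   realignment; defaults to `max_sv_len + 2000` so a contig whose
#'   assembly extends across a window edge (e.g. through a deletion that
#'   ends just inside the window) still aligns to its true flanks instead
#'   of spelling boundary artifacts.
#' @param gap_anchor_len,gap_anchor_identity End-anchoring requirements for
#'   long-read gap closing: at least this many aligned bases per side at at
#'   least this identity.
#' @param match_distance Breakpoint tolerance (bp) for benchmark matching.
#' @param size_similarity Minimum `min(len)/max(len)` for a benchmark match;
#'   set to 0 to disable the size gate.
#' @param mate_lookup_cap Maximum per-window mate-by-name BAM lookups.
#' @param unplaced_regex Reference names matching this pattern count as
#'   unplaced contigs; ignored when `primary_chroms` is given.
#' @param primary_chroms Optional character vector of primary chromosome
#'   names; anything else counts as unplaced.
#' @param random_seed Seed for any stochastic step.
#'
#' @return A list of class `sv_config`.
#' @export
sv_config <- function(segment_length = 50000L,
                      segment_overlap = 10000L,
                      min_barcode_pairs = 3L,
                      min_barcode_span = 5000L,
                      min_base_phred = 20L,
                      max_softclip_fraction = 0.20,
                      min_sv_len = 50L,
                      max_sv_len = 10000L,
                      max_long_reads_per_segment = 100L,
                      kmer_size = 55L,
                      short_solid_min = 2L,
                      long_solid_min = 2L,
                      tip_max_cov = 1.0,
                      bulge_floor_frac = 0.25,
                      tip_rule = TRUE,
                      tip_vicinity_len = NULL,
                      min_contig_len = NULL,
                      align_match = 1L,
                      align_mismatch = 4L,
                      align_gap_open = 6L,
                      align_gap_extend = 1L,
                      align_seed = 31L,
                      min_align_identity = 0.90,
                      align_pad = NULL,
                      gap_anchor_len = 200L,
                      gap_anchor_identity = 0.85,
                      match_distance = 500L,
                      size_similarity = 0.7,
                      mate_lookup_cap = 10000L,
                      unplaced_regex = "(_random|_alt|_decoy|^chrUn|^GL[0-9]|^KI[0-9]|^hs37d5)",
                      primary_chroms = NULL,
                      random_seed = 1L) {
  if (segment_overlap >= segment_length)
    stop("segment_overlap must be smaller than segment_length")
  if (min_sv_len >= max_sv_len)
    stop("min_sv_len must be smaller than max_sv_len")
  if (kmer_size %% 2L == 0L || kmer_size < 15L)
    stop("kmer_size must be odd and >= 15")
  cfg <- list(
    segment_length = as.integer(segment_length),
    segment_overlap = as.integer(segment_overlap),
    min_barcode_pairs = as.integer(min_barcode_pairs),
    min_barcode_span = as.integer(min_barcode_span),
    min_base_phred = as.integer(min_base_phred),
    max_softclip_fraction = max_softclip_fraction,
    min_sv_len = as.integer(min_sv_len),
    max_sv_len = as.integer(max_sv_len),
    max_long_reads_per_segment = as.integer(max_long_reads_per_segment),
    kmer_size = as.integer(kmer_size),
    short_solid_min = as.integer(short_solid_min),
    long_solid_min = as.integer(long_solid_min),
    tip_max_cov = tip_max_cov,
    bulge_floor_frac = bulge_floor_frac,
    tip_rule = isTRUE(tip_rule),
    tip_vicinity_len = as.integer(if (is.null(tip_vicinity_len)) 2L * kmer_size else tip_vicinity_len),
    min_contig_len = as.integer(if (is.null(min_contig_len)) 2L * kmer_size else min_contig_len),
    align_match = as.integer(align_match),
    align_mismatch = as.integer(align_mismatch),
    align_gap_open = as.integer(align_gap_open),
    align_gap_extend = as.integer(align_gap_extend),
    align_seed = as.integer(align_seed),
    min_align_identity = min_align_identity,
    align_pad = as.integer(if (is.null(align_pad)) max_sv_len + 2000L else align_pad),
    gap_anchor_len = as.integer(gap_anchor_len),
    gap_anchor_identity = gap_anchor_identity,
    match_distance = as.integer(match_distance),
    size_similarity = size_similarity,
    mate_lookup_cap = as.integer(mate_lookup_cap),
    unplaced_regex = unplaced_regex,
    primary_chroms = primary_chroms,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "sv_config"
  cfg
}

#' @export
print.sv_config <- function(x, ...) {
  cat("sv_config:\n")
  cat(sprintf("  windows: %d bp, overlap %d bp; k = %d\n",
              x$segment_length, x$segment_overlap, x$kmer_size))
  cat(sprintf("  barcode selection: >= %d pairs, span > %d bp\n",
              x$min_barcode_pairs, x$min_barcode_span))
  cat(sprintf("  SV size window: [%d, %d] bp; breakpoint tolerance %d bp\n",
              x$min_sv_len, x$max_sv_len, x$match_distance))
  invisible(x)
}
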