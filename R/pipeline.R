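# End-to-end orchestration: read-map construction, window tiling, per-window
# barcode selection / gathering / assembly / realignment, genome-wide merge,
# VCF output, and a JSON run manifest. Windows are processed independently
# (results do not depend on processing order); a failure in one window is
# isolated and recorded.

#' Call structural variants from linked reads
#'
#' Runs the full pipeline: recruit badly aligned pairs into the barcode
#' read map, tile the reference into overlapping windows, and per window
#' select barcodes, gather reads (local + recruited + capped long reads in
#' hybrid mode), assemble, realign contigs, and extract indels; finally
#' left-align, deduplicate, sort, and write VCF.
#'
#' For BAMs under `in_memory_limit` bytes the whole file is scanned once and
#' windows are served from memory; larger inputs are streamed per window
#' through the BAM index.
#'
#' @param reference FASTA path or an `sv_reference`.
#' @param bam Indexed, coordinate-sorted linked-read BAM (BX tags).
#' @param long_bam Optional indexed long-read BAM; enables hybrid mode.
#' @param config An [sv_config()].
#' @param out_dir Output directory (created); receives `variants.vcf`,
#'   `manifest.json`, and per-window call caches.
#' @param resume Reuse per-window results already present in `out_dir`.
#' @param in_memory_limit BAM size (bytes) below which the in-memory path
#'   is used.
#' @return Object of class `sv_callset`: `calls` (data.frame), `vcf`,
#'   `manifest`, `config`.
#' @export
sv_call <- function(reference, bam, long_bam = NULL, config = sv_config(),
                    out_dir = tempfile("svweave_run_"), resume = FALSE,
                    in_memory_limit = 5e8) {
  t0 <- proc.time()[["elapsed"]]
  ref <- if (is.character(reference)) read_reference(reference) else reference
  if (is.null(config$primary_chroms)) config$primary_chroms <- names(ref$sequences)
  dir.create(file.path(out_dir, "segments"), recursive = TRUE, showWarnings = FALSE)

  in_memory <- is.character(bam) && file.size(bam) < in_memory_limit
  df_all <- NULL
  if (in_memory) {
    df_all <- .annotate_records(read_bam_records(bam))
  }
  t_scan <- proc.time()[["elapsed"]]
  read_map <- build_read_map(if (in_memory) df_all else bam, config)
  t_map <- proc.time()[["elapsed"]]

  ldf_all <- NULL
  hybrid <- !is.null(long_bam)
  if (hybrid && is.character(long_bam) && file.size(long_bam) < in_memory_limit)
    ldf_all <- .annotate_records(read_bam_records(long_bam))

  segments <- tile_segments(ref, config)
  # in-memory fast path: per-chromosome frames are coordinate-sorted, so a
  # window's reads (plus a pair-insert slack for mates) come from a slice
  chrom_frames <- NULL; chrom_lframes <- NULL
  .with_sort_key <- function(fr) {
    # placed-unmapped records have NA pos; fill forward from the previous
    # mapped record (file order is the BAM's coordinate order)
    s <- fr$pos
    if (anyNA(s)) {
      idx <- cummax(seq_along(s) * !is.na(s))
      s <- s[pmax(idx, 1L)]
      s[is.na(s)] <- 0L
    }
    fr$.spos <- s
    fr
  }
  if (in_memory) {
    mapped <- !is.na(df_all$chrom)
    chrom_frames <- lapply(split(df_all[mapped, , drop = FALSE],
                                 df_all$chrom[mapped]), .with_sort_key)
    if (!is.null(ldf_all)) {
      lm <- !is.na(ldf_all$chrom)
      chrom_lframes <- lapply(split(ldf_all[lm, , drop = FALSE],
                                    ldf_all$chrom[lm]), .with_sort_key)
    }
  }
  .slice <- function(fr, start, end, slack) {
    if (is.null(fr) || nrow(fr) == 0L) return(fr)
    lo <- findInterval(start - slack - 1L, fr$.spos) + 1L
    hi <- findInterval(end + slack, fr$.spos)
    if (hi < lo) return(fr[0, , drop = FALSE])
    fr[lo:hi, , drop = FALSE]
  }
  seg_status <- character(nrow(segments))
  seg_counts <- matrix(0L, nrow(segments), 4,
                       dimnames = list(NULL, c("reads", "barcodes", "contigs", "raw_calls")))
  call_list <- vector("list", nrow(segments))

  for (si in seq_len(nrow(segments))) {
    seg <- segments[si, ]
    cache <- file.path(out_dir, "segments",
                       paste0(gsub("[:/]", "_", seg$segment_id), ".json"))
    if (resume && file.exists(cache)) {
      cached <- jsonlite::fromJSON(cache)
      call_list[[si]] <- if (length(cached$calls)) as.data.frame(cached$calls) else NULL
      seg_status[si] <- "cached"
      next
    }
    seed_i <- (config$random_seed +
                 sum(utf8ToInt(seg$segment_id)) * 7919L) %% .Machine$integer.max
    set.seed(seed_i)
    res <- tryCatch({
      # mates of window pairs can sit a full deletion length away
      dfc <- if (in_memory) .slice(chrom_frames[[seg$chrom]], seg$start,
                                   seg$end, config$max_sv_len + 2000L) else bam
      ldfc <- if (!hybrid) NULL else if (!is.null(chrom_lframes))
        .slice(chrom_lframes[[seg$chrom]], seg$start, seg$end, 15000L) else long_bam
      gs <- gather_segment_reads(seg, dfc, read_map, long_bam = ldfc,
                                 config = config)
      nreads <- nrow(gs$local) + nrow(gs$recruited)
      if (nreads == 0L) {
        list(status = "empty", calls = NULL,
             counts = c(0L, length(gs$barcodes), 0L, 0L))
      } else {
        ctg <- suppressMessages(assemble_segment(gs, config))
        calls <- NULL
        if (nrow(ctg) > 0L) {
          percall <- lapply(seq_len(nrow(ctg)), function(ci) {
            al <- align_contig(ctg$seq[ci], gs, ref, config)
            if (length(al) == 0L) return(NULL)
            cc <- cigar_indels(al[[1L]], ref, config, contig_id = ctg$contig_id[ci],
                               segment_id = seg$segment_id)
            # keep only events fully inside the window proper: every event up
            # to the overlap length is fully contained in some window, and
            # pad-zone junctions belong to (and are called from) a neighbour
            span <- ifelse(cc$svtype == "DEL", cc$svlen, 0L)
            cc[cc$pos >= seg$start & (cc$pos + span) <= seg$end, , drop = FALSE]
          })
          percall <- Filter(Negate(is.null), percall)
          if (length(percall)) calls <- do.call(rbind, percall)
        }
        list(status = "assembled", calls = calls,
             counts = c(nreads, length(gs$barcodes), nrow(ctg),
                        if (is.null(calls)) 0L else nrow(calls)))
      }
    }, error = function(e) list(status = paste0("failed: ", conditionMessage(e)),
                                calls = NULL, counts = c(0L, 0L, 0L, 0L)))
    seg_status[si] <- res$status
    seg_counts[si, ] <- res$counts
    call_list[[si]] <- res$calls
    jsonlite::write_json(list(segment = seg$segment_id, status = res$status,
                              calls = if (is.null(res$calls)) list() else res$calls),
                         cache, auto_unbox = TRUE, digits = NA)
  }
  t_seg <- proc.time()[["elapsed"]]

  calls <- call_genome(call_list, ref)
  vcf <- file.path(out_dir, "variants.vcf")
  write_sv_vcf(calls, ref, vcf)
  failed <- grepl("^failed", seg_status)
  manifest <- list(
    inputs = list(bam = if (is.character(bam)) normalizePath(bam) else "<in-memory>",
                  long_bam = if (is.character(long_bam)) normalizePath(long_bam) else NULL,
                  hybrid = hybrid),
    config = config[setdiff(names(config), "primary_chroms")],
    n_segments = nrow(segments),
    segments = data.frame(segment_id = segments$segment_id, status = seg_status,
                          seg_counts, stringsAsFactors = FALSE),
    counters = list(read_map_pairs = read_map$total_pairs,
                    raw_calls = sum(seg_counts[, "raw_calls"]),
                    deduped_calls = nrow(calls),
                    failed_segments = sum(failed)),
    timings_sec = list(scan = t_scan - t0, read_map = t_map - t_scan,
                       segments = t_seg - t_map,
                       total = proc.time()[["elapsed"]] - t0)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (sum(failed) > 0.1 * nrow(segments))
    warning(sprintf("%d of %d segments failed", sum(failed), nrow(segments)))
  out <- list(calls = calls, vcf = vcf, manifest = manifest, config = config,
              out_dir = out_dir)
  class(out) <- "sv_callset"
  out
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("sv_callset: %d call(s) across %d segment(s)\n",
              nrow(x$calls), x$manifest$n_segments))
  if (nrow(x$calls) > 0L) print(table(x$calls$svtype))
  cat("VCF:", x$vcf, "\n")
  invisible(x)
}

#' @export
summary.sv_callset <- function(object, ...) {
  cat(sprintf("Calls: %d (%d DEL, %d INS)\n", nrow(object$calls),
              sum(object$calls$svtype == "DEL"), sum(object$calls$svtype == "INS")))
  if (nrow(object$calls) > 0L) {
    cat("Size classes:\n")
    print(table(.size_class(object$calls$svlen), object$calls$svtype))
  }
  st <- object$manifest$segments$status
  cat(sprintf("Segments: %d assembled, %d empty, %d failed\n",
              sum(st == "assembled"), sum(st == "empty"),
              sum(grepl("^failed", st))))
  invisible(object)
}
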