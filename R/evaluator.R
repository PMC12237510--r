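# Benchmarking a callset against a truth set with breakpoint tolerance:
# insertions and deletions are compared separately; a call matches a truth
# record on the same chromosome when their positions differ by at most
# `match_distance` bp and (optionally) their sizes agree to the
# `size_similarity` ratio. Matching is nearest-first greedy followed by
# augmenting-path repair, so the matching always has maximum cardinality
# while keeping the greedy's deterministic nearest-first character.

.size_class <- function(len) {
  cut(len, c(0, 100, 500, 1000, 5000, Inf),
      labels = c("50-99", "100-499", "500-999", "1000-4999", "5000+"),
      right = FALSE)
}

#' Match SV calls against a truth set
#'
#' @param calls,truth Data.frames with `chrom`, `pos`, `svtype`, `svlen`
#'   (e.g. from [read_sv_vcf()] or [sv_call()]). Both are restricted to the
#'   configured size window before matching.
#' @param config An [sv_config()]; uses `match_distance`, `size_similarity`,
#'   `min_sv_len`, `max_sv_len`.
#' @return List of class `sv_match`: `tp` (data.frame call_idx/truth_idx/
#'   distance), `fp_idx`, `fn_idx`, the filtered `calls`/`truth`, and
#'   `metrics` (see [sv_metrics()]).
#' @export
match_sv_calls <- function(calls, truth, config = sv_config()) {
  filt <- function(df) {
    df <- df[!is.na(df$svlen) & df$svlen >= config$min_sv_len &
               df$svlen <= config$max_sv_len, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  calls <- filt(calls); truth <- filt(truth)
  nc <- nrow(calls); nt <- nrow(truth)
  match_c <- rep(NA_integer_, nc)
  match_t <- rep(NA_integer_, nt)
  if (nc > 0L && nt > 0L) {
    # eligible pairs
    pairs <- list()
    for (i in seq_len(nc)) {
      ok <- truth$chrom == calls$chrom[i] & truth$svtype == calls$svtype[i] &
        abs(truth$pos - calls$pos[i]) <= config$match_distance
      if (config$size_similarity > 0) {
        ratio <- pmin(truth$svlen, calls$svlen[i]) /
          pmax(truth$svlen, calls$svlen[i])
        ok <- ok & ratio >= config$size_similarity
      }
      if (any(ok))
        pairs[[length(pairs) + 1L]] <- data.frame(
          c = i, t = which(ok), d = abs(truth$pos[which(ok)] - calls$pos[i]))
    }
    if (length(pairs)) {
      pairs <- do.call(rbind, pairs)
      pairs <- pairs[order(pairs$d, pairs$c, pairs$t), , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        ci <- pairs$c[r]; ti <- pairs$t[r]
        if (is.na(match_c[ci]) && is.na(match_t[ti])) {
          match_c[ci] <- ti; match_t[ti] <- ci
        }
      }
      # augmenting-path repair to maximum cardinality
      adj <- split(pairs$t, pairs$c)
      augment <- function(ci, seen) {
        for (ti in adj[[as.character(ci)]]) {
          if (seen[ti]) next
          seen[ti] <- TRUE
          owner <- match_t[ti]
          if (is.na(owner)) {
            match_c[ci] <<- ti; match_t[ti] <<- ci
            return(TRUE)
          }
          res <- augment(owner, seen)
          if (res) { match_c[ci] <<- ti; match_t[ti] <<- ci; return(TRUE) }
        }
        FALSE
      }
      for (ci in unique(pairs$c)) {
        if (is.na(match_c[ci])) augment(ci, rep(FALSE, nt))
      }
    }
  }
  tp <- data.frame(call_idx = which(!is.na(match_c)),
                   truth_idx = match_c[!is.na(match_c)])
  tp$distance <- if (nrow(tp)) abs(calls$pos[tp$call_idx] - truth$pos[tp$truth_idx]) else integer()
  out <- list(tp = tp, fp_idx = which(is.na(match_c)),
              fn_idx = which(is.na(match_t)),
              calls = calls, truth = truth)
  out$metrics <- sv_metrics(out)
  class(out) <- "sv_match"
  out
}

#' Precision / recall / F1 from a matching
#'
#' Overall and per-type rows, plus per-size-class counts. When the callset
#' is empty, precision is undefined and reported as 1 with
#' `precision_defined = FALSE`; recall is 0.
#'
#' @param result An `sv_match` (the `metrics` element is recomputed).
#' @return Data.frame with rows `all`, `DEL`, `INS` and columns `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`, `precision_defined`; attribute
#'   `size_classes` holds the per-size-class TP/FN table.
#' @export
sv_metrics <- function(result) {
  mk <- function(tp, fp, fn) {
    pdef <- (tp + fp) > 0L
    prec <- if (pdef) tp / (tp + fp) else 1.0
    rec <- if (tp + fn > 0L) tp / (tp + fn) else 1.0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
               f1 = f1, precision_defined = pdef)
  }
  rows <- list()
  types_c <- result$calls$svtype
  types_t <- result$truth$svtype
  rows[["all"]] <- mk(nrow(result$tp), length(result$fp_idx), length(result$fn_idx))
  for (ty in c("DEL", "INS")) {
    tp <- sum(types_c[result$tp$call_idx] == ty)
    fp <- sum(types_c[result$fp_idx] == ty)
    fn <- sum(types_t[result$fn_idx] == ty)
    rows[[ty]] <- mk(tp, fp, fn)
  }
  out <- do.call(rbind, rows)
  out <- cbind(set = names(rows), out)
  rownames(out) <- NULL
  if (nrow(result$truth) > 0L) {
    cls <- .size_class(result$truth$svlen)
    hit <- seq_len(nrow(result$truth)) %in% result$tp$truth_idx
    attr(out, "size_classes") <- table(class = cls, matched = hit)
  }
  out
}

#' @export
print.sv_match <- function(x, ...) {
  cat("sv_match:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Benchmark one VCF against another
#'
#' Convenience wrapper: reads both VCFs, matches, and optionally writes a
#' TSV report.
#'
#' @param calls_vcf,truth_vcf VCF paths.
#' @param config An [sv_config()].
#' @param report Optional TSV path for the metrics table.
#' @return An `sv_match`.
#' @export
evaluate_vcf <- function(calls_vcf, truth_vcf, config = sv_config(),
                         report = NULL) {
  res <- match_sv_calls(read_sv_vcf(calls_vcf), read_sv_vcf(truth_vcf), config)
  if (!is.null(report))
    utils::write.table(res$metrics, report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
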