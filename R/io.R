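#' Read a reference genome from FASTA
#'
#' Sequence names are taken up to the first whitespace; sequences are
#' uppercased.
#'
#' @param path FASTA file (plain or gzipped).
#' @return A list of class `sv_reference` with elements `sequences` (named
#'   character vector) and `lengths` (named integer vector).
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) stop("duplicate sequence names in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- nms
  sv_reference(seqs)
}

#' Construct a reference object from named sequences
#'
#' @param sequences Named character vector of chromosome sequences.
#' @return An `sv_reference` list.
#' @export
sv_reference <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  sequences <- toupper(sequences)
  out <- list(sequences = sequences,
              lengths = setNames(nchar(sequences), names(sequences)))
  class(out) <- "sv_reference"
  out
}

#' Write a reference object to FASTA
#' @param reference An `sv_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# flag-bit helpers (SAM flag field)
.fl <- function(flag, bit) bitwAnd(as.integer(flag), bit) > 0L

#' Read alignment records from a BAM file
#'
#' Returns one row per record with the BX tag mapped to `barcode` and the AM
#' tag to `am`. Positions are 0-based. With a `region`, only records whose
#' alignment overlaps the region are returned (in coordinate order); without
#' one, the whole file including unmapped records is read.
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @param region Optional `"chrom:start-end"` string (1-based, inclusive) or
#'   a `GRanges` of length 1.
#' @return A data.frame of records; attribute `n_skipped` counts mapped
#'   records lacking a CIGAR (skipped with a warning).
#' @export
read_bam_records <- function(bam_path, region = NULL) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for: ", bam_path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "seq", "qual")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what, tag = c("BX", "AM"))
  } else {
    gr <- .parse_region(region)
    param <- Rsamtools::ScanBamParam(what = what, tag = c("BX", "AM"), which = gr)
  }
  res <- Rsamtools::scanBam(bam_path, param = param)
  b <- if (length(res) == 1L) res[[1L]] else {
    nm <- names(res[[1L]])
    out <- lapply(nm, function(f) do.call(c, lapply(res, `[[`, f)))
    names(out) <- nm
    out$tag <- list(BX = do.call(c, lapply(res, function(x) x$tag$BX)),
                    AM = do.call(c, lapply(res, function(x) x$tag$AM)))
    out
  }
  .records_from_scan(b)
}

.parse_region <- function(region) {
  if (methods::is(region, "GRanges")) return(region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must look like 'chrom:start-end'")
  GenomicRanges::GRanges(m[2L], IRanges::IRanges(as.integer(m[3L]), as.integer(m[4L])))
}

.records_from_scan <- function(b) {
  n <- length(b$qname)
  df <- data.frame(
    qname = b$qname,
    flag = as.integer(b$flag),
    chrom = as.character(b$rname),
    pos = as.integer(b$pos) - 1L,
    mapq = as.integer(b$mapq),
    cigar = as.character(b$cigar),
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    stringsAsFactors = FALSE
  )
  df$barcode <- if (!is.null(b$tag$BX)) as.character(b$tag$BX) else rep(NA_character_, n)
  df$am <- if (!is.null(b$tag$AM)) as.integer(b$tag$AM) else rep(NA_integer_, n)
  df$mchrom <- as.character(b$mrnm)
  df$mpos <- as.integer(b$mpos) - 1L
  df$is_mapped <- !.fl(df$flag, 4L)
  df$mate_mapped <- !.fl(df$flag, 8L)
  df$first_in_pair <- .fl(df$flag, 64L)
  bad <- df$is_mapped & (is.na(df$cigar) | df$cigar == "*")
  if (any(bad)) {
    warning(sum(bad), " mapped record(s) without CIGAR skipped")
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "n_skipped") <- sum(bad)
  df
}

# derived per-record quantities used by filtering/selection
.annotate_records <- function(df) {
  if (!is.null(df$minq)) return(df)
  df$minq <- .cpp_min_phred(df$qual, 33L)
  st <- .cpp_cigar_stats(df$cigar)
  seqlen <- nchar(df$seq)
  df$ref_end <- ifelse(df$is_mapped, df$pos + st[, "ref_width"], NA_real_)
  df$clip_frac <- ifelse(df$is_mapped & seqlen > 0, st[, "soft_clipped"] / seqlen, 0)
  df$primary <- !.fl(df$flag, 256L) & !.fl(df$flag, 2048L) & !.fl(df$flag, 1024L)
  df
}

#' Write structural variant calls to VCF 4.2
#'
#' Sequence-resolved REF/ALT alleles, INFO keys SVTYPE, SVLEN (negative for
#' deletions) and END, genotype emitted as given (default `./.`). Records
#' are sorted by chromosome (reference order) and position.
#'
#' @param calls Data.frame with columns `chrom`, `pos` (1-based position of
#'   the base before the event), `svtype` ("INS"/"DEL"), `svlen`, `ref`,
#'   `alt`; optional `gt`.
#' @param reference An `sv_reference`; every call's alleles are validated
#'   against it.
#' @param path Output `.vcf` path.
#' @param sample_name Name for the single sample column.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, reference, path, sample_name = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svweave",
    sprintf("##contig=<ID=%s,length=%d>", names(reference$lengths), reference$lengths),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the event; negative for deletions\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  if (is.null(calls) || nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "pos", "svtype", "svlen", "ref", "alt") %in% names(calls)))
  miss <- setdiff(unique(calls$chrom), names(reference$sequences))
  if (length(miss)) stop("call chromosome(s) absent from reference: ",
                         paste(miss, collapse = ", "))
  obs <- substr(rep(reference$sequences[calls$chrom], 1L),
                calls$pos, calls$pos + nchar(calls$ref) - 1L)
  bad <- which(obs != calls$ref)
  if (length(bad))
    stop(sprintf("REF allele mismatch at %s:%d (%s, svlen %d)",
                 calls$chrom[bad[1L]], calls$pos[bad[1L]],
                 calls$svtype[bad[1L]], calls$svlen[bad[1L]]))
  ord <- order(match(calls$chrom, names(reference$sequences)), calls$pos,
               calls$svtype, calls$svlen)
  calls <- calls[ord, , drop = FALSE]
  svlen_signed <- ifelse(calls$svtype == "DEL", -calls$svlen, calls$svlen)
  end <- ifelse(calls$svtype == "DEL", calls$pos + calls$svlen, calls$pos)
  gt <- if (!is.null(calls$gt)) calls$gt else rep("./.", nrow(calls))
  body <- paste(calls$chrom, calls$pos,
                if (!is.null(calls$id)) calls$id else ".",
                calls$ref, calls$alt, ".", "PASS",
                sprintf("SVTYPE=%s;SVLEN=%d;END=%d", calls$svtype, svlen_signed, end),
                "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read structural variant calls from a VCF
#'
#' Parses with `VariantAnnotation::readVcf`. SVTYPE/SVLEN are taken from
#' INFO when present, otherwise inferred from allele lengths.
#'
#' @param path VCF file.
#' @return Data.frame with `chrom`, `pos`, `svtype`, `svlen`, `ref`, `alt`,
#'   and `gt` (NA when absent).
#' @export
read_sv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  empty <- data.frame(chrom = character(), pos = integer(), svtype = character(),
                      svlen = integer(), ref = character(), alt = character(),
                      gt = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a[1L]), character(1L))
  info <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE) else rep(NA_character_, n)
  svlen <- if ("SVLEN" %in% names(info)) {
    sl <- info$SVLEN
    if (is.list(sl) || methods::is(sl, "List"))
      vapply(sl, function(x) if (length(x)) as.integer(x[1L]) else NA_integer_, integer(1L))
    else as.integer(sl)
  } else rep(NA_integer_, n)
  infer <- is.na(svtype)
  svtype[infer] <- ifelse(nchar(alt[infer]) > nchar(ref[infer]), "INS", "DEL")
  svlen[is.na(svlen)] <- (nchar(alt) - nchar(ref))[is.na(svlen)]
  gt <- tryCatch({
    g <- VariantAnnotation::geno(vcf)
    if ("GT" %in% names(g)) as.character(g$GT[, 1L]) else rep(NA_character_, n)
  }, error = function(e) rep(NA_character_, n))
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = BiocGenerics::start(rr),
             svtype = svtype, svlen = abs(svlen),
             ref = ref, alt = alt, gt = gt,
             stringsAsFactors = FALSE)
}

#' Write alignment records to an indexed BAM
#'
#' Emits SAM text (coordinate-sorted; records without a placement go last)
#' and converts with `Rsamtools::asBam`. Used by the simulator and by test
#' fixtures; BX/AM tags are written when present.
#'
#' @param records Data.frame with columns `qname`, `flag`, `chrom` (NA when
#'   unplaced), `pos` (0-based, NA when unplaced), `mapq`, `cigar`,
#'   `mchrom`, `mpos`, `seq`, `qual`; optional `barcode`, `am`.
#' @param reference An `sv_reference` providing the header contigs.
#' @param path Output path; `.bam` appended if missing.
#' @return Path of the indexed BAM.
#' @export
write_reads_bam <- function(records, reference, path) {
  path <- sub("\\.bam$", "", path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lens <- reference$lengths
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  df <- records
  placed <- !is.na(df$chrom) & !is.na(df$pos)
  ord <- order(!placed, match(df$chrom, names(lens)), df$pos, df$qname, method = "radix")
  df <- df[ord, , drop = FALSE]
  placed <- placed[ord]
  rname <- ifelse(placed, df$chrom, "*")
  pos1 <- ifelse(placed, df$pos + 1L, 0L)
  cig <- ifelse(!is.na(df$cigar) & df$cigar != "", df$cigar, "*")
  mplaced <- !is.na(df$mchrom) & !is.na(df$mpos)
  rnext <- ifelse(mplaced, ifelse(df$mchrom == df$chrom & placed, "=", df$mchrom), "*")
  pnext <- ifelse(mplaced, df$mpos + 1L, 0L)
  tlen <- if (!is.null(df$tlen)) df$tlen else 0L
  tags <- character(nrow(df))
  if (!is.null(df$barcode)) {
    hasbx <- !is.na(df$barcode)
    tags[hasbx] <- paste0("\tBX:Z:", df$barcode[hasbx])
  }
  if (!is.null(df$am)) {
    hasam <- !is.na(df$am)
    tags[hasam] <- paste0(tags[hasam], "\tAM:i:", df$am[hasam])
  }
  sam <- paste0(path, ".sam")
  writeLines(hdr, sam)
  body <- data.frame(q = df$qname, f = df$flag, r = rname, p = pos1,
                     mq = ifelse(placed, df$mapq, 0L), c = cig, rn = rnext,
                     pn = pnext, tl = tlen, s = df$seq, ql = paste0(df$qual, tags),
                     stringsAsFactors = FALSE)
  data.table::fwrite(body, sam, sep = "\t", quote = FALSE, col.names = FALSE,
                     append = TRUE)
  bam <- Rsamtools::asBam(sam, destination = path, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
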