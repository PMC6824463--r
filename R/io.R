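## Annotation files use the conventions of their formats (bedGraph 0-based
## half-open, GFF3/origin tables 1-based closed); inside the package all
## bp coordinates are 1-based closed and tracks are addressed by bin index.

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         bedgraph = "bedGraph", bdg = "bedGraph",
         gff = "gff3", gff3 = "gff3", bed = "bed",
         tsv = "tsv", txt = "tsv",
         stop("cannot guess format of '", path, "'"))
}

#' Read a binned signal track
#'
#' Reads a bedGraph (or an equivalent four-column TSV: chrom, start, end,
#' value; 0-based half-open) and rebins the intervals onto a fixed grid by
#' coverage-weighted mean. Bins not covered by any interval are missing.
#' Overlapping intervals are rejected.
#'
#' @param path file path.
#' @param binSize target bin size (bp).
#' @param seqlengths optional named chromosome lengths; inferred from the
#'   largest end coordinate per chromosome when omitted. Coordinates past a
#'   declared chromosome end are an error.
#' @param format "auto" (by extension), "bedGraph" or "tsv".
#' @param label track label.
#' @return A \linkS4class{GenomicTrack}.
#' @export
readTrack <- function(path, binSize = 1000L, seqlengths = NULL,
                      format = c("auto", "bedGraph", "tsv"), label = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (format == "auto") format <- guessFormat(path)
  if (format == "bedGraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     value = gr$score)
  } else {
    df <- utils::read.delim(path, header = TRUE,
                            colClasses = c("character", "numeric",
                                           "numeric", "numeric"))
    names(df) <- c("chrom", "start", "end", "value")
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$end <= df$start | !is.finite(df$value))
  if (length(bad))
    stop("malformed interval at data line ", bad[1], " of '", path, "'")
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(df$end, df$chrom), max, 0)
  } else {
    miss <- setdiff(unique(df$chrom), names(seqlengths))
    if (length(miss))
      stop("chromosome '", miss[1], "' absent from seqlengths")
    over <- df$end > seqlengths[df$chrom]
    if (any(over))
      stop("interval past end of chromosome '",
           df$chrom[over][1], "' at data line ", which(over)[1])
  }
  vals <- lapply(names(seqlengths), function(chr) {
    n <- as.integer(ceiling(seqlengths[[chr]] / binSize))
    sumv <- numeric(n)
    cov <- numeric(n)
    dd <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(dd)) {
      ir <- IRanges::IRanges(start = dd$start + 1L, end = dd$end)
      if (sum(IRanges::width(IRanges::reduce(ir))) <
          sum(IRanges::width(ir)))
        stop("overlapping intervals on chromosome '", chr, "'")
      bins <- IRanges::IRanges(start = (seq_len(n) - 1L) * binSize + 1L,
                               width = binSize)
      ov <- IRanges::findOverlaps(bins, ir)
      if (length(ov)) {
        w <- IRanges::width(IRanges::pintersect(
          bins[S4Vectors::queryHits(ov)], ir[S4Vectors::subjectHits(ov)]))
        sumv <- sumv + as.numeric(tapply(
          w * dd$value[S4Vectors::subjectHits(ov)],
          factor(S4Vectors::queryHits(ov), levels = seq_len(n)), sum,
          default = 0))
        cov <- cov + as.numeric(tapply(
          w, factor(S4Vectors::queryHits(ov), levels = seq_len(n)), sum,
          default = 0))
      }
    }
    out <- sumv / cov
    out[cov == 0] <- NA_real_
    out
  })
  names(vals) <- names(seqlengths)
  GenomicTrack(vals, binSize = binSize, seqlengths = seqlengths,
               label = label)
}

#' Write a track as bedGraph
#'
#' Missing bins are omitted (bedGraph is sparse); coordinates are 0-based
#' half-open. \code{readTrack(writeTrack(x))} is the identity on
#' grid-aligned input.
#'
#' @param track a \linkS4class{GenomicTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrack <- function(track, path) {
  df <- as.data.frame(track)
  df <- df[!is.na(df$value), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end),
                   vapply(df$value, function(v)
                     format(v, digits = 15, scientific = FALSE), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3: only features of type "gene" are kept (a warning is raised if none
#' exist); BED: every record. Strand is required on every returned record.
#' Coordinates are returned 1-based closed.
#'
#' @param path file path (.gff/.gff3 or .bed).
#' @return data.frame with id, chrom, start, end, strand.
#' @export
readGenes <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  fmt <- guessFormat(path)
  gr <- rtracklayer::import(path, format = if (fmt == "gff3") "gff3"
                            else "bed")
  if (fmt == "gff3") {
    keep <- as.character(gr$type) == "gene"
    gr <- gr[keep]
    if (!length(gr)) {
      warning("no 'gene' features in '", path, "'")
      return(data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character()))
    }
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  } else {
    ids <- gr$name
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("record ", which(strand == "*")[1], " in '", path,
         "' is missing a strand")
  if (is.null(ids) || anyNA(ids))
    ids <- sprintf("gene%05d", seq_along(gr))
  data.frame(id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = strand)
}

#' Read / write an origin annotation table
#'
#' Tab-separated with header columns id, chrom, pos, t_rep, status
#' (OriDB-like; pos 1-based).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readOrigins <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.delim(path, header = TRUE)
  need <- c("id", "chrom", "pos", "t_rep", "status")
  if (!all(need %in% names(df)))
    stop("origin table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$pos)) || any(!is.finite(df$t_rep)))
    stop("non-numeric pos or t_rep in '", path, "'")
  df[, need]
}

#' @rdname readOrigins
#' @param origins data.frame to write.
#' @export
writeOrigins <- function(origins, path) {
  utils::write.table(origins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cyc2008-style complex catalog
#'
#' @param path TSV with header columns gene, complex.
#' @return data.frame with gene, complex.
#' @export
readComplexCatalog <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.delim(path, header = TRUE)
  if (!all(c("gene", "complex") %in% names(df)))
    stop("catalog must have columns gene, complex")
  df[, c("gene", "complex")]
}

#' Read a long-format growth-curve table
#'
#' @param path TSV with header columns (at least) gene, background,
#'   replicate, time_days, density.
#' @return data.frame.
#' @export
readGrowthCurves <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.delim(path, header = TRUE)
  need <- c("gene", "background", "replicate", "time_days", "density")
  if (!all(need %in% names(df)))
    stop("growth table must have columns: ", paste(need, collapse = ", "))
  if (any(df$density <= 0)) stop("densities must be positive")
  df
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
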