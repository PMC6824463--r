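#' Normalize a ChIP track to its control
#'
#' Scales IP and control to equal genome-wide totals, then divides bin by
#' bin with a pseudocount: (ip + pseudocount) / (control + pseudocount).
#' Bins whose control count falls below \code{controlFloor} are flagged
#' missing rather than divided.
#'
#' @param ip,control \linkS4class{GenomicTrack}s with identical binning
#'   (e.g. gamma-H2A IP and unmodified H2A, or a GFP IP and its input).
#' @param pseudocount added to both tracks before division.
#' @param controlFloor minimum scaled control signal for a bin to be kept.
#' @return ratio \linkS4class{GenomicTrack}.
#' @export
normalizeChip <- function(ip, control, pseudocount = 1,
                          controlFloor = 1e-8) {
  stopIfBinningMismatch(ip, control)
  totI <- trackSum(ip)
  totC <- trackSum(control)
  if (totC <= 0) stop("control track is all zero")
  if (totI <= 0) stop("IP track is all zero")
  sc <- totC / totI
  trackBinop(ip, control, function(i, c) {
    out <- (i * sc + pseudocount) / (c + pseudocount)
    out[!is.na(c) & c < controlFloor] <- NA_real_
    out
  }, label = "ChIP ratio")
}

#' Normalize a ChIP ratio by the local amount of replication
#'
#' Divides the control-normalized damage signal at each locus by the amount
#' of replication there, so loci that are damaged more than their
#' replication explains stand out. The amount of replication is the
#' smoothed copy number minus 1; bins replicated in fewer than
#' \code{minReplication} of cells are flagged missing rather than divided
#' (never producing infinities).
#'
#' @param chipRatio track from \code{\link{normalizeChip}}.
#' @param profile a \linkS4class{ReplicationProfile} with identical binning.
#' @param minReplication replication floor in fraction-of-cells units
#'   (default 0.05, > 0).
#' @return replication-normalized \linkS4class{GenomicTrack}.
#' @export
normalizeByReplication <- function(chipRatio, profile,
                                   minReplication = 0.05) {
  if (minReplication <= 0) stop("minReplication must be > 0")
  sm <- profile@smoothed
  stopIfBinningMismatch(chipRatio, sm)
  trackBinop(chipRatio, sm, function(r, s) {
    amt <- s - 1
    out <- r / amt
    out[is.na(amt) | amt < minReplication] <- NA_real_
    out
  }, label = "replication-normalized damage")
}

#' Origin-centred metaprofile
#'
#' Extracts a +/- \code{halfWindow} window of the track around every origin
#' (aligned on the origin bin), averages position-wise across origins
#' ignoring missing bins, and reports the average for all origins and for
#' the early (t_rep < trepCutoff; equality counts as early) and late
#' subsets. Windows running past a chromosome end contribute only where
#' defined.
#'
#' @param track a \linkS4class{GenomicTrack}.
#' @param origins data.frame with id, chrom, pos, t_rep, or a
#'   \linkS4class{GenomeModel}.
#' @param halfWindow bp, a multiple of the bin size.
#' @param trepCutoff minutes (default 27.5).
#' @return data.frame with columns offset_bp, mean_all, n_all, mean_early,
#'   n_early, mean_late, n_late. Empty subsets give NaN means and n = 0.
#' @export
metaOriginProfile <- function(track, origins, halfWindow = 20000,
                              trepCutoff = 27.5) {
  if (is(origins, "GenomeModel")) origins <- origins(origins)
  bs <- track@binSize
  if (halfWindow %% bs != 0)
    stop("halfWindow must be a multiple of the bin size")
  hw <- halfWindow %/% bs
  offs <- (-hw):hw
  sets <- list(all = seq_len(nrow(origins)),
               early = which(origins$t_rep <= trepCutoff),
               late = which(origins$t_rep > trepCutoff))
  sums <- counts <- lapply(sets, function(s) numeric(length(offs)))
  for (i in seq_len(nrow(origins))) {
    v <- track@values[[origins$chrom[i]]]
    if (is.null(v))
      stop(sprintf("origin '%s' lies on unknown chromosome '%s'",
                   origins$id[i], origins$chrom[i]))
    b <- binIndexOf(track, origins$pos[i]) + offs
    ok <- b >= 1 & b <= length(v)
    vv <- rep(NA_real_, length(offs))
    vv[ok] <- v[b[ok]]
    use <- !is.na(vv)
    for (nm in names(sets)) {
      if (!(i %in% sets[[nm]])) next
      sums[[nm]][use] <- sums[[nm]][use] + vv[use]
      counts[[nm]][use] <- counts[[nm]][use] + 1
    }
  }
  data.frame(offset_bp = offs * bs,
             mean_all = sums$all / counts$all, n_all = counts$all,
             mean_early = sums$early / counts$early,
             n_early = counts$early,
             mean_late = sums$late / counts$late, n_late = counts$late)
}

#' Classify the gene-pair orientation context of origins
#'
#' Finds, for each origin, the nearest gene lying wholly to its left and
#' wholly to its right (within \code{maxScan}). Replication proceeds
#' outward from the origin, so the left-flanking gene meets its fork
#' head-on iff it is transcribed toward the origin (strand "+" for the left
#' gene, "-" for the right gene). The pair is \emph{convergent} when both
#' flanking genes are head-on (the genes are transcribed toward each other
#' across the origin); any other complete pair (codirectional or divergent)
#' is \emph{nonconvergent}. Origins inside a gene body, or lacking a
#' flanking gene within range, are \emph{unclassified}.
#'
#' @param origins data.frame with id, chrom, pos (and t_rep, carried
#'   through), or a \linkS4class{GenomeModel}.
#' @param genes data.frame with id, chrom, start, end, strand (1-based
#'   closed).
#' @param maxScan bp; how far to look for a flanking gene (default 20 kb).
#' @return data.frame with columns id, chrom, pos, t_rep, left_gene,
#'   right_gene, left_strand, right_strand, pair_class.
#' @examples
#' ori <- data.frame(id = "o1", chrom = "chrI", pos = 10000, t_rep = 20)
#' gn <- data.frame(id = c("gL", "gR"), chrom = "chrI",
#'                  start = c(6000, 12000), end = c(8000, 14000),
#'                  strand = c("+", "-"))
#' classifyOriginGeneContext(ori, gn)$pair_class   # convergent
#' @export
classifyOriginGeneContext <- function(origins, genes, maxScan = 20000) {
  if (is(origins, "GenomeModel")) {
    genes <- origins@genes
    origins <- origins@origins
  }
  n <- nrow(origins)
  out <- data.frame(
    id = origins$id, chrom = origins$chrom, pos = origins$pos,
    t_rep = if ("t_rep" %in% names(origins)) origins$t_rep else NA_real_,
    left_gene = NA_character_, right_gene = NA_character_,
    left_strand = NA_character_, right_strand = NA_character_,
    pair_class = "unclassified")
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == origins$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    pos <- origins$pos[i]
    if (any(g$start <= pos & g$end >= pos)) next   # inside a gene body
    left <- g[g$end < pos & g$end >= pos - maxScan, , drop = FALSE]
    right <- g[g$start > pos & g$start <= pos + maxScan, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    L <- left[which.max(left$end), ]
    R <- right[which.min(right$start), ]
    out$left_gene[i] <- L$id
    out$right_gene[i] <- R$id
    out$left_strand[i] <- L$strand
    out$right_strand[i] <- R$strand
    out$pair_class[i] <-
      if (L$strand == "+" && R$strand == "-") "convergent" else
        "nonconvergent"
  }
  out
}

#' Per-origin damage enrichment binned by replication timing
#'
#' Computes, per origin, the mean replication-normalized damage over
#' +/- \code{window} bp around the origin, then tabulates mean and SEM of
#' that enrichment in T_rep bins, separately for convergent and
#' nonconvergent gene-pair contexts. Unclassified origins are excluded;
#' empty (trep bin x class) combinations are dropped with a warning.
#'
#' @param normalized track from \code{\link{normalizeByReplication}}.
#' @param contexts data.frame from \code{\link{classifyOriginGeneContext}}
#'   (must carry t_rep).
#' @param binEdges minutes; breaks of the T_rep bins (left-closed,
#'   right-open except the last). Default \code{seq(15, 40, by = 5)}.
#' @param window bp; per-origin aggregation half-window (default 2000).
#' @return data.frame with columns trep_lo, trep_hi, trep_mid, pair_class,
#'   n_origins, mean_enrichment, sem. The per-origin enrichments are
#'   attached as attribute \code{"per_origin"}.
#' @export
binnedDamageByTrep <- function(normalized, contexts,
                               binEdges = seq(15, 40, by = 5),
                               window = 2000) {
  if (length(binEdges) < 2) stop("need >= 2 bin edges")
  if (any(diff(binEdges) <= 0)) stop("binEdges must be increasing")
  ctx <- contexts[contexts$pair_class != "unclassified", , drop = FALSE]
  hw <- max(1L, as.integer(window %/% normalized@binSize))
  enr <- vapply(seq_len(nrow(ctx)), function(i) {
    v <- normalized@values[[ctx$chrom[i]]]
    b <- binIndexOf(normalized, ctx$pos[i]) + (-hw):hw
    b <- b[b >= 1 & b <= length(v)]
    mean(v[b], na.rm = TRUE)
  }, 0)
  ctx$enrichment <- enr
  ctx$trep_bin <- cut(ctx$t_rep, breaks = binEdges, right = FALSE,
                      include.lowest = TRUE)
  rows <- list()
  dropped <- 0L
  for (cls in c("convergent", "nonconvergent")) {
    for (lev in levels(ctx$trep_bin)) {
      sel <- ctx$pair_class == cls & !is.na(ctx$trep_bin) &
        ctx$trep_bin == lev & is.finite(ctx$enrichment)
      k <- sum(sel)
      if (k == 0L) {
        dropped <- dropped + 1L
        next
      }
      e <- ctx$enrichment[sel]
      lo <- binEdges[match(lev, levels(ctx$trep_bin))]
      hi <- binEdges[match(lev, levels(ctx$trep_bin)) + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        trep_lo = lo, trep_hi = hi, trep_mid = (lo + hi) / 2,
        pair_class = cls, n_origins = k, mean_enrichment = mean(e),
        sem = if (k > 1) stats::sd(e) / sqrt(k) else NA_real_)
    }
  }
  if (dropped > 0L)
    warning(dropped, " empty (T_rep bin x class) combination(s) dropped")
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trep_lo = numeric(), trep_hi = numeric(),
               trep_mid = numeric(), pair_class = character(),
               n_origins = integer(), mean_enrichment = numeric(),
               sem = numeric())
  attr(res, "per_origin") <- ctx
  res
}
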