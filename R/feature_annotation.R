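# Peak-to-gene feature annotation with the promoter > exon > intron >
# downstream > intergenic priority scheme, per-gene accessibility calls, and
# TSS-centred metagene profiles.

.FEATURE_PRIORITY <- c("promoter", "exon", "intron", "downstream", "intergenic")

#' Promoter window of a gene
#'
#' The promoter is the `upstream` bases immediately 5' of the TSS on the
#' gene's strand (default 1500 bp), returned as a 0-based half-open interval.
#' On the plus strand this is `[tss - upstream, tss)`; on the minus strand
#' the mirror `[tss + 1, tss + 1 + upstream)`.
#'
#' @param gene one row of a `gene_models` table.
#' @param upstream window size in bases (> 0).
#' @param chrom_length optional sequence length; when given, the window is
#'   clipped to `[0, chrom_length)`.
#' @return integer vector `c(start, end)`, 0-based half-open. May be empty
#'   (`start == end`) after clipping at a sequence edge.
#' @export
promoter_interval <- function(gene, upstream = 1500L, chrom_length = NULL) {
  if (upstream <= 0) stop_cellsig("upstream must be > 0")
  tss <- gene$tss
  iv <- if (gene$strand == "+") c(tss - upstream, tss)
        else c(tss + 1L, tss + 1L + upstream)
  .clip_interval(iv, chrom_length)
}

#' Downstream window of a gene
#'
#' The `len` bases immediately 3' of the gene end (TTS), away from the gene
#' body: `[tts + 1, tts + 1 + len)` on the plus strand, `[tts - len, tts)` on
#' the minus strand.
#'
#' @param gene one row of a `gene_models` table.
#' @param len window size in bases (> 0), default 3000.
#' @param chrom_length optional sequence length for clipping.
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
downstream_interval <- function(gene, len = 3000L, chrom_length = NULL) {
  if (len <= 0) stop_cellsig("downstream length must be > 0")
  tts <- gene$tts
  iv <- if (gene$strand == "+") c(tts + 1L, tts + 1L + len)
        else c(tts - len, tts)
  .clip_interval(iv, chrom_length)
}

.clip_interval <- function(iv, chrom_length) {
  iv[1] <- max(iv[1], 0L)
  if (!is.null(chrom_length)) iv[2] <- min(iv[2], chrom_length)
  iv[2] <- max(iv[2], iv[1])
  as.integer(iv)
}

# enumerate every (gene, feature) interval for one gene as a data.frame
.gene_feature_intervals <- function(genes, upstream = 1500L, downstream = 3000L,
                                    chrom_lengths = NULL) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cl <- if (!is.null(chrom_lengths)) chrom_lengths[[g$chrom]] else NULL
    ex <- g$exons[[1]]
    prom <- promoter_interval(g, upstream, cl)
    down <- downstream_interval(g, downstream, cl)
    # introns = gaps between consecutive exons
    intr <- if (nrow(ex) > 1L)
      cbind(start = ex[-nrow(ex), 2], end = ex[-1L, 1]) else
      cbind(start = integer(), end = integer())
    part <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom,
      start = c(prom[1], ex[, 1], intr[, 1], down[1]),
      end = c(prom[2], ex[, 2], intr[, 2], down[2]),
      feature = c("promoter", rep("exon", nrow(ex)),
                  rep("intron", nrow(intr)), "downstream"),
      tss = g$tss, stringsAsFactors = FALSE)
    rows[[i]] <- part[part$start < part$end, , drop = FALSE]
  }
  do.call(rbind, rows)
}

#' Assign peaks to genomic features by priority
#'
#' Each peak is assigned the single highest-priority feature it overlaps by at
#' least one base, in the order promoter > exon > intron > downstream >
#' intergenic. Ties within one priority class are broken by the smallest
#' distance from the peak midpoint to the candidate gene's TSS, then by
#' lexicographic gene id. Peaks overlapping no annotated feature are
#' intergenic with `gene_id = NA`.
#'
#' @param peaks a `peak_set`, or a data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes a `gene_models` table.
#' @param upstream promoter size in bases (default 1500).
#' @param downstream downstream-window size in bases (default 3000).
#' @param chrom_lengths optional named vector of sequence lengths used to clip
#'   windows at sequence edges.
#' @return data.frame with one row per peak: `chrom`, `start`, `end`,
#'   `feature`, `gene_id`.
#' @export
assign_features <- function(peaks, genes, upstream = 1500L, downstream = 3000L,
                            chrom_lengths = NULL) {
  pk <- if (inherits(peaks, "peak_set")) peaks$peaks else as.data.frame(peaks)
  out <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                    feature = "intergenic", gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(pk) == 0L || nrow(genes) == 0L) return(out)
  feat <- .gene_feature_intervals(genes, upstream, downstream, chrom_lengths)
  feat$prio <- match(feat$feature, .FEATURE_PRIORITY)
  for (ch in unique(pk$chrom)) {
    fi <- feat[feat$chrom == ch, , drop = FALSE]
    pi <- which(pk$chrom == ch)
    if (nrow(fi) == 0L || length(pi) == 0L) next
    hits <- IRanges::findOverlaps(.as_iranges(pk$start[pi], pk$end[pi]),
                                  .as_iranges(fi$start, fi$end))
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    mid <- (pk$start[pi] + pk$end[pi]) / 2
    ord <- order(q, fi$prio[s], abs(mid[q] - fi$tss[s]), fi$gene_id[s])
    first <- ord[!duplicated(q[ord])]
    out$feature[pi[q[first]]] <- fi$feature[s[first]]
    out$gene_id[pi[q[first]]] <- fi$gene_id[s[first]]
  }
  out
}

#' Call per-gene chromatin accessibility from peak overlap
#'
#' A gene is called accessible in a condition when at least one peak overlaps
#' the chosen gene region by one base or more. Replicate peak sets for the
#' same condition are merged by interval union before calling.
#'
#' @param peaks a `peak_set` or a list of replicate `peak_set`s to merge.
#' @param genes a `gene_models` table.
#' @param region which region defines accessibility: `"promoter"` (default,
#'   the 1500 bp upstream window), `"gene_body"` (`[start, end)`), or
#'   `"promoter_or_body"`.
#' @param condition condition label for the calls; defaults to the peak set's.
#' @param upstream promoter size in bases.
#' @param chrom_lengths optional named vector of sequence lengths.
#' @return data.frame with columns `gene_id`, `condition`, `accessible`.
#' @export
call_accessibility <- function(peaks, genes,
                               region = c("promoter", "gene_body",
                                          "promoter_or_body"),
                               condition = NULL, upstream = 1500L,
                               chrom_lengths = NULL) {
  region <- match.arg(region)
  if (!inherits(peaks, "peak_set")) peaks <- merge_peak_sets(peaks)
  condition <- condition %||% peaks$condition
  acc <- logical(nrow(genes))
  pk <- peaks$peaks
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cl <- if (!is.null(chrom_lengths)) chrom_lengths[[g$chrom]] else NULL
    ivs <- switch(region,
      promoter = list(promoter_interval(g, upstream, cl)),
      gene_body = list(c(g$start, g$end)),
      promoter_or_body = list(promoter_interval(g, upstream, cl),
                              c(g$start, g$end)))
    p <- pk[pk$chrom == g$chrom, , drop = FALSE]
    if (nrow(p) == 0L) next
    acc[i] <- any(vapply(ivs, function(iv)
      any(.overlaps(p$start, p$end, iv[1], iv[2])), logical(1)))
  }
  data.frame(gene_id = genes$gene_id, condition = condition, accessible = acc,
             stringsAsFactors = FALSE)
}

#' TSS-centred metagene accessibility profile
#'
#' For each gene, per-base binary peak occupancy (1 where covered by at least
#' one peak) is taken over `[tss - window, tss + window)` and reversed for
#' minus-strand genes so that upstream is always on the left. Occupancy is
#' averaged over genes, then over the bases within each bin.
#'
#' @param peaks a `peak_set` or list of replicate `peak_set`s.
#' @param genes a `gene_models` table (at least one gene).
#' @param window half-width in bases (default 1500).
#' @param binwidth bin size in bases (default 10); must divide `window`.
#' @return a list of class `metagene_profile` with `offsets` (bin left edges
#'   relative to the TSS), `values` (mean coverage per bin, in `[0, 1]`) and
#'   `n_genes`.
#' @export
metagene_profile <- function(peaks, genes, window = 1500L, binwidth = 10L) {
  if (nrow(genes) == 0L) stop_cellsig("metagene_profile needs at least one gene")
  if (window %% binwidth != 0L) stop_cellsig("window must be divisible by binwidth")
  if (!inherits(peaks, "peak_set")) peaks <- merge_peak_sets(peaks)
  nb <- as.integer(2L * window / binwidth)
  pk <- peaks$peaks
  total <- numeric(2L * window)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- g$tss - window; hi <- g$tss + window   # [lo, hi), 0-based
    cov <- logical(2L * window)
    p <- pk[pk$chrom == g$chrom & pk$start < hi & pk$end > lo, , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      a <- max(p$start[j], lo) - lo + 1L
      b <- min(p$end[j], hi) - lo
      cov[a:b] <- TRUE
    }
    if (g$strand == "-") cov <- rev(cov)
    total <- total + cov
  }
  per_base <- total / nrow(genes)
  values <- colMeans(matrix(per_base, nrow = binwidth, ncol = nb))
  structure(list(offsets = seq(-window, window - binwidth, by = binwidth),
                 values = values, n_genes = nrow(genes)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("TSS metagene profile: %d genes, %d bins over [%d, %d)\n",
              x$n_genes, length(x$values), min(x$offsets),
              max(x$offsets) + diff(x$offsets[1:2])))
  cat(sprintf("  mean coverage %.3f (max %.3f at offset %d)\n",
              mean(x$values), max(x$values), x$offsets[which.max(x$values)]))
  invisible(x)
}
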