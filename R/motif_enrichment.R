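# Exact-match scanning for a fixed consensus motif (default the palindromic
# MADS-box site CCATATATGG) and Fisher-exact enrichment of motif-containing
# regions between a foreground and a background region set.

#' Reverse complement of a DNA string
#'
#' @param x ACGTN string.
#' @return reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan sequences for exact occurrences of a motif
#'
#' Reports every exact occurrence of the motif on either strand, including
#' overlapping occurrences. For palindromic motifs (reverse complement equal
#' to the motif) the + and - hits at the same position coincide and are
#' collapsed to a single + hit.
#'
#' @param regions named character vector of sequences (names are region ids),
#'   or a list of such.
#' @param motif non-empty ACGT string.
#' @return data.frame with columns `region_id`, `position` (0-based start of
#'   the match), `strand`.
#' @export
scan_motif <- function(regions, motif = "CCATATATGG") {
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop_cellsig("motif must be a non-empty ACGT string")
  regions <- unlist(as.list(regions))
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop_cellsig("regions must be named")
  rc <- revcomp(motif)
  palindromic <- identical(rc, motif)
  subj <- Biostrings::DNAStringSet(regions)
  hit_one <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, subj)
    n <- S4Vectors::elementNROWS(hits)
    pos <- unlist(lapply(hits, IRanges::start), use.names = FALSE)
    data.frame(region_id = rep(names(regions), n),
               position = if (is.null(pos)) integer() else pos - 1L,
               strand = rep(strand, sum(n)), stringsAsFactors = FALSE)
  }
  fwd <- hit_one(motif, "+")
  if (palindromic) {
    out <- fwd
  } else {
    out <- rbind(fwd, hit_one(rc, "-"))
  }
  if (nrow(out) == 0L)
    return(data.frame(region_id = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- out[order(out$region_id, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment between foreground and background regions
#'
#' A region counts as a hit when it contains at least one motif occurrence
#' (either strand). Enrichment of the foreground hit rate over the background
#' hit rate is tested with a one-sided Fisher exact test (hypergeometric
#' upper tail) on the 2x2 table (fg hit, fg miss; bg hit, bg miss). The fold
#' is the ratio of hit fractions; with no background hits the fold is `Inf`
#' (flagged), and with no hits at all it is undefined and an error is raised.
#'
#' @param fg,bg named character vectors of sequences (non-empty).
#' @param motif ACGT string.
#' @return a list of class `motif_enrichment`: `n_fg`, `n_fg_hit`, `n_bg`,
#'   `n_bg_hit`, `fold`, `pvalue`, `motif`.
#' @export
motif_enrichment <- function(fg, bg, motif = "CCATATATGG") {
  if (length(fg) == 0L || length(bg) == 0L)
    stop_cellsig("foreground and background must be non-empty")
  hit_ids <- function(x) unique(scan_motif(x, motif)$region_id)
  n_fg <- length(fg); n_bg <- length(bg)
  n_fg_hit <- length(hit_ids(fg)); n_bg_hit <- length(hit_ids(bg))
  if (n_fg_hit == 0L && n_bg_hit == 0L)
    stop_cellsig("no motif occurrences in foreground or background; fold undefined")
  fold <- (n_fg_hit / n_fg) / (n_bg_hit / n_bg)
  tab <- matrix(c(n_fg_hit, n_fg - n_fg_hit, n_bg_hit, n_bg - n_bg_hit),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(n_fg = n_fg, n_fg_hit = n_fg_hit, n_bg = n_bg,
                 n_bg_hit = n_bg_hit, fold = fold, pvalue = p, motif = motif),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("Motif %s: %d/%d foreground vs %d/%d background regions hit\n",
              x$motif, x$n_fg_hit, x$n_fg, x$n_bg_hit, x$n_bg))
  cat(sprintf("  fold = %s, one-sided Fisher p = %.3g\n",
              if (is.finite(x$fold)) sprintf("%.2f", x$fold) else "Inf",
              x$pvalue))
  invisible(x)
}

#' Extract promoter sequences for a gene set
#'
#' Convenience for motif scanning: pulls each gene's promoter window from the
#' genome, reverse-complementing minus-strand promoters so sequences read 5'
#' to 3' toward the TSS.
#'
#' @param genome named character vector of sequences.
#' @param genes a `gene_models` table.
#' @param upstream promoter size in bases.
#' @return named character vector of promoter sequences (names are gene ids).
#' @export
promoter_sequences <- function(genome, genes, upstream = 1500L) {
  out <- character(nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    iv <- promoter_interval(g, upstream, nchar(genome[[g$chrom]]))
    if (iv[1] >= iv[2]) { out[i] <- ""; next }
    s <- substr(genome[[g$chrom]], iv[1] + 1L, iv[2])
    out[i] <- if (g$strand == "-") revcomp(s) else s
  }
  out[nzchar(out)]
}
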