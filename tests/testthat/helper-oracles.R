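# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the NB pmf is written from the gamma-function form,
# the feature assigner enumerates every (gene, feature) overlap from scratch,
# and the motif scanner is a regex substring scan.

# conditioned two-sided NB exact p by direct enumeration, lgamma-based pmf
oracle_nb_exact <- function(s_a, s_b, n_a, n_b, phi) {
  s <- s_a + s_b
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    p <- n_a / (n_a + n_b)
    pr <- exp(lchoose(s, k) + k * log(p) + (s - k) * log(1 - p))
  } else {
    mu <- s / (n_a + n_b)
    pmf <- function(x, n) {
      size <- n / phi; m <- n * mu
      exp(lgamma(x + size) - lgamma(size) - lfactorial(x) +
            size * log(size / (size + m)) + x * log(m / (size + m)))
    }
    pr <- pmf(k, n_a) * pmf(s - k, n_b)
  }
  min(1, sum(pr[pr <= pr[s_a + 1] * (1 + 1e-7)]) / sum(pr))
}

# brute-force highest-priority feature for one peak: enumerate all candidate
# (gene, feature) intervals with direct strand arithmetic
oracle_assign <- function(p_chrom, p_start, p_end, genes,
                          upstream = 1500, downstream = 3000) {
  prio <- c(promoter = 1, exon = 2, intron = 3, downstream = 4)
  best <- NULL
  mid <- (p_start + p_end) / 2
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != p_chrom) next
    cand <- list()
    if (g$strand == "+") {
      cand$promoter <- c(max(0, g$tss - upstream), g$tss)
      cand$downstream <- c(g$tts + 1, g$tts + 1 + downstream)
    } else {
      cand$promoter <- c(g$tss + 1, g$tss + 1 + upstream)
      cand$downstream <- c(max(0, g$tts - downstream), g$tts)
    }
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex)))
      cand[[paste0("exon", j)]] <- c(ex[j, 1], ex[j, 2])
    if (nrow(ex) > 1)
      for (j in seq_len(nrow(ex) - 1))
        cand[[paste0("intron", j)]] <- c(ex[j, 2], ex[j + 1, 1])
    for (nm in names(cand)) {
      iv <- cand[[nm]]
      if (iv[1] >= iv[2]) next
      if (p_start < iv[2] && iv[1] < p_end) {
        ft <- sub("[0-9]+$", "", nm)
        rec <- list(feature = ft, gene_id = g$gene_id,
                    key = c(prio[[ft]], abs(mid - g$tss)))
        if (is.null(best) ||
            rec$key[1] < best$key[1] ||
            (rec$key[1] == best$key[1] && rec$key[2] < best$key[2]) ||
            (rec$key[1] == best$key[1] && rec$key[2] == best$key[2] &&
             rec$gene_id < best$gene_id))
          best <- rec
      }
    }
  }
  if (is.null(best)) list(feature = "intergenic", gene_id = NA_character_)
  else best[c("feature", "gene_id")]
}

# overlapping-substring scan of seq and its reverse complement via regex
oracle_scan <- function(seqs, motif) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    fwd <- as.integer(gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]])
    fwd <- fwd[fwd > 0]
    rev_hits <- as.integer(gregexpr(paste0("(?=", rc(motif), ")"), s,
                                    perl = TRUE)[[1]])
    rev_hits <- rev_hits[rev_hits > 0]
    hits <- rbind(
      if (length(fwd)) data.frame(region_id = id, position = fwd - 1L,
                                  strand = "+"),
      if (rc(motif) != motif && length(rev_hits))
        data.frame(region_id = id, position = rev_hits - 1L, strand = "-"))
    out[[id]] <- hits
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(region_id = character(),
                                      position = integer(),
                                      strand = character()))
  res <- res[order(res$region_id, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

# small deterministic gene fixture on one chromosome
toy_genes <- function(n = 3, spacing = 10000, seed = 1) {
  set.seed(seed)
  start <- seq(5000, by = spacing, length.out = n)
  len <- sample(800:2500, n, replace = TRUE)
  gene_models(sprintf("g%02d", seq_len(n)), "chr1", start, start + len,
              sample(c("+", "-"), n, replace = TRUE))
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
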