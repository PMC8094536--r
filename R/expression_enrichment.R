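# The RNA-seq statistics chain: CPM filtering, TMM effective library sizes,
# a conditioned negative-binomial exact test with a single common dispersion,
# BH correction, and stage-enrichment classification. TMM and the exact test
# are authored here so the pipeline is self-contained; every constant (trim
# fractions, reference-sample rule, weighting) is documented on the function.

#' Counts per million
#'
#' @param counts a `count_matrix` or plain integer matrix (genes x samples).
#' @param effective_lib_sizes per-sample effective library sizes; defaults to
#'   the raw column sums. All must be > 0.
#' @return numeric matrix: `count / effective_lib_size * 1e6`.
#' @export
cpm <- function(counts, effective_lib_sizes = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  eff <- effective_lib_sizes %||% colSums(m)
  if (any(eff <= 0)) stop_cellsig("effective library sizes must be > 0")
  sweep(m, 2, eff, "/") * 1e6
}

#' Expression filter: minimum CPM in a minimum number of samples
#'
#' A gene is kept when its CPM reaches `min_cpm` in at least `min_samples`
#' samples (any samples, not per group). With the defaults this is the
#' "at least 1 cpm in 2 replicate samples" rule.
#'
#' @param counts a `count_matrix`.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 2); must not exceed the sample count.
#' @param effective_lib_sizes optional per-sample effective sizes for the CPM.
#' @return character vector of retained gene ids, in matrix order.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = 2,
                             effective_lib_sizes = NULL) {
  if (min_samples > ncol(counts$counts))
    stop_cellsig("min_samples exceeds the number of samples")
  x <- cpm(counts, effective_lib_sizes)
  keep <- rowSums(x >= min_cpm) >= min_samples
  rownames(counts$counts)[keep]
}

# weighted trimmed mean of M-values between one sample and the reference;
# returns the log2 scale factor
.tmm_pair <- function(y, y_ref, lib, lib_ref, trim_M, trim_A) {
  keep <- y > 0 & y_ref > 0
  if (!any(keep))
    stop_cellsig("sample shares no nonzero genes with the reference")
  p <- y[keep] / lib; p_ref <- y_ref[keep] / lib_ref
  M <- log2(p / p_ref)
  A <- (log2(p) + log2(p_ref)) / 2
  # asymptotic inverse binomial variance of M
  w <- (lib - y[keep]) / (lib * y[keep]) + (lib_ref - y_ref[keep]) / (lib_ref * y_ref[keep])
  fin <- is.finite(M) & is.finite(A) & is.finite(w)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0L) return(0)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(0)
  f <- sum((M / w)[keep2]) / sum((1 / w)[keep2])
  if (!is.finite(f)) 0 else f
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scale factors. The reference sample is the one
#' whose 75th-percentile count fraction is closest to the mean of that
#' quantity across samples. For each sample, genes with a zero count in
#' either the sample or the reference are dropped; the per-gene log2 ratio of
#' count fractions (M) is doubly trimmed — the most extreme 30% of M at each
#' end and 5% of the average log2 abundance (A) at each end — and the factor
#' is two to the precision-weighted mean of the surviving M values, with
#' weights the inverse asymptotic binomial variance. Factors are finally
#' rescaled to geometric mean 1, so the effective library size is
#' `lib_size * factor`.
#'
#' @param counts a `count_matrix` or integer matrix with at least 2 samples,
#'   each with at least one nonzero count.
#' @param trim_M trim fraction on M at each tail (default 0.30).
#' @param trim_A trim fraction on A at each tail (default 0.05).
#' @return a list of class `tmm_norm`: `lib_sizes`, `tmm_factors`,
#'   `effective_lib_sizes`, `ref_sample`.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2L) stop_cellsig("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop_cellsig("sample with all-zero counts")
  q75 <- apply(m, 2, function(y) stats::quantile(y, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  logf <- vapply(seq_len(ncol(m)), function(j)
    if (j == ref) 0 else .tmm_pair(m[, j], m[, ref], lib[j], lib[ref],
                                   trim_M, trim_A),
    numeric(1))
  f <- 2^logf
  f <- f / exp(mean(log(f)))  # geometric mean 1
  structure(list(lib_sizes = lib, tmm_factors = f,
                 effective_lib_sizes = lib * f,
                 ref_sample = colnames(m)[ref] %||% ref),
            class = "tmm_norm")
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference sample:", x$ref_sample, ")\n")
  print(data.frame(lib_size = x$lib_sizes,
                   factor = round(x$tmm_factors, 4),
                   effective = round(x$effective_lib_sizes)))
  invisible(x)
}

# splits counted as "at least as extreme" with the standard relative tie
# tolerance of exact tests, so mathematically tied probabilities computed in
# different floating-point orders are still ties
.TIE_REL_TOL <- 1 + 1e-7

#' Conditioned negative-binomial exact test for two groups of counts
#'
#' Tests equality of per-sample means between two groups whose counts have
#' been equalized to a common effective library size. The group sums
#' `s_a = sum(y_a)` and `s_b = sum(y_b)` are modelled as negative binomial
#' with dispersion `phi` (size `n/phi`); conditioning on the total
#' `s = s_a + s_b`, the two-sided exact p-value is the probability, under
#' equal per-sample means, of all splits `(k, s - k)` whose probability does
#' not exceed that of the observed split. `phi = 0` is the Poisson limit, in
#' which the test reduces to the exact binomial test of `s_a` successes in
#' `s` trials with probability `n_a / (n_a + n_b)`.
#'
#' @param y_a,y_b non-negative integer counts for the two groups (either the
#'   per-sample vectors or the pre-summed totals with `n_a`/`n_b` given).
#' @param phi common dispersion, `>= 0`.
#' @param n_a,n_b number of samples per group; defaults to `length(y_a)` and
#'   `length(y_b)`.
#' @return two-sided exact p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(y_a, y_b, phi = 0, n_a = length(y_a),
                          n_b = length(y_b)) {
  if (phi < 0) stop_cellsig("dispersion must be >= 0")
  s_a <- sum(y_a); s_b <- sum(y_b); s <- s_a + s_b
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    # Poisson limit: conditional on the total, s_a is binomial
    pr <- stats::dbinom(k, s, n_a / (n_a + n_b))
  } else {
    # sum of n iid NB(mean mu, dispersion phi) is NB(mean n*mu, size n/phi)
    mu <- s / (n_a + n_b)
    pr <- stats::dnbinom(k, size = n_a / phi, mu = n_a * mu) *
      stats::dnbinom(s - k, size = n_b / phi, mu = n_b * mu)
  }
  tot <- sum(pr)
  if (tot <= 0) return(1)
  p_obs <- pr[s_a + 1L]
  min(1, sum(pr[pr <= p_obs * .TIE_REL_TOL]) / tot)
}

#' Common negative-binomial dispersion by method of moments
#'
#' On counts equalized to a common library size, each gene contributes a
#' moment estimate `(variance - mean) / mean^2` pooled across groups with
#' degrees-of-freedom weights; the common dispersion is the mean of the
#' per-gene positive parts, floored at zero. Deterministic and closed-form;
#' no likelihood iteration.
#'
#' @param counts integer matrix (genes x samples) of equalized pseudo-counts,
#'   or a `count_matrix`.
#' @param groups vector assigning each sample to a group; groups of size 1
#'   are ignored (no within-group variance).
#' @return scalar dispersion estimate `>= 0`.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  groups <- as.character(groups)
  idx <- split(seq_len(ncol(m)), groups)
  idx <- idx[vapply(idx, length, integer(1)) >= 2L]
  if (length(idx) == 0L) stop_cellsig("need at least one group with >= 2 samples")
  phi_g <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    num <- 0; den <- 0
    for (j in idx) {
      y <- m[i, j]
      mu <- mean(y)
      if (mu <= 0) next
      v <- stats::var(y)
      w <- length(j) - 1L
      num <- num + w * (v - mu) / mu^2
      den <- den + w
    }
    if (den > 0) phi_g[i] <- num / den
  }
  phi_g <- phi_g[!is.na(phi_g)]
  if (length(phi_g) == 0L) return(0)
  max(0, mean(pmax(phi_g, 0)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving.
#' NA p-values (e.g. filtered genes) propagate as NA.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

# rescale every sample linearly to the geometric mean of the effective
# library sizes and round — the equalized pseudo-counts the exact test sees
.equalize_counts <- function(m, effective) {
  common <- exp(mean(log(effective)))
  round(sweep(m, 2, common / effective, "*"))
}

#' Classify genes as unicellular- or multicellular-enriched
#'
#' Runs the full expression chain: CPM filter (`min_cpm` in `min_samples`
#' samples), TMM effective library sizes, equalization of counts to a common
#' library size, a single common method-of-moments dispersion, a conditioned
#' NB exact test per gene of the unicellular samples against the pooled
#' multicellular samples, and BH correction. A gene is classified
#' `multicellular` when `fdr < alpha` and its log2 fold change
#' (multicellular over unicellular group-mean CPM, prior count 0.5) is
#' positive, `unicellular` when negative, and `even` otherwise; genes failing
#' the CPM filter are `even` with NA p-values.
#'
#' @param counts a `count_matrix`.
#' @param unicellular_stages,multicellular_stages stage labels (matched
#'   against `counts$samples$stage`); each side needs at least 2 samples.
#' @param alpha FDR threshold (default 0.05).
#' @param min_cpm,min_samples expression-filter parameters.
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @return a data.frame of class `enrichment_result` with columns `gene_id`,
#'   `mean_cpm_uni`, `mean_cpm_multi`, `log2fc`, `pvalue`, `fdr`, `class`,
#'   plus attributes `norm` (the `tmm_norm`) and `dispersion`.
#' @export
classify_stage_enrichment <- function(counts, unicellular_stages,
                                      multicellular_stages, alpha = 0.05,
                                      min_cpm = 1, min_samples = 2,
                                      dispersion = NULL) {
  st <- counts$samples$stage
  ia <- which(st %in% unicellular_stages)
  ib <- which(st %in% multicellular_stages)
  if (length(ia) < 2L || length(ib) < 2L)
    stop_cellsig("each side of the contrast needs at least 2 samples")
  sel <- sort(c(ia, ib))  # stable column order: swapping labels flips classes
  m <- counts$counts[, sel, drop = FALSE]
  grp <- ifelse(sel %in% ia, "uni", "multi")

  norm <- tmm_factors(m)
  eff <- norm$effective_lib_sizes
  cm_sub <- count_matrix(m, data.frame(sample_id = colnames(m),
                                       stage = st[sel],
                                       replicate = counts$samples$replicate[sel]))
  kept <- filter_expressed(cm_sub, min_cpm, min_samples, effective_lib_sizes = eff)
  keep <- rownames(m) %in% kept

  eq <- .equalize_counts(m, eff)
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(eq[keep, , drop = FALSE], grp)

  x <- cpm(m, eff)
  mu_uni <- rowMeans(x[, grp == "uni", drop = FALSE])
  mu_multi <- rowMeans(x[, grp == "multi", drop = FALSE])
  prior <- 0.5 * 1e6 / mean(eff)
  log2fc <- log2((mu_multi + prior) / (mu_uni + prior))

  pv <- rep(NA_real_, nrow(m))
  ki <- which(keep)
  for (i in ki)
    pv[i] <- nb_exact_test(eq[i, grp == "uni"], eq[i, grp == "multi"],
                           phi = dispersion)
  fdr <- bh_fdr(pv)
  cls <- rep("even", nrow(m))
  sig <- !is.na(fdr) & fdr < alpha
  cls[sig & log2fc > 0] <- "multicellular"
  cls[sig & log2fc < 0] <- "unicellular"

  out <- data.frame(gene_id = rownames(m), mean_cpm_uni = mu_uni,
                    mean_cpm_multi = mu_multi, log2fc = log2fc,
                    pvalue = pv, fdr = fdr, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "norm") <- norm
  attr(out, "dispersion") <- dispersion
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  tab <- table(factor(x$class, c("unicellular", "even", "multicellular")))
  cat(sprintf(
    "Stage enrichment over %d genes (common dispersion %.4f):\n", nrow(x),
    attr(x, "dispersion")))
  cat(sprintf("  unicellular-enriched: %d\n  multicellular-enriched: %d\n  even: %d\n",
              tab[["unicellular"]], tab[["multicellular"]], tab[["even"]]))
  invisible(x)
}
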