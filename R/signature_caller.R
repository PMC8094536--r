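# Cross-species set algebra: ortholog-restricted accessibility intersections,
# exclusivity filters, the expression-exclusivity reduction to unicellular and
# multicellular signature genes, and the accessibility-expression association.

.calls_lookup <- function(calls) {
  stats::setNames(as.logical(calls$accessible), as.character(calls$gene_id))
}

# OR-combined accessibility over possibly comma-joined reference ids; ids
# missing from the call set are treated inaccessible (and counted)
.lookup_any <- function(ids, lk) {
  miss <- 0L
  acc <- vapply(strsplit(ids, ",", fixed = TRUE), function(parts) {
    v <- lk[parts]
    miss <<- miss + sum(is.na(v))
    any(v, na.rm = TRUE)
  }, logical(1))
  list(accessible = acc, missing = miss)
}

#' Assemble the conserved-gene table
#'
#' One row per ortholog triplet, carrying the focal organism's unicellular and
#' multicellular accessibility, the two reference organisms' accessibility,
#' and the focal expression class. Focal multicellular accessibility is the
#' union over the provided multicellular-stage call sets. Genes missing from
#' a call set are treated as inaccessible, with a warning giving the count.
#'
#' @param orthologs an `ortholog_map`.
#' @param calls_focal_uni accessibility calls (data.frame `gene_id`,
#'   `accessible`) for the focal organism's unicellular stage.
#' @param calls_focal_multi a single call data.frame or a list of them, one
#'   per multicellular stage; combined by union.
#' @param calls_ref_uni,calls_ref_multi calls for the unicellular and
#'   multicellular reference organisms.
#' @param enrichment an `enrichment_result` for the focal organism (or any
#'   data.frame with `gene_id` and `class`); genes absent from it are `even`.
#' @return data.frame of class `conserved_table` with columns
#'   `focal_gene_id`, `ref_uni_gene_id`, `ref_multi_gene_id`,
#'   `acc_focal_uni`, `acc_focal_multi`, `acc_ref_uni`, `acc_ref_multi`,
#'   `expr_class`.
#' @export
build_conserved_table <- function(orthologs, calls_focal_uni,
                                  calls_focal_multi, calls_ref_uni,
                                  calls_ref_multi, enrichment) {
  if (anyDuplicated(orthologs$focal_gene_id))
    stop_cellsig("duplicate focal gene ids in ortholog map")
  if (is.data.frame(calls_focal_multi)) calls_focal_multi <- list(calls_focal_multi)
  lk_fu <- .calls_lookup(calls_focal_uni)
  lk_fm_list <- lapply(calls_focal_multi, .calls_lookup)
  lk_ru <- .calls_lookup(calls_ref_uni)
  lk_rm <- .calls_lookup(calls_ref_multi)

  fid <- orthologs$focal_gene_id
  acc_fu <- lk_fu[fid]; n_miss <- sum(is.na(acc_fu))
  acc_fu[is.na(acc_fu)] <- FALSE
  acc_fm <- rep(FALSE, length(fid))
  for (lk in lk_fm_list) {
    v <- lk[fid]; v[is.na(v)] <- FALSE
    acc_fm <- acc_fm | v
  }
  ru <- .lookup_any(orthologs$ref_uni_gene_id, lk_ru)
  rm_ <- .lookup_any(orthologs$ref_multi_gene_id, lk_rm)
  n_miss <- n_miss + ru$missing + rm_$missing
  if (n_miss > 0L)
    warning(sprintf("%d gene id(s) absent from a call set; treated inaccessible",
                    n_miss), call. = FALSE)

  cls <- rep("even", length(fid))
  hit <- match(fid, enrichment$gene_id)
  cls[!is.na(hit)] <- enrichment$class[hit[!is.na(hit)]]

  out <- data.frame(focal_gene_id = fid,
                    ref_uni_gene_id = orthologs$ref_uni_gene_id,
                    ref_multi_gene_id = orthologs$ref_multi_gene_id,
                    acc_focal_uni = unname(acc_fu),
                    acc_focal_multi = acc_fm,
                    acc_ref_uni = ru$accessible,
                    acc_ref_multi = rm_$accessible,
                    expr_class = cls, stringsAsFactors = FALSE)
  class(out) <- c("conserved_table", "data.frame")
  out
}

#' Call unicellular and multicellular signature genes
#'
#' Within the conserved genes accessible in the focal unicellular stage
#' (the "unicellular parent" set), the shared subset is accessible in the
#' focal multicellular stages or in the multicellular reference, and the
#' exclusive subset is accessible in the unicellular reference while
#' inaccessible in both the focal multicellular stages and the multicellular
#' reference. The multicellular side is the mirror image. Signature genes are
#' the exclusive genes whose focal expression class matches the same side
#' (unicellular-exclusive accessibility and unicellular-enriched expression,
#' and vice versa). Percentages are `100 * count / parent`, half-up rounded
#' to one decimal.
#'
#' @param tab a `conserved_table` (non-empty).
#' @return a list of class `signature_result`: counts (`n_conserved`,
#'   `n_acc_focal_uni`, `n_acc_focal_multi`, `n_uni_shared`,
#'   `n_uni_exclusive`, `n_multi_shared`, `n_multi_exclusive`), percentages
#'   (`pct_uni_shared`, `pct_uni_exclusive`, `pct_multi_shared`,
#'   `pct_multi_exclusive`), gene sets (`uni_exclusive_genes`,
#'   `multi_exclusive_genes`, `unicellular_signature`,
#'   `multicellular_signature`).
#' @export
call_signatures <- function(tab) {
  if (!is.data.frame(tab) || nrow(tab) == 0L)
    stop_cellsig("conserved table is empty")
  fu <- tab$acc_focal_uni; fm <- tab$acc_focal_multi
  ru <- tab$acc_ref_uni; rm_ <- tab$acc_ref_multi

  uni_parent <- fu
  uni_shared <- fu & (fm | rm_)
  uni_excl <- fu & ru & !fm & !rm_
  multi_parent <- fm
  multi_shared <- fm & (fu | ru)
  multi_excl <- fm & rm_ & !fu & !ru

  uni_sig <- uni_excl & tab$expr_class == "unicellular"
  multi_sig <- multi_excl & tab$expr_class == "multicellular"

  pct <- function(k, n) if (n > 0) round_half_up(100 * k / n, 1) else NA_real_
  structure(list(
    n_conserved = nrow(tab),
    n_acc_focal_uni = sum(uni_parent),
    n_acc_focal_multi = sum(multi_parent),
    n_uni_shared = sum(uni_shared),
    n_uni_exclusive = sum(uni_excl),
    n_multi_shared = sum(multi_shared),
    n_multi_exclusive = sum(multi_excl),
    pct_uni_shared = pct(sum(uni_shared), sum(uni_parent)),
    pct_uni_exclusive = pct(sum(uni_excl), sum(uni_parent)),
    pct_multi_shared = pct(sum(multi_shared), sum(multi_parent)),
    pct_multi_exclusive = pct(sum(multi_excl), sum(multi_parent)),
    uni_exclusive_genes = tab$focal_gene_id[uni_excl],
    multi_exclusive_genes = tab$focal_gene_id[multi_excl],
    unicellular_signature = tab$focal_gene_id[uni_sig],
    multicellular_signature = tab$focal_gene_id[multi_sig]
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("Conserved genes: %d\n", x$n_conserved))
  cat(sprintf("  accessible, focal unicellular:   %4d (shared %d = %.1f%%, exclusive %d = %.1f%%)\n",
              x$n_acc_focal_uni, x$n_uni_shared, x$pct_uni_shared,
              x$n_uni_exclusive, x$pct_uni_exclusive))
  cat(sprintf("  accessible, focal multicellular: %4d (shared %d = %.1f%%, exclusive %d = %.1f%%)\n",
              x$n_acc_focal_multi, x$n_multi_shared, x$pct_multi_shared,
              x$n_multi_exclusive, x$pct_multi_exclusive))
  cat(sprintf("  signature genes: %d unicellular, %d multicellular\n",
              length(x$unicellular_signature), length(x$multicellular_signature)))
  invisible(x)
}

#' Accessibility-expression association (Pearson chi-square)
#'
#' Cross-tabulates focal genes by expression class (unicellular vs
#' multicellular enriched) against stage-restricted accessibility (accessible
#' in the unicellular stage only vs in the multicellular stages only). Genes
#' that are evenly expressed, accessible in both stage groups, or accessible
#' in neither are excluded. The statistic is the Pearson chi-square without
#' continuity correction on the resulting 2x2 table.
#'
#' @param enrichment an `enrichment_result` (or data.frame with `gene_id`,
#'   `class`).
#' @param calls_uni accessibility calls for the unicellular stage.
#' @param calls_multi a call data.frame or list of them for the multicellular
#'   stages (union).
#' @return a list of class `contingency_result`: `table`, `chi2`, `df`,
#'   `pvalue`, `warning` (NULL, or a note when an expected cell is < 1).
#' @export
accessibility_expression_association <- function(enrichment, calls_uni,
                                                 calls_multi) {
  if (is.data.frame(calls_multi)) calls_multi <- list(calls_multi)
  lk_u <- .calls_lookup(calls_uni)
  acc_m <- rep(FALSE, length(lk_u))
  names(acc_m) <- names(lk_u)
  for (cm in calls_multi) {
    lk <- .calls_lookup(cm)
    common <- intersect(names(acc_m), names(lk))
    acc_m[common] <- acc_m[common] | lk[common]
  }
  gid <- intersect(enrichment$gene_id, names(lk_u))
  if (length(gid) == 0L) stop_cellsig("no genes shared between inputs")
  cls <- enrichment$class[match(gid, enrichment$gene_id)]
  au <- lk_u[gid]; am <- acc_m[gid]
  use <- cls %in% c("unicellular", "multicellular") & (au != am)
  tab <- table(factor(cls[use], c("unicellular", "multicellular")),
               factor(ifelse(au[use], "acc_unicellular_only",
                             "acc_multicellular_only"),
                      c("acc_unicellular_only", "acc_multicellular_only")))
  chisq_from_table(unclass(tab))
}

#' Pearson chi-square on a contingency table
#'
#' `sum((O - E)^2 / E)` without continuity correction; p-value from the
#' chi-square distribution with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param tab r x c matrix of non-negative counts.
#' @return a `contingency_result` list; when any expected cell is below 1 a
#'   note is attached in `$warning` and the statistic is still returned.
#' @export
chisq_from_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop_cellsig("negative cell counts")
  n <- sum(tab)
  if (n == 0) stop_cellsig("empty contingency table")
  E <- outer(rowSums(tab), colSums(tab)) / n
  warn <- NULL
  if (any(E < 1)) warn <- "expected cell count below 1; chi-square approximation is unreliable"
  chi2 <- sum((tab[E > 0] - E[E > 0])^2 / E[E > 0])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(table = tab, chi2 = chi2, df = df,
                 pvalue = stats::pchisq(chi2, df, lower.tail = FALSE),
                 warning = warn),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.2f, df = %d, p = %.3g\n", x$chi2, x$df, x$pvalue))
  if (!is.null(x$warning)) cat("note:", x$warning, "\n")
  invisible(x)
}

#' Accessibility of the most and least expressed genes
#'
#' Ranks genes by stage-mean CPM (ties broken by gene id) and reports the
#' fraction of accessible genes among the top `k` and bottom `k`.
#'
#' @param counts a `count_matrix`.
#' @param calls accessibility calls for the corresponding stage.
#' @param stage stage label selecting the samples to average.
#' @param k tail size (default 1000); must not exceed the gene count.
#' @return data.frame with one row: `stage`, `k`, `frac_accessible_top`,
#'   `frac_accessible_bottom`.
#' @export
top_bottom_accessibility_contrast <- function(counts, calls, stage, k = 1000L) {
  if (k > nrow(counts$counts))
    stop_cellsig("k exceeds the number of genes")
  sel <- counts$samples$stage == stage
  if (!any(sel)) stop_cellsig("unknown stage '%s'", stage)
  x <- rowMeans(cpm(counts)[, sel, drop = FALSE])
  ord <- order(-x, rownames(counts$counts))
  lk <- .calls_lookup(calls)
  frac <- function(ids) {
    v <- lk[ids]; v[is.na(v)] <- FALSE
    mean(v)
  }
  gid <- rownames(counts$counts)
  data.frame(stage = stage, k = k,
             frac_accessible_top = frac(gid[ord[seq_len(k)]]),
             frac_accessible_bottom = frac(gid[rev(ord)[seq_len(k)]]),
             stringsAsFactors = FALSE)
}
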