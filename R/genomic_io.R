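# Readers/writers for the standard formats consumed by the pipeline, plus the
# validated containers every other module operates on. Internal coordinates
# are uniformly 0-based half-open; GFF3 (1-based closed) is converted at the
# boundary.

# ---- containers -------------------------------------------------------------

#' Construct a validated gene-model table
#'
#' A gene-model table is a `data.frame` with one row per gene and columns
#' `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`
#' (`"+"`/`"-"`), `tss`, `tts` (single base positions) and a list column
#' `exons` of two-column matrices (`start`, `end`, 0-based half-open).
#'
#' The TSS is `start` on the plus strand and `end - 1` on the minus strand;
#' the TTS is the opposite gene end. Exons must be non-empty, sorted,
#' non-overlapping and contained in `[start, end)`.
#'
#' @param gene_id,chrom character vectors.
#' @param start,end integer vectors, 0-based half-open gene spans.
#' @param strand character vector of `"+"` or `"-"`.
#' @param exons optional list of two-column integer matrices; defaults to one
#'   exon spanning the whole gene.
#' @return a `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, exons = NULL) {
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(gene_id)) stop_cellsig("duplicate gene_id values")
  if (any(start >= end)) {
    bad <- gene_id[start >= end][1]
    stop_cellsig("gene '%s': start must be < end", bad)
  }
  if (!all(strand %in% c("+", "-")))
    stop_cellsig("strand must be '+' or '-'")
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i) cbind(start = start[i], end = end[i]))
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(dim(ex)) || nrow(ex) == 0L)
      stop_cellsig("gene '%s': exons must be non-empty", gene_id[i])
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 1] >= ex[, 2]))
      stop_cellsig("gene '%s': exon start must be < end", gene_id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2]))
      stop_cellsig("gene '%s': exons overlap", gene_id[i])
    if (ex[1, 1] < start[i] || ex[nrow(ex), 2] > end[i])
      stop_cellsig("gene '%s': exon outside gene span", gene_id[i])
    colnames(ex) <- c("start", "end")
    exons[[i]] <- ex
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  tts <- ifelse(strand == "+", end - 1L, start)
  out <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = start, end = end, strand = strand,
    tss = as.integer(tss), tts = as.integer(tts),
    stringsAsFactors = FALSE
  )
  out$exons <- exons
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Construct a validated peak set
#'
#' @param chrom,start,end peak intervals, 0-based half-open.
#' @param score numeric peak scores (BED score or narrowPeak signalValue).
#' @param sample_id,condition labels for the originating sample/condition.
#' @return a list of class `peak_set` with elements `sample_id`, `condition`
#'   and `peaks` (a data.frame sorted by `(chrom, start)`).
#' @export
peak_set <- function(chrom, start, end, score = 0, sample_id = "sample",
                     condition = "condition") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop_cellsig("peak start must be < end")
  if (any(start < 0L)) stop_cellsig("peak start must be >= 0")
  peaks <- data.frame(chrom = as.character(chrom), start = start, end = end,
                      score = as.numeric(rep_len(score, length(start))),
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sample_id = sample_id, condition = condition, peaks = peaks),
            class = "peak_set")
}

#' Merge replicate peak sets by interval union
#'
#' @param ... `peak_set` objects (or a single list of them).
#' @param condition condition label for the merged set.
#' @return a `peak_set` holding the union of all input peaks (scores are the
#'   per-merged-interval maximum).
#' @export
merge_peak_sets <- function(..., condition = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "peak_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  pk <- do.call(rbind, lapply(sets, function(s) s$peaks))
  if (nrow(pk) == 0L)
    return(peak_set(character(), integer(), integer(),
                    sample_id = "merged",
                    condition = condition %||% sets[[1]]$condition))
  out <- do.call(rbind, lapply(split(pk, pk$chrom), function(d) {
    ir <- IRanges::reduce(.as_iranges(d$start, d$end))
    hits <- IRanges::findOverlaps(.as_iranges(d$start, d$end), ir)
    sc <- tapply(d$score[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), max)
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), score = as.numeric(sc),
               stringsAsFactors = FALSE)
  }))
  peak_set(out$chrom, out$start, out$end, out$score, sample_id = "merged",
           condition = condition %||% sets[[1]]$condition)
}

#' Construct a validated count matrix with sample metadata
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `stage`, `replicate`,
#'   one row per column of `counts`, in column order.
#' @return a list of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_cellsig("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop_cellsig("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop_cellsig("duplicate sample ids")
  if (!all(c("sample_id", "stage", "replicate") %in% names(samples)))
    stop_cellsig("samples needs columns sample_id, stage, replicate")
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop_cellsig("samples$sample_id must match counts columns in order")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_cellsig("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        stage = as.character(samples$stage),
                        replicate = as.character(samples$replicate),
                        stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' Construct a validated ortholog triplet map
#'
#' Each row links one focal-organism gene to its ortholog in the unicellular
#' reference and in the multicellular reference. Focal ids must be unique;
#' paralog fans should be collapsed upstream (see [read_ortholog_tsv()]).
#'
#' @param focal_gene_id,ref_uni_gene_id,ref_multi_gene_id character vectors.
#' @return a `data.frame` of class `ortholog_map`.
#' @export
ortholog_map <- function(focal_gene_id, ref_uni_gene_id, ref_multi_gene_id) {
  ids <- list(focal_gene_id, ref_uni_gene_id, ref_multi_gene_id)
  if (any(vapply(ids, function(x) any(is.na(x) | !nzchar(x)), logical(1))))
    stop_cellsig("ortholog map contains empty identifiers")
  if (anyDuplicated(focal_gene_id))
    stop_cellsig("duplicate focal_gene_id in ortholog map")
  out <- data.frame(focal_gene_id = as.character(focal_gene_id),
                    ref_uni_gene_id = as.character(ref_uni_gene_id),
                    ref_multi_gene_id = as.character(ref_multi_gene_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("ortholog_map", "data.frame")
  out
}

# ---- FASTA ------------------------------------------------------------------

#' Read a genome FASTA into a named character vector
#'
#' Sequences are upper-cased and validated against the \{A,C,G,T,N\} alphabet.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_cellsig("sequence '%s' contains characters outside {A,C,G,T,N}",
                 names(seqs)[bad][1])
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

# ---- GFF3 -------------------------------------------------------------------

.gff3_precheck <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stop_cellsig("malformed GFF3 at line %d: expected 9 tab-separated fields, got %d",
                   i, nf)
  }
  invisible(TRUE)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features, converts 1-based closed GFF3
#' coordinates to 0-based half-open, and attaches exons to their parent gene
#' (resolving through `mRNA`/transcript parents where present). Genes without
#' exon children become single-exon genes spanning the whole gene. Where
#' several isoforms exist, exons are collapsed to their interval union — one
#' model per gene.
#'
#' @param path GFF3 file.
#' @return a `gene_models` table.
#' @export
read_gff3 <- function(path) {
  .gff3_precheck(path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gr$type))
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop_cellsig("no gene features in '%s'", path)
  gid <- as.character(genes$ID)
  if (any(is.na(gid))) stop_cellsig("gene feature without ID attribute")
  # transcript-level features whose Parent is a gene
  parent1 <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  tx <- gr[type %in% c("mrna", "transcript")]
  tx2gene <- if (length(tx)) stats::setNames(parent1(tx), as.character(tx$ID))
             else character()
  ex <- gr[type == "exon"]
  ex_parent <- if (length(ex)) parent1(ex) else character()
  idx <- match(ex_parent, names(tx2gene))
  ex_gene <- ifelse(!is.na(idx), unname(tx2gene[idx]), ex_parent)

  exons <- vector("list", length(genes))
  names(exons) <- gid
  if (length(ex)) {
    by_gene <- split(seq_along(ex), ex_gene)
    for (g in intersect(names(by_gene), gid)) {
      ir <- IRanges::reduce(IRanges::ranges(ex[by_gene[[g]]]))
      exons[[g]] <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }
  }
  g_start <- GenomicRanges::start(genes) - 1L
  g_end <- GenomicRanges::end(genes)
  for (i in seq_along(gid)) {
    if (is.null(exons[[i]])) {
      exons[[i]] <- cbind(start = g_start[i], end = g_end[i])
    } else if (exons[[i]][1, 1] < g_start[i] ||
               exons[[i]][nrow(exons[[i]]), 2] > g_end[i]) {
      stop_cellsig("gene '%s': exon outside parent gene span", gid[i])
    }
  }
  gene_models(gene_id = gid,
              chrom = as.character(GenomicRanges::seqnames(genes)),
              start = g_start, end = g_end,
              strand = as.character(GenomicRanges::strand(genes)),
              exons = exons)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: emits one `gene` line and its `exon` children per
#' model, converting back to 1-based closed coordinates.
#'
#' @param genes a `gene_models` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  n_ex <- vapply(genes$exons, nrow, integer(1))
  ex_start <- unlist(lapply(genes$exons, function(e) e[, 1]))
  ex_end <- unlist(lapply(genes$exons, function(e) e[, 2]))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id,
    Parent = IRanges::CharacterList(rep(list(character()), nrow(genes))))
  gid_rep <- rep(genes$gene_id, n_ex)
  gr_ex <- GenomicRanges::GRanges(
    rep(genes$chrom, n_ex), IRanges::IRanges(ex_start + 1L, ex_end),
    strand = rep(genes$strand, n_ex), type = "exon",
    ID = paste0(gid_rep, ".exon", unlist(lapply(n_ex, seq_len))),
    Parent = IRanges::CharacterList(as.list(gid_rep)))
  rtracklayer::export(c(gr_genes, gr_ex), path, format = "gff3")
  invisible(path)
}

# ---- BED / narrowPeak -------------------------------------------------------

.bed_precheck <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nf <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_cellsig("malformed BED at line %d: fewer than 3 fields", i)
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s >= e)
      stop_cellsig("invalid interval at line %d: start must be < end", i)
    if (is.na(nf)) nf <- length(f)
  }
  nf
}

#' Read a BED6 or ENCODE narrowPeak file into a peak set
#'
#' BED coordinates are already 0-based half-open and are kept as-is. For
#' narrowPeak input (10 columns) the `signalValue` column is used as the peak
#' score; for BED6 the score column is used. The narrowPeak summit offset is
#' parsed but not used downstream (whole-peak overlap semantics).
#'
#' @param path BED6 or narrowPeak file.
#' @param sample_id,condition labels attached to the returned set.
#' @return a `peak_set`, sorted by `(chrom, start)`.
#' @export
read_bed <- function(path, sample_id = basename(path), condition = sample_id) {
  nf <- .bed_precheck(path)
  if (is.na(nf))  # empty file
    return(peak_set(character(), integer(), integer(),
                    sample_id = sample_id, condition = condition))
  if (nf >= 10L) {
    gr <- rtracklayer::import(path, format = "narrowPeak")
    score <- as.numeric(gr$signalValue)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    score <- as.numeric(gr$score %||% rep(0, length(gr)))
    score[is.na(score)] <- 0
  }
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           score, sample_id = sample_id, condition = condition)
}

#' Write a peak set as an ENCODE narrowPeak file
#'
#' Scores go to the `signalValue` column; name, p/q columns and the summit
#' offset are written as placeholders (`.`/`-1`).
#'
#' @param ps a `peak_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(ps, path) {
  pk <- ps$peaks
  if (nrow(pk) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  df <- data.frame(pk$chrom, pk$start, pk$end,
                   paste0(ps$sample_id, "_peak", seq_len(nrow(pk))),
                   0L, ".", format(pk$score, trim = TRUE), -1, -1, -1,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- counts + metadata ------------------------------------------------------

#' Read a gene-by-sample count table with sample metadata
#'
#' @param path TSV whose first column is `gene_id` and remaining columns are
#'   samples.
#' @param metadata_path TSV with columns `sample_id`, `stage`, `replicate`.
#'   Every count column must appear here; the matrix is reordered to the
#'   metadata row order.
#' @return a `count_matrix`.
#' @export
read_counts <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage", "replicate") %in% names(meta)))
    stop_cellsig("metadata needs columns sample_id, stage, replicate")
  gene_id <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(suppressWarnings(as.numeric(m)))) || any(m != round(as.numeric(m))))
    stop_cellsig("non-integer count in '%s'", path)
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop_cellsig("metadata missing sample(s): %s", paste(missing, collapse = ", "))
  meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
  m <- m[, as.character(meta$sample_id), drop = FALSE]
  rownames(m) <- gene_id
  count_matrix(m, meta)
}

#' Write a count matrix and its sample metadata as TSV
#'
#' @param cm a `count_matrix`.
#' @param path,metadata_path output TSV files.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, metadata_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- ortholog map -----------------------------------------------------------

#' Read an ortholog triplet map from TSV
#'
#' Expects a header with columns `focal_gene_id`, `ref_uni_gene_id`,
#' `ref_multi_gene_id`. Focal genes listed more than once (paralog fans) are
#' collapsed to a single row keeping the first reference id per organism, with
#' a message noting the collapse; downstream accessibility for collapsed rows
#' is OR-combined when calls are built.
#'
#' @param path TSV file.
#' @return an `ortholog_map`.
#' @export
read_ortholog_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("focal_gene_id", "ref_uni_gene_id", "ref_multi_gene_id")
  if (!all(need %in% names(tab)))
    stop_cellsig("ortholog TSV needs header columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(tab$focal_gene_id)) {
    dup <- unique(tab$focal_gene_id[duplicated(tab$focal_gene_id)])
    message(sprintf("collapsing %d focal gene(s) mapped to multiple triplets",
                    length(dup)))
    orig_order <- unique(tab$focal_gene_id)
    join <- function(x) paste(unique(x), collapse = ",")
    agg <- lapply(split(tab, tab$focal_gene_id), function(d)
      data.frame(focal_gene_id = d$focal_gene_id[1],
                 ref_uni_gene_id = join(d$ref_uni_gene_id),
                 ref_multi_gene_id = join(d$ref_multi_gene_id),
                 stringsAsFactors = FALSE))
    tab <- do.call(rbind, agg)
    tab <- tab[order(match(tab$focal_gene_id, orig_order)), , drop = FALSE]
  }
  ortholog_map(tab$focal_gene_id, tab$ref_uni_gene_id, tab$ref_multi_gene_id)
}

#' Write an ortholog triplet map as TSV
#'
#' @param om an `ortholog_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_tsv <- function(om, path) {
  utils::write.table(as.data.frame(om), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
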