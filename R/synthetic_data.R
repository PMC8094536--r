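# Seeded generator for a complete three-"species" study: genomes and gene
# models, an ortholog triplet map, stage-wise promoter peak sets, NB count
# matrices with planted stage effects, promoter-planted motifs, and nucleus
# images with planted dark-chromatin fractions. Every output is a
# deterministic function of the configuration and its seed; each simulate_*
# step draws from a sub-seed at a fixed offset so stages can be regenerated
# independently.

#' Simulation configuration
#'
#' Defaults mirror the study design: a focal organism sampled at one
#' unicellular stage (vegetative) and three multicellular stages (streaming,
#' mound, fruiting) with two replicates each, one unicellular and one
#' multicellular reference organism with peak data only, 500 conserved gene
#' triplets, and 30 planted signature genes per side. The focal genome is
#' AT-rich (GC 0.23); promoter peaks are 200-400 bp; counts are negative
#' binomial with dispersion 0.05 and 8-fold planted stage effects.
#'
#' @param seed integer master seed.
#' @param n_genes genes per species (conserved genes are the first
#'   `n_conserved` of each).
#' @param n_conserved ortholog triplets.
#' @param n_uni_signature,n_multi_signature planted signature genes per side.
#' @param uni_stage,multi_stages focal stage labels.
#' @param n_reps replicates per focal stage.
#' @param acc_rate background probability of accessibility per
#'   (gene, condition).
#' @param expr_probs probabilities of expression class (even, unicellular,
#'   multicellular) for non-signature genes.
#' @param peak_fp,peak_fn accessibility false-positive/negative rates per
#'   (gene, condition).
#' @param mean_range log-uniform range of baseline expression means.
#' @param fold planted fold change for enriched genes.
#' @param phi negative-binomial dispersion of counts.
#' @param gc_focal,gc_ref genome GC content.
#' @param motif planted consensus motif.
#' @param motif_rate_fg,motif_rate_bg motif planting rates in promoters of
#'   multicellular-accessible genes and of all other genes.
#' @param n_images nucleus images per group.
#' @param img_size image side length in pixels.
#' @param dark_frac planted dark-area fractions, one per image group.
#' @param img_noise_sd Gaussian intensity noise.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 600L, n_conserved = 500L,
                       n_uni_signature = 30L, n_multi_signature = 30L,
                       uni_stage = "vegetative",
                       multi_stages = c("streaming", "mound", "fruiting"),
                       n_reps = 2L, acc_rate = 0.4,
                       expr_probs = c(even = 0.791, unicellular = 0.156,
                                      multicellular = 0.053),
                       peak_fp = 0, peak_fn = 0,
                       mean_range = c(20, 2000), fold = 8, phi = 0.05,
                       gc_focal = 0.23, gc_ref = 0.36,
                       motif = "CCATATATGG",
                       motif_rate_fg = 0.4, motif_rate_bg = 0.02,
                       n_images = 30L, img_size = 96L,
                       dark_frac = c(wildtype = 0.25, mutant = 0.15),
                       img_noise_sd = 0.03) {
  if (n_uni_signature + n_multi_signature > n_conserved)
    stop_cellsig("signature counts exceed n_conserved")
  if (n_conserved > n_genes) stop_cellsig("n_conserved exceeds n_genes")
  if (any(c(peak_fp, peak_fn) < 0) || any(c(peak_fp, peak_fn) > 1))
    stop_cellsig("noise rates must lie in [0, 1]")
  if (phi < 0) stop_cellsig("dispersion must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

.sub_seed <- function(cfg, offset) {
  as.integer((as.integer(cfg$seed) %% 2000000L) * 1000L + offset)
}

.random_genome <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome and its gene models
#'
#' Genes are laid out on one chromosome with large intergenic gaps so that
#' promoter windows (1500 bp) never collide with each other or with a
#' neighbouring gene body, mixed strands, and 1-4 exons each.
#'
#' @param cfg a `sim_config`.
#' @param species `"focal"`, `"ref_uni"` or `"ref_multi"` (controls the gene
#'   id prefix, GC content and sub-seed).
#' @return list with `genome` (named character vector) and `genes`
#'   (a `gene_models` table).
#' @export
simulate_annotation <- function(cfg, species = "focal") {
  off <- match(species, c("focal", "ref_uni", "ref_multi"))
  if (is.na(off)) stop_cellsig("unknown species '%s'", species)
  set.seed(.sub_seed(cfg, off))
  n <- cfg$n_genes
  gc <- if (species == "focal") cfg$gc_focal else cfg$gc_ref
  prefix <- c(focal = "FOC", ref_uni = "RUN", ref_multi = "RMU")[[species]]
  chrom <- paste0(prefix, "_chr1")

  gene_len <- sample(500:3000, n, replace = TRUE)
  gap <- sample(3200:4000, n, replace = TRUE)  # room for promoters both sides
  start <- 2000L + cumsum(c(0L, gene_len[-n] + gap[-n]))
  end <- start + gene_len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exons <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    if (k == 1L) return(cbind(start = start[i], end = end[i]))
    cuts <- sort(sample(seq(start[i] + 50L, end[i] - 50L), 2L * (k - 1L)))
    s <- c(start[i], cuts[seq(2, length(cuts), by = 2)])
    e <- c(cuts[seq(1, length(cuts), by = 2)], end[i])
    cbind(start = as.integer(s), end = as.integer(e))
  })
  glen <- end[n] + 4000L
  genome <- stats::setNames(.random_genome(glen, gc), chrom)
  genes <- gene_models(sprintf("%s_g%04d", prefix, seq_len(n)),
                       chrom, start, end, strand, exons)
  list(genome = genome, genes = genes)
}

#' Simulate the planted ground truth for the three-species study
#'
#' Assigns, per conserved triplet, the accessibility truth in the focal
#' unicellular stage, the focal multicellular stages (one flag applied to all
#' of them), and the two references, plus the focal expression class. The
#' first `n_uni_signature` conserved genes are planted unicellular signature
#' genes (accessible in focal-uni and the unicellular reference only,
#' unicellular-enriched expression); the next `n_multi_signature` are the
#' mirrored multicellular plants. Background genes draw accessibility
#' independently at `acc_rate` and an expression class from `expr_probs`;
#' any background gene whose random pattern would be side-exclusive has one
#' reference flag dropped, so exclusive accessibility patterns — and hence
#' signature membership — belong to the planted genes alone.
#'
#' @param cfg a `sim_config`.
#' @return a list of class `sim_truth`: `conserved` (data.frame of per-gene
#'   truth), `focal_extra` (truth for non-conserved focal genes),
#'   `uni_signature`, `multi_signature` (planted focal gene id sets).
#' @export
simulate_truth <- function(cfg) {
  set.seed(.sub_seed(cfg, 10L))
  nc <- cfg$n_conserved
  fid <- sprintf("FOC_g%04d", seq_len(cfg$n_genes))
  uid <- sprintf("RUN_g%04d", seq_len(cfg$n_genes))
  mid <- sprintf("RMU_g%04d", seq_len(cfg$n_genes))

  n_us <- cfg$n_uni_signature; n_ms <- cfg$n_multi_signature
  is_us <- seq_len(nc) <= n_us
  is_ms <- seq_len(nc) > n_us & seq_len(nc) <= n_us + n_ms

  rb <- function() stats::runif(nc) < cfg$acc_rate
  acc_fu <- rb(); acc_fm <- rb(); acc_ru <- rb(); acc_rm <- rb()
  cls <- sample(names(cfg$expr_probs), nc, replace = TRUE,
                prob = cfg$expr_probs)

  acc_fu[is_us] <- TRUE;  acc_ru[is_us] <- TRUE
  acc_fm[is_us] <- FALSE; acc_rm[is_us] <- FALSE
  cls[is_us] <- "unicellular"
  acc_fm[is_ms] <- TRUE;  acc_rm[is_ms] <- TRUE
  acc_fu[is_ms] <- FALSE; acc_ru[is_ms] <- FALSE
  cls[is_ms] <- "multicellular"

  # background genes never receive an exclusive accessibility pattern, so the
  # planted genes are exactly the signature truth (dropping one reference
  # flag breaks exclusivity without touching parent or shared membership)
  bg <- !(is_us | is_ms)
  uni_like <- bg & acc_fu & acc_ru & !acc_fm & !acc_rm
  acc_ru[uni_like] <- FALSE
  multi_like <- bg & acc_fm & acc_rm & !acc_fu & !acc_ru
  acc_rm[multi_like] <- FALSE

  conserved <- data.frame(
    focal_gene_id = fid[seq_len(nc)], ref_uni_gene_id = uid[seq_len(nc)],
    ref_multi_gene_id = mid[seq_len(nc)],
    acc_focal_uni = acc_fu, acc_focal_multi = acc_fm,
    acc_ref_uni = acc_ru, acc_ref_multi = acc_rm,
    expr_class = cls, stringsAsFactors = FALSE)

  n_extra <- cfg$n_genes - nc
  focal_extra <- data.frame(
    focal_gene_id = fid[nc + seq_len(n_extra)],
    acc_focal_uni = stats::runif(n_extra) < cfg$acc_rate,
    acc_focal_multi = stats::runif(n_extra) < cfg$acc_rate,
    expr_class = sample(names(cfg$expr_probs), n_extra, replace = TRUE,
                        prob = cfg$expr_probs),
    stringsAsFactors = FALSE)

  structure(list(conserved = conserved, focal_extra = focal_extra,
                 uni_signature = fid[seq_len(nc)][is_us],
                 multi_signature = fid[seq_len(nc)][is_ms]),
            class = "sim_truth")
}

# condition-level accessibility truth vectors for one species
.species_truth <- function(truth, species, condition) {
  cons <- truth$conserved
  if (species == "focal") {
    acc <- if (condition == "uni") c(cons$acc_focal_uni,
                                     truth$focal_extra$acc_focal_uni)
           else c(cons$acc_focal_multi, truth$focal_extra$acc_focal_multi)
    ids <- c(cons$focal_gene_id, truth$focal_extra$focal_gene_id)
  } else if (species == "ref_uni") {
    acc <- cons$acc_ref_uni; ids <- cons$ref_uni_gene_id
  } else {
    acc <- cons$acc_ref_multi; ids <- cons$ref_multi_gene_id
  }
  stats::setNames(acc, ids)
}

#' Simulate one replicate peak set for a (species, condition)
#'
#' Wherever the truth marks a gene accessible, a 200-400 bp peak with a
#' jittered centre is placed inside the gene's promoter. Condition-level
#' noise is applied before replication: each accessible gene is dropped with
#' probability `peak_fn` and each inaccessible gene gains a promoter peak
#' with probability `peak_fp` (these flips are shared by replicates of the
#' same condition; replicates differ in peak geometry and scores).
#'
#' @param cfg a `sim_config`.
#' @param ann output of [simulate_annotation()] for the species.
#' @param truth a `sim_truth`.
#' @param species `"focal"`, `"ref_uni"` or `"ref_multi"`.
#' @param condition a focal stage label, or the reference condition label
#'   (`"ref_uni"`/`"ref_multi"`).
#' @param replicate replicate number.
#' @return a `peak_set`.
#' @export
simulate_peaks <- function(cfg, ann, truth, species = "focal",
                           condition = cfg$uni_stage, replicate = 1L) {
  side <- if (species != "focal") species
          else if (condition == cfg$uni_stage) "uni" else "multi"
  tv <- .species_truth(truth, species,
                       if (species == "focal") side else condition)
  genes <- ann$genes
  cond_idx <- if (species == "focal")
    match(condition, c(cfg$uni_stage, cfg$multi_stages)) else 1L

  # condition-level noise: fixed per (species, condition), not per replicate
  set.seed(.sub_seed(cfg, 100L + 10L * match(species, c("focal", "ref_uni",
                                                        "ref_multi")) + cond_idx))
  acc <- tv[genes$gene_id]
  acc[is.na(acc)] <- FALSE
  flip_off <- acc & stats::runif(length(acc)) < cfg$peak_fn
  flip_on <- !acc & stats::runif(length(acc)) < cfg$peak_fp
  acc <- (acc & !flip_off) | flip_on

  # replicate-level geometry
  set.seed(.sub_seed(cfg, 500L + 37L * cond_idx + replicate +
                       100L * match(species, c("focal", "ref_uni", "ref_multi"))))
  idx <- which(acc)
  if (length(idx) == 0L)
    return(peak_set(character(), integer(), integer(),
                    sample_id = sprintf("%s_%s_rep%d", species, condition, replicate),
                    condition = condition))
  w <- sample(200:400, length(idx), replace = TRUE)
  d <- sample(50:300, length(idx), replace = TRUE)  # gap between peak and TSS
  g <- genes[idx, ]
  plus <- g$strand == "+"
  end <- ifelse(plus, g$tss - d, NA_integer_)
  start <- ifelse(plus, end - w, g$tss + 1L + d)
  end[!plus] <- start[!plus] + w[!plus]
  peak_set(g$chrom, start, end, stats::runif(length(idx), 5, 50),
           sample_id = sprintf("%s_%s_rep%d", species, condition, replicate),
           condition = condition)
}

#' Simulate the focal organism's count matrix
#'
#' Baseline per-gene means are log-uniform over `mean_range`; genes whose
#' planted class is `unicellular` have their mean multiplied by `fold` in the
#' unicellular-stage samples, and `multicellular` genes in the
#' multicellular-stage samples. Counts are negative binomial with dispersion
#' `phi` (Poisson when `phi = 0`) around `mean * depth`, with per-sample
#' depth factors uniform in `[0.8, 1.2]`.
#'
#' @param cfg a `sim_config`.
#' @param truth a `sim_truth`.
#' @return a `count_matrix` over all focal genes with 2 replicates per stage.
#' @export
simulate_counts <- function(cfg, truth) {
  set.seed(.sub_seed(cfg, 300L))
  cls <- c(truth$conserved$expr_class, truth$focal_extra$expr_class)
  gid <- c(truth$conserved$focal_gene_id, truth$focal_extra$focal_gene_id)
  n <- length(gid)
  stages <- rep(c(cfg$uni_stage, cfg$multi_stages), each = cfg$n_reps)
  reps <- rep(seq_len(cfg$n_reps), times = 1L + length(cfg$multi_stages))
  sid <- sprintf("%s_rep%d", stages, reps)
  base <- exp(stats::runif(n, log(cfg$mean_range[1]), log(cfg$mean_range[2])))
  depth <- stats::runif(length(sid), 0.8, 1.2)
  m <- matrix(0L, n, length(sid), dimnames = list(gid, sid))
  for (j in seq_along(sid)) {
    is_uni <- stages[j] == cfg$uni_stage
    mu <- base
    mu[cls == "unicellular" & is_uni] <- mu[cls == "unicellular" & is_uni] * cfg$fold
    mu[cls == "multicellular" & !is_uni] <- mu[cls == "multicellular" & !is_uni] * cfg$fold
    mu <- mu * depth[j]
    m[, j] <- if (cfg$phi == 0) stats::rpois(n, mu)
              else stats::rnbinom(n, size = 1 / cfg$phi, mu = mu)
  }
  count_matrix(m, data.frame(sample_id = sid, stage = stages,
                             replicate = as.character(reps)))
}

#' Plant a motif into focal promoters
#'
#' Overwrites a motif-length window at a random interior position of the
#' promoter of each selected gene. Genes accessible in the focal
#' multicellular stages (per truth) are planted at `motif_rate_fg`; all other
#' genes at `motif_rate_bg`.
#'
#' @param cfg a `sim_config`.
#' @param ann focal [simulate_annotation()] output.
#' @param truth a `sim_truth`.
#' @return list with the modified `genome` and `planted` (logical per gene,
#'   named by gene id).
#' @export
simulate_motifs <- function(cfg, ann, truth) {
  set.seed(.sub_seed(cfg, 400L))
  genes <- ann$genes
  genome <- ann$genome
  acc_multi <- .species_truth(truth, "focal", "multi")[genes$gene_id]
  acc_multi[is.na(acc_multi)] <- FALSE
  rate <- ifelse(acc_multi, cfg$motif_rate_fg, cfg$motif_rate_bg)
  planted <- stats::runif(nrow(genes)) < rate
  L <- nchar(cfg$motif)
  for (i in which(planted)) {
    iv <- promoter_interval(genes[i, ], chrom_length = nchar(genome[[genes$chrom[i]]]))
    pos <- sample(seq(iv[1] + 10L, iv[2] - L - 10L), 1)  # 0-based
    substr(genome[[genes$chrom[i]]], pos + 1L, pos + L) <- cfg$motif
  }
  list(genome = genome, planted = stats::setNames(planted, genes$gene_id))
}

#' Simulate nucleus images with planted dark-area fractions
#'
#' Each image holds an elliptical nucleus with a smaller interior nucleolus;
#' dark chromatin clumps are grown around random centres until they cover
#' exactly the planted fraction of the evaluation area (nucleus minus
#' nucleolus), then Gaussian intensity noise is added and clipped to [0, 1].
#'
#' @param cfg a `sim_config`.
#' @param fracs planted dark fractions, one per image (defaults to
#'   `cfg$dark_frac` expanded to `cfg$n_images` images per group).
#' @return list with `images` (list of `nucleus_image`), `groups`, and
#'   `true_frac`.
#' @export
simulate_images <- function(cfg, fracs = NULL) {
  set.seed(.sub_seed(cfg, 600L))
  if (is.null(fracs)) {
    groups <- rep(names(cfg$dark_frac), each = cfg$n_images)
    fracs <- rep(unname(cfg$dark_frac), each = cfg$n_images)
  } else {
    groups <- rep("all", length(fracs))
  }
  sz <- cfg$img_size
  xy <- expand.grid(x = seq_len(sz), y = seq_len(sz))
  cx <- sz / 2
  nuc <- matrix(((xy$x - cx)^2 / (0.42 * sz)^2 +
                 (xy$y - cx)^2 / (0.36 * sz)^2) <= 1, sz, sz)
  nol <- matrix(((xy$x - cx * 1.2)^2 / (0.12 * sz)^2 +
                 (xy$y - cx * 0.9)^2 / (0.12 * sz)^2) <= 1, sz, sz) & nuc
  eval_mask <- nuc & !nol
  eval_idx <- which(eval_mask)
  images <- vector("list", length(fracs))
  for (k in seq_along(fracs)) {
    target <- round(fracs[k] * length(eval_idx))
    px <- matrix(0.9, sz, sz)
    px[!nuc] <- 1
    px[nol] <- 0.75
    if (target > 0) {
      centers <- sample(eval_idx, 4)
      cxy <- cbind((centers - 1) %% sz + 1, (centers - 1) %/% sz + 1)
      exy <- cbind((eval_idx - 1) %% sz + 1, (eval_idx - 1) %/% sz + 1)
      dmin <- apply(cxy, 1, function(cc)
        sqrt((exy[, 1] - cc[1])^2 + (exy[, 2] - cc[2])^2))
      dark <- eval_idx[order(apply(dmin, 1, min))[seq_len(target)]]
      px[dark] <- 0.05
    }
    px <- pmin(1, pmax(0, px + stats::rnorm(sz * sz, 0, cfg$img_noise_sd)))
    images[[k]] <- nucleus_image(matrix(px, sz, sz), nuc, nol)
  }
  list(images = images, groups = groups, true_frac = fracs)
}

#' Simulate the complete study in memory
#'
#' Runs all generators with sub-seeds derived from `cfg$seed` and returns the
#' full three-species fixture plus the planted truth.
#'
#' @param cfg a `sim_config`.
#' @param images generate nucleus images too (default FALSE; they are the
#'   slowest component and independent of the genomic pipeline).
#' @return a list of class `sim_study` with elements `focal`, `ref_uni`,
#'   `ref_multi` (each: `genome`, `genes`, and for the focal organism
#'   `counts` and per-condition replicate `peaks`), `orthologs`, `truth`,
#'   and optionally `em`.
#' @export
simulate_study <- function(cfg, images = FALSE) {
  truth <- simulate_truth(cfg)
  focal <- simulate_annotation(cfg, "focal")
  ref_uni <- simulate_annotation(cfg, "ref_uni")
  ref_multi <- simulate_annotation(cfg, "ref_multi")

  mot <- simulate_motifs(cfg, focal, truth)
  focal$genome <- mot$genome
  truth$motif_planted <- mot$planted

  focal_conditions <- c(cfg$uni_stage, cfg$multi_stages)
  focal$peaks <- lapply(stats::setNames(focal_conditions, focal_conditions),
    function(cond) lapply(seq_len(cfg$n_reps), function(r)
      simulate_peaks(cfg, focal, truth, "focal", cond, r)))
  ref_uni$peaks <- list(ref_uni = list(
    simulate_peaks(cfg, ref_uni, truth, "ref_uni", "ref_uni", 1L)))
  ref_multi$peaks <- list(ref_multi = list(
    simulate_peaks(cfg, ref_multi, truth, "ref_multi", "ref_multi", 1L)))

  focal$counts <- simulate_counts(cfg, truth)
  orthologs <- ortholog_map(truth$conserved$focal_gene_id,
                            truth$conserved$ref_uni_gene_id,
                            truth$conserved$ref_multi_gene_id)
  out <- list(focal = focal, ref_uni = ref_uni, ref_multi = ref_multi,
              orthologs = orthologs, truth = truth, config = cfg)
  if (images) out$em <- simulate_images(cfg)
  structure(out, class = "sim_study")
}

#' Write a simulated study to files
#'
#' Emits FASTA and GFF3 per species, narrowPeak files per
#' (condition, replicate), the focal counts and metadata TSVs, the ortholog
#' TSV, and the planted truth as JSON. File layout matches what
#' [run_pipeline()] consumes.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return the pipeline configuration list pointing at the written files,
#'   invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  cfg <- study$config
  peak_paths <- list()
  for (sp in c("focal", "ref_uni", "ref_multi")) {
    write_fasta(study[[sp]]$genome, p(paste0(sp, ".fa")))
    write_gff3(study[[sp]]$genes, p(paste0(sp, ".gff3")))
    for (cond in names(study[[sp]]$peaks)) {
      reps <- study[[sp]]$peaks[[cond]]
      peak_paths[[cond]] <- vapply(seq_along(reps), function(r) {
        fp <- p(sprintf("%s_%s_rep%d.narrowPeak", sp, cond, r))
        write_narrowpeak(reps[[r]], fp)
        fp
      }, character(1))
    }
  }
  write_counts(study$focal$counts, p("focal_counts.tsv"), p("focal_meta.tsv"))
  write_ortholog_tsv(study$orthologs, p("orthologs.tsv"))
  jsonlite::write_json(
    list(uni_signature = study$truth$uni_signature,
         multi_signature = study$truth$multi_signature,
         conserved = study$truth$conserved),
    p("truth.json"))
  config <- list(
    genes = list(focal = p("focal.gff3"), ref_uni = p("ref_uni.gff3"),
                 ref_multi = p("ref_multi.gff3")),
    genome = list(focal = p("focal.fa")),
    peaks = list(
      focal_uni = as.character(peak_paths[[cfg$uni_stage]]),
      focal_multi = lapply(cfg$multi_stages, function(s)
        as.character(peak_paths[[s]])),
      ref_uni = as.character(peak_paths[["ref_uni"]]),
      ref_multi = as.character(peak_paths[["ref_multi"]])),
    counts = p("focal_counts.tsv"), metadata = p("focal_meta.tsv"),
    orthologs = p("orthologs.tsv"),
    stages = list(unicellular = cfg$uni_stage,
                  multicellular = as.list(cfg$multi_stages)),
    params = list(upstream = 1500, downstream = 3000, min_cpm = 1,
                  min_samples = 2, alpha = 0.05, motif = cfg$motif,
                  region = "promoter"))
  invisible(config)
}
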