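# CPM, expression filtering, TMM, the NB exact test, dispersion estimation,
# BH correction and stage-enrichment classification.

make_cm <- function(m, stages = NULL) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  stages <- stages %||% rep("x", ncol(m))
  count_matrix(m, data.frame(sample_id = colnames(m), stage = stages,
                             replicate = as.character(seq_len(ncol(m)))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cpm scales by effective library size", {
  m <- matrix(c(10L, 0L), 1, 2, dimnames = list("g1", c("a", "b")))
  x <- cpm(m, effective_lib_sizes = c(1e6, 1e6))
  expect_equal(unname(x[1, ]), c(10, 0))
  expect_error(cpm(m, effective_lib_sizes = c(0, 1e6)), "> 0")
  set.seed(2)
  r <- matrix(rpois(12, 40), 3, 4, dimnames = list(paste0("g", 1:3),
                                                   paste0("s", 1:4)))
  expect_equal(colSums(cpm(r)), 1e6 * colSums(r) / colSums(r))
})

test_that("expression filter keeps genes with min CPM in enough samples", {
  m <- rbind(g1 = c(12L, 8L, 15L, 1L),    # cpm 1.2, 0.8, 1.5, 0.1
             g2 = c(9L, 9L, 9L, 9L))      # cpm 0.9 everywhere
  colnames(m) <- paste0("s", 1:4)
  cm <- make_cm(m)
  kept <- filter_expressed(cm, min_cpm = 1, min_samples = 2,
                           effective_lib_sizes = rep(1e7, 4))
  expect_equal(kept, "g1")
  expect_error(filter_expressed(cm, min_samples = 9), "exceeds")

  set.seed(9)
  r <- matrix(rnbinom(200, mu = 30, size = 2), 50, 4)
  cmr <- make_cm(r)
  x <- cpm(cmr)
  want <- rownames(r <- cmr$counts)[rowSums(x >= 1) >= 2]
  expect_equal(filter_expressed(cmr), want)
})

test_that("TMM gives unit factors for identical and purely rescaled samples", {
  set.seed(4)
  y <- rnbinom(400, mu = 50, size = 5) + 1L
  ident <- cbind(a = y, b = y)
  rownames(ident) <- paste0("g", seq_along(y))
  expect_equal(tmm_factors(ident)$tmm_factors, c(1, 1), tolerance = 1e-12)
  scaled <- cbind(a = y, b = 2L * y)
  rownames(scaled) <- paste0("g", seq_along(y))
  expect_equal(tmm_factors(scaled)$tmm_factors, c(1, 1), tolerance = 1e-12)
})

test_that("TMM factors have geometric mean 1 and ignore gene order", {
  set.seed(6)
  m <- matrix(rnbinom(300 * 3, mu = 60, size = 3), 300, 3,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:3)))
  m[sample(300, 40), 2] <- m[sample(300, 40), 2] * 5L
  f <- tmm_factors(m)$tmm_factors
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  perm <- sample(300)
  expect_equal(tmm_factors(m[perm, ])$tmm_factors, f)
})

test_that("TMM matches the reference implementation on mixed libraries", {
  set.seed(42)
  for (r in 1:5) {
    ns <- sample(2:4, 1)
    m <- matrix(rnbinom(250 * ns, mu = exp(runif(250 * ns, log(5), log(400))),
                        size = 5), 250, ns,
                dimnames = list(paste0("g", 1:250), paste0("s", seq_len(ns))))
    m[sample(250, 25), 1] <- m[sample(250, 25), 1] * 4L
    f_pkg <- tmm_factors(m)$tmm_factors
    f_ref <- as.numeric(edgeR::calcNormFactors(m))
    expect_equal(f_pkg, f_ref, tolerance = 0.02)
  }
})

test_that("NB exact test is symmetric, exchangeable and properly bounded", {
  expect_equal(nb_exact_test(c(5L, 5L), c(6L, 4L), phi = 0.1), 1)
  set.seed(7)
  for (i in 1:20) {
    ya <- rpois(2, 40); yb <- rpois(3, 40)
    p1 <- nb_exact_test(ya, yb, phi = 0.2)
    p2 <- nb_exact_test(yb, ya, phi = 0.2)
    expect_equal(p1, p2)
    expect_true(p1 > 0 && p1 <= 1)
  }
  expect_error(nb_exact_test(1L, 2L, phi = -0.1), ">= 0")
})

test_that("NB exact test matches direct enumeration on a representative split", {
  got <- nb_exact_test(10L, 2L, phi = 0.1, n_a = 2L, n_b = 2L)
  expect_equal(got, oracle_nb_exact(10L, 2L, 2L, 2L, 0.1), tolerance = 1e-12)
})

test_that("common dispersion is zero on constant rows and recovers phi", {
  m <- matrix(rep(c(10L, 25L, 40L), each = 4), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(estimate_common_dispersion(m, rep("a", 4)), 0)

  set.seed(15)
  mu <- exp(runif(500, log(50), log(500)))
  pois <- matrix(rpois(500 * 4, rep(mu, 4)), 500, 4)
  dimnames(pois) <- list(paste0("g", 1:500), paste0("s", 1:4))
  expect_lt(estimate_common_dispersion(pois, rep(c("a", "b"), each = 2)), 0.02)

  nb <- matrix(rnbinom(500 * 4, mu = rep(mu, 4), size = 1 / 0.2), 500, 4)
  dimnames(nb) <- dimnames(pois)
  phi_hat <- estimate_common_dispersion(nb, rep(c("a", "b"), each = 2))
  expect_gt(phi_hat, 0.1)
  expect_lt(phi_hat, 0.3)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
})

test_that("identical groups classify as even; label swap flips classes", {
  set.seed(31)
  base <- matrix(rnbinom(200 * 2, mu = 80, size = 10), 200, 2)
  m <- cbind(base, base, base, base)
  colnames(m) <- paste0("s", 1:8)
  rownames(m) <- paste0("g", 1:200)
  stages <- rep(c("veg", "str", "mnd", "frt"), each = 2)
  cm <- count_matrix(m, data.frame(sample_id = colnames(m), stage = stages,
                                   replicate = rep(c("1", "2"), 4)))
  res <- classify_stage_enrichment(cm, "veg", c("str", "mnd", "frt"))
  expect_true(all(res$class == "even"))

  # planted effects, then swap the group labels
  cfg <- sim_config(seed = 5, n_genes = 300, n_conserved = 300,
                    n_uni_signature = 40, n_multi_signature = 40)
  st <- simulate_study(cfg)
  a <- classify_stage_enrichment(st$focal$counts, "vegetative",
                                 c("streaming", "mound", "fruiting"))
  b <- classify_stage_enrichment(st$focal$counts,
                                 c("streaming", "mound", "fruiting"),
                                 "vegetative")
  flip <- c(unicellular = "multicellular", even = "even",
            multicellular = "unicellular")
  expect_equal(unname(flip[a$class]), b$class)
})
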