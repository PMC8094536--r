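# Cross-species set algebra, the chi-square association, and the
# top/bottom expression-accessibility contrast.

calls_df <- function(ids, acc, condition = "c") {
  data.frame(gene_id = ids, condition = condition, accessible = acc,
             stringsAsFactors = FALSE)
}

test_that("conserved table mirrors its inputs on a hand-built toy", {
  om <- ortholog_map(c("f1", "f2", "f3"), c("u1", "u2", "u3"),
                     c("m1", "m2", "m3"))
  enr <- data.frame(gene_id = c("f1", "f2"),
                    class = c("unicellular", "multicellular"))
  tab <- build_conserved_table(
    om,
    calls_df(c("f1", "f2", "f3"), c(TRUE, FALSE, TRUE)),
    list(calls_df(c("f1", "f2", "f3"), c(FALSE, TRUE, FALSE)),
         calls_df(c("f1", "f2", "f3"), c(FALSE, FALSE, TRUE))),
    calls_df(c("u1", "u2", "u3"), c(TRUE, FALSE, FALSE)),
    calls_df(c("m1", "m2", "m3"), c(FALSE, TRUE, FALSE)),
    enr)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$acc_focal_uni, c(TRUE, FALSE, TRUE))
  expect_equal(tab$acc_focal_multi, c(FALSE, TRUE, TRUE))  # union of stages
  expect_equal(tab$acc_ref_uni, c(TRUE, FALSE, FALSE))
  expect_equal(tab$expr_class, c("unicellular", "multicellular", "even"))
})

test_that("genes absent from a call set are inaccessible, with a warning", {
  om <- ortholog_map("f1", "u1", "m1")
  enr <- data.frame(gene_id = "f1", class = "even")
  expect_warning(
    tab <- build_conserved_table(om, calls_df("f1", TRUE), calls_df("f1", TRUE),
                                 calls_df("other", TRUE), calls_df("m1", TRUE),
                                 enr),
    "absent")
  expect_false(tab$acc_ref_uni)
})

test_that("signature calls recover planted truth and are permutation-stable", {
  cfg <- sim_config(seed = 33, n_genes = 250, n_conserved = 200,
                    n_uni_signature = 20, n_multi_signature = 30)
  truth <- simulate_truth(cfg)
  tab <- truth$conserved
  class(tab) <- c("conserved_table", "data.frame")
  sig <- call_signatures(tab)
  expect_setequal(sig$unicellular_signature, truth$uni_signature)
  expect_setequal(sig$multicellular_signature, truth$multi_signature)

  # permutation invariance and idempotence
  sig2 <- call_signatures(tab[sample(nrow(tab)), ])
  for (f in c("n_acc_focal_uni", "n_uni_shared", "n_uni_exclusive",
              "n_multi_shared", "n_multi_exclusive"))
    expect_equal(sig2[[f]], sig[[f]], info = f)
  expect_setequal(sig2$multicellular_signature, sig$multicellular_signature)

  # percentages recompute exactly from their counts
  expect_equal(sig$pct_uni_shared,
               round_half_up(100 * sig$n_uni_shared / sig$n_acc_focal_uni, 1))
  expect_equal(sig$pct_multi_exclusive,
               round_half_up(100 * sig$n_multi_exclusive / sig$n_acc_focal_multi, 1))
  expect_error(call_signatures(tab[0, ]), "empty")
})

test_that("signature recall degrades monotonically with accessibility noise", {
  base_truth <- simulate_truth(sim_config(seed = 44, n_genes = 300,
                                          n_conserved = 300,
                                          n_uni_signature = 40,
                                          n_multi_signature = 40))
  recall <- vapply(c(0, 0.05, 0.2), function(eps) {
    set.seed(99)
    tab <- base_truth$conserved
    for (col in c("acc_focal_uni", "acc_focal_multi", "acc_ref_uni",
                  "acc_ref_multi")) {
      flip <- runif(nrow(tab)) < eps
      tab[[col]] <- xor(tab[[col]], flip)
    }
    class(tab) <- c("conserved_table", "data.frame")
    sig <- call_signatures(tab)
    mean(base_truth$uni_signature %in% sig$unicellular_signature)
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  expect_equal(recall[1], 1)
})

test_that("Pearson chi-square matches the closed form and its scale property", {
  r <- chisq_from_table(matrix(c(50, 10, 10, 50), 2, byrow = TRUE))
  expect_equal(r$chi2, 160 / 3)
  expect_equal(r$df, 1L)
  flat <- chisq_from_table(matrix(25, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$pvalue, 1)
  doubled <- chisq_from_table(2 * matrix(c(50, 10, 10, 50), 2, byrow = TRUE))
  expect_equal(doubled$chi2, 2 * r$chi2)
  small <- chisq_from_table(matrix(c(1, 0, 0, 1), 2))
  expect_match(small$warning, "expected cell")
  expect_gte(small$chi2, 0)
  # cross-check against the standard implementation
  ref <- suppressWarnings(chisq.test(matrix(c(50, 10, 10, 50), 2),
                                     correct = FALSE))
  expect_equal(r$chi2, unname(ref$statistic))
  expect_equal(r$pvalue, ref$p.value)
})

test_that("accessibility-expression association builds the right 2x2 table", {
  ids <- paste0("g", 1:8)
  enr <- data.frame(gene_id = ids,
                    class = c("unicellular", "unicellular", "multicellular",
                              "multicellular", "even", "unicellular",
                              "multicellular", "unicellular"))
  acc_u <- calls_df(ids, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  acc_m <- calls_df(ids, c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  # g5 is even, g6/g7 accessible in both, g8 uni-class but multi-accessible
  r <- accessibility_expression_association(enr, acc_u, acc_m)
  expect_equal(unname(r$table["unicellular", "acc_unicellular_only"]), 2)
  expect_equal(unname(r$table["multicellular", "acc_multicellular_only"]), 2)
  expect_equal(unname(r$table["unicellular", "acc_multicellular_only"]), 1)
  expect_equal(sum(r$table), 5)
})

test_that("planted accessibility-expression coupling yields a large chi2", {
  set.seed(55)
  n <- 400
  ids <- paste0("g", seq_len(n))
  cls <- sample(c("unicellular", "multicellular"), n, replace = TRUE)
  match_side <- runif(n) < 0.9
  acc_uni_only <- ifelse(cls == "unicellular", match_side, !match_side)
  enr <- data.frame(gene_id = ids, class = cls)
  r <- accessibility_expression_association(
    enr, calls_df(ids, acc_uni_only), calls_df(ids, !acc_uni_only))
  expect_gt(r$chi2, 100)
  expect_lt(r$pvalue, 1e-10)
})

test_that("top/bottom accessibility contrast detects planted correlation", {
  set.seed(66)
  n <- 2000
  mu <- exp(runif(n, log(5), log(5000)))
  m <- matrix(rpois(2 * n, rep(mu, 2)), n, 2,
              dimnames = list(paste0("g", 1:n), c("s1", "s2")))
  cm <- count_matrix(m, data.frame(sample_id = c("s1", "s2"),
                                   stage = c("veg", "veg"),
                                   replicate = c("1", "2")))
  # accessibility correlated with expression
  acc <- runif(n) < (rank(mu) / n)
  r <- top_bottom_accessibility_contrast(cm, calls_df(rownames(m), acc),
                                         "veg", k = 200)
  expect_gt(r$frac_accessible_top, r$frac_accessible_bottom)

  # uniform accessibility: tails differ by less than 0.1
  acc0 <- runif(n) < 0.5
  r0 <- top_bottom_accessibility_contrast(cm, calls_df(rownames(m), acc0),
                                          "veg", k = 200)
  expect_lt(abs(r0$frac_accessible_top - r0$frac_accessible_bottom), 0.1)
  expect_error(top_bottom_accessibility_contrast(cm, calls_df(rownames(m), acc0),
                                                 "veg", k = 5000), "exceeds")
})
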