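mk_labeled <- function(n, labels, docs_per_class = 10) {
  k <- length(labels)
  data.frame(
    assay_id = sprintf("A%03d", seq_len(n)),
    label = rep(labels, length.out = n),
    document_id = sprintf("D%02d", rep(seq_len(k * docs_per_class),
                                       length.out = n)),
    stringsAsFactors = FALSE)
}

# two linearly separable Gaussian classes in feature space
mk_separable <- function(n, p = 10, shift = 4, seed = 1) {
  set.seed(seed)
  lab <- mk_labeled(n, c("pos", "neg"))
  X <- matrix(rnorm(n * p), n, p)
  X[lab$label == "pos", 1] <- X[lab$label == "pos", 1] + shift
  rownames(X) <- lab$assay_id
  list(labeled = lab, X = X)
}

test_that("ATC class labeling applies the unambiguity rule", {
  assays <- data.frame(
    assay_id = c("A1", "A2", "A3", "A4"),
    description = "x", species = "rat",
    document_id = c("D1", "D1", "D2", "D3"), stringsAsFactors = FALSE)
  assays$compound_ids <- list("C1", c("C1", "C2"), "C3", "C4")
  compounds <- data.frame(
    compound_id = c("C1", "C2", "C3", "C4"),
    name = c("aed", "antidiabetic", "novel", "multi"),
    max_phase = c(4L, 4L, 0L, 4L), stringsAsFactors = FALSE)
  compounds$atc_codes <- list("N03AX09", "A10BA02", character(),
                              c("C01EB03", "M01AB01", "M02AA23", "S01BC01"))
  lab <- assign_class_labels(assays, compounds, links = NULL,
                             problem = class_problem("top5_multiclass"))
  # A1: single class; A2: N03 + A10 -> ambiguous; A3: no approved drug;
  # A4: indomethacin-style multi-code drug maps to one class via the code set
  expect_equal(lab$label[lab$assay_id == "A1"], "antiepileptics")
  expect_false("A2" %in% lab$assay_id)
  expect_false("A3" %in% lab$assay_id)
  expect_equal(lab$label[lab$assay_id == "A4"], "anti_inflammatory")
  excl <- attr(lab, "exclusions")
  expect_equal(unname(excl[["ambiguous"]]), 1L)
  expect_equal(unname(excl[["no_approved_drug"]]), 1L)

  # binary problems map unlisted prefixes to the complement class
  lab2 <- assign_class_labels(assays, compounds, problem = class_problem("cidal_binary"))
  expect_equal(lab2$label[lab2$assay_id == "A1"], "non_cidal")
  lab3 <- assign_class_labels(assays, compounds, problem = class_problem("nervous_binary"))
  expect_equal(lab3$label[lab3$assay_id == "A1"], "nervous")
  expect_equal(lab3$label[lab3$assay_id == "A4"], "other")
  # class code sets are pairwise disjoint in every problem
  for (p in c("cidal_binary", "nervous_binary", "top5_multiclass",
              "nervous_subclass")) {
    cp <- class_problem(p)
    expect_false(anyDuplicated(unlist(cp$classes)) > 0)
  }
})

test_that("fold assignment balances assays and never splits documents", {
  lab <- mk_labeled(100, c("a", "b"))
  f <- make_folds(lab, "assay", k = 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(10L, 10))
  # determinism
  expect_identical(f, make_folds(lab, "assay", k = 10, seed = 1))
  expect_false(identical(f, make_folds(lab, "assay", k = 10, seed = 2)))

  # 10 documents x 5 assays, k = 10: each fold is exactly one document
  lab2 <- data.frame(assay_id = sprintf("A%02d", 1:50), label = "a",
                     document_id = rep(sprintf("D%02d", 1:10), each = 5),
                     stringsAsFactors = FALSE)
  f2 <- make_folds(lab2, "document", k = 10, seed = 3)
  expect_true(all(tapply(f2, lab2$document_id, function(x) length(unique(x))) == 1))
  expect_equal(sort(as.integer(table(f2))), rep(5L, 10))
  # fewer documents than folds is an error
  lab3 <- mk_labeled(20, "a", docs_per_class = 5)
  expect_error(make_folds(lab3, "document", k = 10, seed = 1), "at least k")
})

test_that("random-forest CV separates separable classes and reports honestly", {
  sep <- mk_separable(200, seed = 4)
  folds <- make_folds(sep$labeled, "assay", k = 10, seed = 4)
  rep <- cross_validate_rf(sep$labeled, sep$X, folds, n_trees = 100, seed = 4)
  expect_gte(rep$accuracy, 0.95)
  expect_gte(rep$oob_estimate, 0.9)
  # confusion-matrix identities
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion), rep$accuracy)
  expect_equal(unname(rowSums(rep$confusion)),
               rep$per_class$support[match(rownames(rep$confusion),
                                           rep$per_class$class)])
  # determinism
  rep2 <- cross_validate_rf(sep$labeled, sep$X, folds, n_trees = 100, seed = 4)
  expect_equal(rep$accuracy, rep2$accuracy)
  expect_equal(rep$confusion, rep2$confusion)
  # single-class input rejected
  one <- sep$labeled; one$label <- "same"
  expect_error(cross_validate_rf(one, sep$X, folds), "two classes")
})

test_that("permuted labels collapse CV accuracy to chance", {
  sep <- mk_separable(200, seed = 6)
  accs <- vapply(1:5, function(s) {
    lab <- sep$labeled
    set.seed(s)
    lab$label <- sample(lab$label)
    folds <- make_folds(lab, "assay", k = 10, seed = s)
    cross_validate_rf(lab, sep$X, folds, n_trees = 100, seed = s)$accuracy
  }, numeric(1))
  expect_true(all(abs(accs - 0.5) <= 0.1))
})

test_that("Fisher enrichment matches exact hypergeometric values", {
  # forced case: phrase in 3/3 in-class, 0/3 out-of-class -> p = 1/C(6,3)
  expect_equal(vm_fisher_greater(3, 3, 3, 3), 0.05)
  # phrase in every assay of both groups -> p = 1
  expect_equal(vm_fisher_greater(3, 3, 3, 6), 1)

  phrase_table <- data.frame(
    assay_id = c("A1", "A2", "A3", "A4", "A5", "A6"),
    phrase = c(rep("paw_edema", 3), rep("seizures", 3)),
    stringsAsFactors = FALSE)
  labels <- data.frame(assay_id = sprintf("A%d", 1:6),
                       label = rep(c("inflam", "epi"), each = 3),
                       stringsAsFactors = FALSE)
  enr <- enriched_phrases(phrase_table, labels)
  expect_equal(enr$p_value[enr$label == "inflam" & enr$phrase == "paw_edema"],
               0.05)
  expect_equal(enr$rank[enr$label == "inflam" & enr$phrase == "paw_edema"], 1L)

  # independent oracle: explicit combinatorial enumeration
  oracle <- function(k, n_in, n_out, draws) {
    js <- k:min(n_in, draws)
    sum(choose(n_in, js) * choose(n_out, draws - js)) / choose(n_in + n_out, draws)
  }
  set.seed(11)
  for (i in 1:200) {
    n_in <- sample(0:20, 1); n_out <- sample(0:20, 1)
    draws <- sample(0:(n_in + n_out), 1)
    k <- sample(0:min(n_in, draws), 1)
    expect_equal(vm_fisher_greater(k, n_in, n_out, draws),
                 oracle(k, n_in, n_out, draws), tolerance = 1e-12)
  }
})
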