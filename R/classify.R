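#' The four ATC classification problems
#'
#' Each problem maps class names to sets of ATC level-2 prefixes (the first
#' three characters of a full code):
#' * `cidal_binary` — cidal/cytotoxic drugs (antineoplastics L01,
#'   antibacterials J01, other anti-infectives J02/J04/J05, antiprotozoals
#'   P01 and other antiparasitics P02/P03) versus all other approved drugs.
#' * `nervous_binary` — any nervous-system drug (ATC level 1 "N") versus
#'   the rest.
#' * `top5_multiclass` — the five most common therapeutic groups:
#'   antiepileptics (N03), psycholeptics (N05), antineoplastics (L01),
#'   antidiabetics (A10) and anti-inflammatory drugs (the C01/M01/M02/S01
#'   combination carried by indomethacin).
#' * `nervous_subclass` — six nervous-system subgroups: N03, N05, N02,
#'   N06, N04, N01.
#'
#' The cidal code set beyond the four printed prefixes is an editable
#' default. For the binary problems the complement class is written
#' `"other"` and matches any approved drug whose codes hit no listed
#' prefix.
#'
#' @param name problem name.
#' @return a `vm_class_problem`: list with `name`, `classes` (named list of
#'   prefix vectors) and `complement` (name of the catch-all class or NA).
#' @export
class_problem <- function(name = c("cidal_binary", "nervous_binary",
                                   "top5_multiclass", "nervous_subclass")) {
  name <- match.arg(name)
  spec <- switch(name,
    cidal_binary = list(
      classes = list(cidal = c("L01", "J01", "J02", "J04", "J05",
                               "P01", "P02", "P03")),
      complement = "non_cidal"),
    nervous_binary = list(
      classes = list(nervous = paste0("N0", 1:9)),
      complement = "other"),
    top5_multiclass = list(
      classes = list(antiepileptics = "N03",
                     psycholeptics = "N05",
                     antineoplastics = "L01",
                     antidiabetics = "A10",
                     anti_inflammatory = c("C01", "M01", "M02", "S01")),
      complement = NA_character_),
    nervous_subclass = list(
      classes = list(antiepileptics = "N03",
                     psycholeptics = "N05",
                     analgesics = "N02",
                     psychoanaleptics = "N06",
                     antiparkinsonians = "N04",
                     anaesthetics = "N01"),
      complement = NA_character_))
  # prefix sets must be pairwise disjoint within a problem
  all_codes <- unlist(spec$classes, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    stop("class code sets overlap in problem ", name)
  }
  structure(list(name = name, classes = spec$classes,
                 complement = spec$complement),
            class = "vm_class_problem")
}

# ATC level-2 prefix (first 3 characters) of a full or partial code
vm_atc_level2 <- function(codes) {
  codes <- codes[nchar(codes) >= 3]
  unique(substr(codes, 1, 3))
}

#' Label assays by the ATC class of their reference drugs
#'
#' For each assay, collects the ATC level-2 prefixes of all approved drugs
#' (development phase 4) tested in it, maps them onto the problem's
#' classes, and keeps the assay if and only if exactly one class results
#' (the unambiguity rule). For binary problems, approved drugs matching no
#' listed prefix map to the complement class. Excluded assays are reported
#' with reason codes (`no_approved_drug`, `no_atc_class`, `ambiguous`).
#'
#' @param assays assay table.
#' @param compounds compound table with `atc_codes` and `max_phase`.
#' @param links optional assay-compound link table.
#' @param problem a [class_problem()].
#' @return data.frame `assay_id`, `label`, `document_id`; attribute
#'   `exclusions` tabulates the reason codes.
#' @export
assign_class_labels <- function(assays, compounds, links = NULL,
                                problem = class_problem("top5_multiclass")) {
  ac <- vm_assay_compounds(assays, links)
  appr <- compounds[compounds$max_phase == 4L, , drop = FALSE]
  code_of <- stats::setNames(appr$atc_codes, appr$compound_id)
  out <- data.frame(assay_id = character(), label = character(),
                    document_id = character(), stringsAsFactors = FALSE)
  reasons <- character()
  for (i in seq_len(nrow(assays))) {
    cids <- intersect(ac[[i]], appr$compound_id)
    if (!length(cids)) { reasons <- c(reasons, "no_approved_drug"); next }
    prefixes <- vm_atc_level2(unlist(code_of[cids], use.names = FALSE))
    if (!length(prefixes)) { reasons <- c(reasons, "no_atc_class"); next }
    hit <- names(problem$classes)[vapply(problem$classes,
                                         function(p) any(prefixes %in% p),
                                         logical(1))]
    if (!is.na(problem$complement) &&
        any(!prefixes %in% unlist(problem$classes))) {
      hit <- union(hit, problem$complement)
    }
    if (!length(hit)) { reasons <- c(reasons, "no_atc_class"); next }
    if (length(hit) > 1L) { reasons <- c(reasons, "ambiguous"); next }
    out <- rbind(out, data.frame(assay_id = assays$assay_id[i], label = hit,
                                 document_id = assays$document_id[i],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- table(reasons)
  attr(out, "problem") <- problem$name
  out
}

#' Cross-validation fold assignment
#'
#' Randomly partitions labeled assays into `k` folds, either assay-wise
#' (plain random split into near-equal folds) or document-wise: documents
#' are randomly assigned to folds so that all assays curated from one
#' publication share a fold, which prevents near-duplicate descriptions
#' from leaking between train and test.
#'
#' @param labeled output of [assign_class_labels()].
#' @param method `"assay"` or `"document"`.
#' @param k number of folds (default 10).
#' @param seed integer seed; the same seed always yields the same folds.
#' @return integer vector of fold indices (1..k) aligned with `labeled`;
#'   attributes `method`, `k`, `seed`.
#' @export
make_folds <- function(labeled, method = c("assay", "document"), k = 10L,
                       seed = 1L) {
  method <- match.arg(method)
  n <- nrow(labeled)
  if (k < 2L) stop("k must be at least 2")
  rng <- vm_rng(seed)
  if (method == "assay") {
    fold <- rep(seq_len(k), length.out = n)[vm_sample(rng, n)]
  } else {
    docs <- unique(labeled$document_id)
    if (length(docs) < k) {
      stop("document split needs at least k = ", k, " distinct documents, got ",
           length(docs))
    }
    dfold <- rep(seq_len(k), length.out = length(docs))[vm_sample(rng, length(docs))]
    fold <- dfold[match(labeled$document_id, docs)]
  }
  structure(as.integer(fold), method = method, k = k, seed = seed)
}

# small deterministic RNG (xorshift) so folds do not disturb .Random.seed
vm_rng <- function(seed) {
  e <- new.env()
  e$s <- as.numeric(seed) %% 2147483647 + 1
  e
}
vm_rng_next <- function(rng) {
  # Park-Miller minimal standard generator
  rng$s <- (rng$s * 48271) %% 2147483647
  rng$s / 2147483647
}
vm_sample <- function(rng, n) {
  # Fisher-Yates permutation driven by the package RNG
  idx <- seq_len(n)
  if (n < 2) return(idx)
  for (i in n:2) {
    j <- floor(vm_rng_next(rng) * i) + 1
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx
}

#' Random-forest cross-validation over assay vectors
#'
#' Runs k-fold cross-validation of a random-forest classifier (200 trees by
#' default, Gini splits, `sqrt(p)` features per split, balanced class
#' weights `n/(K * n_c)`) on unit assay vectors. Pooled held-out
#' predictions give the confusion matrix and per-class report; an
#' out-of-bag estimate comes from a fit on the full labeled set. Folds in
#' which a test class is absent from training are predicted anyway and the
#' condition is noted in the report's warnings.
#'
#' @param labeled output of [assign_class_labels()].
#' @param features numeric matrix of assay vectors with rownames matching
#'   `labeled$assay_id`.
#' @param folds fold assignment from [make_folds()].
#' @param n_trees trees per forest (default 200).
#' @param seed integer seed.
#' @return object of class `vm_classification_report`.
#' @export
cross_validate_rf <- function(labeled, features, folds, n_trees = 200L,
                              seed = 1L) {
  stopifnot(nrow(labeled) == length(folds))
  X <- features[labeled$assay_id, , drop = FALSE]
  if (any(!is.finite(X))) stop("non-finite feature values")
  classes <- sort(unique(labeled$label))
  K <- length(classes)
  if (K < 2L) stop("need at least two classes, got ", K)
  y <- match(labeled$label, classes) - 1L
  mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  balanced_weights <- function(yy) {
    tab <- tabulate(yy + 1L, nbins = K)
    w <- length(yy) / (K * pmax(tab, 1L))
    w[tab == 0] <- 0
    w
  }
  pooled_pred <- integer(n); pooled_prob <- matrix(NA_real_, n, K)
  warnings <- character()
  k <- attr(folds, "k")
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    if (!length(te)) next
    miss <- setdiff(unique(y[te]), unique(y[tr]))
    if (length(miss)) {
      warnings <- c(warnings, paste0(
        "fold ", f, ": class(es) ", paste(classes[miss + 1L], collapse = ", "),
        " absent from training folds"))
    }
    fit <- vm_rf_cpp(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE],
                     K, as.integer(n_trees), mtry,
                     balanced_weights(y[tr]), vm_derive_seed(seed, f))
    pooled_prob[te, ] <- fit$prob_test
    pooled_pred[te] <- max.col(fit$prob_test, ties.method = "first") - 1L
  }
  cm <- table(factor(classes[y + 1L], levels = classes),
              factor(classes[pooled_pred + 1L], levels = classes))
  acc_pooled <- sum(diag(cm)) / sum(cm)
  acc_folds <- vapply(seq_len(k), function(f) {
    te <- which(folds == f)
    if (!length(te)) return(NA_real_)
    mean(pooled_pred[te] == y[te])
  }, numeric(1))
  per_class <- do.call(rbind, lapply(seq_along(classes), function(ki) {
    tp <- cm[ki, ki]; fp <- sum(cm[, ki]) - tp; fn <- sum(cm[ki, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(class = classes[ki], precision = p, recall = r,
               f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
               support = sum(cm[ki, ]), stringsAsFactors = FALSE)
  }))
  # OOB estimate from a fit on the full labeled set
  full <- vm_rf_cpp(X, y, X[0, , drop = FALSE], K, as.integer(n_trees), mtry,
                    balanced_weights(y), vm_derive_seed(seed, 0L))
  seen <- full$oob_count > 0
  oob_pred <- max.col(full$oob_prob, ties.method = "first") - 1L
  oob <- if (any(seen)) mean(oob_pred[seen] == y[seen]) else NA_real_
  structure(list(
    accuracy = acc_pooled,
    accuracy_mean_folds = mean(acc_folds, na.rm = TRUE),
    per_class = per_class,
    confusion = cm,
    oob_estimate = oob,
    problem = attr(labeled, "problem"),
    split_method = attr(folds, "method"),
    k = k, n_trees = as.integer(n_trees), seed = as.integer(seed),
    classes = classes, warnings = warnings),
    class = "vm_classification_report")
}

#' @export
print.vm_classification_report <- function(x, ...) {
  cat(sprintf("Random-forest CV report (%s split, %d folds, %d trees, seed %d)\n",
              x$split_method, x$k, x$n_trees, x$seed))
  cat(sprintf("  pooled accuracy %.3f | mean-over-folds %.3f | OOB %.3f\n",
              x$accuracy, x$accuracy_mean_folds, x$oob_estimate))
  print(x$per_class, digits = 3, row.names = FALSE)
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Fisher-exact phrase enrichment per class
#'
#' For every class and phrase, tests over-representation of the phrase in
#' the class's assays with a one-sided Fisher exact test on the 2x2 table
#' (phrase present/absent x in-class/out-of-class), computed from the
#' hypergeometric distribution. Phrases are ranked by ascending p-value,
#' ties broken by descending in-class frequency then lexicographically.
#'
#' @param phrase_table data.frame with columns `assay_id`, `phrase`
#'   (presence of a phrase in an assay; duplicates ignored).
#' @param labels data.frame `assay_id`, `label` covering the assays.
#' @param top_k phrases to keep per class (default 5).
#' @return data.frame `label`, `phrase`, `n_in`, `n_out`, `p_value`, `rank`.
#' @export
enriched_phrases <- function(phrase_table, labels, top_k = 5L) {
  pt <- unique(phrase_table[, c("assay_id", "phrase")])
  pt <- pt[pt$assay_id %in% labels$assay_id, , drop = FALSE]
  lab_of <- stats::setNames(labels$label, labels$assay_id)
  n_total <- nrow(labels)
  out <- list()
  for (cls in sort(unique(labels$label))) {
    in_ids <- labels$assay_id[labels$label == cls]
    n_in_cls <- length(in_ids)
    phr <- unique(pt$phrase)
    if (!length(phr)) next
    rows <- do.call(rbind, lapply(phr, function(ph) {
      ids <- pt$assay_id[pt$phrase == ph]
      k_in <- sum(ids %in% in_ids)
      k_out <- length(ids) - k_in
      data.frame(label = cls, phrase = ph, n_in = k_in, n_out = k_out,
                 p_value = vm_fisher_greater(k_in, n_in_cls,
                                             n_total - n_in_cls,
                                             k_in + k_out),
                 stringsAsFactors = FALSE)
    }))
    rows <- rows[order(rows$p_value, -rows$n_in, rows$phrase), , drop = FALSE]
    rows$rank <- seq_len(nrow(rows))
    out[[cls]] <- utils::head(rows, top_k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sided Fisher exact p-value (over-representation)
#'
#' P(X >= k) for X hypergeometric: `k` of the `n_draws` assays containing
#' the phrase fall in a class of size `n_in` out of `n_in + n_out` assays.
#'
#' @param k in-class assays containing the phrase.
#' @param n_in class size.
#' @param n_out out-of-class size.
#' @param n_draws total assays containing the phrase.
#' @return p-value.
#' @export
vm_fisher_greater <- function(k, n_in, n_out, n_draws) {
  if (n_draws == 0) return(1)
  stats::phyper(k - 1, n_in, n_out, n_draws, lower.tail = FALSE)
}
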