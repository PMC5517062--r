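# small co-occurrence corpus: A and B always share contexts, C never does
cooccur_corpus <- function(n = 500, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ab <- sample(c("tokA", "tokB"), 1)
    if (i %% 2 == 0) c("ctx1", ab, "ctx2", "ctx3")
    else c("ctx4", "tokC", "ctx5", "ctx6")
  })
}

test_that("vocabulary respects the minimum-count threshold", {
  corpus <- c(rep(list(c("rare", "common")), 29),
              rep(list(c("common", "filler")), 31))
  m <- train_embeddings(corpus, dim = 8, min_count = 30, epochs = 1, seed = 1)
  expect_false("rare" %in% rownames(m$vectors))   # 29 occurrences < 30
  expect_true("common" %in% rownames(m$vectors))  # 60 occurrences
  expect_error(train_embeddings(list(c("a", "b")), min_count = 30, seed = 1),
               "empty vocabulary")
})

test_that("shared contexts give higher cosine than disjoint contexts", {
  for (sd in 1:3) {
    m <- train_embeddings(cooccur_corpus(seed = sd), dim = 16, window = 5,
                          min_count = 5, epochs = 10, seed = sd)
    expect_gt(cosine_similarity(m, "tokA", "tokB"),
              cosine_similarity(m, "tokA", "tokC"))
  }
  # both architectures recover the planted structure
  ms <- train_embeddings(cooccur_corpus(seed = 1), dim = 16, window = 5,
                         min_count = 5, epochs = 10, seed = 1,
                         architecture = "skipgram")
  expect_gt(cosine_similarity(ms, "tokA", "tokB"),
            cosine_similarity(ms, "tokA", "tokC"))
})

test_that("training is reproducible for a fixed seed", {
  m1 <- train_embeddings(cooccur_corpus(seed = 2), dim = 16, min_count = 5,
                         epochs = 3, seed = 42)
  m2 <- train_embeddings(cooccur_corpus(seed = 2), dim = 16, min_count = 5,
                         epochs = 3, seed = 42)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- train_embeddings(cooccur_corpus(seed = 2), dim = 16, min_count = 5,
                         epochs = 3, seed = 43)
  expect_false(identical(m1$vectors, m3$vectors))
})

test_that("nearest-term queries exclude the query and rank by cosine", {
  m <- train_embeddings(cooccur_corpus(), dim = 16, min_count = 5,
                        epochs = 10, seed = 1)
  expect_equal(cosine_similarity(m, "tokA", "tokA"), 1.0, tolerance = 1e-12)
  nn <- nearest_terms(m, "tokA", k = 5)
  expect_false("tokA" %in% nn$token)
  expect_true(all(diff(nn$cosine) <= 1e-12))
  expect_error(nearest_terms(m, "unseen"), "unseen")
  # cosine symmetry across the vocabulary
  v <- rownames(m$vectors)
  for (i in 1:3) {
    p <- sample(v, 2)
    expect_equal(cosine_similarity(m, p[1], p[2]),
                 cosine_similarity(m, p[2], p[1]), tolerance = 1e-12)
  }
})

test_that("analogy with a == b reduces to nearest neighbours of c", {
  m <- train_embeddings(cooccur_corpus(), dim = 16, min_count = 5,
                        epochs = 10, seed = 1)
  an <- analogy_query(m, "ctx1", "ctx1", "tokC", k = 3)
  nn <- nearest_terms(m, "tokC", k = 4)
  nn <- nn[nn$token != "ctx1", ]
  expect_equal(an$token, head(nn$token, 3))
  expect_error(analogy_query(m, "ctx1", "nope", "tokC"), "nope")
})

test_that("assay vectors are unit-norm means with a degenerate contract", {
  m <- train_embeddings(cooccur_corpus(), dim = 16, min_count = 5,
                        epochs = 5, seed = 1)
  # single token: that vector normalized
  v1 <- assay_vector(m, "tokA")
  expect_equal(sum(v1^2), 1, tolerance = 1e-9)
  expect_equal(drop(v1 %*% m$vectors["tokA", ]) /
                 sqrt(sum(m$vectors["tokA", ]^2)), 1, tolerance = 1e-9)
  # two tokens equal the direct arithmetic
  v2 <- assay_vector(m, c("tokA", "tokC"))
  ref <- (m$vectors["tokA", ] + m$vectors["tokC", ]) / 2
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(unname(as.numeric(v2)), unname(ref), tolerance = 1e-12)
  # OOV tokens ignored; all-OOV flagged zero vector
  v3 <- assay_vector(m, c("tokA", "zzz"))
  expect_equal(unname(as.numeric(v3)), unname(as.numeric(v1)), tolerance = 1e-12)
  v0 <- assay_vector(m, c("zzz", "qqq"))
  expect_true(attr(v0, "degenerate"))
  expect_equal(sum(v0^2), 0)
})

test_that("similarity matrices Z-score rows and cluster by average linkage", {
  m <- train_embeddings(cooccur_corpus(), dim = 16, min_count = 5,
                        epochs = 10, seed = 1)
  v <- rownames(m$vectors)
  sm <- similarity_matrix(m, v, v)
  expect_true(all(abs(diag(sm$raw) - 1) < 1e-9))
  expect_equal(sm$raw, t(sm$raw), tolerance = 1e-12)
  expect_true(all(sm$raw >= -1 - 1e-9 & sm$raw <= 1 + 1e-9))
  # each Z-scored row has mean 0, sd 1
  expect_true(all(abs(rowMeans(sm$zscored)) < 1e-9))
  expect_true(all(abs(apply(sm$zscored, 1, sd) - 1) < 1e-9))
  expect_error(similarity_matrix(m, c(v[1], "missing")), "missing")

  # 3x3 linkage equals brute-force average-linkage agglomeration
  sm3 <- similarity_matrix(m, v[1:3], v)
  z <- sm3$zscored
  d <- as.matrix(dist(z))
  # first merge: closest pair; second merge height: average distance from
  # the remaining singleton to the pair's members
  pair <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
  rest <- setdiff(1:3, pair)
  h <- sm3$row_hclust$height
  expect_equal(h[1], d[pair[1], pair[2]], tolerance = 1e-12)
  expect_equal(h[2], mean(d[rest, pair]), tolerance = 1e-12)
})

test_that("2-D projection reduces via PCA and separates planted clusters", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40 * 6, mean = 0), ncol = 6),
             matrix(rnorm(40 * 6, mean = 6), ncol = 6))
  Y <- project_assays_2d(X, seed = 9, perplexity = 10)
  expect_equal(dim(Y), c(80L, 2L))
  expect_equal(attr(Y, "seed"), 9)
  lab <- rep(1:2, each = 40)
  # silhouette of the planted two-cluster structure in 2-D
  D <- as.matrix(dist(Y))
  sil <- vapply(seq_len(nrow(Y)), function(i) {
    a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  # rank-2 input: 20-component PCA stage is lossless
  R2 <- matrix(rnorm(30 * 2), ncol = 2) %*% matrix(rnorm(2 * 10), nrow = 2)
  pc <- prcomp(R2, center = TRUE)
  keep <- min(20, ncol(pc$x))
  recon <- pc$x[, 1:keep] %*% t(pc$rotation[, 1:keep])
  recon <- sweep(recon, 2, -pc$center)
  expect_equal(recon, R2, tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated rows land on near-coincident points
  X2 <- rbind(X, X[1, ], X[1, ])
  Y2 <- project_assays_2d(X2, seed = 9, perplexity = 10)
  n <- nrow(Y2)
  dup_dist <- sqrt(sum((Y2[n, ] - Y2[n - 1, ])^2))
  span <- max(dist(Y2))
  expect_lt(dup_dist, span * 0.05)
  expect_error(project_assays_2d(X[1:2, ], seed = 1), "at least 3")
})

test_that("plain-text export round-trips vocabulary and vectors", {
  m <- train_embeddings(cooccur_corpus(), dim = 8, min_count = 5,
                        epochs = 2, seed = 1)
  path <- tempfile(fileext = ".vec")
  write_embedding(m, path)
  back <- read_embedding(path)
  expect_equal(rownames(back$vectors), rownames(m$vectors))
  expect_equal(back$vectors, m$vectors, tolerance = 1e-6)
})
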