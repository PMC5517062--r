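#' Train a word-embedding model on the token corpus
#'
#' Learns dense vector representations of corpus tokens (words, joined noun
#' phrases, normalized strain names) with a single-threaded CBOW or
#' skip-gram model with negative sampling. Defaults follow the analysis the
#' package implements: 250 features, context window 5, minimum token
#' frequency 30. Training is deterministic for a fixed seed.
#'
#' @param token_corpus list of character vectors, one per assay description
#'   (the output of [tokens_for_embedding()] across the corpus).
#' @param dim embedding dimensionality (default 250).
#' @param window maximum distance between current and predicted token
#'   (default 5).
#' @param min_count minimum token frequency for vocabulary inclusion
#'   (default 30).
#' @param architecture `"cbow"` (default) or `"skipgram"`.
#' @param epochs training iterations over the corpus (default 5).
#' @param negative number of negative samples per update (default 5).
#' @param alpha initial learning rate.
#' @param sample frequency-subsampling threshold; 0 (default) disables
#'   subsampling so small corpora keep all planted tokens.
#' @param seed integer seed recorded in the model metadata.
#' @return object of class `vm_embedding`: `vectors` (vocabulary x dim
#'   matrix with token rownames), `counts`, and `params`.
#' @export
train_embeddings <- function(token_corpus, dim = 250L, window = 5L,
                             min_count = 30L,
                             architecture = c("cbow", "skipgram"),
                             epochs = 5L, negative = 5L, alpha = 0.025,
                             sample = 0, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(is.list(token_corpus))
  tokens <- unlist(token_corpus, use.names = FALSE)
  if (!length(tokens)) stop("empty corpus")
  cnt <- table(tokens)
  cnt <- cnt[cnt >= min_count]
  if (!length(cnt)) {
    stop("empty vocabulary: no token reaches min_count = ", min_count)
  }
  # stable ordering: frequency descending, token ascending
  ord <- order(-as.integer(cnt), names(cnt))
  vocab <- names(cnt)[ord]
  counts <- as.integer(cnt)[ord]
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  sentences <- lapply(token_corpus, function(s) {
    v <- idx[s]
    as.integer(v[!is.na(v)])
  })
  vecs <- vm_w2v_train_cpp(sentences, counts, as.integer(dim),
                           as.integer(window), as.integer(negative),
                           as.integer(epochs), alpha,
                           architecture == "cbow", sample, as.integer(seed))
  rownames(vecs) <- vocab
  structure(list(vectors = vecs, counts = stats::setNames(counts, vocab),
                 params = list(dim = as.integer(dim), window = as.integer(window),
                               min_count = as.integer(min_count),
                               architecture = architecture,
                               epochs = as.integer(epochs),
                               negative = as.integer(negative),
                               alpha = alpha, sample = sample,
                               seed = as.integer(seed))),
            class = "vm_embedding")
}

#' @export
print.vm_embedding <- function(x, ...) {
  p <- x$params
  cat(sprintf("Embedding model: %d tokens x %d dims (%s, window %d, min_count %d, seed %d)\n",
              nrow(x$vectors), p$dim, p$architecture, p$window, p$min_count, p$seed))
  invisible(x)
}

vm_check_vocab <- function(model, tokens) {
  miss <- setdiff(tokens, rownames(model$vectors))
  if (length(miss)) {
    stop("token(s) not in vocabulary: ", paste(miss, collapse = ", "))
  }
}

# unit-normalized copy of the vector matrix
vm_unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Cosine similarity between two tokens
#'
#' @param model a `vm_embedding`.
#' @param a,b tokens.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(model, a, b) {
  vm_check_vocab(model, c(a, b))
  va <- model$vectors[a, ]; vb <- model$vectors[b, ]
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Nearest terms by cosine similarity
#'
#' @param model a `vm_embedding`.
#' @param query in-vocabulary token.
#' @param k number of neighbours.
#' @return data.frame `token`, `cosine`, descending; the query itself is
#'   excluded.
#' @export
nearest_terms <- function(model, query, k = 10L) {
  vm_check_vocab(model, query)
  U <- vm_unit_rows(model$vectors)
  sims <- drop(U %*% U[query, ])
  sims <- sims[names(sims) != query]
  ord <- order(-sims, names(sims))
  utils::head(data.frame(token = names(sims)[ord], cosine = unname(sims[ord]),
                         stringsAsFactors = FALSE), k)
}

#' Analogy query by vector arithmetic
#'
#' Answers "`a` is to `b` as ? is to `c`" by ranking the vocabulary by
#' cosine similarity to `vec(a) - vec(b) + vec(c)`; the three query tokens
#' are excluded from the results. With `a == b` the arithmetic cancels and
#' the ranking reduces to the nearest neighbours of `c`.
#'
#' @param model a `vm_embedding`.
#' @param a,b,c in-vocabulary tokens.
#' @param k number of results.
#' @return data.frame `token`, `cosine`.
#' @export
analogy_query <- function(model, a, b, c, k = 10L) {
  vm_check_vocab(model, c(a, b, c))
  U <- vm_unit_rows(model$vectors)
  target <- U[a, ] - U[b, ] + U[c, ]
  tn <- sqrt(sum(target^2))
  if (tn > 0) target <- target / tn
  sims <- drop(U %*% target)
  sims <- sims[!names(sims) %in% c(a, b, c)]
  ord <- order(-sims, names(sims))
  utils::head(data.frame(token = names(sims)[ord], cosine = unname(sims[ord]),
                         stringsAsFactors = FALSE), k)
}

#' Assay vector: unit-normalized mean of token embeddings
#'
#' Averages the embeddings of the in-vocabulary tokens of one description
#' and scales the mean to unit norm. When every token is out of vocabulary
#' the zero vector is returned with attribute `degenerate = TRUE` (the
#' documented degenerate contract; such assays are excluded from
#' classification).
#'
#' @param model a `vm_embedding`.
#' @param tokens character vector of tokens (OOV tokens permitted).
#' @return numeric vector of length `dim` with attribute `degenerate`.
#' @export
assay_vector <- function(model, tokens) {
  hit <- tokens[tokens %in% rownames(model$vectors)]
  d <- model$params$dim
  if (!length(hit)) {
    return(structure(rep(0, d), degenerate = TRUE))
  }
  v <- colMeans(model$vectors[hit, , drop = FALSE])
  n <- sqrt(sum(v^2))
  if (n == 0) return(structure(rep(0, d), degenerate = TRUE))
  structure(v / n, degenerate = FALSE)
}

#' Assay-vector matrix for a token corpus
#'
#' @param model a `vm_embedding`.
#' @param token_corpus list of token vectors, optionally named by assay id.
#' @return list: `matrix` (assays x dim) and logical `degenerate`.
#' @export
assay_vectors <- function(model, token_corpus) {
  vs <- lapply(token_corpus, assay_vector, model = model)
  M <- do.call(rbind, vs)
  rownames(M) <- names(token_corpus)
  list(matrix = M,
       degenerate = vapply(vs, function(v) isTRUE(attr(v, "degenerate")),
                           logical(1)))
}

#' Pairwise semantic-similarity matrix with hierarchical clustering
#'
#' Builds the raw cosine matrix between two term sets, Z-scores each row
#' (zero mean, unit variance where variance is positive), and clusters rows
#' and columns hierarchically with average linkage on Euclidean distances
#' of the Z-scored matrix. Column clustering is computed on both the raw
#' and Z-scored orientations (which of the two a heatmap should use is a
#' presentation choice; both dendrograms are returned).
#'
#' @param model a `vm_embedding`.
#' @param row_terms,col_terms in-vocabulary tokens.
#' @return object of class `vm_semantic_matrix`: `raw`, `zscored`,
#'   `row_hclust`, `col_hclust`, `col_hclust_raw`.
#' @export
similarity_matrix <- function(model, row_terms, col_terms = row_terms) {
  vm_check_vocab(model, c(row_terms, col_terms))
  U <- vm_unit_rows(model$vectors)
  raw <- U[row_terms, , drop = FALSE] %*% t(U[col_terms, , drop = FALSE])
  z <- t(apply(raw, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) r - mean(r) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(raw)
  row_h <- if (nrow(z) > 1) stats::hclust(stats::dist(z), method = "average") else NULL
  col_h <- if (ncol(z) > 1) stats::hclust(stats::dist(t(z)), method = "average") else NULL
  col_h_raw <- if (ncol(raw) > 1) stats::hclust(stats::dist(t(raw)), method = "average") else NULL
  structure(list(raw = raw, zscored = z, row_hclust = row_h,
                 col_hclust = col_h, col_hclust_raw = col_h_raw),
            class = "vm_semantic_matrix")
}

#' Project assay vectors to 2-D (PCA then t-SNE)
#'
#' Reduces the assay-vector matrix to at most 20 principal components (or
#' the matrix rank if lower), then embeds in two dimensions with t-SNE.
#' The seed and perplexity are recorded in the result's attributes.
#'
#' @param vectors numeric matrix (assays x dim), at least 3 rows.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   when the sample is too small for it).
#' @param pca_dims number of PCA components before t-SNE (default 20).
#' @return matrix (assays x 2) with attributes `seed`, `perplexity`,
#'   `pca_dims`.
#' @export
project_assays_2d <- function(vectors, seed = 1L, perplexity = 30,
                              pca_dims = 20L) {
  if (is.null(dim(vectors)) || nrow(vectors) < 3L) {
    stop("need at least 3 vectors to project")
  }
  n <- nrow(vectors)
  pca_dims <- min(pca_dims, n - 1L, ncol(vectors))
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  keep <- min(pca_dims, ncol(pc$x))
  red <- pc$x[, seq_len(keep), drop = FALSE]
  perp <- min(perplexity, floor((n - 1) / 3))
  perp <- max(perp, 1)
  set.seed(seed)
  ts <- Rtsne::Rtsne(red, dims = 2, perplexity = perp, pca = FALSE,
                     check_duplicates = FALSE, max_iter = 500, verbose = FALSE)
  out <- ts$Y
  rownames(out) <- rownames(vectors)
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perp
  attr(out, "pca_dims") <- keep
  out
}

#' Export a model in plain-text word2vec format
#'
#' First line: `<vocab size> <dim>`; then one token per line followed by
#' its vector components, space-separated.
#'
#' @param model a `vm_embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(model$vectors), model$params$dim), con)
  for (i in seq_len(nrow(model$vectors))) {
    writeLines(paste(rownames(model$vectors)[i],
                     paste(sprintf("%.8g", model$vectors[i, ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  rows <- lapply(strsplit(lines[-1], " ", fixed = TRUE),
                 function(x) x[nzchar(x)])
  vocab <- vapply(rows, `[`, "", 1)
  M <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(hdr[2])))
  rownames(M) <- vocab
  structure(list(vectors = M,
                 counts = stats::setNames(rep(NA_integer_, hdr[1]), vocab),
                 params = list(dim = hdr[2], window = NA_integer_,
                               min_count = NA_integer_,
                               architecture = NA_character_,
                               epochs = NA_integer_, negative = NA_integer_,
                               alpha = NA_real_, sample = NA_real_,
                               seed = NA_integer_)),
            class = "vm_embedding")
}
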