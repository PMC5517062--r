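test_that("strain mentions normalize synonyms, substrains and modifiers", {
  pipe <- test_pipeline()
  pp <- preprocess_description("Survival of C56BL/6J male mouse vs control")
  m <- match_dictionary_entities(pp$sentence, pipe$mouse_dict)
  expect_equal(m$normalized, "C57BL mouse")
  expect_equal(m$surface, "C56BL/6J male mouse")

  pp2 <- preprocess_description(
    "Inhibition of carrageenan-induced paw oedema in Sprague-Dawley rat")
  m2 <- match_dictionary_entities(pp2$sentence, pipe$rat_dict)
  expect_equal(m2$normalized, "Sprague Dawley rat")

  # punctuation variant resolves through the alphanumeric key
  pp3 <- preprocess_description("Glucose lowering in ob-ob mouse")
  m3 <- match_dictionary_entities(pp3$sentence, pipe$mouse_dict)
  expect_equal(m3$normalized, "ob/ob mouse")

  # no dictionary terms: empty result
  pp4 <- preprocess_description("Reduction of arterial pressure")
  expect_equal(nrow(match_dictionary_entities(pp4$sentence, pipe$rat_dict)), 0L)
})

test_that("rule patterns capture induced and transgenic model mentions", {
  pp <- preprocess_description(
    "Protection against Freund's complete adjuvant induced arthritis")
  m <- extract_rule_entities(pp$sentence, pp$phrases)
  em <- m[m$entity_class == "experimental_model", ]
  expect_equal(em$surface, "Freund's complete adjuvant induced")

  # head-noun assay names need no trigger keyword
  pp2 <- preprocess_description("Activity in the glucose tolerance test in rat")
  m2 <- extract_rule_entities(pp2$sentence, pp2$phrases)
  expect_true("glucose tolerance test" %in% m2$surface)

  # transgenesis keywords yield transgenic_model mentions
  pp3 <- preprocess_description("Cholesterol increase in APOA1 transgenic mouse")
  m3 <- extract_rule_entities(pp3$sentence, pp3$phrases)
  tm <- m3[m3$entity_class == "transgenic_model", ]
  expect_equal(tm$surface, "APOA1 transgenic")

  # infection phrases: organism name + infected
  pp4 <- preprocess_description("Survival of Staphylococcus aureus infected mice")
  m4 <- extract_rule_entities(pp4$sentence, pp4$phrases)
  expect_true("Staphylococcus aureus infected" %in% m4$surface)

  # mentions never overlap within one class
  for (pp_i in list(pp, pp2, pp3, pp4)) {
    mm <- extract_rule_entities(pp_i$sentence, pp_i$phrases)
    for (cls in unique(mm$entity_class)) {
      mc <- mm[mm$entity_class == cls, ]
      mc <- mc[order(mc$start), ]
      if (nrow(mc) > 1) expect_true(all(mc$start[-1] >= mc$end[-nrow(mc)]))
    }
  }
})

test_that("corpus annotation finds the canonical example's three entities", {
  pipe <- test_pipeline()
  assays <- data.frame(
    assay_id = "A1",
    description = "Inhibition of carrageenan-induced paw oedema in Sprague-Dawley rat at 5.16 mg/kg, sc after 3 hrs",
    species = "rat", document_id = "D1", stringsAsFactors = FALSE)
  assays$compound_ids <- list(character())
  m <- annotate_corpus(assays, pipe)
  expect_setequal(
    m$normalized[m$entity_class %in%
                   c("genetic_strain", "experimental_model", "phenotype")],
    c("Sprague Dawley rat", "carrageenan induced", "paw oedema"))
  expect_equal(m$surface[m$entity_class == "experimental_model"],
               "carrageenan-induced")
  # raw spans match the original description text
  for (r in seq_len(nrow(m))) {
    expect_equal(substring(assays$description, m$raw_start[r] + 1L, m$raw_end[r]),
                 m$surface[r])
  }
  # empty corpus: empty table
  expect_equal(nrow(annotate_corpus(assays[0, ], pipe)), 0L)
})

test_that("NER evaluation scores exact and partial matches correctly", {
  gold <- list(list(
    doc_id = "A1", text = "carrageenan induced paw oedema in SHR rat",
    mentions = data.frame(
      entity_class = c("experimental_model", "phenotype"),
      start = c(0L, 20L), end = c(19L, 30L),
      surface = c("carrageenan induced", "paw oedema"),
      stringsAsFactors = FALSE)))
  # perfect predictions: P = R = F1 = 1 everywhere
  pred <- data.frame(assay_id = "A1",
                     entity_class = c("experimental_model", "phenotype"),
                     start = c(0L, 20L), end = c(19L, 30L),
                     stringsAsFactors = FALSE)
  ev <- evaluate_ner(pred, gold, "exact")
  expect_true(all(ev$metrics$f1 == 1))

  # one correct + one spurious vs two gold: P = R = F1 = 0.5
  pred2 <- data.frame(assay_id = "A1",
                      entity_class = c("experimental_model", "phenotype"),
                      start = c(0L, 34L), end = c(19L, 37L),
                      stringsAsFactors = FALSE)
  ev2 <- evaluate_ner(pred2, gold, "exact")
  micro <- ev2$metrics[ev2$metrics$entity_class == "micro", ]
  expect_equal(micro$precision, 0.5)
  expect_equal(micro$recall, 0.5)
  expect_equal(micro$f1, 0.5)

  # off-by-one span counts under partial matching but not exact
  pred3 <- data.frame(assay_id = "A1", entity_class = "phenotype",
                      start = 21L, end = 30L, stringsAsFactors = FALSE)
  exact <- evaluate_ner(pred3, gold, "exact")$metrics
  partial <- evaluate_ner(pred3, gold, "partial")$metrics
  expect_equal(exact$tp[exact$entity_class == "phenotype"], 0)
  expect_equal(partial$tp[partial$entity_class == "phenotype"], 1)

  # spans outside the text are fatal
  gold_bad <- gold
  gold_bad[[1]]$mentions$end[1] <- 999L
  expect_error(evaluate_ner(pred, gold_bad, "exact"), "outside")
})

test_that("exact F1 never exceeds partial F1 (randomized property)", {
  set.seed(7)
  classes <- c("genetic_strain", "experimental_model", "phenotype")
  for (i in 1:200) {
    n_g <- sample(0:4, 1); n_p <- sample(0:4, 1)
    text <- paste(rep("x", 60), collapse = "")
    mk <- function(n) {
      if (n == 0) return(data.frame(entity_class = character(),
                                    start = integer(), end = integer(),
                                    surface = character(),
                                    stringsAsFactors = FALSE))
      s <- sample(0:49, n)
      data.frame(entity_class = sample(classes, n, replace = TRUE),
                 start = s, end = s + sample(1:10, n, replace = TRUE),
                 surface = "x", stringsAsFactors = FALSE)
    }
    gold <- list(list(doc_id = "A1", text = text, mentions = mk(n_g)))
    pred <- cbind(data.frame(assay_id = rep("A1", n_p)), mk(n_p)[, 1:3])
    fe <- evaluate_ner(pred, gold, "exact")$metrics
    fp <- evaluate_ner(pred, gold, "partial")$metrics
    expect_lte(fe$f1[fe$entity_class == "micro"],
               fp$f1[fp$entity_class == "micro"] + 1e-12)
  }
})

test_that("mention frequencies count distinct assays with stable ties", {
  m <- data.frame(
    assay_id = c("A1", "A1", "A2", "A3", "A3", "A4"),
    entity_class = "genetic_strain",
    surface = "x",
    normalized = c("X", "X", "X", "Y", "X", "Y"),
    start = 0L, end = 1L, stringsAsFactors = FALSE)
  f <- mention_frequencies(m)
  expect_equal(f$name, c("X", "Y"))
  expect_equal(f$n_assays, c(3L, 2L))   # duplicate mention in A1 counted once
  expect_equal(nrow(mention_frequencies(m[0, ])), 0L)
  # equal counts break ties lexicographically
  m2 <- m[m$assay_id == "A3", ]
  f2 <- mention_frequencies(m2)
  expect_equal(f2$n_assays, c(1L, 1L))
  expect_equal(f2$name, c("X", "Y"))
})

test_that("BRAT standoff files round-trip through write and read", {
  corp <- generate_corpus(synthetic_config(seed = 3, n_documents = 5))
  dir <- tempfile("brat")
  write_brat(corp$gold, dir)
  back <- read_brat(dir)
  expect_equal(length(back), length(corp$gold))
  ids <- vapply(back, `[[`, "", "doc_id")
  for (g in corp$gold) {
    b <- back[[match(g$doc_id, ids)]]
    expect_equal(b$text, g$text)
    expect_equal(b$mentions$start, g$mentions$start)
    expect_equal(b$mentions$end, g$mentions$end)
    expect_equal(b$mentions$entity_class, g$mentions$entity_class)
  }
})
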