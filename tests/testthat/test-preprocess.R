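test_that("species names and administration acronyms are normalized", {
  r <- normalize_description("Inhibition of oedema in Rattus norvegicus at 5 mg/kg, sc")
  expect_equal(r$text, "Inhibition of oedema in rat at 5 mg/kg, subcutaneous")
  expect_equal(normalize_description("qd dosing of Mus musculus")$text,
               "daily dosing of mouse")
  # untouched text: identity offset map
  r0 <- normalize_description("Inhibition of paw oedema")
  expect_equal(r0$text, "Inhibition of paw oedema")
  expect_equal(nrow(r0$offsets), 1L)
  expect_false(r0$offsets$replaced)
  # acronyms only replace whole tokens
  expect_equal(normalize_description("scopolamine disc")$text, "scopolamine disc")
})

test_that("offset maps round-trip character spans through normalization", {
  raw <- "Oedema in Rattus norvegicus at 5 mg/kg, sc after 3 hrs"
  r <- normalize_description(raw)
  # span of "Oedema" unchanged
  expect_equal(map_span(r$offsets, 0L, 6L, to = "raw"), c(0L, 6L))
  # spans inside a replacement map to the whole replaced region
  norm <- r$text
  sc_start <- regexpr("subcutaneous", norm, fixed = TRUE)[1] - 1L
  back <- map_span(r$offsets, sc_start, sc_start + nchar("subcutaneous"), to = "raw")
  expect_equal(substring(raw, back[1] + 1L, back[2]), "sc")
  # forward mapping of a raw span after the replacements
  hrs_raw <- regexpr("hrs", raw, fixed = TRUE)[1] - 1L
  fwd <- map_span(r$offsets, hrs_raw, hrs_raw + 3L, to = "norm")
  expect_equal(substring(norm, fwd[1] + 1L, fwd[2]), "hrs")
})

test_that("tokenizer records exact offsets and splits hyphens/possessives", {
  t1 <- vm_tokenize("carrageenan-induced paw oedema")
  expect_equal(t1$text, c("carrageenan", "induced", "paw", "oedema"))
  expect_equal(t1$start[1:2], c(0L, 12L))
  t2 <- vm_tokenize("Freund's complete adjuvant")
  expect_equal(t2$text[1:2], c("Freund", "'s"))
  t3 <- vm_tokenize("C57BL/6J at 5.16 mg/kg,")
  expect_equal(t3$text, c("C57BL/6J", "at", "5.16", "mg/kg", ","))
  expect_equal(vm_tokenize("")$text, character())
  # offsets reconstruct every token from the source
  txt <- "Inhibition of TNF alpha induced oedema, iv"
  tk <- vm_tokenize(txt)
  expect_equal(substring(txt, tk$start + 1L, tk$end), tk$text)
})

test_that("bundled tagger assigns POS and biological entity flags", {
  s <- tag_tokens("Inhibition of oedema")
  expect_equal(s$pos, c("NN", "IN", "NN"))
  s2 <- tag_tokens("Concanavalin A induced necrosis")
  expect_equal(s2$custom[1:2], c("PROT", "PROT"))
  s3 <- tag_tokens("L1210 leukemia")
  expect_equal(s3$custom[1], "CELL")
  expect_equal(nrow(tag_tokens("")), 0L)
  # determinism
  expect_identical(tag_tokens("maximal electroshock induced clonic seizures"),
                   tag_tokens("maximal electroshock induced clonic seizures"))
})

test_that("custom tags mark procedure, transgenesis and species keywords", {
  s <- apply_custom_tags(tag_tokens("streptozotocin induced diabetes"))
  expect_equal(s$custom[2], "IND")
  s2 <- apply_custom_tags(tag_tokens("APOA1 transgenic mouse"))
  expect_equal(s2$custom[2], "TRANSG")
  expect_equal(s2$custom[3], "SP")
  # PROT/CELL flags are never overwritten
  s3 <- apply_custom_tags(tag_tokens("Concanavalin A induced"))
  expect_equal(s3$custom, c("PROT", "PROT", "IND"))
  # no keywords: unchanged
  s4 <- tag_tokens("Reduction of arterial pressure")
  expect_identical(apply_custom_tags(s4)$custom, s4$custom)
})

test_that("base noun phrases follow the chunking grammar and split at triggers", {
  pp <- preprocess_description(
    "a perorally dosed Freund's complete adjuvant induced rat inflammatory pain model")
  expect_true("inflammatory pain model" %in% pp$phrases$surface)
  expect_false(any(grepl("induced", pp$phrases$surface)))
  expect_false(any(grepl("\\brat\\b", pp$phrases$surface)))
  expect_false(any(grepl("^a\\b", pp$phrases$surface)))

  pp2 <- preprocess_description("concanavalin A induced hepatic cell necrosis")
  expect_setequal(pp2$phrases$surface,
                  c("concanavalin A", "hepatic cell necrosis"))

  # only verbs/prepositions: no phrases
  s <- make_sentence(c("was", "assessed", "in"), c("VBD", "VBN", "IN"))
  expect_equal(nrow(extract_noun_phrases(s)), 0L)
})

test_that("grammar matches brute-force leftmost-longest enumeration", {
  oracle_phrases <- function(cls) {
    code <- ifelse(cls == "JJ", "J", ifelse(grepl("^NN", cls), "N",
            ifelse(cls == "PROT", "P", ifelse(cls == "CELL", "C", "O"))))
    s <- paste(code, collapse = "")
    n <- nchar(s); out <- list(); i <- 1L
    while (i <= n) {
      best <- 0L
      for (j in i:n) {
        if (grepl("^[JN]*[NPC]+$", substr(s, i, j))) best <- j
      }
      if (best >= i) { out[[length(out) + 1L]] <- c(i, best); i <- best + 1L }
      else i <- i + 1L
    }
    out
  }
  check <- function(cls) {
    pos <- ifelse(cls %in% c("PROT", "CELL"), "NN", cls)
    custom <- ifelse(cls %in% c("PROT", "CELL"), cls, NA_character_)
    got <- extract_noun_phrases(make_sentence(paste0("w", seq_along(cls)), pos, custom))
    want <- oracle_phrases(cls)
    identical(nrow(got), length(want)) &&
      all(got$first == vapply(want, `[`, 0, 1)) &&
      all(got$last == vapply(want, `[`, 0, 2))
  }
  # randomized sequences over the full tag alphabet
  alph_full <- c("JJ", "NN", "NNS", "NNP", "PROT", "CELL", "IN", "IND",
                 "CD", "DT", "VBN")
  set.seed(99)
  for (rep in 1:500) {
    cls <- sample(alph_full, sample(2:8, 1), replace = TRUE)
    expect_true(check(cls), label = paste("sequence", paste(cls, collapse = " ")))
  }
})

test_that("embedding token stream joins phrases, normalizes strains, drops noise", {
  pp <- preprocess_description("Reduction of arterial pressure in the rat")
  toks <- tokens_for_embedding(pp$sentence, pp$phrases)
  expect_true("arterial_pressure" %in% toks)
  expect_false("the" %in% toks)

  # strain normalization produces a single preferred-name token
  pipe <- test_pipeline()
  pp2 <- preprocess_description("Survival of C56BL/6J male mouse at 5 mg/kg")
  sm <- match_dictionary_entities(pp2$sentence, pipe$mouse_dict)
  toks2 <- tokens_for_embedding(pp2$sentence, pp2$phrases, strain_mentions = sm)
  expect_true("c57bl_mouse" %in% toks2)
  expect_false("5" %in% toks2)

  # all-removable input gives an empty stream
  pp3 <- preprocess_description("the 5 mg")
  expect_length(tokens_for_embedding(pp3$sentence, pp3$phrases), 0)

  # byte-identical token streams for identical input
  t_a <- tokens_for_embedding(pp$sentence, pp$phrases)
  t_b <- tokens_for_embedding(pp$sentence, pp$phrases)
  expect_identical(t_a, t_b)
})
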