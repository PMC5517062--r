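test_that("alphanumeric match keys collapse punctuation variants", {
  expect_equal(match_key("ob-ob mouse"), "obobmouse")
  expect_equal(match_key("ob-ob mouse"), match_key("ob/ob mouse"))
  expect_equal(match_key("SHR"), "shr")
  expect_equal(match_key(""), "")
  expect_equal(match_key(c("A-B", NA)), c("ab", ""))
})

test_that("substrain designations parse back to their parental strain", {
  basic <- c("AKR", "C57BL", "NOD", "BALB/c")
  expect_equal(parse_substrain_parent("AKR/NCr", basic), "AKR")
  expect_equal(parse_substrain_parent("AKR", basic), "AKR")
  expect_equal(parse_substrain_parent("C57BL/6J", basic), "C57BL")
  # unknown prefixes stay intact (protects hybrids and intrinsic slashes)
  expect_equal(parse_substrain_parent("B6D2F1/J", basic), "B6D2F1/J")
  expect_equal(parse_substrain_parent("ob/ob", basic), "ob/ob")
  # idempotence: parent(parent(x)) == parent(x)
  for (nm in c("AKR/NCr", "C57BL/6J", "ob/ob", "B6D2F1/J", "NOD")) {
    p <- parse_substrain_parent(nm, basic)
    expect_equal(parse_substrain_parent(p, basic), p)
  }
})

test_that("strain dictionary compiles names, synonyms and substrains", {
  listing <- data.frame(
    name = c("NOD", "C57BL", "Swiss"),
    type = c("inbred", "inbred", "outbred"),
    synonyms = c("non obese diabetic", "Black 6;C57black", ""),
    substrains = c("NOD/ShiLtJ", "C57BL/6J;C57BL/6N", ""),
    stringsAsFactors = FALSE)
  dict <- compile_strain_dictionary(listing, "mouse")
  expect_equal(nrow(dict$entries), 3L)
  # synonym and preferred name resolve to the same entry
  expect_equal(unname(dict$key_index[match_key("non obese diabetic")]),
               unname(dict$key_index[match_key("NOD")]))
  # self-resolution invariant for every entry
  for (i in seq_len(nrow(dict$entries))) {
    k <- match_key(dict$entries$preferred_name[i])
    expect_equal(unname(dict$key_index[k]), i)
  }
  # empty listing: empty dictionary, no error
  empty <- compile_strain_dictionary(listing[0, ], "mouse")
  expect_equal(nrow(empty$entries), 0L)
  # key collisions across entries are a build failure
  bad <- data.frame(name = c("SHR", "S-H-R"), type = "inbred",
                    synonyms = "", substrains = "", stringsAsFactors = FALSE)
  expect_error(compile_strain_dictionary(bad, "rat"), "collision")
})

test_that("dictionary build is deterministic and JSON round-trips", {
  l1 <- synth_strain_listing("mouse")
  d1 <- compile_strain_dictionary(l1, "mouse")
  d2 <- compile_strain_dictionary(synth_strain_listing("mouse"), "mouse")
  expect_identical(d1, d2)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_dictionary(d1, p1)
  write_dictionary(read_dictionary(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  rt <- read_dictionary(p1)
  expect_equal(rt$species, d1$species)
  expect_equal(rt$key_index, d1$key_index)
  expect_equal(rt$entries$preferred_name, d1$entries$preferred_name)
})

test_that("OBO parsing extracts terms, synonyms, scopes and obsolescence", {
  terms <- read_obo_terms(toy_obo())
  expect_true(all(c("edema", "writhing") %in% terms$name))
  expect_true("oedema" %in% terms$synonym[terms$scope == "EXACT"])
  expect_true("fluid retention" %in% terms$synonym[terms$scope == "RELATED"])
  expect_true(any(terms$obsolete[terms$name == "old seizure term"]))
  expect_error(read_obo_terms(file.path(tempdir(), "missing.obo")), "OBO")
})

test_that("phenotype dictionary folds synonyms and applies exclusions", {
  obo <- toy_obo()
  dict <- load_phenotype_dictionary(obo, blocklist = "activity")
  # synonym and label map to the same preferred label
  s <- make_sentence(c("severe", "oedema"), c("JJ", "NN"))
  m <- match_dictionary_entities(s, dict)
  expect_equal(m$normalized, "edema")
  expect_equal(m$surface, "oedema")
  # obsolete terms, blocklisted terms and short terms are excluded
  expect_false("old seizure term" %in% dict$terms$label)
  expect_false("activity" %in% dict$terms$label)
  expect_false("pb" %in% dict$terms$label)   # below min_len = 3
  # exact-only by default; widened scope picks up related synonyms
  expect_false("fluid retention" %in% names(dict$key_index))
  wide <- load_phenotype_dictionary(obo, blocklist = "activity",
                                    synonym_scope = "all")
  expect_true(any(grepl("fluid retention", names(wide$key_index))))
})

test_that("measurement words after a protein token are not phenotypes", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: TOY:1", "name: production", "",
               "[Term]", "id: TOY:2", "name: blood glucose level", ""), obo)
  dict <- load_phenotype_dictionary(obo)
  s <- apply_custom_tags(tag_tokens("Concanavalin A induced IL4 production"))
  s$custom[4] <- "PROT"   # IL4 flagged by the tagging backend
  expect_equal(nrow(match_dictionary_entities(s, dict)), 0L)
  # the same word without a protein context still matches
  s2 <- tag_tokens("reduction of production")
  expect_equal(match_dictionary_entities(s2, dict)$normalized, "production")
  # multi-word physiological readouts are never suppressed
  s3 <- tag_tokens("decrease in blood glucose level")
  expect_equal(match_dictionary_entities(s3, dict)$normalized,
               "blood glucose level")
})
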