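# Shared fixtures: built in code at test time, cached per session.

# pipeline whose dictionaries exactly cover the synthetic vocabulary
test_pipeline <- local({
  pipe <- NULL
  function() {
    if (is.null(pipe)) pipe <<- synth_pipeline()
    pipe
  }
})

# a hand-built tagged sentence from explicit tags (bypasses the tagger)
make_sentence <- function(words, pos, custom = rep(NA_character_, length(words)),
                          assay_id = "T1") {
  n <- length(words)
  starts <- cumsum(c(0L, nchar(words[-n]) + 1L))
  sent <- data.frame(text = words, pos = pos, custom = custom,
                     start = starts, end = starts + nchar(words),
                     stringsAsFactors = FALSE)
  structure(sent, class = c("vm_tagged_sentence", "data.frame"),
            assay_id = assay_id, text = paste(words, collapse = " "))
}

# preprocess + dictionary + rule NER token stream for one corpus
corpus_tokens <- function(corp, pipe = test_pipeline()) {
  tok <- lapply(seq_len(nrow(corp$assays)), function(i) {
    pp <- preprocess_description(corp$assays$description[i],
                                 assay_id = corp$assays$assay_id[i])
    sdict <- if (corp$assays$species[i] == "mouse") pipe$mouse_dict else pipe$rat_dict
    sm <- match_dictionary_entities(pp$sentence, sdict)
    tokens_for_embedding(pp$sentence, pp$phrases, strain_mentions = sm)
  })
  names(tok) <- corp$assays$assay_id
  tok
}

# mention table re-expressed in raw-description coordinates for gold scoring
mentions_in_raw <- function(mentions) {
  m <- mentions
  m$start <- m$raw_start
  m$end <- m$raw_end
  m
}

# write a small temporary TSV and return its path
write_tsv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# tiny toy ontology exercising synonyms, obsolescence and scopes
toy_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: TOY:0000001",
    "name: edema",
    "synonym: \"oedema\" EXACT []",
    "synonym: \"fluid retention\" RELATED []",
    "",
    "[Term]",
    "id: TOY:0000002",
    "name: writhing",
    "",
    "[Term]",
    "id: TOY:0000003",
    "name: old seizure term",
    "is_obsolete: true",
    "",
    "[Term]",
    "id: TOY:0000004",
    "name: activity",
    "",
    "[Term]",
    "id: TOY:0000005",
    "name: pb",
    ""), path)
  path
}
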