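#' Normalize a raw assay description
#'
#' Applies the two text-level normalizations that precede shallow parsing:
#' binomial species names are replaced by their common names ("Rattus
#' norvegicus" -> "rat", "Mus musculus" -> "mouse"), and whole-token
#' administration acronyms are expanded ("sc" -> "subcutaneous",
#' "qd" -> "daily"). An offset map is returned so that character spans in
#' the normalized text can be mapped back to the raw description (and gold
#' annotation spans mapped forward).
#'
#' @param text raw description (character scalar).
#' @param acronym_map data.frame with columns `acronym`, `expansion`;
#'   defaults to [vm_acronym_map()].
#' @return list with elements `text` (normalized description) and `offsets`
#'   (data.frame `norm_start`, `norm_end`, `raw_start`, `raw_end`,
#'   `replaced`), usable with [map_span()].
#' @export
normalize_description <- function(text, acronym_map = vm_acronym_map()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  repl <- list()
  add_matches <- function(pattern, replacement, subject, perl = TRUE,
                          ignore.case = FALSE) {
    m <- gregexpr(pattern, subject, perl = perl, ignore.case = ignore.case)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"),
               replacement = replacement, stringsAsFactors = FALSE)
  }
  species <- data.frame(
    pattern = c("\\bRattus\\s+norvegicus\\b", "\\bMus\\s+musculus\\b"),
    replacement = c("rat", "mouse"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(species))) {
    repl[[length(repl) + 1L]] <- add_matches(species$pattern[i],
                                             species$replacement[i], text,
                                             ignore.case = TRUE)
  }
  if (!is.null(acronym_map) && nrow(acronym_map)) {
    for (i in seq_len(nrow(acronym_map))) {
      pat <- paste0("(?<![A-Za-z0-9])",
                    gsub("([\\W])", "\\\\\\1", acronym_map$acronym[i], perl = TRUE),
                    "(?![A-Za-z0-9])")
      repl[[length(repl) + 1L]] <- add_matches(pat, acronym_map$expansion[i],
                                               text, ignore.case = TRUE)
    }
  }
  repl <- do.call(rbind, repl)
  if (is.null(repl) || !nrow(repl)) {
    offs <- data.frame(norm_start = 0L, norm_end = nchar(text),
                       raw_start = 0L, raw_end = nchar(text),
                       replaced = FALSE)
    return(list(text = text, offsets = offs))
  }
  repl <- repl[order(repl$start, -repl$end), , drop = FALSE]
  # drop overlapping matches, keep leftmost-longest
  keep <- logical(nrow(repl)); last_end <- 0L
  for (i in seq_len(nrow(repl))) {
    if (repl$start[i] >= last_end) { keep[i] <- TRUE; last_end <- repl$end[i] }
  }
  repl <- repl[keep, , drop = FALSE]

  pieces <- character(); offs <- list(); cursor <- 0L; norm_pos <- 0L
  for (i in seq_len(nrow(repl))) {
    if (repl$start[i] > cursor) {
      lit <- substring(text, cursor + 1L, repl$start[i])
      pieces <- c(pieces, lit)
      offs[[length(offs) + 1L]] <- data.frame(
        norm_start = norm_pos, norm_end = norm_pos + nchar(lit),
        raw_start = cursor, raw_end = repl$start[i], replaced = FALSE)
      norm_pos <- norm_pos + nchar(lit)
    }
    rep_txt <- repl$replacement[i]
    pieces <- c(pieces, rep_txt)
    offs[[length(offs) + 1L]] <- data.frame(
      norm_start = norm_pos, norm_end = norm_pos + nchar(rep_txt),
      raw_start = repl$start[i], raw_end = repl$end[i], replaced = TRUE)
    norm_pos <- norm_pos + nchar(rep_txt)
    cursor <- repl$end[i]
  }
  if (cursor < nchar(text)) {
    lit <- substring(text, cursor + 1L, nchar(text))
    pieces <- c(pieces, lit)
    offs[[length(offs) + 1L]] <- data.frame(
      norm_start = norm_pos, norm_end = norm_pos + nchar(lit),
      raw_start = cursor, raw_end = nchar(text), replaced = FALSE)
  }
  list(text = paste(pieces, collapse = ""), offsets = do.call(rbind, offs))
}

#' Map a character span through a normalization offset map
#'
#' @param offsets offset map from [normalize_description()].
#' @param start,end 0-based half-open span.
#' @param to direction: `"raw"` maps normalized-text coordinates back to the
#'   raw description; `"norm"` maps raw coordinates forward.
#' @return integer vector `c(start, end)` in the target coordinate frame.
#' @export
map_span <- function(offsets, start, end, to = c("raw", "norm")) {
  to <- match.arg(to)
  if (to == "raw") {
    a <- "norm_start"; b <- "norm_end"; x <- "raw_start"; y <- "raw_end"
  } else {
    a <- "raw_start"; b <- "raw_end"; x <- "norm_start"; y <- "norm_end"
  }
  map_pos <- function(p, is_end) {
    i <- which(offsets[[a]] <= p & p <= offsets[[b]])
    if (is_end) i <- i[length(i)] else i <- i[1]
    if (!length(i) || is.na(i)) stop("position ", p, " outside offset map")
    if (offsets$replaced[i]) {
      if (is_end) offsets[[y]][i] else offsets[[x]][i]
    } else {
      offsets[[x]][i] + (p - offsets[[a]][i])
    }
  }
  c(map_pos(start, FALSE), map_pos(end, TRUE))
}

# ---------------------------------------------------------------------------
# POS tagging

#' Bundled deterministic POS tagger
#'
#' A lexicon + suffix-rule tagger used as the default tagging backend. It
#' assigns Penn-Treebank-style tags (NN, JJ, IN, DT, CD, VBN, VBG, RB, CC,
#' POS, punctuation) and flags protein / cell-line tokens from
#' [vm_bio_lexicon()]. It exists so the pipeline is fully reproducible
#' without the external biomedical tagger binary the method was designed
#' around; any backend obeying the same contract (a function taking a token
#' data.frame and returning `pos`, `prot`, `cell` columns) can be plugged
#' into [tag_tokens()].
#'
#' @param bio_lexicon list as returned by [vm_bio_lexicon()].
#' @return a tagger function.
#' @export
vm_default_tagger <- function(bio_lexicon = vm_bio_lexicon()) {
  closed <- c(
    "the" = "DT", "a" = "DT", "an" = "DT", "this" = "DT", "that" = "DT",
    "its" = "PRP$", "their" = "PRP$", "his" = "PRP$", "her" = "PRP$",
    "of" = "IN", "in" = "IN", "at" = "IN", "on" = "IN", "by" = "IN",
    "with" = "IN", "for" = "IN", "to" = "TO", "from" = "IN", "after" = "IN",
    "before" = "IN", "during" = "IN", "under" = "IN", "over" = "IN",
    "into" = "IN", "as" = "IN", "versus" = "IN", "vs" = "IN", "per" = "IN",
    "against" = "IN", "upon" = "IN", "toward" = "IN", "towards" = "IN",
    "within" = "IN", "without" = "IN", "among" = "IN", "through" = "IN",
    "between" = "IN", "across" = "IN", "via" = "IN",
    "and" = "CC", "or" = "CC", "but" = "CC",
    "is" = "VBZ", "are" = "VBP", "was" = "VBD", "were" = "VBD",
    "be" = "VB", "been" = "VBN",
    "when" = "WRB", "compared" = "VBN", "assessed" = "VBN",
    "evaluated" = "VBN", "measured" = "VBN", "determined" = "VBN",
    "relative" = "JJ", "'s" = "POS",
    "not" = "RB", "no" = "DT",
    "hrs" = "NNS", "hr" = "NN", "mins" = "NNS", "min" = "NN",
    "days" = "NNS", "day" = "NN", "weeks" = "NNS", "week" = "NN",
    # chemical nouns whose endings look adjectival to the suffix rules
    "pentobarbital" = "NN", "phenobarbital" = "NN", "adjuvant" = "NN",
    "chloral" = "NN", "haloperidol" = "NN")
  jj_suffix <- "(ic|ical|al|ous|ive|ary|ory|ile|ant|ent|able|ible|ar|oid)$"
  prot_keys <- vapply(strsplit(bio_lexicon$protein, "\\s+"), function(x)
    paste(match_key(x), collapse = " "), "")
  cell_keys <- vapply(strsplit(bio_lexicon$cell, "\\s+"), function(x)
    paste(match_key(x), collapse = " "), "")

  function(tokens) {
    n <- nrow(tokens)
    pos <- character(n); prot <- logical(n); cell <- logical(n)
    low <- tolower(tokens$text)
    for (i in seq_len(n)) {
      tok <- tokens$text[i]; lt <- low[i]
      pos[i] <- if (grepl("^[,;:()%=]$", tok)) tok
      else if (!is.na(closed[lt])) unname(closed[lt])
      else if (vm_is_number(tok) || grepl("^[0-9.]+(mg|ml|kg|g|um|nm|mm)?(/(kg|ml|g|day|kg/day))?$", lt)) "CD"
      else if (grepl("ly$", lt) && nchar(lt) > 3L) "RB"
      else if (grepl("ed$", lt) && nchar(lt) > 3L) "VBN"
      else if (grepl("ing$", lt) && nchar(lt) > 4L) "VBG"
      else if (grepl(jj_suffix, lt) && nchar(lt) > 4L && !grepl("[0-9/]", tok)) "JJ"
      else if (i > 1L && grepl("^[A-Z][a-z]+$", tok)) "NNP"
      else "NN"
    }
    # multi-token bio-entity matching on alphanumeric keys
    keys <- match_key(low)
    mark <- function(entry_keys, flag) {
      for (ek in entry_keys) {
        parts <- strsplit(ek, " ")[[1]]
        L <- length(parts)
        if (L == 0L) next
        for (s in seq_len(max(0L, n - L + 1L))) {
          if (all(keys[s:(s + L - 1L)] == parts)) {
            if (flag == "prot") prot[s:(s + L - 1L)] <<- TRUE
            else cell[s:(s + L - 1L)] <<- TRUE
          }
        }
      }
    }
    mark(prot_keys, "prot")
    mark(cell_keys, "cell")
    data.frame(pos = pos, prot = prot, cell = cell, stringsAsFactors = FALSE)
  }
}

#' Tokenize and POS-tag a normalized description
#'
#' Produces a tagged sentence: one row per token with its Penn-Treebank POS
#' tag, an (initially empty) custom tag slot, and character offsets into the
#' normalized description. Protein / cell-line flags from the tagging
#' backend are written into the custom tag slot as `PROT` / `CELL`.
#'
#' @param text normalized description.
#' @param tagger tagging backend; defaults to the bundled
#'   [vm_default_tagger()]. Must be deterministic.
#' @param assay_id optional source assay identifier carried as an attribute.
#' @return a `vm_tagged_sentence`: data.frame with columns `text`, `pos`,
#'   `custom`, `start`, `end`; attributes `assay_id` and `text`.
#' @export
tag_tokens <- function(text, tagger = vm_default_tagger(), assay_id = NA_character_) {
  toks <- vm_tokenize(text)
  if (nrow(toks)) {
    tags <- tagger(toks)
    stopifnot(nrow(tags) == nrow(toks), all(c("pos", "prot", "cell") %in% names(tags)))
    toks$pos <- tags$pos
    toks$custom <- ifelse(tags$prot, "PROT", ifelse(tags$cell, "CELL", NA_character_))
  } else {
    toks$pos <- character(0); toks$custom <- character(0)
  }
  toks <- toks[, c("text", "pos", "custom", "start", "end")]
  structure(toks, class = c("vm_tagged_sentence", "data.frame"),
            assay_id = assay_id, text = text)
}

#' Apply custom procedure/transgenesis/species tags
#'
#' Overlays the custom tags `IND`, `IND_B`, `TRANSG`, `EXPR`, `KNOCK` and
#' `SP` on a tagged sentence by case-insensitive keyword matching. Existing
#' `PROT`/`CELL` tags are never overwritten.
#'
#' @param sentence a `vm_tagged_sentence` from [tag_tokens()].
#' @param keyword_config named keyword lists; see [vm_keyword_config()].
#' @return the sentence with `custom` tags filled in.
#' @export
apply_custom_tags <- function(sentence, keyword_config = vm_keyword_config()) {
  low <- tolower(sentence$text)
  sets <- list(IND = keyword_config$ind, IND_B = keyword_config$ind_b,
               TRANSG = keyword_config$transg, EXPR = keyword_config$expr,
               KNOCK = keyword_config$knock, SP = keyword_config$sp)
  for (tag in names(sets)) {
    hit <- low %in% tolower(sets[[tag]]) & is.na(sentence$custom)
    sentence$custom[hit] <- tag
  }
  sentence
}

# grammar symbol of a token: custom tag wins over POS
vm_grammar_symbol <- function(sentence) {
  ifelse(is.na(sentence$custom), sentence$pos, sentence$custom)
}

#' Extract base noun phrases
#'
#' Finds maximal non-overlapping token runs matching the chunking grammar
#' `NP: {<JJ|NN.*>* <PROT|CELL|NN.*>+}` over grammar symbols in which a
#' token's custom tag (IND, TRANSG, SP, PROT, CELL, ...) takes precedence
#' over its POS tag. Because procedure triggers carry IND rather than a
#' noun/adjective tag, phrases are automatically split at trigger words, so
#' "concanavalin A induced hepatic cell necrosis" yields the stimulus
#' ("concanavalin A") and the outcome ("hepatic cell necrosis") as separate
#' base phrases. Determiners and numbers never enter a phrase unless the
#' tagger marked them part of a protein or cell-line name.
#'
#' @param sentence a custom-tagged `vm_tagged_sentence`.
#' @return data.frame with one row per phrase: `surface`, `start`, `end`
#'   (character span), `first`, `last` (token indices, 1-based inclusive).
#' @export
extract_noun_phrases <- function(sentence) {
  n <- nrow(sentence)
  empty <- data.frame(surface = character(), start = integer(), end = integer(),
                      first = integer(), last = integer(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  sym <- vm_grammar_symbol(sentence)
  prefix_ok <- grepl("^(JJ|NN)", sym)            # <JJ|NN.*>
  tail_ok <- grepl("^NN", sym) | sym %in% c("PROT", "CELL")  # <PROT|CELL|NN.*>
  # leftmost-longest match of {prefix* tail+} starting at i: the longest j
  # such that tokens i..j split into a (possibly empty) prefix-run followed
  # by a non-empty tail-run
  match_at <- function(i) {
    best <- 0L
    for (j in i:n) {
      if (!(prefix_ok[j] || tail_ok[j])) break
      if (!tail_ok[j]) next
      g <- j
      while (g > i && tail_ok[g - 1L]) g <- g - 1L
      if (g == i || all(prefix_ok[i:(g - 1L)])) best <- j
    }
    best
  }
  out <- list(); i <- 1L
  while (i <= n) {
    j <- match_at(i)
    if (j >= i) {
      out[[length(out) + 1L]] <- data.frame(
        surface = paste(sentence$text[i:j], collapse = " "),
        start = sentence$start[i], end = sentence$end[j],
        first = i, last = j, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Build the embedding token stream for one sentence
#'
#' Converts a tagged sentence plus its base noun phrases into the token
#' list used for embedding training: multi-word phrases become single
#' underscore-joined tokens, strain mentions are replaced by their
#' normalized preferred names, numbers and stopwords are removed, and
#' everything is lower-cased.
#'
#' @param sentence a custom-tagged `vm_tagged_sentence`.
#' @param phrases output of [extract_noun_phrases()] for the same sentence.
#' @param strain_mentions optional data.frame of strain mentions covering
#'   this sentence (columns `first`, `last` token indices and `normalized`),
#'   e.g. from [match_dictionary_entities()]; covered tokens are replaced by
#'   the underscore-joined normalized name.
#' @param stopwords character vector; defaults to [vm_stopwords()].
#' @return character vector of tokens (possibly empty).
#' @export
tokens_for_embedding <- function(sentence, phrases = extract_noun_phrases(sentence),
                                 strain_mentions = NULL,
                                 stopwords = vm_stopwords()) {
  n <- nrow(sentence)
  if (!n) return(character())
  unit <- rep(NA_integer_, n)   # grouping id per token
  unit_text <- character()
  add_unit <- function(idx, txt) {
    unit_text[length(unit_text) + 1L] <<- txt
    unit[idx] <<- length(unit_text)
  }
  if (!is.null(strain_mentions) && nrow(strain_mentions)) {
    for (r in seq_len(nrow(strain_mentions))) {
      idx <- strain_mentions$first[r]:strain_mentions$last[r]
      add_unit(idx, gsub("\\s+", "_", tolower(strain_mentions$normalized[r])))
    }
  }
  if (!is.null(phrases) && nrow(phrases)) {
    for (r in seq_len(nrow(phrases))) {
      idx <- phrases$first[r]:phrases$last[r]
      idx <- idx[is.na(unit[idx])]
      if (length(idx)) {
        add_unit(idx, gsub("\\s+", "_",
                           tolower(paste(sentence$text[idx], collapse = " "))))
      }
    }
  }
  units <- c("mg", "kg", "g", "ug", "ng", "ml", "l", "ul", "mm", "cm", "um",
             "nm", "hr", "hrs", "min", "mins", "sec", "day", "days", "week",
             "weeks")
  droppable <- function(tok) {
    parts <- strsplit(tok, "[_/]")[[1]]
    all(vm_is_number(parts) | parts %in% units)
  }
  out <- character(); emitted <- logical(length(unit_text))
  for (i in seq_len(n)) {
    if (!is.na(unit[i])) {
      if (!emitted[unit[i]]) {
        emitted[unit[i]] <- TRUE
        if (!droppable(unit_text[unit[i]])) out <- c(out, unit_text[unit[i]])
      }
    } else {
      tok <- tolower(sentence$text[i])
      if (grepl("^[,;:()%=]$", tok) || tok == "'s") next
      if (tok %in% stopwords) next
      if (droppable(tok)) next
      out <- c(out, tok)
    }
  }
  out
}

#' Preprocess one description end to end
#'
#' Convenience wrapper chaining [normalize_description()], [tag_tokens()],
#' [apply_custom_tags()] and [extract_noun_phrases()].
#'
#' @param text raw description.
#' @param assay_id optional identifier.
#' @param tagger tagging backend.
#' @param acronym_map,keyword_config configuration tables.
#' @return list with `norm` (normalization result), `sentence`, `phrases`.
#' @export
preprocess_description <- function(text, assay_id = NA_character_,
                                   tagger = vm_default_tagger(),
                                   acronym_map = vm_acronym_map(),
                                   keyword_config = vm_keyword_config()) {
  norm <- normalize_description(text, acronym_map)
  sent <- tag_tokens(norm$text, tagger = tagger, assay_id = assay_id)
  sent <- apply_custom_tags(sent, keyword_config)
  list(norm = norm, sentence = sent, phrases = extract_noun_phrases(sent))
}
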