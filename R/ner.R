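vm_empty_mentions <- function() {
  data.frame(assay_id = character(), entity_class = character(),
             surface = character(), normalized = character(),
             start = integer(), end = integer(),
             first = integer(), last = integer(), stringsAsFactors = FALSE)
}

#' Match dictionary entities in a tagged sentence
#'
#' Longest-match, non-overlapping dictionary recognition over token
#' sequences. Strain matching uses concatenated alphanumeric keys (so
#' punctuation variants collide), folds substrains onto their inbred
#' parents, tolerates interleaved sex/age modifier words ("male", "female",
#' "adult") inside the span, and normalizes to "<preferred name> <species>".
#' Phenotype matching uses space-joined per-token keys against ontology
#' labels and exact synonyms, normalizing to the term label.
#'
#' @param sentence a `vm_tagged_sentence`.
#' @param dict a `vm_strain_dict` or `vm_pheno_dict`.
#' @param entity_class class label for emitted mentions; defaults to
#'   `"genetic_strain"` for strain dictionaries and `"phenotype"` for
#'   phenotype dictionaries.
#' @return mention data.frame (`assay_id`, `entity_class`, `surface`,
#'   `normalized`, `start`, `end`, `first`, `last`); offsets refer to the
#'   normalized description.
#' @export
match_dictionary_entities <- function(sentence, dict, entity_class = NULL) {
  UseMethod("match_dictionary_entities", dict)
}

#' @export
match_dictionary_entities.vm_strain_dict <- function(sentence, dict,
                                                     entity_class = "genetic_strain") {
  n <- nrow(sentence)
  out <- vm_empty_mentions()
  if (!n || !length(dict$key_index)) return(out)
  modifiers <- c("male", "female", "adult", "young", "aged")
  low <- tolower(sentence$text)
  keys <- match_key(sentence$text)
  # effective key: substrains fold to the inbred parent before lookup
  parents <- parse_substrain_parent(sentence$text, dict$inbred_basic)
  eff <- ifelse(parents != sentence$text, match_key(parents), keys)
  max_span <- 6L
  i <- 1L
  while (i <= n) {
    best_last <- NA_integer_; best_entry <- NA_integer_
    if (nzchar(eff[i]) && !(low[i] %in% modifiers)) {
      acc <- ""
      j <- i
      while (j <= min(n, i + max_span - 1L)) {
        if (low[j] %in% modifiers && j > i) { j <- j + 1L; next }
        if (!nzchar(eff[j]) && j > i) break
        acc <- paste0(acc, eff[j])
        hit <- dict$key_index[acc]
        if (!is.na(hit)) { best_last <- j; best_entry <- hit }
        j <- j + 1L
      }
    }
    if (!is.na(best_last)) {
      pref <- dict$entries$preferred_name[best_entry]
      out <- rbind(out, data.frame(
        assay_id = attr(sentence, "assay_id"), entity_class = entity_class,
        surface = substring(attr(sentence, "text"),
                            sentence$start[i] + 1L, sentence$end[best_last]),
        normalized = paste(pref, dict$species),
        start = sentence$start[i], end = sentence$end[best_last],
        first = i, last = best_last, stringsAsFactors = FALSE))
      i <- best_last + 1L
    } else i <- i + 1L
  }
  rownames(out) <- NULL
  out
}

#' @param biomarker_suffixes measurement words that, when they make up a
#'   phenotype match directly following a protein/cell-line token, mark a
#'   molecular biomarker ("IL4 production") rather than a phenotype; such
#'   matches are suppressed.
#' @rdname match_dictionary_entities
#' @export
match_dictionary_entities.vm_pheno_dict <- function(sentence, dict,
                                                    entity_class = "phenotype",
                                                    biomarker_suffixes =
                                                      c("level", "levels",
                                                        "production", "amount",
                                                        "content")) {
  n <- nrow(sentence)
  out <- vm_empty_mentions()
  if (!n || !length(dict$key_index)) return(out)
  keys <- match_key(sentence$text)
  low <- tolower(sentence$text)
  max_span <- 6L
  i <- 1L
  while (i <= n) {
    best_last <- NA_integer_; best_term <- NA_integer_
    if (nzchar(keys[i])) {
      for (j in i:min(n, i + max_span - 1L)) {
        if (!all(nzchar(keys[i:j]))) break
        hit <- dict$key_index[paste(keys[i:j], collapse = " ")]
        if (!is.na(hit)) { best_last <- j; best_term <- hit }
      }
    }
    if (!is.na(best_last) && i > 1L &&
        isTRUE(sentence$custom[i - 1L] %in% c("PROT", "CELL")) &&
        all(low[i:best_last] %in% biomarker_suffixes)) {
      best_last <- NA_integer_   # molecular biomarker, not a phenotype
    }
    if (!is.na(best_last)) {
      out <- rbind(out, data.frame(
        assay_id = attr(sentence, "assay_id"), entity_class = entity_class,
        surface = substring(attr(sentence, "text"),
                            sentence$start[i] + 1L, sentence$end[best_last]),
        normalized = dict$terms$label[best_term],
        start = sentence$start[i], end = sentence$end[best_last],
        first = i, last = best_last, stringsAsFactors = FALSE))
      i <- best_last + 1L
    } else i <- i + 1L
  }
  rownames(out) <- NULL
  out
}

#' Rule-based extraction of induced and transgenic animal models
#'
#' Applies the extraction-pattern set over phrase-level chunks and custom
#' tags. The core pattern `{<NP|FW|POS>* <IND>+}` captures a run of noun
#' phrases / foreign words / possessive endings followed by one or more
#' procedure triggers ("Freund's complete adjuvant induced",
#' "Staphylococcus aureus infected"). Companion patterns cover head-noun
#' assay names ("glucose tolerance test/assay/model"), diet phrases
#' ("high-fat diet fed"), surgical, infection and xenograft phrases, and
#' the transgenic family `{<NP>* <TRANSG|EXPR|KNOCK>+}` ("APOA1
#' transgenic"). IND-family matches are emitted as `experimental_model`
#' mentions, transgenesis matches as `transgenic_model`.
#'
#' @param sentence a custom-tagged `vm_tagged_sentence`.
#' @param phrases base noun phrases from [extract_noun_phrases()].
#' @param head_nouns lexical heads that turn a preceding noun phrase into an
#'   assay/model mention even without a trigger tag.
#' @return mention data.frame as in [match_dictionary_entities()].
#' @export
extract_rule_entities <- function(sentence, phrases = extract_noun_phrases(sentence),
                                  head_nouns = c("test", "assay", "model",
                                                 "paradigm", "task")) {
  n <- nrow(sentence)
  out <- vm_empty_mentions()
  if (!n) return(out)
  sym <- vm_grammar_symbol(sentence)
  in_phrase <- logical(n)
  if (nrow(phrases)) {
    for (r in seq_len(nrow(phrases))) in_phrase[phrases$first[r]:phrases$last[r]] <- TRUE
  }
  # chunk symbol per token: NP if inside a base noun phrase, else own symbol
  chunk <- ifelse(in_phrase, "NP", sym)
  low <- tolower(sentence$text)
  add <- function(first, last, cls) {
    out <<- rbind(out, data.frame(
      assay_id = attr(sentence, "assay_id"), entity_class = cls,
      surface = substring(attr(sentence, "text"),
                          sentence$start[first] + 1L, sentence$end[last]),
      normalized = paste(sentence$text[first:last], collapse = " "),
      start = sentence$start[first], end = sentence$end[last],
      first = first, last = last, stringsAsFactors = FALSE))
  }
  trigger <- list(experimental_model = c("IND", "IND_B"),
                  transgenic_model = c("TRANSG", "EXPR", "KNOCK"))
  for (cls in names(trigger)) {
    tags <- trigger[[cls]]
    i <- 1L
    while (i <= n) {
      if (chunk[i] %in% tags) {
        # extend trigger run rightwards
        last <- i
        while (last < n && chunk[last + 1L] %in% tags) last <- last + 1L
        # extend <NP|FW|POS>* run leftwards
        first <- i
        while (first > 1L && chunk[first - 1L] %in% c("NP", "FW", "POS")) {
          first <- first - 1L
        }
        add(first, last, cls)
        i <- last + 1L
      } else i <- i + 1L
    }
  }
  # head-noun assay names: base NP whose final token is a lexical head
  if (nrow(phrases)) {
    for (r in seq_len(nrow(phrases))) {
      lastTok <- low[phrases$last[r]]
      if (lastTok %in% head_nouns && phrases$last[r] > phrases$first[r]) {
        add(phrases$first[r], phrases$last[r], "experimental_model")
      }
    }
  }
  if (nrow(out)) {
    out <- out[order(out$entity_class, out$start, -out$end), , drop = FALSE]
    # non-overlapping within one class: keep leftmost-longest
    keep <- logical(nrow(out))
    for (cls in unique(out$entity_class)) {
      idx <- which(out$entity_class == cls); last_end <- -1L
      for (k in idx) {
        if (out$start[k] >= last_end) { keep[k] <- TRUE; last_end <- out$end[k] }
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Pipeline configuration for corpus annotation
#'
#' @param mouse_dict,rat_dict compiled strain dictionaries (optional).
#' @param pheno_dict compiled phenotype dictionary (optional).
#' @param tagger tagging backend.
#' @param acronym_map,keyword_config preprocessing configuration.
#' @return a `vm_pipeline` configuration list.
#' @export
vm_pipeline <- function(mouse_dict = NULL, rat_dict = NULL, pheno_dict = NULL,
                        tagger = vm_default_tagger(),
                        acronym_map = vm_acronym_map(),
                        keyword_config = vm_keyword_config()) {
  structure(list(mouse_dict = mouse_dict, rat_dict = rat_dict,
                 pheno_dict = pheno_dict, tagger = tagger,
                 acronym_map = acronym_map, keyword_config = keyword_config),
            class = "vm_pipeline")
}

#' Annotate a corpus of assay descriptions
#'
#' Runs preprocessing, dictionary and rule-based recognition over every
#' assay and returns one row per mention. Spans are reported both in
#' normalized-description coordinates (`start`, `end`) and mapped back to
#' the raw description (`raw_start`, `raw_end`) through the normalization
#' offset map. Individual description failures are recorded and skipped,
#' never fatal.
#'
#' @param assays assay table from [load_assay_table()] (or the synthetic
#'   generator).
#' @param pipeline a [vm_pipeline()] configuration.
#' @return mention table; attribute `summary` holds the number of distinct
#'   normalized model names and the number of assays with at least one
#'   animal-model mention, attribute `failures` the ids of skipped assays.
#' @export
annotate_corpus <- function(assays, pipeline = vm_pipeline()) {
  res <- list(); failures <- character()
  for (i in seq_len(nrow(assays))) {
    aid <- assays$assay_id[i]
    m <- tryCatch({
      pp <- preprocess_description(assays$description[i], assay_id = aid,
                                   tagger = pipeline$tagger,
                                   acronym_map = pipeline$acronym_map,
                                   keyword_config = pipeline$keyword_config)
      sent <- pp$sentence
      dicts <- list()
      sdict <- switch(assays$species[i], mouse = pipeline$mouse_dict,
                      rat = pipeline$rat_dict)
      if (!is.null(sdict)) {
        dicts[[length(dicts) + 1L]] <- match_dictionary_entities(sent, sdict)
      }
      if (!is.null(pipeline$pheno_dict)) {
        dicts[[length(dicts) + 1L]] <-
          match_dictionary_entities(sent, pipeline$pheno_dict)
      }
      dicts[[length(dicts) + 1L]] <- extract_rule_entities(sent, pp$phrases)
      m <- do.call(rbind, dicts)
      if (nrow(m)) {
        raw <- t(vapply(seq_len(nrow(m)), function(r)
          map_span(pp$norm$offsets, m$start[r], m$end[r], to = "raw"),
          integer(2)))
        m$raw_start <- raw[, 1]; m$raw_end <- raw[, 2]
      } else {
        m$raw_start <- integer(); m$raw_end <- integer()
      }
      m
    }, error = function(e) {
      failures <<- c(failures, aid)
      NULL
    })
    if (!is.null(m) && nrow(m)) res[[length(res) + 1L]] <- m
  }
  out <- if (length(res)) do.call(rbind, res) else {
    e <- vm_empty_mentions(); e$raw_start <- integer(); e$raw_end <- integer(); e
  }
  rownames(out) <- NULL
  model_classes <- c("genetic_strain", "experimental_model", "transgenic_model")
  is_model <- out$entity_class %in% model_classes
  attr(out, "summary") <- list(
    n_distinct_model_names = length(unique(out$normalized[is_model])),
    n_assays_with_model = length(unique(out$assay_id[is_model])))
  attr(out, "failures") <- failures
  out
}

#' Ranked mention frequencies
#'
#' Counts, for each normalized name, the number of distinct assays whose
#' description mentions it; descending, ties broken lexicographically.
#'
#' @param mentions mention table from [annotate_corpus()].
#' @param classes optional entity-class filter.
#' @param top_k maximum rows to return (default all).
#' @return data.frame `name`, `entity_class`, `n_assays`.
#' @export
mention_frequencies <- function(mentions, classes = NULL, top_k = Inf) {
  m <- mentions
  if (!is.null(classes)) m <- m[m$entity_class %in% classes, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(name = character(), entity_class = character(),
                      n_assays = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(m$entity_class, m$normalized, sep = "\r")
  pairs <- unique(data.frame(key = key, assay_id = m$assay_id,
                             stringsAsFactors = FALSE))
  cnt <- table(pairs$key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  out <- data.frame(name = vapply(parts, `[`, "", 2),
                    entity_class = vapply(parts, `[`, "", 1),
                    n_assays = as.integer(cnt), stringsAsFactors = FALSE)
  out <- out[order(-out$n_assays, out$name), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

# ---------------------------------------------------------------------------
# BRAT standoff I/O

#' Read / write BRAT standoff annotations
#'
#' BRAT pairs a `<doc>.txt` file containing the description with a
#' `<doc>.ann` file of text-bound annotations
#' (`T1<TAB>Class start end<TAB>surface`). `read_brat` loads every pair in
#' a directory; `write_brat` writes one pair per annotated description.
#'
#' @param dir directory of `.txt`/`.ann` pairs.
#' @return list of annotated descriptions: each has `doc_id`, `text` and
#'   `mentions` (data.frame `entity_class`, `start`, `end`, `surface`).
#' @export
read_brat <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tf) {
    doc_id <- sub("\\.txt$", "", basename(tf))
    text <- paste(readLines(tf, warn = FALSE), collapse = "\n")
    af <- file.path(dir, paste0(doc_id, ".ann"))
    men <- data.frame(entity_class = character(), start = integer(),
                      end = integer(), surface = character(),
                      stringsAsFactors = FALSE)
    if (file.exists(af)) {
      lines <- readLines(af, warn = FALSE)
      lines <- lines[grepl("^T", lines)]
      if (length(lines)) {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        men <- do.call(rbind, lapply(parts, function(p) {
          hdr <- strsplit(p[2], " ", fixed = TRUE)[[1]]
          data.frame(entity_class = hdr[1],
                     start = as.integer(hdr[2]), end = as.integer(hdr[3]),
                     surface = if (length(p) >= 3) p[3] else NA_character_,
                     stringsAsFactors = FALSE)
        }))
        bad <- men$start < 0 | men$end > nchar(text) | men$start >= men$end
        if (any(bad)) stop("invalid gold span in ", af)
      }
    }
    list(doc_id = doc_id, text = text, mentions = men)
  })
}

#' @rdname read_brat
#' @param annotated list of annotated descriptions (as returned by
#'   [read_brat()] or emitted by the synthetic generator).
#' @export
write_brat <- function(annotated, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in annotated) {
    writeLines(d$text, file.path(dir, paste0(d$doc_id, ".txt")))
    men <- d$mentions
    lines <- character()
    if (!is.null(men) && nrow(men)) {
      surf <- vapply(seq_len(nrow(men)), function(r)
        substring(d$text, men$start[r] + 1L, men$end[r]), "")
      lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(men)),
                       men$entity_class, men$start, men$end, surf)
    }
    writeLines(lines, file.path(dir, paste0(d$doc_id, ".ann")))
  }
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Evaluation

#' Evaluate predicted mentions against gold annotations
#'
#' Computes precision, recall and F1 per entity class and micro-averaged,
#' under exact matching (identical class and character span) or partial
#' matching (same class, any character overlap). Predicted and gold spans
#' must share a coordinate frame; a gold span outside its description is a
#' fatal error. Inter-annotator agreement between two annotation sets is
#' computed with the same machinery (pass one set as `predicted`).
#'
#' @param predicted mention table with columns `assay_id` (or `doc_id`),
#'   `entity_class`, `start`, `end` — e.g. from [annotate_corpus()] (use
#'   `raw_start`/`raw_end` by renaming when gold is in raw coordinates).
#' @param gold list of annotated descriptions ([read_brat()] output) whose
#'   `doc_id` values match `predicted$assay_id`.
#' @param mode `"exact"` or `"partial"`.
#' @return object of class `vm_ner_metrics`: per-class data.frame
#'   (`entity_class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `support`) plus micro-averaged row `"micro"`.
#' @export
evaluate_ner <- function(predicted, gold, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  gold_tab <- do.call(rbind, lapply(gold, function(d) {
    if (nrow(d$mentions) &&
        any(d$mentions$end > nchar(d$text) | d$mentions$start < 0)) {
      stop("gold span outside description text for ", d$doc_id)
    }
    if (!nrow(d$mentions)) return(NULL)
    cbind(data.frame(assay_id = d$doc_id, stringsAsFactors = FALSE),
          d$mentions[, c("entity_class", "start", "end")])
  }))
  if (is.null(gold_tab)) {
    gold_tab <- data.frame(assay_id = character(), entity_class = character(),
                           start = integer(), end = integer())
  }
  pred <- predicted[predicted$assay_id %in% vapply(gold, `[[`, "", "doc_id"), ,
                    drop = FALSE]
  classes <- sort(unique(c(gold_tab$entity_class, pred$entity_class)))
  score_class <- function(cls) {
    g <- gold_tab[gold_tab$entity_class == cls, , drop = FALSE]
    p <- pred[pred$entity_class == cls, , drop = FALSE]
    matched_g <- logical(nrow(g)); tp <- 0L
    for (r in seq_len(nrow(p))) {
      cand <- which(!matched_g & g$assay_id == p$assay_id[r] &
        (if (mode == "exact") g$start == p$start[r] & g$end == p$end[r]
         else g$start < p$end[r] & p$start[r] < g$end))
      if (length(cand)) { matched_g[cand[1]] <- TRUE; tp <- tp + 1L }
    }
    c(tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp, support = nrow(g))
  }
  rows <- t(vapply(classes, score_class, c(tp = 0L, fp = 0L, fn = 0L, support = 0L)))
  rows <- rbind(rows, micro = colSums(rows))
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  met <- t(apply(rows, 1, function(x) prf(x["tp"], x["fp"], x["fn"])))
  out <- data.frame(entity_class = rownames(rows), rows,
                    precision = met[, 1], recall = met[, 2], f1 = met[, 3],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(metrics = out, mode = mode), class = "vm_ner_metrics")
}

#' @export
print.vm_ner_metrics <- function(x, ...) {
  cat("NER evaluation (", x$mode, " matching)\n", sep = "")
  print(x$metrics, digits = 3)
  invisible(x)
}
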