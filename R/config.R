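#' Default administration-route/regimen acronym table
#'
#' The preprocessing step expands common dosing acronyms so that route and
#' schedule words are available to the grammar and the embedding model.
#' Two entries are printed in the source literature ("sc" -> subcutaneous,
#' "qd" -> daily); the remainder are standard pharmacology abbreviations
#' added to reach the documented table size of twenty and are editable.
#'
#' @return data.frame with columns `acronym`, `expansion`.
#' @export
vm_acronym_map <- function() {
  data.frame(
    acronym = c("sc", "iv", "ip", "po", "im", "icv", "it", "ipl",
                "ig", "id", "inh", "pr", "sl", "top", "ivt",
                "qd", "od", "bid", "tid", "qid"),
    expansion = c("subcutaneous", "intravenous", "intraperitoneal", "oral",
                  "intramuscular", "intracerebroventricular", "intrathecal",
                  "intraplantar", "intragastric", "intradermal", "inhalation",
                  "rectal", "sublingual", "topical", "intravitreal",
                  "daily", "once daily", "twice daily", "three times daily",
                  "four times daily"),
    stringsAsFactors = FALSE
  )
}

#' Keyword configuration for custom token tags
#'
#' Lists the trigger keywords that receive custom tags during shallow
#' parsing. `IND`/`IND_B` mark experimental-procedure triggers (the `IND_B`
#' subset may legitimately begin a phrase, e.g. "fasted"); `TRANSG`,
#' `EXPR` and `KNOCK` mark transgenesis keywords; `SP` marks species words.
#' The printed trigger examples (induced, infected, xenografted, fed,
#' operated, treated, pretreated, stimulated; transgenic, overexpressing,
#' knockout) are included verbatim; the rest extrapolate the families to
#' the documented size of twenty-four procedure keywords and are editable.
#'
#' @return named list of character vectors: `ind`, `ind_b`, `transg`,
#'   `expr`, `knock`, `sp`.
#' @export
vm_keyword_config <- function() {
  list(
    ind = c("induced", "infected", "xenografted", "fed", "operated",
            "treated", "pretreated", "stimulated", "challenged",
            "sensitized", "immunized", "implanted", "inoculated",
            "ligated", "lesioned", "irradiated", "injected", "evoked",
            "loaded", "grafted"),
    ind_b = c("fasted", "trained", "deprived", "exposed"),
    transg = c("transgenic"),
    expr = c("overexpressing", "expressing"),
    knock = c("knockout", "knockdown", "knockin", "deficient"),
    sp = c("rat", "rats", "mouse", "mice")
  )
}

#' Bundled English stopword list
#'
#' A fixed snapshot of a standard English stopword list (articles,
#' prepositions, pronouns, auxiliaries). Shipped verbatim in the package so
#' the embedding-token stream is reproducible.
#'
#' @return character vector of lower-case stopwords.
#' @export
vm_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "than", "that",
    "this", "these", "those", "of", "in", "on", "at", "by", "for", "to",
    "from", "with", "without", "as", "is", "are", "was", "were", "be",
    "been", "being", "am", "it", "its", "itself", "he", "him", "his",
    "she", "her", "hers", "they", "them", "their", "theirs", "we", "us",
    "our", "ours", "you", "your", "yours", "i", "me", "my", "mine",
    "not", "no", "nor", "so", "too", "very", "can", "will", "just",
    "do", "does", "did", "doing", "have", "has", "had", "having",
    "what", "which", "who", "whom", "when", "where", "why", "how",
    "all", "any", "both", "each", "few", "more", "most", "other",
    "some", "such", "only", "own", "same", "s", "t", "don", "should",
    "now", "during", "before", "after", "above", "below", "up", "down",
    "out", "off", "over", "under", "again", "further", "once", "here",
    "there", "about", "against", "between", "into", "through", "while",
    "because", "until", "per", "via", "vs", "versus")
}

#' Bundled protein and cell-line lexicons for the fallback tagger
#'
#' The recommended tagging backend is an external biomedical tagger whose
#' named-entity output supplies the `PROT`/`CELL` custom tags. The bundled
#' fallback tagger approximates that behaviour with small editable lexicons
#' of multi-word protein names and tumor cell lines common in rodent assay
#' descriptions.
#'
#' @return list with character vectors `protein` and `cell` (lower case;
#'   multi-word entries are matched on token boundaries).
#' @export
vm_bio_lexicon <- function() {
  list(
    protein = c("concanavalin a", "angiotensin 2", "angiotensin ii",
                "interleukin 2", "il-2", "il4", "tnf alpha", "insulin",
                "leptin", "apolipoprotein a-i", "apoa1", "collagen"),
    cell = c("l1210", "p388", "b16", "m5076", "hela", "mcf7", "ht29",
             "lewis lung", "ehrlich ascites", "walker 256")
  )
}
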