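#' Table dialect configuration
#'
#' Supplementary exports of assay/compound tables come in varying column
#' layouts; a dialect maps the file's column names onto the package's
#' canonical names and sets the delimiter.
#'
#' @param sep field delimiter (default tab).
#' @param columns named character vector mapping canonical names
#'   (`assay_id`, `description`, `species`, `document_id`, `compound_ids`,
#'   `compound_id`, `name`, `atc_codes`, `max_phase`) to file column names.
#'   Canonical names absent from the vector are assumed to be used verbatim
#'   in the file.
#' @param list_sep separator for multi-valued cells (compound id lists,
#'   ATC code lists); default ";".
#' @return a `vm_dialect` list.
#' @export
vm_dialect <- function(sep = "\t", columns = character(), list_sep = ";") {
  structure(list(sep = sep, columns = columns, list_sep = list_sep),
            class = "vm_dialect")
}

vm_read_table <- function(path, dialect) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  utils::read.delim(path, sep = dialect$sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

vm_map_columns <- function(df, dialect, required, optional = character()) {
  for (canon in c(required, optional)) {
    src <- if (canon %in% names(dialect$columns)) dialect$columns[[canon]] else canon
    if (src %in% names(df)) {
      names(df)[names(df) == src] <- canon
    } else if (canon %in% required) {
      stop("required column '", canon, "' (file column '", src,
           "') missing from table")
    }
  }
  df
}

#' Load an assay table
#'
#' Reads a delimited table of assay records (one row per assay: identifier,
#' free-text description, species, source-document identifier, tested
#' compound identifiers) and validates each row: the description must be
#' non-empty after trimming, the species must be "rat" or "mouse" (binomial
#' names are accepted and normalized), and the document identifier must be
#' non-empty. Failing rows are dropped and counted in the attached load
#' report.
#'
#' @param path file path.
#' @param dialect a [vm_dialect()].
#' @return data.frame with columns `assay_id`, `description`, `species`,
#'   `document_id` and list-column `compound_ids`; attribute `load_report`
#'   is a list with `n_read`, `n_kept`, `n_dropped`.
#' @export
load_assay_table <- function(path, dialect = vm_dialect()) {
  df <- vm_read_table(path, dialect)
  df <- vm_map_columns(df, dialect,
                       required = c("assay_id", "description", "species",
                                    "document_id"),
                       optional = "compound_ids")
  n_read <- nrow(df)
  sp <- tolower(trimws(as.character(df$species)))
  sp[sp == "rattus norvegicus"] <- "rat"
  sp[sp == "mus musculus"] <- "mouse"
  desc <- trimws(as.character(df$description))
  doc <- trimws(as.character(df$document_id))
  ok <- nzchar(desc) & !is.na(desc) & sp %in% c("rat", "mouse") &
    nzchar(doc) & !is.na(doc)
  cids <- if ("compound_ids" %in% names(df)) {
    lapply(strsplit(as.character(df$compound_ids), dialect$list_sep, fixed = TRUE),
           function(x) trimws(x[nzchar(trimws(x)) & !is.na(x)]))
  } else rep(list(character()), n_read)
  out <- data.frame(assay_id = as.character(df$assay_id), description = desc,
                    species = sp, document_id = doc, stringsAsFactors = FALSE)
  out$compound_ids <- cids
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- list(n_read = n_read, n_kept = sum(ok),
                                   n_dropped = n_read - sum(ok))
  out
}

#' Load a compound table
#'
#' Reads compound records (identifier, name, ATC codes, development phase).
#' ATC codes are upper-cased and validated against the ATC pattern (a
#' letter, two digits, optionally two letters and two further digits, or a
#' valid prefix thereof); malformed codes are dropped with a warning, but
#' the record itself is retained — compounds with no ATC code are needed
#' for novel-compound accounting.
#'
#' @inheritParams load_assay_table
#' @return data.frame with columns `compound_id`, `name`, `max_phase` and
#'   list-column `atc_codes`.
#' @export
load_compound_table <- function(path, dialect = vm_dialect()) {
  df <- vm_read_table(path, dialect)
  df <- vm_map_columns(df, dialect, required = "compound_id",
                       optional = c("name", "atc_codes", "max_phase"))
  codes <- if ("atc_codes" %in% names(df)) {
    lapply(strsplit(as.character(df$atc_codes), dialect$list_sep, fixed = TRUE),
           function(x) {
      x <- toupper(trimws(x)); x <- x[nzchar(x) & !is.na(x)]
      bad <- !vm_is_atc(x)
      if (any(bad)) warning("dropping malformed ATC code(s): ",
                            paste(x[bad], collapse = ", "), call. = FALSE)
      x[!bad]
    })
  } else rep(list(character()), nrow(df))
  mp <- if ("max_phase" %in% names(df)) {
    p <- suppressWarnings(as.integer(df$max_phase))
    p[is.na(p) | p < 0L | p > 4L] <- 0L
    p
  } else rep(0L, nrow(df))
  out <- data.frame(
    compound_id = as.character(df$compound_id),
    name = if ("name" %in% names(df)) as.character(df$name) else NA_character_,
    max_phase = mp, stringsAsFactors = FALSE)
  out$atc_codes <- codes
  rownames(out) <- NULL
  out
}

#' Validate ATC code strings
#'
#' A full ATC code is 7 characters: letter, 2 digits, 2 letters, 2 digits
#' (e.g. "N03AX09"); valid prefixes (levels 1-4: "N", "N03", "N03A",
#' "N03AX") are also accepted.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
vm_is_atc <- function(x) {
  grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", x)
}

#' Load an assay-compound link table
#'
#' The assay/compound join is many-to-many; this reads a two-column mapping
#' (`assay_id`, `compound_id`).
#'
#' @inheritParams load_assay_table
#' @return data.frame with columns `assay_id`, `compound_id`.
#' @export
load_link_table <- function(path, dialect = vm_dialect()) {
  df <- vm_read_table(path, dialect)
  df <- vm_map_columns(df, dialect, required = c("assay_id", "compound_id"))
  data.frame(assay_id = as.character(df$assay_id),
             compound_id = as.character(df$compound_id),
             stringsAsFactors = FALSE)
}

# assay_id -> character vector of compound ids, from links or list column
vm_assay_compounds <- function(assays, links = NULL) {
  if (!is.null(links) && nrow(links)) {
    split(links$compound_id, factor(links$assay_id, levels = assays$assay_id))
  } else {
    stats::setNames(assays$compound_ids, assays$assay_id)
  }
}

#' Corpus summary statistics
#'
#' Computes the description-length and linkage statistics used to
#' characterize the corpus: assay counts (overall, per species, per
#' document), distinct compounds, the number of assays involving at least
#' one approved drug (development phase 4), and the mean/median description
#' length in words. Words are counted by stripping punctuation and
#' splitting on whitespace; `expand_acronyms` controls whether counting
#' happens before or after acronym expansion.
#'
#' @param assays assay table from [load_assay_table()].
#' @param compounds compound table from [load_compound_table()].
#' @param links optional link table; when `NULL` the assay table's
#'   `compound_ids` column is used.
#' @param expand_acronyms logical; tokenize the acronym-expanded text
#'   (default `FALSE`: raw descriptions).
#' @param acronym_map acronym table used when `expand_acronyms = TRUE`.
#' @return list of class `vm_corpus_stats`.
#' @export
corpus_stats <- function(assays, compounds = NULL, links = NULL,
                         expand_acronyms = FALSE,
                         acronym_map = vm_acronym_map()) {
  n <- nrow(assays)
  if (!n) {
    return(structure(list(
      n_assays = 0L, n_per_species = c(mouse = 0L, rat = 0L),
      n_documents = 0L, n_distinct_compounds = 0L,
      n_assays_with_approved_drug = 0L,
      desc_length_mean = 0, desc_length_median = 0),
      class = "vm_corpus_stats"))
  }
  texts <- assays$description
  if (expand_acronyms) {
    texts <- vapply(texts, function(t) normalize_description(t, acronym_map)$text, "")
  }
  wc <- vapply(texts, function(t) {
    t <- gsub("[^A-Za-z0-9]+", " ", t)
    length(strsplit(trimws(t), "\\s+")[[1]])
  }, integer(1), USE.NAMES = FALSE)
  ac <- vm_assay_compounds(assays, links)
  all_cids <- unique(unlist(ac, use.names = FALSE))
  approved <- character()
  if (!is.null(compounds) && nrow(compounds)) {
    approved <- compounds$compound_id[compounds$max_phase == 4L]
  }
  n_appr <- sum(vapply(ac, function(x) any(x %in% approved), logical(1)))
  structure(list(
    n_assays = n,
    n_per_species = vapply(c(mouse = "mouse", rat = "rat"),
                           function(s) sum(assays$species == s), integer(1)),
    n_documents = length(unique(assays$document_id)),
    n_distinct_compounds = length(all_cids),
    n_assays_with_approved_drug = as.integer(n_appr),
    desc_length_mean = mean(wc),
    desc_length_median = stats::median(wc)),
    class = "vm_corpus_stats")
}

#' @export
print.vm_corpus_stats <- function(x, ...) {
  cat("Corpus:", x$n_assays, "assays in", x$n_documents, "documents\n")
  cat("  species:", paste(names(x$n_per_species), x$n_per_species,
                          collapse = ", "), "\n")
  cat("  distinct compounds:", x$n_distinct_compounds,
      "| assays with approved drug:", x$n_assays_with_approved_drug, "\n")
  cat(sprintf("  description length: mean %.1f, median %.1f words\n",
              x$desc_length_mean, x$desc_length_median))
  invisible(x)
}

#' Write assay/link tables back to disk
#'
#' Writes the normalized TSV snapshot consumed by [load_assay_table()]
#' (round-trip stable) and, optionally, a JSON load report.
#'
#' @param assays assay table.
#' @param path output TSV path.
#' @param report_path optional path for the JSON load report.
#' @param dialect a [vm_dialect()].
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(assays, path, report_path = NULL,
                              dialect = vm_dialect()) {
  df <- assays
  df$compound_ids <- vapply(assays$compound_ids, paste,
                            collapse = dialect$list_sep, FUN.VALUE = "")
  utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(report_path)) {
    rep <- attr(assays, "load_report")
    if (is.null(rep)) rep <- list(n_read = nrow(assays), n_kept = nrow(assays),
                                  n_dropped = 0L)
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE)
  }
  invisible(path)
}
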