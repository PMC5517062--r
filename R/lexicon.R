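#' Parse a substrain designation back to its parental strain
#'
#' Rodent substrain names append laboratory codes to the parental strain
#' after a slash ("AKR/NCr" is the Charles River substrain of AKR). The
#' parse strips the trailing laboratory-code segments if and only if the
#' remainder matches a known basic strain; otherwise the name is returned
#' unchanged, which protects hybrid designations ("B6D2F1") and names whose
#' slash is intrinsic ("ob/ob"). The operation is idempotent.
#'
#' @param name strain designation (character vector).
#' @param basic character vector of known basic strain names.
#' @return character vector of parent designations.
#' @export
parse_substrain_parent <- function(name, basic = character()) {
  bk <- match_key(basic)
  vapply(name, function(nm) {
    if (is.na(nm) || !grepl("/", nm)) return(nm)
    prefix <- sub("/.*$", "", nm)
    i <- match(match_key(prefix), bk)
    if (!is.na(i)) basic[i] else nm
  }, "", USE.NAMES = FALSE)
}

#' Compile a strain dictionary from a listing table
#'
#' Builds the species dictionary used for genetic-strain recognition. The
#' listing provides one row per basic strain with its type (inbred,
#' outbred, hybrid, congenic, coisogenic, other), synonyms and registered
#' substrains (";"-separated). Substrains of inbred strains are folded
#' under their parent; hybrid/congenic/coisogenic names remain individual
#' entries. Every name, synonym and substrain contributes alphanumeric
#' match keys (with and without the trailing species word) to the key
#' index; a key resolving to two different entries is a build error.
#'
#' @param listings data.frame with columns `name`, `type` and optionally
#'   `synonyms`, `substrains` (";"-separated strings or list columns).
#' @param species `"mouse"` or `"rat"`.
#' @return object of class `vm_strain_dict`.
#' @export
compile_strain_dictionary <- function(listings, species = c("mouse", "rat")) {
  species <- match.arg(species)
  empty <- structure(list(species = species,
                          entries = data.frame(preferred_name = character(),
                                               strain_type = character(),
                                               stringsAsFactors = FALSE),
                          key_index = integer(), inbred_basic = character()),
                     class = "vm_strain_dict")
  if (is.null(listings) || !nrow(listings)) return(empty)
  as_list_col <- function(x) {
    if (is.list(x)) lapply(x, function(v) trimws(v[nzchar(trimws(v))]))
    else lapply(strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE),
                function(v) trimws(v[nzchar(trimws(v))]))
  }
  syn <- if ("synonyms" %in% names(listings)) as_list_col(listings$synonyms)
         else rep(list(character()), nrow(listings))
  sub <- if ("substrains" %in% names(listings)) as_list_col(listings$substrains)
         else rep(list(character()), nrow(listings))
  type <- tolower(trimws(as.character(listings$type)))
  type[!type %in% c("inbred", "outbred", "hybrid", "congenic", "coisogenic")] <- "other"
  entries <- data.frame(preferred_name = trimws(as.character(listings$name)),
                        strain_type = type, stringsAsFactors = FALSE)
  entries$synonyms <- syn
  entries$substrains <- sub
  # invariant: preferred name never listed among its own synonyms
  for (i in seq_len(nrow(entries))) {
    entries$synonyms[[i]] <-
      setdiff(entries$synonyms[[i]], entries$preferred_name[i])
  }
  key_index <- integer(); key_of <- character()
  add_key <- function(k, i) {
    if (!nzchar(k)) return()
    j <- key_index[k]
    if (!is.na(j) && j != i) {
      stop("strain key collision: '", k, "' maps to both '",
           entries$preferred_name[j], "' and '", entries$preferred_name[i], "'")
    }
    key_index[k] <<- i
  }
  for (i in seq_len(nrow(entries))) {
    names_i <- c(entries$preferred_name[i], entries$synonyms[[i]],
                 entries$substrains[[i]])
    for (nm in names_i) {
      k <- match_key(nm)
      add_key(k, i)
      add_key(paste0(k, species), i)
    }
  }
  structure(list(species = species, entries = entries, key_index = key_index,
                 inbred_basic = entries$preferred_name[entries$strain_type == "inbred"]),
            class = "vm_strain_dict")
}

#' @export
print.vm_strain_dict <- function(x, ...) {
  cat("Strain dictionary (", x$species, "): ", nrow(x$entries), " entries, ",
      length(x$key_index), " match keys\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# OBO parsing and the phenotype dictionary

#' Parse a minimal OBO file
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 file, extracting term id, name,
#' synonyms (with scope) and obsolescence. Only the fields needed for
#' dictionary construction are parsed.
#'
#' @param path OBO file path.
#' @return data.frame with columns `id`, `name`, `synonym`, `scope`,
#'   `obsolete`; the term's own name appears as a row with scope `"label"`.
#' @export
read_obo_terms <- function(path) {
  if (!file.exists(path)) stop("cannot parse OBO file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rows <- list(); cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    nm <- if (is.null(cur$name)) NA_character_ else cur$name
    syn <- cur$syn; scope <- cur$scope
    data.frame(id = cur$id,
               name = nm,
               synonym = c(nm, syn),
               scope = c("label", scope),
               obsolete = isTRUE(cur$obsolete),
               stringsAsFactors = FALSE)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      rows[[length(rows) + 1L]] <- if (in_term) flush(cur) else NULL
      cur <- list(syn = character(), scope = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      rows[[length(rows) + 1L]] <- if (in_term) flush(cur) else NULL
      in_term <- FALSE
    } else if (in_term) {
      if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
      else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
      else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
      else if (grepl("^synonym:", ln)) {
        m <- regmatches(ln, regexec("^synonym:\\s*\"([^\"]*)\"\\s*([A-Z]*)", ln))[[1]]
        if (length(m) == 3L && nzchar(m[2])) {
          cur$syn <- c(cur$syn, m[2])
          cur$scope <- c(cur$scope, ifelse(nzchar(m[3]), m[3], "RELATED"))
        }
      }
    }
  }
  rows[[length(rows) + 1L]] <- if (in_term) flush(cur) else NULL
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(id = character(), name = character(), synonym = character(),
                      scope = character(), obsolete = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build the phenotype dictionary from OBO ontologies
#'
#' Indexes term labels (and, by default, exact synonyms) of non-obsolete
#' terms from a set of phenotype/trait/disease/behavior ontologies. Terms
#' shorter than `min_len` characters and terms on the blocklist (generic
#' English words that would flood the matcher, e.g. "activity") are
#' excluded. Synonyms fold onto the term label, which becomes the
#' normalized mention form; duplicated labels across ontologies are merged
#' keeping all source ids.
#'
#' @param obo_paths character vector of OBO files.
#' @param min_len minimum term length in characters (default 3).
#' @param blocklist character vector of lower-case terms to exclude.
#' @param synonym_scope `"exact"` (default) to index EXACT synonyms only,
#'   `"all"` to widen to narrow/broad/related synonyms.
#' @return object of class `vm_pheno_dict`: `terms` (data.frame `label`,
#'   `sources`) and `key_index` (named integer: space-joined token match
#'   keys -> row in `terms`).
#' @export
load_phenotype_dictionary <- function(obo_paths, min_len = 3L,
                                      blocklist = character(),
                                      synonym_scope = c("exact", "all")) {
  synonym_scope <- match.arg(synonym_scope)
  all_terms <- lapply(obo_paths, read_obo_terms)
  tab <- do.call(rbind, all_terms)
  if (is.null(tab)) tab <- data.frame(id = character(), name = character(),
                                      synonym = character(), scope = character(),
                                      obsolete = logical())
  tab$source <- rep(basename(obo_paths),
                    vapply(all_terms, nrow, integer(1)))
  tab <- tab[!tab$obsolete & !is.na(tab$name) & !is.na(tab$synonym), , drop = FALSE]
  if (synonym_scope == "exact") {
    tab <- tab[tab$scope %in% c("label", "EXACT"), , drop = FALSE]
  }
  tab <- tab[nchar(tab$synonym) >= min_len, , drop = FALSE]
  tab <- tab[!tolower(tab$synonym) %in% tolower(blocklist) &
             !tolower(tab$name) %in% tolower(blocklist), , drop = FALSE]
  labels <- sort(unique(tab$name))
  terms <- data.frame(label = labels, stringsAsFactors = FALSE)
  terms$sources <- lapply(labels, function(l) sort(unique(tab$id[tab$name == l])))
  key_of <- function(s) {
    toks <- vm_tokenize(s)
    paste(match_key(toks$text), collapse = " ")
  }
  key_index <- integer()
  for (r in seq_len(nrow(tab))) {
    k <- key_of(tab$synonym[r])
    if (!nzchar(gsub(" ", "", k))) next
    i <- match(tab$name[r], labels)
    # first writer wins on cross-term ambiguity; duplicates to same term fine
    if (is.na(key_index[k])) key_index[k] <- i
  }
  structure(list(terms = terms, key_index = key_index, min_len = min_len),
            class = "vm_pheno_dict")
}

#' @export
print.vm_pheno_dict <- function(x, ...) {
  cat("Phenotype dictionary:", nrow(x$terms), "terms,",
      length(x$key_index), "match keys\n")
  invisible(x)
}

#' Serialize / restore compiled dictionaries
#'
#' Dictionaries serialize to a versioned JSON artifact so recognition runs
#' are reproducible without rebuilding from listings.
#'
#' @param dict a `vm_strain_dict` or `vm_pheno_dict`.
#' @param path JSON output path.
#' @return `path` invisibly (write) / the dictionary (read).
#' @export
write_dictionary <- function(dict, path) {
  data <- unclass(dict)
  # named vectors must serialize as JSON objects, not bare arrays
  data$key_index <- as.list(data$key_index)
  payload <- list(format_version = 1L, class = class(dict)[1], data = data)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- payload$data
  if (payload$class == "vm_strain_dict") {
    ki <- unlist(d$key_index)
    entries <- as.data.frame(d$entries, stringsAsFactors = FALSE)
    if (!is.list(entries$synonyms)) entries$synonyms <- as.list(entries$synonyms)
    if (!is.list(entries$substrains)) entries$substrains <- as.list(entries$substrains)
    structure(list(species = d$species, entries = entries,
                   key_index = stats::setNames(as.integer(ki), names(ki)),
                   inbred_basic = as.character(unlist(d$inbred_basic))),
              class = "vm_strain_dict")
  } else {
    ki <- unlist(d$key_index)
    terms <- as.data.frame(d$terms, stringsAsFactors = FALSE)
    if (!is.list(terms$sources)) terms$sources <- as.list(terms$sources)
    structure(list(terms = terms,
                   key_index = stats::setNames(as.integer(ki), names(ki)),
                   min_len = d$min_len),
              class = "vm_pheno_dict")
  }
}
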