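#' Tokenize text with character offsets
#'
#' Splits a description into word-like tokens, numbers and punctuation,
#' recording 0-based half-open character offsets into the input string.
#' Hyphens act as separators (so "carrageenan-induced" yields two tokens,
#' which lets procedure-trigger keywords carry their own tag), while "/",
#' "." and "'" are kept inside tokens so strain designations ("C57BL/6J",
#' "ob/ob"), decimal doses ("5.16") and names ("Freund's") survive intact.
#' A trailing possessive "'s" is split off as its own token (tagged POS
#' downstream), matching Penn-Treebank conventions.
#'
#' @param text character scalar.
#' @return data.frame with columns `text`, `start`, `end` (0-based,
#'   half-open offsets into `text`).
#' @export
vm_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  pat <- "[A-Za-z0-9](?:[A-Za-z0-9/.']*[A-Za-z0-9])?|[,;:()%=]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  toks <- substring(text, starts + 1L, starts + lens)
  out <- data.frame(text = toks, start = starts, end = starts + lens,
                    stringsAsFactors = FALSE)
  # split possessive 's into its own token
  poss <- grepl("[A-Za-z0-9]'s$", out$text)
  if (any(poss)) {
    rows <- vector("list", nrow(out))
    for (i in seq_len(nrow(out))) {
      r <- out[i, ]
      if (poss[i]) {
        base_end <- r$end - 2L
        rows[[i]] <- data.frame(
          text = c(substr(r$text, 1L, nchar(r$text) - 2L), "'s"),
          start = c(r$start, base_end),
          end = c(base_end, r$end),
          stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- r
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  out
}

#' Alphanumeric match key
#'
#' Canonical form used for all dictionary lookups: lower-cased with every
#' non-alphanumeric character removed, so that punctuation variants of the
#' same strain name ("ob-ob mouse", "ob/ob mouse") collide on one key.
#'
#' @param s character vector.
#' @return character vector of keys (empty string for empty/NA input).
#' @examples
#' match_key("ob-ob mouse") == match_key("ob/ob mouse")
#' @export
match_key <- function(s) {
  s[is.na(s)] <- ""
  gsub("[^a-z0-9]", "", tolower(s))
}

# is a token purely numeric / measurement-like (dropped from embeddings)
vm_is_number <- function(tok) {
  grepl("^[0-9][0-9.,/]*$", tok)
}

# stable seed derivation that stays inside 32-bit integer range
vm_derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}
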