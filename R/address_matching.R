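# Fuzzy matching of free-text addresses to the reference address base and its
# property reference numbers (UPRNs) — the linkage key between exposure rows
# and person-level records.
#
# Normalization uppercases, strips punctuation, collapses whitespace, expands
# a street-type abbreviation table and canonicalizes the postcode token.
# Matching is exact on the normalized string where possible, otherwise a
# token-set (order-insensitive) similarity with a hard postcode-mismatch
# penalty; ties break by postcode agreement, then by the numerically smaller
# UPRN, so results are fully deterministic.

ADDRESS_ABBREV <- c(
  "ST" = "STREET", "RD" = "ROAD", "AVE" = "AVENUE", "AV" = "AVENUE",
  "LN" = "LANE", "DR" = "DRIVE", "CT" = "COURT", "PL" = "PLACE",
  "CRES" = "CRESCENT", "GDNS" = "GARDENS", "TER" = "TERRACE",
  "SQ" = "SQUARE", "CL" = "CLOSE", "GRV" = "GROVE", "PK" = "PARK",
  "HSE" = "HOUSE", "APT" = "APARTMENT", "FLR" = "FLOOR"
)

POSTCODE_RE <- "([A-Z]{1,2}[0-9][A-Z0-9]?)\\s*([0-9][A-Z]{2})"

#' Normalize a free-text address
#'
#' Uppercases, replaces punctuation with spaces, collapses whitespace,
#' expands street-type abbreviations (ST -> STREET, RD -> ROAD, ...) and
#' canonicalizes any postcode to a single internal space. Idempotent.
#'
#' @param raw Address string.
#' @return Character vector of tokens (empty for blank input), with the
#'   detected postcode (or `NA`) in attribute `postcode`.
#' @export
normalize_address <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    return(structure(character(0), postcode = NA_character_))
  }
  s <- toupper(raw)
  s <- gsub("[[:punct:]]", " ", s)
  s <- gsub("\\s+", " ", trimws(s))
  pc <- NA_character_
  m <- regmatches(s, regexec(paste0("\\b", POSTCODE_RE, "\\b"), s))[[1L]]
  if (length(m) == 3L + 0L) {
    pc <- paste(m[2L], m[3L])
    s <- trimws(gsub(paste0("\\b", POSTCODE_RE, "\\b"), "", s))
    s <- gsub("\\s+", " ", s)
  }
  tokens <- strsplit(s, " ", fixed = TRUE)[[1L]]
  tokens <- tokens[nzchar(tokens)]
  hit <- !is.na(ADDRESS_ABBREV[tokens])
  tokens[hit] <- ADDRESS_ABBREV[tokens[hit]]
  if (!is.na(pc)) tokens <- c(tokens, strsplit(pc, " ")[[1L]])
  structure(tokens, postcode = pc)
}

# Multiset Sorensen-Dice similarity between two token vectors.
token_set_similarity <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  inter <- sum(pmin(ta[common], tb[common]))
  2 * inter / (length(a) + length(b))
}

#' Prepare a reference address base for matching
#'
#' @param addressbase Data frame with `uprn`, `address` and optionally
#'   `postcode`.
#' @return The address base with precomputed normalized tokens/keys.
#' @export
prepare_addressbase <- function(addressbase) {
  stopifnot(all(c("uprn", "address") %in% names(addressbase)))
  norm <- lapply(addressbase$address, normalize_address)
  addressbase$.tokens <- norm
  addressbase$.key <- vapply(norm, paste, character(1), collapse = " ")
  addressbase$.postcode <- vapply(norm, function(t) {
    p <- attr(t, "postcode")
    if (is.na(p) || is.null(p)) NA_character_ else p
  }, character(1))
  if ("postcode" %in% names(addressbase)) {
    explicit <- vapply(addressbase$postcode, function(p) {
      t <- normalize_address(as.character(p))
      attr(t, "postcode") %||% NA_character_
    }, character(1))
    addressbase$.postcode <- ifelse(is.na(addressbase$.postcode), explicit,
                                    addressbase$.postcode)
  }
  addressbase
}

#' Match one address against the reference base
#'
#' @param raw Free-text address string.
#' @param addressbase Reference base, ideally pre-processed with
#'   [prepare_addressbase()].
#' @param threshold Minimum fuzzy score to accept a match (default 0.85).
#' @return One-row data frame: `query`, `uprn` (NA if unmatched), `score`,
#'   `method` (`exact` / `fuzzy` / `none`).
#' @export
match_address <- function(raw, addressbase, threshold = 0.85) {
  if (is.null(addressbase$.key)) addressbase <- prepare_addressbase(addressbase)
  if (nrow(addressbase) == 0L) stop("empty address base", call. = FALSE)
  qt <- normalize_address(raw)
  result <- function(uprn, score, method) {
    data.frame(query = if (is.na(raw)) "" else raw, uprn = uprn,
               score = score, method = method, stringsAsFactors = FALSE)
  }
  if (length(qt) == 0L) return(result(NA_real_, 0, "none"))
  qkey <- paste(qt, collapse = " ")
  qpc <- attr(qt, "postcode")
  hits <- which(addressbase$.key == qkey)
  if (length(hits) > 0L) {
    return(result(min(addressbase$uprn[hits]), 1, "exact"))
  }
  scores <- vapply(addressbase$.tokens, token_set_similarity, numeric(1), b = qt)
  # hard penalty when both sides state a postcode and they disagree
  pc_mismatch <- !is.na(qpc) & !is.na(addressbase$.postcode) &
    addressbase$.postcode != qpc
  scores[pc_mismatch] <- scores[pc_mismatch] * 0.5
  best <- max(scores)
  if (best < threshold) return(result(NA_real_, best, "none"))
  cand <- which(scores >= best - 1e-12)
  if (length(cand) > 1L) {
    agree <- !is.na(qpc) & !is.na(addressbase$.postcode[cand]) &
      addressbase$.postcode[cand] == qpc
    if (any(agree)) cand <- cand[agree]
  }
  result(min(addressbase$uprn[cand]), best, "fuzzy")
}

#' Match many addresses
#'
#' @param queries Character vector (or data frame with `raw_address`).
#' @inheritParams match_address
#' @return Data frame with one `MatchResult` row per query.
#' @export
match_addresses <- function(queries, addressbase, threshold = 0.85) {
  if (is.data.frame(queries)) queries <- queries$raw_address
  addressbase <- prepare_addressbase(addressbase)
  do.call(rbind, lapply(queries, match_address, addressbase = addressbase,
                        threshold = threshold))
}
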