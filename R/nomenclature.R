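# Parsing of verbatim scientific names and the taxon-concept rule table.

RANK_ALIASES <- c(
  "var" = "var", "var." = "var", "v." = "var",
  "subsp" = "subsp", "subsp." = "subsp", "ssp" = "subsp", "ssp." = "subsp",
  "subspecies" = "subsp",
  "f" = "f", "f." = "f", "forma" = "f", "form" = "f"
)

CATEGORY_LEVELS <- c("correct", "misidentification", "soft_change",
                     "hard_change", "not_identified",
                     "excluded_circularity", "unresolvable")

CHANGE_TYPES <- c("same_concept", "synonym", "rank_change", "merge",
                  "split_allopatric", "split_sympatric",
                  "nomenclatural_confusion", "plain_error")

# change types admissible for each rule category
CATEGORY_CHANGE_TYPES <- list(
  correct           = "same_concept",
  misidentification = "plain_error",
  soft_change       = c("synonym", "rank_change", "merge", "split_allopatric"),
  hard_change       = c("split_sympatric", "nomenclatural_confusion")
)

#' Parse verbatim taxon names
#'
#' Parses free-text determinations such as `"H. helix var. canariensis Willd."`
#' into genus, specific epithet and an optional infraspecific rank and epithet.
#' Authorship strings are stripped, the rank abbreviations `var.`, `subsp.`,
#' `ssp.`, `f.`, `forma` are normalised, a leading `"H."` is expanded to
#' `"Hedera"`, and case is normalised so that `"hedera HELIX"` and
#' `"Hedera helix"` parse identically.
#'
#' Empty strings, `"NA"`, bare genus names and `"Hedera sp."` have no species
#' epithet and yield an all-`NA` row (an absent name).
#'
#' @param x character vector of verbatim names.
#' @param genus_default genus substituted for a single-letter abbreviation
#'   (`"H."`); default `"Hedera"`.
#' @return data.frame with one row per input and columns `genus`, `epithet`,
#'   `rank` (one of `"var"`, `"subsp"`, `"f"` or `NA`) and `infra`. A row is
#'   all-`NA` when the name is absent or unparseable.
#' @examples
#' parse_name(c("H. helix var. canariensis", "Hedera helix L.", "Hedera"))
#' @export
parse_name <- function(x, genus_default = "Hedera") {
  x <- as.character(x)
  out <- data.frame(genus = rep(NA_character_, length(x)),
                    epithet = NA_character_, rank = NA_character_,
                    infra = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) next
    v <- gsub("×", " ", v)            # hybrid sign treated as noise
    v <- trimws(gsub("\\s+", " ", v))
    if (v == "" || toupper(v) == "NA") next
    toks <- strsplit(v, " ", fixed = TRUE)[[1]]
    g <- toks[1]
    if (grepl("^[A-Za-z]\\.$", g)) g <- genus_default
    if (!grepl("^[A-Za-z][A-Za-z-]*$", g)) next
    g <- paste0(toupper(substr(g, 1, 1)), tolower(substr(g, 2, nchar(g))))
    if (length(toks) < 2) { next }         # genus only -> absent
    ep <- tolower(toks[2])
    if (ep %in% c("sp.", "sp", "spec.", "species")) next
    if (!grepl("^[a-z][a-z-]*$", ep)) next # authorship right after genus
    rank <- NA_character_; infra <- NA_character_
    j <- 3
    while (j <= length(toks)) {
      rk <- RANK_ALIASES[tolower(toks[j])]
      if (!is.na(rk)) {
        if (j < length(toks) && grepl("^[a-z][a-z-]*$", tolower(toks[j + 1]))) {
          rank <- unname(rk)
          infra <- tolower(toks[j + 1])
        }
        break
      }
      j <- j + 1
    }
    out$genus[i] <- g; out$epithet[i] <- ep
    out$rank[i] <- rank; out$infra[i] <- infra
  }
  out
}

#' Rank-collapsed matching key of a parsed name
#'
#' Infraspecific rank markers are dropped so that `"H. helix var. canariensis"`
#' and `"H. helix subsp. canariensis"` share the key
#' `"Hedera helix canariensis"` — herbarium labels use the ranks
#' interchangeably for the same legacy concepts, so rules and matrix rows are
#' keyed rank-free.
#'
#' @param parsed data.frame from [parse_name()].
#' @return character vector of keys; `NA` where the name is absent.
#' @export
name_key <- function(parsed) {
  ifelse(is.na(parsed$epithet), NA_character_,
         ifelse(is.na(parsed$infra),
                paste(parsed$genus, parsed$epithet),
                paste(parsed$genus, parsed$epithet, parsed$infra)))
}

#' Display label for a name key
#'
#' Three-token keys are rendered with a generic `var.` marker standing for any
#' infraspecific rank (var./subsp./f.), matching how classification-matrix
#' rows group infraspecific legacy names.
#'
#' @param key character vector of keys from [name_key()].
#' @return character vector of labels.
#' @export
label_from_key <- function(key) {
  vapply(key, function(k) {
    if (is.na(k)) return(NA_character_)
    toks <- strsplit(k, " ", fixed = TRUE)[[1]]
    if (length(toks) == 3) paste(toks[1], toks[2], "var.", toks[3]) else k
  }, character(1), USE.NAMES = FALSE)
}

#' Load and validate a taxon-concept rule table
#'
#' The knowledge base is a delimited file with columns `original_name`,
#' `revised_species`, `category`, `change_type` and `note`. Each row states
#' how one (original determination, revised species) pair is to be read:
#' as a correct identification, a misidentification, or a soft or hard
#' taxonomic change. Categories are data, not code: the same original name
#' can be a misidentification against one revised species and a nomenclatural
#' change against another.
#'
#' Validation enforces: known categories and change types, category/change-type
#' consistency (soft changes are synonyms, rank changes, merges or allopatric
#' splits; hard changes are sympatric splits or nomenclatural confusion), and
#' uniqueness of (original, revised) pairs after rank collapsing.
#'
#' @param path file path; defaults to the packaged Hedera rule table.
#' @return data.frame of class `concept_kb` with the file's columns plus
#'   `original_key` and `revised_key`.
#' @export
load_concept_kb <- function(path = system.file("extdata",
                                               "hedera_concept_rules.csv",
                                               package = "ivyaudit")) {
  kb <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("original_name", "revised_species", "category", "change_type")
  miss <- setdiff(need, names(kb))
  if (length(miss) > 0)
    stop("rule table missing columns: ", paste(miss, collapse = ", "))
  bad_cat <- setdiff(unique(kb$category), names(CATEGORY_CHANGE_TYPES))
  if (length(bad_cat) > 0)
    stop("invalid rule categories: ", paste(bad_cat, collapse = ", "))
  bad_ct <- setdiff(unique(kb$change_type), CHANGE_TYPES)
  if (length(bad_ct) > 0)
    stop("invalid change types: ", paste(bad_ct, collapse = ", "))
  ok <- mapply(function(cat, ct) ct %in% CATEGORY_CHANGE_TYPES[[cat]],
               kb$category, kb$change_type)
  if (!all(ok))
    stop("category/change_type mismatch in rows: ",
         paste(which(!ok), collapse = ", "))
  kb$original_key <- name_key(parse_name(kb$original_name))
  kb$revised_key <- name_key(parse_name(kb$revised_species))
  if (anyNA(kb$original_key) || anyNA(kb$revised_key))
    stop("rule table contains unparseable names")
  dup <- duplicated(paste(kb$original_key, kb$revised_key, sep = " -> "))
  if (any(dup))
    stop("duplicate (original, revised) pairs: ",
         paste(unique(paste(kb$original_key[dup], kb$revised_key[dup],
                            sep = " -> ")), collapse = "; "))
  class(kb) <- c("concept_kb", "data.frame")
  kb
}

#' Look up the rule for an (original name, revised species) pair
#'
#' Matching is exact on the rank-collapsed keys of both names. Returns `NULL`
#' when the pair is not catalogued.
#'
#' @param name a parsed name (one-row data.frame from [parse_name()]) or a key
#'   string from [name_key()].
#' @param revised revised species name (character) or its key.
#' @param kb a `concept_kb` from [load_concept_kb()].
#' @return one-row data.frame (the rule) or `NULL`.
#' @export
lookup_rule <- function(name, revised, kb) {
  k <- if (is.data.frame(name)) {
    name_key(name)
  } else if (name %in% kb$original_key) {   # already a rank-collapsed key
    name
  } else {
    name_key(parse_name(name))
  }
  rk <- if (is.character(revised) && revised %in% kb$revised_key) revised else
    name_key(parse_name(revised))
  hit <- which(kb$original_key == k & kb$revised_key == rk)
  if (length(hit) == 0) return(NULL)
  kb[hit[1], , drop = FALSE]
}
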