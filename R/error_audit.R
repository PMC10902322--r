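# Record-level identification-error audit: circularity filtering,
# per-record error classification, and the classification matrix.

#' Default circularity-blocked surnames
#'
#' The taxonomists behind the reference species concept; records they
#' determined are removed before auditing (see [filter_circularity()]).
#' @export
BLOCKED_IDENTIFIERS <- c("Valcárcel", "McAllister", "Vargas", "Rutherford")

NOT_IDENTIFIED_LABEL <- "Not identified"

# "incorrect" in rate tables and the GLM response
INCORRECT_CATEGORIES <- c("misidentification", "soft_change", "hard_change",
                          "not_identified")

# lower-cased letters only: accent- and punctuation-insensitive matching
fold_ascii <- function(x) {
  y <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  y[is.na(y)] <- x[is.na(y)]
  gsub("[^a-z]", "", tolower(y))
}

#' Remove records determined by the reference taxonomists
#'
#' Records originally identified by the botanists whose criterion serves as
#' the audit's ground truth must be excluded, otherwise the audit would
#' score the reference against itself. Matching is by surname token,
#' case- and accent-insensitive, because herbarium label formats vary
#' ("det. Valcarcel, V.", "V. Valcárcel").
#'
#' @param records `occ_df` data.frame.
#' @param blocked surnames to block; defaults to the genus reference
#'   taxonomists (Valcárcel, McAllister, Vargas, Rutherford).
#' @return list with `kept` and `excluded` occurrence data.frames, both in
#'   input order.
#' @export
filter_circularity <- function(records, blocked = BLOCKED_IDENTIFIERS) {
  idf <- fold_ascii(ifelse(is.na(records$identified_by), "",
                           records$identified_by))
  pat <- fold_ascii(blocked)
  hit <- rep(FALSE, nrow(records))
  for (p in pat) hit <- hit | grepl(p, idf, fixed = TRUE)
  list(kept = records[!hit, , drop = FALSE],
       excluded = records[hit, , drop = FALSE])
}

#' Classify identification errors record by record
#'
#' Applies the audit decision tree to each record, comparing the verbatim
#' original determination with the revised species:
#' \enumerate{
#'   \item no parseable species-rank original name (empty, bare genus,
#'     "Hedera sp.") — `not_identified`;
#'   \item the (original, revised) pair is catalogued in the rule table —
#'     that rule's category (`correct`, `misidentification`, `soft_change`
#'     or `hard_change`);
#'   \item not catalogued, but the original equals the revised species
#'     rank-free (including the autonym infraspecific) — `correct`;
#'   \item otherwise `unresolvable` (reported, excluded from denominators).
#' }
#'
#' @param records `occ_df` data.frame; every record must carry a revised
#'   species (the audit requires a reviewed determination).
#' @param kb `concept_kb` rule table from [load_concept_kb()].
#' @return data.frame with `record_id`, `category`, `original_key`
#'   (rank-collapsed key of the parsed original name, `NA` when absent) and
#'   `revised_key`.
#' @export
classify_records <- function(records, kb) {
  if (anyNA(records$revised_species))
    stop("classification requires revised_species on every record")
  parsed <- parse_name(records$original_name_verbatim)
  okey <- name_key(parsed)
  rparsed <- parse_name(records$revised_species)
  rkey <- name_key(rparsed)
  if (anyNA(rkey)) stop("unparseable revised_species present")

  kbpair <- paste(kb$original_key, kb$revised_key, sep = " -> ")
  idx <- match(paste(okey, rkey, sep = " -> "), kbpair)

  category <- rep(NA_character_, nrow(records))
  category[is.na(okey)] <- "not_identified"
  hit <- !is.na(idx) & is.na(category)
  category[hit] <- kb$category[idx[hit]]
  # rank-free equality fallback: binomial match, infra absent or autonymic
  open <- is.na(category)
  if (any(open)) {
    binom <- paste(parsed$genus, parsed$epithet)
    rbinom <- paste(rparsed$genus, rparsed$epithet)
    autonym <- is.na(parsed$infra) |
      (!is.na(parsed$infra) & parsed$infra == parsed$epithet)
    category[open & binom == rbinom & autonym] <- "correct"
  }
  n_unres <- sum(is.na(category))
  if (n_unres > 0)
    warning(n_unres, " record(s) unresolvable: original name not in the ",
            "rule table")
  category[is.na(category)] <- "unresolvable"
  data.frame(record_id = records$record_id, category = category,
             original_key = okey, revised_key = rkey,
             stringsAsFactors = FALSE)
}

# deterministic matrix row order: binomials alphabetically, each followed by
# its infraspecifics, "Not identified" last
order_matrix_rows <- function(labels) {
  lab <- setdiff(labels, NOT_IDENTIFIED_LABEL)
  toks <- strsplit(lab, " ", fixed = TRUE)
  binom <- vapply(toks, function(t) paste(t[1], t[2]), character(1))
  infra <- vapply(toks, function(t) if (length(t) >= 4) t[4] else "",
                  character(1))
  sorted <- lab[order(binom, infra != "", infra, method = "radix")]
  c(sorted, if (NOT_IDENTIFIED_LABEL %in% labels) NOT_IDENTIFIED_LABEL)
}

#' Build a classification matrix from classified records
#'
#' Rows are the display labels of the original determinations (infraspecific
#' ranks collapsed to a generic `var.` marker) plus a final
#' `"Not identified"` row; columns are the revised species in alphabetical
#' order; cells count records. Records classified `unresolvable` are not
#' tabulated.
#'
#' @param classifications data.frame from [classify_records()].
#' @return integer matrix with dimnames, class `classification_matrix`.
#' @export
build_matrix <- function(classifications) {
  cl <- classifications[classifications$category != "unresolvable", ,
                        drop = FALSE]
  rowlab <- as.character(ifelse(cl$category == "not_identified",
                                NOT_IDENTIFIED_LABEL,
                                label_from_key(cl$original_key)))
  collab <- as.character(cl$revised_key)
  rows <- order_matrix_rows(unique(rowlab))
  cols <- sort(unique(collab))
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  if (nrow(cl) > 0) {
    tab <- table(factor(rowlab, levels = rows),
                 factor(collab, levels = cols))
    m[] <- as.integer(tab)
  }
  class(m) <- c("classification_matrix", class(m))
  m
}

#' Expand a classification matrix into record-level occurrences
#'
#' Emits exactly `cell` records per (original label, revised species) cell:
#' `original_name_verbatim` is the row label (empty for the
#' `"Not identified"` row), `revised_species` the column label; regions and
#' coordinates are absent. Records are emitted in a seeded random order with
#' ids assigned after shuffling, so the fixture is deterministic per seed.
#' `build_matrix()` of the expansion recovers the matrix exactly.
#'
#' @param m matrix with original-name row labels and revised-species column
#'   labels, non-negative integer cells.
#' @param seed integer seed for the emission order.
#' @param id_prefix prefix for record ids.
#' @return `occ_df` data.frame with `sum(m)` rows.
#' @export
expand_matrix <- function(m, seed = 1L, id_prefix = "fixture") {
  stopifnot(all(m >= 0))
  cells <- which(m > 0, arr.ind = TRUE)
  orig <- rep(rownames(m)[cells[, 1]], m[cells])
  revs <- rep(colnames(m)[cells[, 2]], m[cells])
  orig[orig == NOT_IDENTIFIED_LABEL] <- NA_character_
  perm <- withr_seed(seed, sample.int(length(orig)))
  occurrence_df(original_name_verbatim = orig[perm],
                revised_species = revs[perm],
                source = if (length(orig) > 0) "reviewed" else character(0),
                id_prefix = id_prefix)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Read / write a classification matrix
#'
#' Delimited text: first column `original` holds the row label, remaining
#' columns are revised species.
#'
#' @param path file path.
#' @return integer matrix (`classification_matrix`).
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  class(m) <- c("classification_matrix", class(m))
  m
}

#' @rdname read_matrix
#' @param m matrix to write.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(original = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The packaged ivy classification-matrix fixture
#'
#' The published classification table of the morphologically reviewed ivy
#' occurrence database (1011 records after circularity filtering): rows are
#' original determinations, columns the six revised western European
#' *Hedera* species.
#'
#' @return integer matrix (`classification_matrix`), 6 columns, cell sum 1011.
#' @export
hedera_matrix <- function() {
  read_matrix(system.file("extdata", "hedera_classification_matrix.csv",
                          package = "ivyaudit"))
}
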