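# End-to-end orchestration: audit and merge runs with stage-count logging.

#' Assemble a run configuration
#'
#' @param occurrences path to the occurrence file (audit runs) or the
#'   reviewed file (merge runs).
#' @param online optional path to the online occurrence file (merge runs).
#' @param kb path to the concept-rule table; default packaged.
#' @param region_table path to the region-uncertainty table; default
#'   packaged.
#' @param out_dir output directory, created if needed.
#' @param blocked circularity-blocked surnames.
#' @param thinning `thinning_config`.
#' @param seed integer seed.
#' @param sep input delimiter.
#' @return list of class `run_config`.
#' @export
run_config <- function(occurrences, online = NULL,
                       kb = system.file("extdata", "hedera_concept_rules.csv",
                                        package = "ivyaudit"),
                       region_table = system.file(
                         "extdata", "hedera_region_uncertainty.csv",
                         package = "ivyaudit"),
                       out_dir = ".", blocked = BLOCKED_IDENTIFIERS,
                       thinning = thinning_config(), seed = 1L, sep = ",") {
  for (p in c(occurrences, online, kb, region_table))
    if (!file.exists(p)) stop("no such file: ", p)
  structure(list(occurrences = occurrences, online = online, kb = kb,
                 region_table = region_table, out_dir = out_dir,
                 blocked = blocked, thinning = thinning,
                 seed = as.integer(seed), sep = sep),
            class = "run_config")
}

log_line <- function(log, ...) c(log, paste0(...))

#' Run the full identification-error audit
#'
#' read -> circularity filter -> per-record classification -> classification
#' matrix -> rate tables (overall, per species, per uncertainty region, per
#' country). Writes `classifications.csv`, `classification_matrix.csv`,
#' `rate_table_*.csv` and `audit_log.txt` into the output directory and
#' logs record counts at every stage.
#'
#' @param cfg `run_config`.
#' @return invisibly, a list with `classifications`, `matrix`, `rates`
#'   (named list of rate tables) and `log` (character vector).
#' @export
run_audit <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  kb <- load_concept_kb(cfg$kb)
  regions <- region_uncertainty(cfg$region_table)
  records <- read_occurrences(cfg$occurrences, sep = cfg$sep)
  log <- log_line(character(0), "read: ", nrow(records), " records")

  parts <- filter_circularity(records, cfg$blocked)
  log <- log_line(log, "excluded_circularity: ", nrow(parts$excluded))
  kept <- parts$kept

  if (nrow(kept) > 0) {
    cl <- classify_records(kept, kb)
  } else {
    cl <- data.frame(record_id = character(0), category = character(0),
                     original_key = character(0),
                     revised_key = character(0), stringsAsFactors = FALSE)
  }
  for (k in c("correct", INCORRECT_CATEGORIES, "unresolvable"))
    log <- log_line(log, k, ": ", sum(cl$category == k))
  stopifnot(nrow(records) == nrow(parts$excluded) + nrow(cl))

  m <- build_matrix(cl)
  rates <- list(all = rate_table(cl, "all"),
                species = rate_table(cl, "species"))
  has_region <- any(!is.na(kept$country) | !is.na(kept$island_group))
  if (has_region) {
    rates$uncertainty <- rate_table(cl, "uncertainty", records = kept,
                                    region_table = regions)
    rates$country <- rate_table(cl, "country", records = kept)
  }

  utils::write.csv(cl, file.path(cfg$out_dir, "classifications.csv"),
                   row.names = FALSE)
  write_matrix(m, file.path(cfg$out_dir, "classification_matrix.csv"))
  for (g in names(rates))
    utils::write.csv(rates[[g]],
                     file.path(cfg$out_dir, paste0("rate_table_", g, ".csv")),
                     row.names = FALSE)
  writeLines(log, file.path(cfg$out_dir, "audit_log.txt"))
  invisible(list(classifications = cl, matrix = m, rates = rates,
                 log = log))
}

#' Run the mixed-database compilation
#'
#' Reviewed records with coordinates are merged with online records
#' filtered to low-uncertainty regions and buffer-thinned. Writes
#' `mixocc.csv`, `mixocc.geojson` and `merge_log.txt`.
#'
#' @param cfg `run_config`; `cfg$occurrences` is the reviewed file,
#'   `cfg$online` the online file (may be `NULL` for a reviewed-only run).
#' @return invisibly, a list with `merged` and `log`.
#' @export
run_merge <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  regions <- region_uncertainty(cfg$region_table)
  reviewed <- read_occurrences(cfg$occurrences, sep = cfg$sep)
  reviewed$source <- rep("reviewed", nrow(reviewed))
  online <- if (is.null(cfg$online)) {
    occurrence_df(original_name_verbatim = character(0))
  } else {
    x <- read_occurrences(cfg$online, sep = cfg$sep)
    x$source <- rep("online", nrow(x))
    x
  }
  log <- log_line(character(0), "reviewed read: ", nrow(reviewed))
  log <- log_line(log, "online read: ", nrow(online))
  n_rev_xy <- sum(!is.na(reviewed$latitude))
  log <- log_line(log, "reviewed with coordinates: ", n_rev_xy)
  kept_online <- filter_online(online, regions)
  log <- log_line(log, "online dropped by region filter: ",
                  nrow(online) - nrow(kept_online))
  merged <- merge_mixocc(reviewed, online, regions, cfg$thinning)
  n_onl_out <- sum(merged$source == "online")
  log <- log_line(log, "online dropped by thinning/duplicates: ",
                  nrow(kept_online) - n_onl_out)
  log <- log_line(log, "merged: ", nrow(merged), " (reviewed ",
                  sum(merged$source == "reviewed"), ", online ",
                  n_onl_out, ")")
  write_occurrences(merged, file.path(cfg$out_dir, "mixocc.csv"))
  write_geojson(merged, file.path(cfg$out_dir, "mixocc.geojson"))
  writeLines(log, file.path(cfg$out_dir, "merge_log.txt"))
  invisible(list(merged = merged, log = log))
}
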