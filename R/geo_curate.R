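# Regional taxonomic-uncertainty scoring, online-record filtering,
# distance-buffer thinning and the reviewed/online database merge.

EARTH_RADIUS_M <- 6371008.8

#' The packaged region-uncertainty table
#'
#' Number of native congeneric ivy species sharing range boundaries per
#' region: 3 in mainland Spain; 2 in mainland Portugal, France, the United
#' Kingdom and Ireland; 1 in every other country and in each Macaronesian
#' archipelago. Regions with one species are of low expected taxonomic
#' uncertainty, regions with two or more of high uncertainty.
#'
#' @param path optional path to an alternative delimited table with columns
#'   `region_key`, `island_group`, `n_species`.
#' @return data.frame with `region_key`, `island_group`, `n_species`,
#'   `uncertainty` (`"low"`/`"high"`).
#' @export
region_uncertainty <- function(path = system.file(
    "extdata", "hedera_region_uncertainty.csv", package = "ivyaudit")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  stopifnot(all(c("region_key", "n_species") %in% names(tab)),
            all(tab$n_species >= 1))
  if (!"island_group" %in% names(tab)) tab$island_group <- NA_character_
  tab$uncertainty <- ifelse(tab$n_species >= 2, "high", "low")
  tab
}

#' Assign regional taxonomic uncertainty to records
#'
#' Looks each record up in the region table: the island group takes
#' precedence over the country for Macaronesian records (the archipelagos
#' are scored as regions of their own). Regions absent from the table
#' default to one species (low uncertainty) with a warning — the
#' rest-of-countries rule. Records with neither country nor island group
#' are unassignable and get `NA`.
#'
#' @param records `occ_df` data.frame.
#' @param table region table from [region_uncertainty()].
#' @return data.frame aligned with `records`: `region_key`, `n_species`,
#'   `uncertainty`, `matched` (logical; `FALSE` for defaulted regions).
#' @export
assign_uncertainty <- function(records, table = region_uncertainty()) {
  region <- ifelse(!is.na(records$island_group), records$island_group,
                   records$country)
  idx <- match(region, table$region_key)
  unmatched <- !is.na(region) & is.na(idx)
  if (any(unmatched))
    warning(sum(unmatched), " record(s) from regions not in the table; ",
            "defaulting to 1 species (low uncertainty): ",
            paste(unique(region[unmatched]), collapse = ", "))
  n_sp <- ifelse(is.na(region), NA_integer_,
                 ifelse(is.na(idx), 1L, table$n_species[idx]))
  data.frame(region_key = region, n_species = n_sp,
             uncertainty = ifelse(is.na(n_sp), NA_character_,
                                  ifelse(n_sp >= 2, "high", "low")),
             matched = !is.na(idx), stringsAsFactors = FALSE)
}

#' Keep online records from low-uncertainty regions only
#'
#' Online records cannot be morphologically validated, so only those from
#' regions where a single congener occurs (where a name-level validation
#' suffices) are retained. Reviewed records must not be passed through this
#' filter.
#'
#' @param records online-source `occ_df` data.frame.
#' @param table region table.
#' @return the retained records (input order preserved).
#' @export
filter_online <- function(records, table = region_uncertainty()) {
  if (nrow(records) == 0) return(records)
  if (any(records$source != "online", na.rm = TRUE))
    stop("filter_online is for source == 'online' records only")
  unc <- assign_uncertainty(records, table)$uncertainty
  records[!is.na(unc) & unc == "low", , drop = FALSE]
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees; vectorised.
#' @param radius sphere radius in metres (mean Earth radius by default).
#' @return distance in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius = EARTH_RADIUS_M) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Thinning configuration
#'
#' Minimum inter-record distances enforced per species: 10 km in
#' continental areas, 1 km within the Macaronesian archipelagos (island
#' endemics have ranges two orders of magnitude smaller, so the continental
#' buffer would erase them).
#'
#' @param buffer_continental_m,buffer_island_m positive distances in metres.
#' @return list of class `thinning_config`.
#' @export
thinning_config <- function(buffer_continental_m = 10000,
                            buffer_island_m = 1000) {
  stopifnot(buffer_continental_m > 0, buffer_island_m > 0)
  structure(list(buffer_continental_m = buffer_continental_m,
                 buffer_island_m = buffer_island_m),
            class = "thinning_config")
}

#' Distance-buffer spatial thinning
#'
#' Greedy sequential thinning per species to damp unequal sampling effort:
#' records are visited in a deterministic order (reviewed source first,
#' then record_id ascending) and retained iff their great-circle distance
#' to every already-retained record of the same species is at least the
#' applicable buffer (island buffer when `island_group` is set, continental
#' otherwise). Records of different species never suppress each other.
#' Records without coordinates cannot be thinned and pass through.
#'
#' @param records `occ_df` data.frame with `revised_species` set.
#' @param cfg `thinning_config`.
#' @return retained records, in the visiting order.
#' @export
thin_by_buffer <- function(records, cfg = thinning_config()) {
  if (nrow(records) == 0) return(records)
  has_xy <- !is.na(records$latitude) & !is.na(records$longitude)
  src_rank <- ifelse(!is.na(records$source) & records$source == "reviewed",
                     0L, 1L)
  ord <- order(src_rank, records$record_id, method = "radix")
  recs <- records[ord, , drop = FALSE]
  has_xy <- has_xy[ord]
  buffer <- ifelse(is.na(recs$island_group), cfg$buffer_continental_m,
                   cfg$buffer_island_m)
  keep <- rep(TRUE, nrow(recs))
  for (sp in unique(recs$revised_species)) {
    ii <- which(recs$revised_species %in% sp & has_xy)
    kept_idx <- integer(0)
    for (i in ii) {
      if (length(kept_idx) > 0) {
        d <- haversine_m(recs$latitude[i], recs$longitude[i],
                         recs$latitude[kept_idx], recs$longitude[kept_idx])
        if (any(d < buffer[i])) { keep[i] <- FALSE; next }
      }
      kept_idx <- c(kept_idx, i)
    }
  }
  recs[keep, , drop = FALSE]
}

#' Compile a mixed reviewed/online spatial database
#'
#' Keeps every reviewed record that carries coordinates (the reviewed
#' database is taken as already curated and buffered), adds the online
#' records that survive the low-uncertainty region filter and per-species
#' buffer thinning among themselves, and resolves exact duplicates across
#' sources (same species, distance zero) in favour of the reviewed record.
#'
#' @param reviewed,online `occ_df` data.frames (sources as named).
#' @param table region table.
#' @param cfg `thinning_config`.
#' @return merged `occ_df`; provenance stays in the `source` field.
#' @export
merge_mixocc <- function(reviewed, online, table = region_uncertainty(),
                         cfg = thinning_config()) {
  rev_xy <- reviewed[!is.na(reviewed$latitude) & !is.na(reviewed$longitude), ,
                     drop = FALSE]
  onl <- filter_online(online, table)
  onl <- onl[!is.na(onl$latitude) & !is.na(onl$longitude), , drop = FALSE]
  onl <- thin_by_buffer(onl, cfg)
  if (nrow(onl) > 0 && nrow(rev_xy) > 0) {
    dup_key <- function(df) paste(df$revised_species, df$latitude,
                                  df$longitude)
    onl <- onl[!(dup_key(onl) %in% dup_key(rev_xy)), , drop = FALSE]
  }
  out <- rbind(rev_xy, onl)
  rownames(out) <- NULL
  out
}
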