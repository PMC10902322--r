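# Occurrence-record container and Darwin Core-style delimited I/O.

# canonical column order of an occurrence data.frame
OCC_COLUMNS <- c("record_id", "original_name_verbatim", "revised_species",
                 "identified_by", "country", "island_group",
                 "latitude", "longitude", "coordinate_uncertainty_m",
                 "source", "locality_verbatim", "coord_invalid")

ISLAND_GROUPS <- c("Azores", "Madeira", "Canary Islands")

# Darwin Core term -> internal field, the default field map for readers
DWC_FIELD_MAP <- c(
  record_id = "occurrenceID",
  original_name_verbatim = "verbatimIdentification",
  revised_species = "scientificName",
  identified_by = "identifiedBy",
  country = "country",
  island_group = "islandGroup",
  latitude = "decimalLatitude",
  longitude = "decimalLongitude",
  coordinate_uncertainty_m = "coordinateUncertaintyInMeters",
  source = "source",
  locality_verbatim = "locality"
)

#' Build a validated occurrence data.frame
#'
#' Normalises a set of field vectors into the package's occurrence container:
#' one row per record, fixed column order, absent values as `NA`. Coordinate
#' validation never drops a record; out-of-range or half-missing coordinate
#' pairs are blanked and flagged in the logical `coord_invalid` column.
#'
#' @param record_id identifiers; if `NULL`, zero-padded ordinals prefixed by
#'   `id_prefix` are synthesised (stable tie-breaks for thinning).
#' @param original_name_verbatim,revised_species,identified_by,country,island_group,locality_verbatim
#'   character fields; empty strings and `"NA"` become `NA`.
#' @param latitude,longitude decimal degrees WGS84.
#' @param coordinate_uncertainty_m non-negative metres.
#' @param source `"reviewed"` or `"online"`.
#' @param id_prefix prefix for synthesised ids.
#' @return data.frame of class `occ_df` with columns in [OCC_COLUMNS] order.
#' @export
occurrence_df <- function(record_id = NULL, original_name_verbatim = NA,
                          revised_species = NA, identified_by = NA,
                          country = NA, island_group = NA,
                          latitude = NA, longitude = NA,
                          coordinate_uncertainty_m = NA, source = "reviewed",
                          locality_verbatim = NA, id_prefix = "rec") {
  lens <- lengths(list(original_name_verbatim, revised_species,
                       identified_by, country, island_group, latitude,
                       longitude, coordinate_uncertainty_m, source,
                       locality_verbatim))
  if (!is.null(record_id)) lens <- c(lens, length(record_id))
  # a zero-length field signals an empty record set
  n <- if (any(lens == 0)) 0L else max(lens)
  blank <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (trimws(x) == "" | toupper(trimws(x)) == "NA")] <- NA
    rep_len(x, n)
  }
  num <- function(x) {
    x <- blank(x)
    suppressWarnings(as.numeric(x))
  }
  if (is.null(record_id)) {
    record_id <- sprintf("%s-%0*d", id_prefix, max(4, nchar(n)), seq_len(n))
  } else {
    record_id <- rep_len(as.character(record_id), n)
  }
  df <- data.frame(
    record_id = record_id,
    original_name_verbatim = blank(original_name_verbatim),
    revised_species = blank(revised_species),
    identified_by = blank(identified_by),
    country = blank(country),
    island_group = blank(island_group),
    latitude = num(latitude),
    longitude = num(longitude),
    coordinate_uncertainty_m = num(coordinate_uncertainty_m),
    source = blank(source),
    locality_verbatim = blank(locality_verbatim),
    stringsAsFactors = FALSE
  )
  bad_src <- !is.na(df$source) & !(df$source %in% c("reviewed", "online"))
  if (any(bad_src))
    stop("source must be 'reviewed' or 'online'; got: ",
         paste(unique(df$source[bad_src]), collapse = ", "))
  bad_ig <- !is.na(df$island_group) & !(df$island_group %in% ISLAND_GROUPS)
  if (any(bad_ig))
    stop("island_group must be one of ",
         paste(ISLAND_GROUPS, collapse = ", "))
  bad_unc <- !is.na(df$coordinate_uncertainty_m) &
    df$coordinate_uncertainty_m < 0
  if (any(bad_unc)) stop("coordinate_uncertainty_m must be >= 0")
  # coordinate pair validation: both-or-none, in range; invalid -> blank + flag
  has_lat <- !is.na(df$latitude); has_lon <- !is.na(df$longitude)
  bad <- (has_lat != has_lon) |
    (has_lat & (abs(df$latitude) > 90)) |
    (has_lon & (abs(df$longitude) > 180))
  df$coord_invalid <- bad
  df$latitude[bad] <- NA_real_
  df$longitude[bad] <- NA_real_
  class(df) <- c("occ_df", "data.frame")
  df
}

#' Read a delimited occurrence file
#'
#' Columns are mapped to internal fields through a named field map (Darwin
#' Core terms by default). Missing cells become `NA`, row order is preserved
#' and no row is silently dropped: records failing coordinate validation are
#' kept with `coord_invalid = TRUE`.
#'
#' @param path delimited text file.
#' @param field_map named character vector `internal_field = column_name`;
#'   defaults to the Darwin Core terms in `DWC_FIELD_MAP`. Columns absent
#'   from the file are read as all-`NA` fields, but at least one of the
#'   identification columns (`original_name_verbatim`, `revised_species`)
#'   must be present.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return `occ_df` data.frame; `record_id` synthesised from the file stem
#'   and row number when the id column is absent.
#' @export
read_occurrences <- function(path, field_map = DWC_FIELD_MAP, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, comment.char = "",
                           na.strings = character(0))
  fm <- DWC_FIELD_MAP
  fm[names(field_map)] <- field_map
  if (!(fm[["original_name_verbatim"]] %in% names(raw)) &&
      !(fm[["revised_species"]] %in% names(raw)))
    stop("field map matches neither an original nor a revised ",
         "identification column in ", path)
  pick <- function(field) {
    col <- fm[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  ids <- pick("record_id")
  if (all(is.na(ids)) || all(trimws(ids) == "")) ids <- NULL
  occurrence_df(
    record_id = ids,
    original_name_verbatim = pick("original_name_verbatim"),
    revised_species = pick("revised_species"),
    identified_by = pick("identified_by"),
    country = pick("country"),
    island_group = pick("island_group"),
    latitude = pick("latitude"),
    longitude = pick("longitude"),
    coordinate_uncertainty_m = pick("coordinate_uncertainty_m"),
    source = {
      s <- pick("source")
      s[is.na(s) | trimws(s) == ""] <- "reviewed"
      s
    },
    locality_verbatim = pick("locality_verbatim"),
    id_prefix = tools::file_path_sans_ext(basename(path))
  )
}

#' Write occurrences as delimited text
#'
#' Writes Darwin Core column names in a fixed order; absent values are
#' written as empty strings. `read_occurrences(write_occurrences(x))`
#' round-trips field-by-field for records without validation flags.
#'
#' @param records `occ_df` data.frame.
#' @param path output file.
#' @param sep delimiter.
#' @return number of data rows written, invisibly.
#' @export
write_occurrences <- function(records, path, sep = ",") {
  out <- data.frame(lapply(setdiff(OCC_COLUMNS, "coord_invalid"), function(f) {
    x <- if (f %in% names(records)) records[[f]] else NA
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }), stringsAsFactors = FALSE)
  names(out) <- unname(DWC_FIELD_MAP[setdiff(OCC_COLUMNS, "coord_invalid")])
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(nrow(out))
}

#' Export occurrences as GeoJSON points
#'
#' One feature per record with coordinates; records without a valid
#' coordinate pair are skipped. All non-coordinate fields travel as feature
#' properties.
#'
#' @param records `occ_df` data.frame.
#' @param path output `.geojson` file.
#' @return number of features written, invisibly.
#' @export
write_geojson <- function(records, path) {
  keep <- !is.na(records$latitude) & !is.na(records$longitude)
  recs <- records[keep, , drop = FALSE]
  props <- setdiff(OCC_COLUMNS, c("latitude", "longitude", "coord_invalid"))
  features <- lapply(seq_len(nrow(recs)), function(i) {
    p <- lapply(props, function(f) {
      v <- recs[[f]][i]
      if (is.na(v)) NULL else v
    })
    names(p) <- props
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(recs$longitude[i], recs$latitude[i])),
         properties = p[!vapply(p, is.null, logical(1))])
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(nrow(recs))
}
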