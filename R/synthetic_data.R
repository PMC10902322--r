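# Seeded synthetic occurrence generator with ground-truth error labels.
#
# The generator states a world with the error structure the audit assumes:
# per-species systematic misidentification targets, legacy (soft/hard)
# name usage, records never identified to species, regional species pools
# and point coordinates. Each emitted record carries the category that was
# sampled, so audits can be checked against truth exactly.

TRUTH_CATEGORIES <- c("correct", "misidentification", "soft_change",
                      "hard_change", "not_identified")

BLOCKED_NAME_POOL <- c("V. Valcárcel", "H. A. McAllister", "P. Vargas",
                       "A. Rutherford")
NEUTRAL_NAME_POOL <- c("J. Smith", "M. García", "A. Dupont", "K. Müller")

#' Build and validate a generator configuration
#'
#' @param regions list; each element a list with `region_key`,
#'   `island_group` (`NA` for continental), `pool` (character vector of
#'   species), `bbox` (`c(lon_min, lon_max, lat_min, lat_max)` decimal
#'   degrees) and `n_records`.
#' @param name_model named list keyed by species: a data.frame with columns
#'   `name` (emitted verbatim name; `""` for a record left unidentified),
#'   `category` (the truth label the name carries against that species) and
#'   `prob`. Probabilities must sum to 1 (tolerance 1e-9).
#' @param uncertainty_effect log-odds added to each record's total error
#'   mass per congeneric species beyond the first in its region
#'   (default 0: the name model applies verbatim everywhere). Within the
#'   error mass, name probabilities keep their relative weights.
#' @param p_blocked_identifier probability that a record carries an
#'   identifier from the circularity-blocked list (default 0; enabled only
#'   to exercise the circularity filter).
#' @param seed integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(regions, name_model, uncertainty_effect = 0,
                             p_blocked_identifier = 0, seed = 1L) {
  stopifnot(length(regions) > 0, p_blocked_identifier >= 0,
            p_blocked_identifier <= 1)
  for (r in regions) {
    stopifnot(is.character(r$region_key), length(r$pool) >= 1,
              length(r$bbox) == 4, r$n_records >= 0,
              r$bbox[1] <= r$bbox[2], r$bbox[3] <= r$bbox[4])
    missing_sp <- setdiff(r$pool, names(name_model))
    if (length(missing_sp) > 0)
      stop("species in region pool without a name model: ",
           paste(missing_sp, collapse = ", "))
  }
  for (sp in names(name_model)) {
    nm <- name_model[[sp]]
    stopifnot(all(c("name", "category", "prob") %in% names(nm)),
              all(nm$category %in% TRUTH_CATEGORIES), all(nm$prob >= 0))
    if (abs(sum(nm$prob) - 1) > 1e-9)
      stop("name-model probabilities for ", sp, " sum to ", sum(nm$prob))
  }
  structure(list(regions = regions, name_model = name_model,
                 uncertainty_effect = uncertainty_effect,
                 p_blocked_identifier = p_blocked_identifier,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# region-adjusted name model: total error mass shifted on the logit scale
# by effect * (n_species_in_pool - 1); relative weights within the error
# mass preserved; degenerate models (all-correct, no-correct) unchanged
adjust_model <- function(nm, n_pool, effect) {
  if (effect == 0 || n_pool <= 1) return(nm)
  inc <- nm$category != "correct"
  p_inc <- sum(nm$prob[inc])
  if (p_inc <= 0 || p_inc >= 1) return(nm)
  p_new <- stats::plogis(stats::qlogis(p_inc) + effect * (n_pool - 1))
  nm$prob[inc] <- nm$prob[inc] * p_new / p_inc
  nm$prob[!inc] <- nm$prob[!inc] * (1 - p_new) / (1 - p_inc)
  nm
}

#' Generate a synthetic occurrence database with truth labels
#'
#' For each region, draws `n_records` true species uniformly from the
#' regional pool, a verbatim original name from that species' (possibly
#' region-adjusted) name model, and coordinates uniformly within the
#' region's bounding box. The revised species is the true species — the
#' generator emulates a database whose every record was re-determined by
#' the reference taxonomist.
#'
#' @param cfg `generator_config`.
#' @return list with `records` (an `occ_df`) and `truth` (data.frame
#'   `record_id`, `true_species`, `category`).
#' @export
generate_occurrences <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr_seed(cfg$seed, {
    per_region <- lapply(cfg$regions, function(r) {
      n <- r$n_records
      if (n == 0) return(NULL)
      sp <- sample(r$pool, n, replace = TRUE)
      verbatim <- character(n); categ <- character(n)
      for (s in unique(sp)) {
        ii <- which(sp == s)
        nm <- adjust_model(cfg$name_model[[s]], length(r$pool),
                           cfg$uncertainty_effect)
        draw <- sample.int(nrow(nm), length(ii), replace = TRUE,
                           prob = nm$prob)
        verbatim[ii] <- nm$name[draw]
        categ[ii] <- nm$category[draw]
      }
      blocked <- stats::runif(n) < cfg$p_blocked_identifier
      identifier <- ifelse(
        blocked,
        sample(BLOCKED_NAME_POOL, n, replace = TRUE),
        sample(NEUTRAL_NAME_POOL, n, replace = TRUE))
      list(region_key = rep(r$region_key, n),
           island_group = rep(if (is.null(r$island_group)) NA_character_
                              else r$island_group, n),
           true_species = sp, verbatim = verbatim, category = categ,
           identifier = identifier,
           lon = stats::runif(n, r$bbox[1], r$bbox[2]),
           lat = stats::runif(n, r$bbox[3], r$bbox[4]))
    })
    per_region <- per_region[!vapply(per_region, is.null, logical(1))]
    pull <- function(f) unlist(lapply(per_region, `[[`, f),
                               use.names = FALSE)
    n_tot <- length(pull("true_species"))
    records <- occurrence_df(
      original_name_verbatim = pull("verbatim"),
      revised_species = pull("true_species"),
      identified_by = pull("identifier"),
      country = pull("region_key"),
      island_group = pull("island_group"),
      latitude = pull("lat"), longitude = pull("lon"),
      source = if (n_tot > 0) "reviewed" else character(0),
      id_prefix = "sim")
    truth <- data.frame(record_id = records$record_id,
                        true_species = pull("true_species"),
                        category = pull("category"),
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Exact expected category rates under a generator configuration
#'
#' Marginalises the (region-adjusted) name models over the regions a
#' species occurs in, weighting each region by its expected contribution
#' of records of that species (`n_records / pool size`). These are the
#' generative probabilities that audited category rates estimate.
#'
#' @param cfg `generator_config`.
#' @return data.frame: `species`, one column per truth category.
#' @export
expected_category_rates <- function(cfg) {
  species <- sort(names(cfg$name_model))
  rows <- lapply(species, function(s) {
    w <- 0; p <- stats::setNames(numeric(length(TRUTH_CATEGORIES)),
                                 TRUTH_CATEGORIES)
    for (r in cfg$regions) {
      if (!(s %in% r$pool) || r$n_records == 0) next
      wr <- r$n_records / length(r$pool)
      nm <- adjust_model(cfg$name_model[[s]], length(r$pool),
                         cfg$uncertainty_effect)
      pr <- vapply(TRUTH_CATEGORIES,
                   function(k) sum(nm$prob[nm$category == k]), numeric(1))
      p <- p + wr * pr; w <- w + wr
    }
    if (w > 0) p <- p / w
    cbind(data.frame(species = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(p)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# empirical name model of one revised species: distribution of original
# names in its classification-matrix column, categorised by the rule table
name_model_from_matrix <- function(m, species, kb) {
  cnt <- m[, species]
  keep <- cnt > 0
  labels <- rownames(m)[keep]
  cnt <- cnt[keep]
  category <- vapply(labels, function(lab) {
    if (lab == NOT_IDENTIFIED_LABEL) return("not_identified")
    rule <- lookup_rule(lab, species, kb)
    if (is.null(rule)) {
      key <- name_key(parse_name(lab))
      if (identical(key, species)) "correct" else
        stop("matrix row not covered by the rule table: ", lab,
             " -> ", species)
    } else rule$category
  }, character(1))
  data.frame(name = ifelse(labels == NOT_IDENTIFIED_LABEL, "", labels),
             category = unname(category), prob = as.numeric(cnt / sum(cnt)),
             stringsAsFactors = FALSE)
}

#' The real-structure benchmark configuration
#'
#' A packaged configuration that restates the audited ivy world: six
#' species, the packaged region table (three congeners in mainland Spain,
#' two in mainland Portugal, France, the United Kingdom and Ireland, one
#' elsewhere), and per-species name models equal to the empirical
#' original-name distributions of the packaged classification-matrix
#' columns. Region record counts are balanced so each species expects
#' about `n_per_species` records.
#'
#' @param n_per_species target expected records per species (default 2000).
#' @param uncertainty_effect log-odds of error per additional congener in
#'   the region (default 0.9, the value implied by the contrast between
#'   the audited error rates of low- and high-uncertainty regions).
#' @param seed integer seed.
#' @return `generator_config`.
#' @export
real_structure_config <- function(n_per_species = 2000,
                                  uncertainty_effect = 0.9, seed = 1L) {
  m <- hedera_matrix()
  kb <- load_concept_kb()
  species <- colnames(m)
  name_model <- stats::setNames(
    lapply(species, function(s) name_model_from_matrix(m, s, kb)), species)
  f <- n_per_species / 2000
  rg <- function(key, ig, pool, bbox, n)
    list(region_key = key, island_group = ig, pool = pool, bbox = bbox,
         n_records = as.integer(round(n * f)))
  hel <- "Hedera helix"; hib <- "Hedera hibernica"; ibe <- "Hedera iberica"
  regions <- list(
    rg("Spain", NA, c(hel, hib, ibe), c(-9.0, 3.0, 36.0, 43.5), 1800),
    rg("Portugal", NA, c(hib, ibe), c(-9.5, -6.2, 37.0, 42.0), 2000),
    rg("France", NA, c(hel, hib), c(-4.5, 7.5, 43.0, 50.5), 700),
    rg("United Kingdom", NA, c(hel, hib), c(-7.5, 1.5, 50.0, 58.5), 700),
    rg("Ireland", NA, c(hel, hib), c(-10.3, -6.0, 51.5, 55.3), 200),
    rg("Germany", NA, hel, c(6.0, 14.8, 47.5, 54.8), 700),
    rg("Azores", "Azores", "Hedera azorica",
       c(-31.2, -25.0, 36.9, 39.7), 2000),
    rg("Canary Islands", "Canary Islands", "Hedera canariensis",
       c(-18.2, -13.5, 27.6, 29.4), 2000),
    rg("Madeira", "Madeira", "Hedera maderensis",
       c(-17.3, -16.3, 32.4, 33.1), 2000)
  )
  generator_config(regions, name_model,
                   uncertainty_effect = uncertainty_effect, seed = seed)
}
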