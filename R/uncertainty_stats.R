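# Error-rate tables, two-level chi-squared goodness-of-fit tests with
# significance codes, and the binomial GLM of identification error.

SIG_LEVELS <- c("****", "***", "**", "*", "m.s.", "n.s.")

#' Significance code for a p-value
#'
#' Thresholds: `****` p <= 1e-4, `***` <= 1e-3, `**` <= 0.01, `*` <= 0.05,
#' `m.s.` (marginally significant) <= 0.08, `n.s.` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
sig_code <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, 0.08, Inf),
      labels = SIG_LEVELS) |> as.character()
}

#' Two-level chi-squared goodness-of-fit test
#'
#' Tests whether two outcome counts (here: correct vs incorrect
#' identifications) are equally frequent. Against equal expected
#' frequencies the statistic reduces to `(a - b)^2 / (a + b)` on 1 df;
#' no continuity correction is applied.
#'
#' @param a,b non-negative counts.
#' @return list with `chi2`, `p_value` and `sig_code`.
#' @export
chisq_two_level <- function(a, b) {
  if (a + b <= 0) stop("chi-squared goodness of fit undefined for a + b = 0")
  chi2 <- (a - b)^2 / (a + b)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p_value = p, sig_code = sig_code(p))
}

round_half_up <- function(x) floor(x + 0.5)

# one rate-table row from a category vector
rate_row <- function(categories) {
  n <- length(categories)
  cnt <- function(k) sum(categories == k)
  n_mis <- cnt("misidentification"); n_noiden <- cnt("not_identified")
  n_hard <- cnt("hard_change"); n_soft <- cnt("soft_change")
  n_incorrect <- n_mis + n_noiden + n_hard + n_soft
  n_correct <- cnt("correct")
  stopifnot(n_correct + n_incorrect == n)
  pct <- function(k) if (n > 0) round_half_up(100 * k / n) else NA_real_
  if (n > 0) {
    ts <- chisq_two_level(n_correct, n_incorrect)
  } else {
    ts <- list(chi2 = NA_real_, p_value = NA_real_, sig_code = NA_character_)
  }
  data.frame(n = n, n_correct = n_correct, n_incorrect = n_incorrect,
             n_mis = n_mis, n_noiden = n_noiden, n_hard = n_hard,
             n_soft = n_soft,
             pct_correct = pct(n_correct), pct_incorrect = pct(n_incorrect),
             pct_mis = pct(n_mis), pct_noiden = pct(n_noiden),
             pct_hard = pct(n_hard), pct_soft = pct(n_soft),
             chi2 = ts$chi2, p_value = ts$p_value, sig_code = ts$sig_code,
             stringsAsFactors = FALSE)
}

#' Per-group error-rate table
#'
#' Counts and integer percentages (rounded half-up) of correct records and
#' of the four incorrect categories (misidentification, not identified,
#' hard and soft taxonomic change), with a two-level chi-squared
#' goodness-of-fit test of correct vs incorrect per group. Records
#' classified `unresolvable` or `excluded_circularity` never enter the
#' denominators.
#'
#' @param classifications data.frame from [classify_records()].
#' @param grouping one of `"all"`, `"species"` (by revised species),
#'   `"uncertainty"` (low vs high regional taxonomic uncertainty) or
#'   `"country"`.
#' @param records `occ_df` data.frame, required for the region-based
#'   groupings (`"uncertainty"`, `"country"`); must align with
#'   `classifications` by `record_id`.
#' @param region_table region-uncertainty table (see [region_uncertainty()]);
#'   default the packaged assignment.
#' @return data.frame with one row per group (`group` column first), the
#'   counts/percentages and `chi2`, `p_value`, `sig_code`.
#' @export
rate_table <- function(classifications,
                       grouping = c("all", "species", "uncertainty",
                                    "country"),
                       records = NULL, region_table = region_uncertainty()) {
  grouping <- match.arg(grouping)
  cl <- classifications[!classifications$category %in%
                          c("unresolvable", "excluded_circularity"), ,
                        drop = FALSE]
  key <- switch(grouping,
    all = rep("all", nrow(cl)),
    species = cl$revised_key,
    uncertainty = ,
    country = {
      if (is.null(records))
        stop("records are required for region-based groupings")
      idx <- match(cl$record_id, records$record_id)
      if (anyNA(idx)) stop("classifications and records do not align")
      if (grouping == "country") {
        records$country[idx]
      } else {
        assign_uncertainty(records[idx, , drop = FALSE],
                           region_table)$uncertainty
      }
    })
  keep <- !is.na(key)
  cl <- cl[keep, , drop = FALSE]; key <- key[keep]
  groups <- if (grouping == "uncertainty") {
    intersect(c("low", "high"), unique(key))
  } else sort(unique(key))
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          rate_row(cl$category[key == g]))
  }))
  rownames(out) <- NULL
  out
}

#' Binomial GLM of identification error
#'
#' Logistic regression of the per-record error indicator (incorrect = 1,
#' where incorrect pools misidentification, not-identified, hard and soft
#' change) on the revised species (categorical, reference = alphabetically
#' first level present) and the number of congeneric species sharing range
#' boundaries in the record's region (numeric, 1-3).
#'
#' @param classifications data.frame from [classify_records()]; rows with
#'   category `unresolvable` are dropped.
#' @param records aligned `occ_df` data.frame (for regions).
#' @param region_table region-uncertainty table.
#' @return object of class `error_glm`: list with `fit` (the `glm`),
#'   `coefficients` (estimate / std error / p per term),
#'   `reference_level` and `separation` (logical flag for quasi-complete
#'   separation, detected by outsized estimates or non-convergence;
#'   estimates are still returned).
#' @export
fit_error_glm <- function(classifications, records,
                          region_table = region_uncertainty()) {
  cl <- classifications[!classifications$category %in%
                          c("unresolvable", "excluded_circularity"), ,
                        drop = FALSE]
  idx <- match(cl$record_id, records$record_id)
  if (anyNA(idx)) stop("classifications and records do not align")
  dat <- data.frame(
    incorrect = as.integer(cl$category %in% INCORRECT_CATEGORIES),
    species = factor(cl$revised_key),
    n_species_region = assign_uncertainty(records[idx, , drop = FALSE],
                                          region_table)$n_species
  )
  if (nlevels(dat$species) < 2)
    stop("GLM requires at least two species levels")
  fit <- withCallingHandlers(
    stats::glm(incorrect ~ species + n_species_region, data = dat,
               family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      std_error = sm[, 2], p_value = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (sep)
    warning("possible (quasi-)complete separation; estimates unreliable")
  structure(list(fit = fit, coefficients = coefs,
                 reference_level = levels(dat$species)[1],
                 separation = sep),
            class = "error_glm")
}

#' @export
print.error_glm <- function(x, ...) {
  cat("Binomial GLM of identification error\n")
  cat("  reference species:", x$reference_level, "\n")
  if (x$separation) cat("  WARNING: possible complete separation\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
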