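test_that("regional uncertainty follows the species-count rule", {
  recs <- occurrence_df(
    revised_species = "Hedera helix",
    country = c("Spain", "Portugal", "Germany", "Portugal", NA),
    island_group = c(NA, NA, NA, "Azores", NA))
  u <- suppressWarnings(assign_uncertainty(recs, the_regions))
  expect_equal(u$n_species, c(3, 2, 1, 1, NA))
  expect_equal(u$uncertainty, c("high", "high", "low", "low", NA))
  # island group beats country; unknown country defaults with a warning
  expect_equal(u$region_key[4], "Azores")
  expect_warning(assign_uncertainty(recs[3, ], the_regions), "defaulting")
})

test_that("online filter keeps exactly the low-uncertainty records", {
  recs <- occurrence_df(
    revised_species = "Hedera helix",
    country = c("Portugal", "Spain", "Poland", "Spain"),
    island_group = c(NA, NA, NA, "Canary Islands"),
    source = "online")
  kept <- suppressWarnings(filter_online(recs, the_regions))
  expect_equal(kept$country, c("Poland", "Spain"))
  expect_equal(kept$island_group, c(NA, "Canary Islands"))
  # idempotent; empty in -> empty out; reviewed records are refused
  expect_equal(suppressWarnings(filter_online(kept, the_regions)), kept)
  empty <- occurrence_df(revised_species = character(0), source = character(0))
  expect_equal(nrow(filter_online(empty, the_regions)), 0)
  expect_error(filter_online(occurrence_df(revised_species = "x"),
                             the_regions), "online")
})

test_that("haversine matches a known baseline", {
  # one degree of latitude at the equator
  expect_equal(haversine_m(0, 0, 1, 0), 111194.9, tolerance = 1e-4)
  expect_equal(haversine_m(40, -3, 40, -3), 0)
  # antipodal half-circumference
  expect_equal(haversine_m(0, 0, 0, 180), pi * 6371008.8, tolerance = 1e-6)
})

test_that("buffers separate continental and island records", {
  # ~5 km apart: thinned on the continent (10 km), kept on the Azores (1 km)
  mk <- function(ig) occurrence_df(
    revised_species = "Hedera helix",
    latitude = c(38.00, 38.045), longitude = c(-27, -27),
    island_group = ig, country = if (is.na(ig[1])) "Spain" else NA)
  expect_equal(nrow(thin_by_buffer(mk(NA))), 1)
  expect_equal(nrow(thin_by_buffer(mk("Azores"))), 2)
})

test_that("different species never suppress each other", {
  recs <- occurrence_df(
    revised_species = c("Hedera helix", "Hedera hibernica"),
    latitude = c(40, 40), longitude = c(-3, -3), country = "Spain")
  expect_equal(nrow(thin_by_buffer(recs)), 2)
})

test_that("records without coordinates pass through thinning", {
  recs <- occurrence_df(revised_species = rep("Hedera helix", 3),
                        latitude = c(40, 40.001, NA),
                        longitude = c(-3, -3, NA), country = "Spain")
  out <- thin_by_buffer(recs)
  expect_equal(nrow(out), 2)  # one thinned, the coordinate-free one kept
  expect_true(any(is.na(out$latitude)))
})

test_that("thinning is maximal-greedy against a brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 200
    recs <- occurrence_df(
      revised_species = sample(c("Hedera helix", "Hedera hibernica"), n,
                               replace = TRUE),
      latitude = runif(n, 39.5, 40.5), longitude = runif(n, -4, -3),
      country = "Spain",
      source = sample(c("reviewed", "online"), n, replace = TRUE))
    out <- thin_by_buffer(recs)
    buf <- 10000
    # all retained pairwise distances within a species >= buffer
    for (sp in unique(out$revised_species)) {
      o <- out[out$revised_species == sp, ]
      if (nrow(o) > 1) {
        pairs <- utils::combn(nrow(o), 2)
        d <- haversine_m(o$latitude[pairs[1, ]], o$longitude[pairs[1, ]],
                         o$latitude[pairs[2, ]], o$longitude[pairs[2, ]])
        expect_true(all(d >= buf), label = paste("seed", seed, sp))
      }
    }
    # every dropped record is within buffer of some retained same-species one
    dropped <- recs[!(recs$record_id %in% out$record_id), ]
    for (i in seq_len(nrow(dropped))) {
      o <- out[out$revised_species == dropped$revised_species[i], ]
      d <- haversine_m(dropped$latitude[i], dropped$longitude[i],
                       o$latitude, o$longitude)
      expect_true(any(d < buf), label = paste("seed", seed, "drop", i))
    }
    # idempotence and determinism
    expect_identical(thin_by_buffer(out), out)
    expect_identical(thin_by_buffer(recs), out)
  }
})

test_that("merge keeps reviewed records and accounts for online ones", {
  set.seed(42)
  reviewed <- occurrence_df(
    revised_species = "Hedera helix", country = "Spain",
    latitude = runif(30, 39, 41), longitude = runif(30, -4, -2),
    source = "reviewed", id_prefix = "rev")
  online <- occurrence_df(
    revised_species = "Hedera helix",
    country = c(rep("Germany", 25), rep("Spain", 5)),
    latitude = c(runif(25, 48, 54), runif(5, 39, 41)),
    longitude = c(runif(25, 7, 14), runif(5, -4, -2)),
    source = "online", id_prefix = "onl")
  merged <- suppressWarnings(merge_mixocc(reviewed, online, the_regions))
  # reviewed records pass through untouched, even if mutually close
  expect_true(all(reviewed$record_id %in% merged$record_id))
  # no online record from a high-uncertainty region survives
  expect_false(any(merged$source == "online" & merged$country == "Spain"))
  # accounting identity
  onl_kept <- thin_by_buffer(suppressWarnings(filter_online(online, the_regions)))
  expect_equal(nrow(merged), 30 + nrow(onl_kept))
})

test_that("exact cross-source duplicates resolve in favour of reviewed", {
  reviewed <- occurrence_df(revised_species = "Hedera helix",
                            country = "Germany", latitude = 50,
                            longitude = 9, source = "reviewed",
                            id_prefix = "rev")
  online <- occurrence_df(revised_species = "Hedera helix",
                          country = "Germany", latitude = 50,
                          longitude = 9, source = "online",
                          id_prefix = "onl")
  merged <- suppressWarnings(merge_mixocc(reviewed, online, the_regions))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$source, "reviewed")
})

test_that("reviewed-only merge passes through coordinate records", {
  reviewed <- occurrence_df(revised_species = "Hedera helix",
                            country = "Germany",
                            latitude = c(50, NA), longitude = c(9, NA),
                            source = "reviewed")
  empty <- occurrence_df(revised_species = character(0),
                         source = character(0))
  merged <- suppressWarnings(merge_mixocc(reviewed, empty, the_regions))
  expect_equal(nrow(merged), 1)
})
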