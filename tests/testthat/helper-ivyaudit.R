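# shared fixtures, built in code

the_kb <- load_concept_kb()
the_matrix <- hedera_matrix()
the_regions <- region_uncertainty()

# small two-species world with a custom region table, used by GLM tests
toy_region_table <- function(keys, n_species) {
  data.frame(region_key = keys, island_group = NA_character_,
             n_species = n_species,
             uncertainty = ifelse(n_species >= 2, "high", "low"),
             stringsAsFactors = FALSE)
}

# a name model that is correct with probability p_correct, otherwise
# unidentified — self-classifying without any rule table entry
plain_name_model <- function(species, p_correct) {
  data.frame(name = c(species, ""),
             category = c("correct", "not_identified"),
             prob = c(p_correct, 1 - p_correct), stringsAsFactors = FALSE)
}

# random small classification matrix supported on the packaged matrix's
# nonzero cells (so every (row, col) pair is classifiable by the rule table)
random_matrix <- function(seed, nrow_max = 8, ncol_max = 5) {
  set.seed(seed)
  rows <- sample(rownames(the_matrix), sample(3:nrow_max, 1))
  cols <- sample(colnames(the_matrix), sample(2:ncol_max, 1))
  sup <- the_matrix[rows, cols, drop = FALSE] > 0
  m <- sup * matrix(rpois(length(sup), 3), nrow = nrow(sup))
  dimnames(m) <- list(rows, cols)
  storage.mode(m) <- "integer"
  m
}

# (row label, column label, count) triples of the nonzero cells, sorted —
# order- and zero-invariant matrix comparison
matrix_triples <- function(m) {
  ix <- which(m > 0, arr.ind = TRUE)
  out <- data.frame(row = rownames(m)[ix[, 1]], col = colnames(m)[ix[, 2]],
                    n = as.integer(m[ix]), stringsAsFactors = FALSE)
  out[order(out$row, out$col), , drop = FALSE]
}
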