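# Shared fixtures, built in code.

# The triphasic decay model fitted to an exponential-phase killing curve
# (fast lysis of growing cells, an intermediate phase, and a slow persister
# tail); used throughout the decay-fit tests.
triphasic_model <- function() {
  multiexp_model(c(7.46e6, 1.42e6, 64.1), c(9.89, 3.09, 0.508))
}

# A hand-built lineage forest: founder 1 divides twice along one branch,
# founder 10 never divides (constant area), founder 20 loses tracking in
# the window. Exposure onset at 1.5 h.
toy_lineage_table <- function() {
  data.frame(
    cell_id   = c(1L, 2L, 3L, 4L, 5L, 10L, 20L),
    parent_id = c(NA, 1L, 1L, 2L, 2L, NA, NA),
    chamber_id = c(1L, 1L, 1L, 1L, 1L, 2L, 3L),
    birth_h   = c(0, 0.5, 0.5, 1.0, 1.0, 0, 0),
    end_h     = c(0.5, 1.0, 7.5, 7.5, 7.5, 7.5, 1.2),
    fate      = c("division", "division", "lysis", "lysis", "lysis",
                  "censored", "tracking_lost"),
    persister = c(FALSE, NA, NA, NA, NA, FALSE, FALSE),
    area_birth_um2 = c(1, 1, 1, 1, 1, 2, 1),
    area_end_um2   = c(2, 2, 2, 2, 2, 2, 1.05),
    stringsAsFactors = FALSE)
}

# A full binary tree of the given depth, all divisions before `onset`;
# leaves never divide. Used for sister-sampling enumeration tests.
binary_tree_table <- function(depth = 3, onset = 1.5) {
  dt <- onset / (depth + 1)
  rows <- list(data.frame(cell_id = 1L, parent_id = NA_integer_,
                          chamber_id = 1L, birth_h = 0, end_h = dt,
                          fate = "division", persister = FALSE,
                          area_birth_um2 = 1, area_end_um2 = 2,
                          stringsAsFactors = FALSE))
  prev <- 1L; next_id <- 1L
  for (lev in seq_len(depth)) {
    b <- lev * dt
    e <- if (lev == depth) onset + 1 else (lev + 1) * dt
    fate <- if (lev == depth) "censored" else "division"
    ids <- next_id + seq_len(2 * length(prev))
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = ids, parent_id = rep(prev, each = 2), chamber_id = 1L,
      birth_h = b, end_h = e, fate = fate, persister = NA,
      area_birth_um2 = 1, area_end_um2 = 2, stringsAsFactors = FALSE)
    next_id <- max(ids); prev <- ids
  }
  do.call(rbind, rows)
}

# Merge two simulated lineage sets into one table, flagging the founders of
# the first as persisters and of the second as non-persisters; cell ids of
# the second set are shifted to stay unique.
merge_as_groups <- function(tab_persister, tab_non) {
  shift <- max(tab_persister$cell_id) + 1L
  tab_non$cell_id <- tab_non$cell_id + shift
  tab_non$parent_id <- tab_non$parent_id + shift
  tab_non$chamber_id <- tab_non$chamber_id + max(tab_persister$chamber_id)
  tab_persister$persister[is.na(tab_persister$parent_id)] <- TRUE
  tab_non$persister[is.na(tab_non$parent_id)] <- FALSE
  rbind(tab_persister, tab_non)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
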