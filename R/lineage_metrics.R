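# Single-cell lineage statistics: division rates, growing/non-growing
# classification in the pre-exposure window, binomial fractions, persister
# frequency from chamber counts, shape metrics, and rank-sum comparisons.

.LINEAGE_COLS <- c("cell_id", "parent_id", "chamber_id", "birth_h", "end_h",
                   "fate", "persister")
.FATES <- c("division", "lysis", "tracking_lost", "censored")

#' Validate a lineage table
#'
#' Checks the forest structure of a cell-lineage table: required columns,
#' unique cell ids, known fates, parents that exist, no cycles, and child
#' birth times equal to the parent's division time.
#'
#' @param table Data frame with columns `cell_id`, `parent_id` (`NA` for
#'   founders), `chamber_id`, `birth_h`, `end_h`, `fate` (one of
#'   `division`, `lysis`, `tracking_lost`, `censored`), `persister`
#'   (logical, meaningful on founders).
#' @return The table, invisibly, with `parent_id` normalised; errors name
#'   the offending cell id.
#' @export
validate_lineage_table <- function(table) {
  miss <- setdiff(.LINEAGE_COLS, names(table))
  if (length(miss)) stop("missing lineage columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$cell_id))
    stop("duplicate cell_id: ", table$cell_id[duplicated(table$cell_id)][1])
  if (!all(table$fate %in% .FATES))
    stop("unknown fate value(s): ",
         paste(unique(setdiff(table$fate, .FATES)), collapse = ", "))
  has_parent <- !is.na(table$parent_id)
  if (any(has_parent & !(table$parent_id %in% table$cell_id)))
    stop("parent_id not present in table: ",
         table$parent_id[has_parent & !(table$parent_id %in% table$cell_id)][1])
  if (any(table$end_h < table$birth_h))
    stop("end_h before birth_h for cell ", table$cell_id[table$end_h < table$birth_h][1])
  # cycle check: follow parents; depth can never exceed the number of cells
  idx <- match(table$parent_id, table$cell_id)
  for (i in which(has_parent)) {
    seen <- 0L; j <- i
    while (!is.na(idx[j])) {
      j <- idx[j]; seen <- seen + 1L
      if (seen > nrow(table))
        stop("lineage cycle detected involving cell ", table$cell_id[i])
    }
  }
  pmatch_birth <- table$birth_h[has_parent] - table$end_h[idx[has_parent]]
  if (any(abs(pmatch_birth) > 1e-9 & table$fate[idx[has_parent]] == "division"))
    stop("child birth time does not match parent division time for cell ",
         table$cell_id[has_parent][which(abs(pmatch_birth) > 1e-9)[1]])
  invisible(table)
}

#' Division rate of a cell lineage
#'
#' The mean division rate of a single-cell lineage is the number of
#' divisions observed along it during the pre-exposure period divided by
#' the duration of that period, in doublings per hour.
#'
#' @param divisions Number of divisions D along the lineage (vectorized).
#' @param duration_h Pre-exposure duration T in hours, `> 0`.
#' @return Division rate D/T in doublings/h.
#' @examples
#' division_rate(3, 1.5)  # 2 doublings/h
#' @export
division_rate <- function(divisions, duration_h) {
  if (any(duration_h <= 0)) stop("duration_h must be positive")
  if (any(divisions < 0)) stop("divisions must be non-negative")
  divisions / duration_h
}

#' Sample one independent lineage per founder
#'
#' Walks each founder's lineage forward in time up to the onset of drug
#' exposure, choosing one of the two sister cells uniformly at random at
#' every division, so that the sampled lineages are statistically
#' independent (one per founding cell).
#'
#' @param table Lineage table (see [validate_lineage_table()]).
#' @param t_exposure_onset Exposure onset in hours; divisions at or after
#'   this time are not traversed.
#' @param seed Integer seed; the sister choices are deterministic given it.
#' @return Data frame, one row per founder: `founder_id`, `cell_id` (the
#'   lineage's occupant at onset), `n_divisions` (divisions strictly before
#'   onset along the path), `duration_h` (onset minus founder birth),
#'   `division_rate`, plus a list-column `path` of row indices into `table`.
#' @export
sample_independent_lineages <- function(table, t_exposure_onset, seed = 1) {
  stopifnot(nrow(table) >= 1)
  founders <- which(is.na(table$parent_id))
  kidx <- split(seq_len(nrow(table)), match(table$parent_id, table$cell_id))
  kids <- vector("list", nrow(table))  # children row indices per parent row
  kids[as.integer(names(kidx))] <- kidx
  out_cell <- integer(length(founders))
  out_div <- integer(length(founders))
  paths <- vector("list", length(founders))
  .with_seed(.child_seed(seed, "sample_independent_lineages"), {
    for (i in seq_along(founders)) {
      cur <- founders[i]; ndiv <- 0L; path <- cur
      repeat {
        if (table$fate[cur] != "division" ||
            table$end_h[cur] >= t_exposure_onset) break
        ch <- kids[[cur]]
        if (is.null(ch) || !length(ch)) break
        cur <- if (length(ch) == 1L) ch else ch[sample.int(length(ch), 1L)]
        ndiv <- ndiv + 1L
        path <- c(path, cur)
      }
      out_cell[i] <- cur; out_div[i] <- ndiv; paths[[i]] <- path
    }
  })
  dur <- t_exposure_onset - table$birth_h[founders]
  res <- data.frame(founder_id = table$cell_id[founders],
                    cell_id = table$cell_id[out_cell],
                    n_divisions = out_div, duration_h = dur,
                    division_rate = ifelse(dur > 0, out_div / dur, NA_real_),
                    stringsAsFactors = FALSE)
  res$path <- paths
  res
}

# Area of cells (vector of rows) at times t: exponential interpolation
# between the recorded birth and end areas. Growth is assumed to stop at
# `cap` (exposure onset): cells whose record extends past the cap carry
# their end area from the cap onwards, matching growth arrest under drug.
.area_at <- function(table, rows, t, cap = Inf) {
  a0 <- table$area_birth_um2[rows]; a1 <- table$area_end_um2[rows]
  b <- table$birth_h[rows]; e <- pmin(table$end_h[rows], cap)
  t <- pmin(pmax(t, b), e)
  ifelse(e > b, a0 * (a1 / a0)^((t - b) / (e - b)), a0)
}

#' Classify lineages as growing or non-growing before exposure
#'
#' Applies the pre-exposure window rule: a lineage is `non_growing` iff it
#' shows no division inside the window immediately before exposure AND its
#' relative area increase over the window is below `elongation_threshold`;
#' it is `indeterminate` if tracking was lost inside the window; otherwise
#' `growing`.
#'
#' Cell areas are taken from `area_birth_um2`/`area_end_um2` columns with
#' exponential interpolation in between; if a `frames` table
#' (`cell_id`, `t_h`, `area_um2`) is supplied, the nearest recorded frames
#' are used instead.
#'
#' @param table Lineage table with area columns.
#' @param sampled Output of [sample_independent_lineages()] (one lineage per
#'   founder). If `NULL`, it is computed with `seed`.
#' @param t_exposure_onset Exposure onset, hours.
#' @param window Window length in hours (default 1.5, i.e. the 90 min
#'   immediately before exposure).
#' @param elongation_threshold Relative area increase below which a
#'   non-dividing lineage counts as not elongating (default 0.1).
#' @param frames Optional per-frame area table.
#' @param seed Used only when `sampled` is `NULL`.
#' @return Factor of labels (`growing`, `non_growing`, `indeterminate`),
#'   one per founder, named by `founder_id`.
#' @export
classify_pre_exposure <- function(table, sampled = NULL, t_exposure_onset,
                                  window = 1.5, elongation_threshold = 0.1,
                                  frames = NULL, seed = 1) {
  if (window <= 0) stop("window must be positive")
  if (is.null(sampled))
    sampled <- sample_independent_lineages(table, t_exposure_onset, seed)
  wstart <- t_exposure_onset - window
  if (any(table$birth_h[is.na(table$parent_id)] > wstart + 1e-9))
    stop("window extends before the start of observation for some founders")
  # the walk in sample_independent_lineages stops at the first non-division
  # fate, so the path's last cell (occupant) summarises the window: its
  # birth is the time of the most recent division along the path, and a
  # lost track inside the window makes it the occupant too.
  occ <- vapply(sampled$path, function(p) p[length(p)], integer(1))
  lost <- table$fate[occ] == "tracking_lost" &
    table$end_h[occ] > wstart & table$end_h[occ] <= t_exposure_onset
  divided <- table$birth_h[occ] > wstart + 1e-12
  a_start <- .win_area(table, frames, occ, rep(wstart, length(occ)),
                       t_exposure_onset)
  a_end <- .win_area(table, frames, occ,
                     pmin(t_exposure_onset, table$end_h[occ]),
                     t_exposure_onset)
  rel <- a_end / a_start - 1
  labels <- ifelse(lost, "indeterminate",
            ifelse(divided | !(is.finite(rel) & rel < elongation_threshold),
                   "growing", "non_growing"))
  factor(stats::setNames(labels, sampled$founder_id),
         levels = c("growing", "non_growing", "indeterminate"))
}

.win_area <- function(table, frames, rows, t, cap) {
  if (!is.null(frames)) {
    return(vapply(seq_along(rows), function(i) {
      sub <- frames[frames$cell_id == table$cell_id[rows[i]], , drop = FALSE]
      if (nrow(sub)) sub$area_um2[which.min(abs(sub$t_h - t[i]))]
      else .area_at(table, rows[i], t[i], cap)
    }, numeric(1)))
  }
  if (!all(c("area_birth_um2", "area_end_um2") %in% names(table)))
    stop("no area information available (need frames or area columns)")
  .area_at(table, rows, t, cap)
}

#' Binomial fraction with Wald standard error
#'
#' @param k Numerator count.
#' @param n Denominator count (after exclusions).
#' @param n_excluded Count excluded from both numerator and denominator
#'   (e.g. indeterminate lineages), carried for reporting.
#' @return Object of class `fraction_se`: list with `k`, `n`, `p = k/n`,
#'   `se = sqrt(p (1 - p) / n)`, `n_excluded`.
#' @examples
#' fraction_se(318, 521)   # 0.610 +/- 0.021
#' @export
fraction_se <- function(k, n, n_excluded = 0L) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  p <- k / n
  structure(list(k = k, n = n, p = p, se = sqrt(p * (1 - p) / n),
                 n_excluded = n_excluded),
            class = "fraction_se")
}

#' @export
print.fraction_se <- function(x, ...) {
  cat(sprintf("fraction %.3g +/- %.2g (k = %g, n = %g%s)\n", x$p, x$se,
              x$k, x$n,
              if (x$n_excluded > 0) paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}

#' Non-growing cell fraction with binomial standard error
#'
#' Indeterminate labels are excluded from both numerator and denominator;
#' the excluded count is reported.
#'
#' @param labels Factor or character vector of labels from
#'   [classify_pre_exposure()].
#' @return A [fraction_se()] object for the non-growing fraction.
#' @export
non_growing_fraction <- function(labels) {
  labels <- as.character(labels)
  excl <- sum(labels == "indeterminate")
  k <- sum(labels == "non_growing")
  n <- sum(labels %in% c("growing", "non_growing"))
  if (n == 0) stop("no determinate labels")
  fraction_se(k, n, n_excluded = excl)
}

#' Persister frequency from chamber-level counts
#'
#' The number of drug-exposed cells is estimated as the mean cell count over
#' a random sample of chambers multiplied by the total number of chambers
#' tracked; the persister frequency is the persister count over that total,
#' with a binomial standard error.
#'
#' @param persister_count Number of persisters observed.
#' @param sampled_chamber_cell_counts Cell counts in the sampled chambers
#'   (conventionally 20 chambers).
#' @param n_chambers Total chambers tracked.
#' @return A list of class `persister_frequency` with `total_cells`,
#'   `frequency` (a `fraction_se`-style list with `p` and `se`).
#' @export
persister_frequency_from_chambers <- function(persister_count,
                                              sampled_chamber_cell_counts,
                                              n_chambers) {
  if (!length(sampled_chamber_cell_counts))
    stop("sampled chamber counts must be non-empty")
  if (persister_count < 0) stop("persister_count must be >= 0")
  m <- mean(sampled_chamber_cell_counts)
  if (m <= 0) stop("mean chamber cell count is zero")
  total <- m * n_chambers
  p <- persister_count / total
  structure(list(total_cells = total, persister_count = persister_count,
                 p = p, se = sqrt(p * (1 - p) / total)),
            class = "persister_frequency")
}

#' @export
print.persister_frequency <- function(x, ...) {
  cat(sprintf("persister frequency %.3g +/- %.2g (%g persisters / %.3g cells)\n",
              x$p, x$se, x$persister_count, x$total_cells))
  invisible(x)
}

# ---- polygon shape metrics ----------------------------------------------

.drop_dup_vertices <- function(poly) {
  if (nrow(poly) > 1) {
    dup <- c(FALSE, rowSums((poly[-1, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2) < 1e-24)
    poly <- poly[!dup, , drop = FALSE]
  }
  # drop a closing vertex identical to the first
  if (nrow(poly) > 1 && sum((poly[1, ] - poly[nrow(poly), ])^2) < 1e-24)
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

.segs_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.is_simple <- function(poly) {
  n <- nrow(poly)
  segs <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) break
      if (.segs_intersect(poly[segs[i, 1], ], poly[segs[i, 2], ],
                          poly[segs[j, 1], ], poly[segs[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

#' Area, perimeter and circularity of a cell outline polygon
#'
#' Computes the shoelace area (absolute value), the Euclidean perimeter, and
#' the circularity `4 pi A / P^2` of a simple closed polygon. Circularity is
#' 1 for a circle and decreases toward 0 for elongated shapes.
#'
#' @param poly Two-column numeric matrix of vertices (x, y), in order; a
#'   duplicated closing vertex and duplicate consecutive vertices are
#'   dropped.
#' @param check_simple Verify the polygon does not self-intersect
#'   (default TRUE; O(n^2), disable for large trusted outlines).
#' @return List with `area`, `perimeter`, `circularity`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' shape_metrics(sq)$circularity  # pi/4
#' @export
shape_metrics <- function(poly, check_simple = TRUE) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2) stop("poly must have two columns (x, y)")
  poly <- .drop_dup_vertices(poly)
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices")
  if (check_simple && !.is_simple(poly)) stop("polygon is self-intersecting")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area = area, perimeter = perimeter,
       circularity = 4 * pi * area / perimeter^2)
}

# ---- rank-sum test -------------------------------------------------------

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by complete enumeration of rank assignments when both
#' samples have at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest `min(n, m)` for which enumeration is used
#'   (default 10).
#' @return List with `U` (Mann-Whitney statistic of `x`), `p_value`
#'   (two-sided), and `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && min(n, m) <= exact_max && max(n, m) <= exact_max) {
    combos <- utils::combn(N, n)
    allranks <- seq_len(N)
    us <- colSums(matrix(allranks[combos], nrow = n)) - n * (n + 1) / 2
    p_le <- mean(us <= U); p_ge <- mean(us >= U)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- n * m / 2
  tab <- table(r)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma   # continuity correction
  p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  list(U = U, p_value = p, method = "normal")
}

#' Compare pre-exposure division rates between persisters and non-persisters
#'
#' Samples one independent lineage per founder, splits founders by the
#' persister flag, and reports the per-group mean and standard error of the
#' division rate D/T together with a two-sided rank-sum p value.
#'
#' @param table Lineage table with a logical `persister` column on founders.
#' @param t_exposure_onset Exposure onset, hours.
#' @param seed Seed for the random sister choices.
#' @return List with `groups` (data frame: group, n, mean, se), `U`,
#'   `p_value`.
#' @export
compare_division_rates <- function(table, t_exposure_onset, seed = 1) {
  sampled <- sample_independent_lineages(table, t_exposure_onset, seed)
  founders <- table[is.na(table$parent_id), ]
  flag <- founders$persister[match(sampled$founder_id, founders$cell_id)]
  rp <- sampled$division_rate[flag %in% TRUE]
  rn <- sampled$division_rate[flag %in% FALSE]
  if (!length(rp) || !length(rn))
    stop("both persister and non-persister groups must be non-empty")
  gr <- function(v, lab) data.frame(
    group = lab, n = length(v), mean = mean(v),
    se = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  test <- rank_sum_test(rp, rn)
  list(groups = rbind(gr(rp, "persister"), gr(rn, "non_persister")),
       U = test$U, p_value = test$p_value, method = test$method)
}
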