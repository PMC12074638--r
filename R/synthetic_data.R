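# Synthetic-data generators: replicate killing curves with lognormal noise
# around a multi-exponential mean, Poisson allocation of viable cells into
# limiting-dilution wells, two-state (growing/non-growing) chamber lineage
# trees with state-dependent persister probabilities, and spherocylinder
# cell outlines for shape-metric tests.

#' Simulate replicate killing-curve measurements
#'
#' Draws `replicates` killing curves whose log10 density at each time is the
#' log10 of the multi-exponential mean plus Gaussian noise of standard
#' deviation `noise_sd_log10` (i.e. lognormal noise on the density scale).
#'
#' @param model A [multiexp_model()].
#' @param times Sampling times in hours, non-empty, all `>= 0`.
#' @param noise_sd_log10 Standard deviation of the log10 noise, `>= 0`.
#' @param replicates Number of replicate curves.
#' @param seed Integer seed; output is deterministic given it.
#' @return A `killing_curve` object whose `$curve` holds the replicate
#'   densities.
#' @export
simulate_multiexp_samples <- function(model, times, noise_sd_log10 = 0.1,
                                      replicates = 3, seed = 1) {
  stopifnot(inherits(model, "multiexp_model"))
  if (!length(times)) stop("times must be non-empty")
  if (any(times < 0)) stop("times must be non-negative")
  if (noise_sd_log10 < 0) stop("noise_sd_log10 must be non-negative")
  if (replicates < 1) stop("need at least one replicate")
  mean_log10 <- log10(multiexp_eval(model, times))
  curve <- .with_seed(.child_seed(seed, "simulate_multiexp_samples"), {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      noise <- stats::rnorm(length(times), 0, noise_sd_log10)
      data.frame(replicate = sprintf("sim%02d", r), time_h = times,
                 density = 10^(mean_log10 + noise), stringsAsFactors = FALSE)
    }))
  })
  summarize_killing_curve(curve)
}

#' Simulate limiting-dilution plates under Poisson allocation
#'
#' Each well of volume `well_volume` at dilution `d` receives a Poisson
#' number of viable cells with mean `d * y * Nv`, so it stays non-turbid
#' with probability `exp(-d * y * Nv)`; the non-turbid count per plate is
#' binomial.
#'
#' @param true_density True viable density Nv in cells/mL, `>= 0`.
#' @param dilutions Dilution levels in (0, 1].
#' @param wells_per_dilution Wells dispensed per dilution (scalar or vector).
#' @param well_volume Well volume in mL (default 0.2).
#' @param seed Integer seed.
#' @param time_h,replicate Metadata carried into the plate records.
#' @return Data frame of plates (columns as in [well_plate()]).
#' @export
simulate_limiting_dilution <- function(true_density, dilutions,
                                       wells_per_dilution = 12,
                                       well_volume = 0.2, seed = 1,
                                       time_h = NA_real_,
                                       replicate = "sim") {
  if (true_density < 0) stop("true_density must be >= 0")
  if (any(dilutions <= 0 | dilutions > 1)) stop("dilutions must be in (0, 1]")
  if (well_volume <= 0) stop("well_volume must be positive")
  W <- rep_len(as.integer(wells_per_dilution), length(dilutions))
  p_empty <- exp(-dilutions * well_volume * true_density)
  k <- .with_seed(.child_seed(seed, "simulate_limiting_dilution"),
                  stats::rbinom(length(dilutions), W, p_empty))
  data.frame(replicate = replicate, time_h = time_h, dilution = dilutions,
             wells = W, non_turbid = k, volume_ml = well_volume,
             stringsAsFactors = FALSE)
}

#' Configuration for the chamber-lineage population simulator
#'
#' Encodes the two-state (growing/non-growing) population model. Defaults
#' describe an exponential-phase E. coli population in rich medium under a
#' lethal beta-lactam dose: fast growth (2.26 doublings/h), a rare
#' non-growing subpopulation, state-dependent killing (fast lysis of
#' growing cells, slow decay of non-growing cells), and state-dependent
#' persister probabilities.
#'
#' @param n_founders Number of founding cells (one per chamber).
#' @param p_nongrowing Probability a founder starts non-growing.
#' @param division_rate Doublings/h in the growing state; division waiting
#'   times are exponential with rate `division_rate`, so the lineage
#'   statistic D(sigma)/T(sigma) recovers `division_rate` in expectation.
#' @param switch_gn,switch_ng Growing-to-non-growing and reverse switching
#'   rates (1/h).
#' @param kill_growing,kill_nongrowing Lysis rates under antibiotic (1/h)
#'   for non-persister cells of each state.
#' @param s_growing,s_nongrowing Probability a cell in that state at
#'   exposure onset is a persister (survives and regrows).
#' @param t_pre,t_exposure,t_post Durations (h) of the pre-exposure, drug
#'   exposure, and post-exposure observation periods.
#' @param frame_interval_h Frame interval for emitted areas (default 0.05 h,
#'   i.e. 3 min).
#' @param seed Root RNG seed.
#' @return Validated list of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_founders = 1000,
                           p_nongrowing = 2.9e-4,
                           division_rate = 2.26,
                           switch_gn = 0, switch_ng = 0,
                           kill_growing = 9.89, kill_nongrowing = 0.508,
                           s_growing = 1.6e-5, s_nongrowing = 8.4e-2,
                           t_pre = 1.5, t_exposure = 6, t_post = 6,
                           frame_interval_h = 0.05, seed = 1) {
  cfg <- list(n_founders = as.integer(n_founders),
              p_nongrowing = p_nongrowing, division_rate = division_rate,
              switch_gn = switch_gn, switch_ng = switch_ng,
              kill_growing = kill_growing, kill_nongrowing = kill_nongrowing,
              s_growing = s_growing, s_nongrowing = s_nongrowing,
              t_pre = t_pre, t_exposure = t_exposure, t_post = t_post,
              frame_interval_h = frame_interval_h, seed = as.integer(seed))
  rates <- c(cfg$division_rate, cfg$switch_gn, cfg$switch_ng,
             cfg$kill_growing, cfg$kill_nongrowing)
  probs <- c(cfg$p_nongrowing, cfg$s_growing, cfg$s_nongrowing)
  if (cfg$n_founders < 1) stop("n_founders must be >= 1")
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be >= 0")
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(c(cfg$t_pre, cfg$t_exposure, cfg$t_post) < 0))
    stop("durations must be >= 0")
  if (cfg$frame_interval_h <= 0) stop("frame_interval_h must be positive")
  structure(cfg, class = "pop_sim_config")
}

# exposure-phase outcome for a batch of cells alive at exposure onset;
# returns list(end_h, fate, persister) vectors. Persisters regrow (first
# post-removal division); non-persisters lyse at the state kill rate or are
# censored at the end of observation.
.exposure_fates <- function(n, state, cfg) {
  t_on <- cfg$t_pre; t_off <- cfg$t_pre + cfg$t_exposure
  t_end <- t_off + cfg$t_post
  s <- ifelse(state == "growing", cfg$s_growing, cfg$s_nongrowing)
  kill <- ifelse(state == "growing", cfg$kill_growing, cfg$kill_nongrowing)
  persister <- stats::runif(n) < s
  end <- numeric(n); fate <- character(n)
  # non-persisters: exponential lysis clock during exposure
  np <- which(!persister)
  if (length(np)) {
    lys <- ifelse(kill[np] > 0, stats::rexp(length(np), pmax(kill[np], 1e-300)),
                  Inf)
    died <- lys <= cfg$t_exposure
    end[np] <- ifelse(died, t_on + lys, t_end)
    fate[np] <- ifelse(died, "lysis", "censored")
  }
  # persisters: regrowth division after drug removal, within t_post
  pp <- which(persister)
  if (length(pp)) {
    rate <- max(cfg$division_rate, 1)
    lag <- stats::rexp(length(pp), rate)
    lag <- pmin(lag, 0.9 * max(cfg$t_post, 1e-6))
    end[pp] <- t_off + lag
    fate[pp] <- "division"
  }
  list(end_h = end, fate = fate, persister = persister)
}

#' Simulate chamber lineage trees from a two-state switching population
#'
#' Event-driven simulation of founder cells in microchambers. During the
#' pre-exposure period, growing cells divide with exponential waiting times
#' at rate `division_rate` (one doubling per division along a lineage, so
#' D(sigma)/T(sigma) recovers the configured doublings/h) and switch state
#' at the configured
#' rates. At exposure onset every live cell draws its persister fate from
#' the state-dependent probability; non-persisters lyse at the state kill
#' rate during exposure (or are censored), persisters regrow (divide) after
#' drug removal. Cell areas grow exponentially while in the growing state
#' and halve at division.
#'
#' The per-founder ground truth records the state at exposure onset of the
#' first-child lineage (equal to the founder state whenever the switching
#' rates are zero) and whether any cell of the founder's subtree was a
#' persister.
#'
#' @param config A [pop_sim_config()].
#' @param frames Emit a per-frame area table (default FALSE; costly for
#'   large populations).
#' @return List of class `simulated_lineages`: `table` (lineage table with
#'   `area_birth_um2`/`area_end_um2` columns), `truth` (founder_id,
#'   true_state_at_exposure, true_persister), `frames` (or `NULL`),
#'   `config`.
#' @export
simulate_chamber_lineages <- function(config, frames = FALSE) {
  stopifnot(inherits(config, "pop_sim_config"))
  cfg <- config
  out <- .with_seed(.child_seed(cfg$seed, "simulate_chamber_lineages"), {
    if (cfg$switch_gn == 0 && cfg$switch_ng == 0)
      .simulate_lineages_fast(cfg)
    else
      .simulate_lineages_general(cfg)
  })
  tab <- out$table
  # the persister flag is a founder-level property (did any cell of the
  # founder's subtree survive and regrow); cell-level fates remain visible
  # through the post-exposure "division" events
  tab$persister <- NA
  fr_idx <- which(is.na(tab$parent_id))
  tab$persister[fr_idx] <- out$truth$true_persister[
    match(tab$cell_id[fr_idx], out$truth$founder_id)]
  fr <- if (frames) .emit_frames(tab, cfg) else NULL
  structure(list(table = tab, truth = out$truth, frames = fr, config = cfg),
            class = "simulated_lineages")
}

# No-switching case: states are fixed, so growing subtrees can be advanced
# one generation at a time with vectorized draws.
.simulate_lineages_general <- function(cfg) {
  r_div0 <- cfg$division_rate          # division events per hour (growing)
  g <- cfg$division_rate * log(2)      # area growth rate while growing
  t_pre <- cfg$t_pre
  # per-cell records accumulated in growable vectors
  cap <- max(64L, cfg$n_founders * 4L)
  id <- integer(cap); parent <- integer(cap); chamber <- integer(cap)
  birth <- numeric(cap); endv <- numeric(cap); fate <- character(cap)
  a0 <- numeric(cap); a1 <- numeric(cap); pers <- logical(cap)
  st_exp <- character(cap)  # state at exposure, "" if dead before
  n_rec <- 0L
  push <- function(...) {
    rec <- list(...)
    n_rec <<- n_rec + 1L
    if (n_rec > length(id)) {
      id <<- c(id, integer(length(id))); parent <<- c(parent, integer(length(parent)))
      chamber <<- c(chamber, integer(length(chamber)))
      birth <<- c(birth, numeric(length(birth))); endv <<- c(endv, numeric(length(endv)))
      fate <<- c(fate, character(length(fate)))
      a0 <<- c(a0, numeric(length(a0))); a1 <<- c(a1, numeric(length(a1)))
      pers <<- c(pers, logical(length(pers))); st_exp <<- c(st_exp, character(length(st_exp)))
    }
    i <- n_rec
    id[i] <<- rec$id; parent[i] <<- rec$parent; chamber[i] <<- rec$chamber
    birth[i] <<- rec$birth; endv[i] <<- rec$end; fate[i] <<- rec$fate
    a0[i] <<- rec$a0; a1[i] <<- rec$a1; pers[i] <<- rec$pers
    st_exp[i] <<- rec$st
    i
  }
  next_id <- 0L
  founder_state <- ifelse(stats::runif(cfg$n_founders) < cfg$p_nongrowing,
                          "non_growing", "growing")
  truth_state <- character(cfg$n_founders)
  truth_pers <- logical(cfg$n_founders)
  for (f in seq_len(cfg$n_founders)) {
    # stack of cells to process: list(id, parent, birth, state, area, first_child_line)
    next_id <- next_id + 1L
    stack <- list(list(id = next_id, parent = NA_integer_, birth = 0,
                       state = founder_state[f], area = 1, line = TRUE))
    any_pers <- FALSE
    while (length(stack)) {
      cell <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      t <- cell$birth; state <- cell$state; area <- cell$area
      grow_t <- 0
      repeat {
        r_div <- if (state == "growing") r_div0 else 0
        r_sw <- if (state == "growing") cfg$switch_gn else cfg$switch_ng
        w_div <- if (r_div > 0) stats::rexp(1, r_div) else Inf
        w_sw <- if (r_sw > 0) stats::rexp(1, r_sw) else Inf
        w <- min(w_div, w_sw)
        if (t + w >= t_pre) {
          # alive at exposure onset
          if (state == "growing") grow_t <- grow_t + (t_pre - t)
          fx <- .exposure_fates(1, state, cfg)
          area_end <- cell$area * exp(g * grow_t)
          idx <- push(id = cell$id, parent = cell$parent, chamber = f,
                      birth = cell$birth, end = fx$end_h + 0,
                      fate = fx$fate, a0 = cell$area, a1 = area_end,
                      pers = fx$persister, st = state)
          if (fx$persister) {
            any_pers <- TRUE
            # regrowth children, censored at end of observation
            t_end <- t_pre + cfg$t_exposure + cfg$t_post
            for (cidx in 1:2) {
              next_id <- next_id + 1L
              push(id = next_id, parent = cell$id, chamber = f,
                   birth = endv[idx], end = t_end, fate = "censored",
                   a0 = area_end / 2, a1 = area_end / 2, pers = FALSE,
                   st = "")
            }
          }
          if (cell$line) truth_state[f] <- state
          break
        }
        if (w_sw < w_div) {
          if (state == "growing") grow_t <- grow_t + w_sw
          state <- if (state == "growing") "non_growing" else "growing"
          t <- t + w_sw
        } else {
          # division at t + w_div
          grow_t <- grow_t + w_div
          t_div <- t + w_div
          area_end <- cell$area * exp(g * grow_t)
          push(id = cell$id, parent = cell$parent, chamber = f,
               birth = cell$birth, end = t_div, fate = "division",
               a0 = cell$area, a1 = area_end, pers = FALSE, st = "")
          for (cidx in 1:2) {
            next_id <- next_id + 1L
            stack[[length(stack) + 1L]] <-
              list(id = next_id, parent = cell$id, birth = t_div,
                   state = state, area = area_end / 2,
                   line = cell$line && cidx == 1L)
          }
          break
        }
      }
    }
    truth_pers[f] <- any_pers
    if (truth_state[f] == "") truth_state[f] <- founder_state[f]
  }
  keep <- seq_len(n_rec)
  tab <- data.frame(cell_id = id[keep], parent_id = ifelse(is.na(parent[keep]),
                                                           NA_integer_, parent[keep]),
                    chamber_id = chamber[keep], birth_h = birth[keep],
                    end_h = endv[keep], fate = fate[keep],
                    persister = pers[keep],
                    area_birth_um2 = a0[keep], area_end_um2 = a1[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cell_id), ]
  rownames(tab) <- NULL
  truth <- data.frame(founder_id = tab$cell_id[is.na(tab$parent_id)],
                      true_state_at_exposure = truth_state,
                      true_persister = truth_pers, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

.simulate_lineages_fast <- function(cfg) {
  r_div <- cfg$division_rate           # division events per hour (growing)
  g <- cfg$division_rate * log(2)      # area growth rate while growing
  t_pre <- cfg$t_pre
  t_end <- t_pre + cfg$t_exposure + cfg$t_post
  n <- cfg$n_founders
  state0 <- ifelse(stats::runif(n) < cfg$p_nongrowing, "non_growing", "growing")
  rows <- list()
  next_id <- n  # founders take ids 1..n
  # active growing cells advancing generation by generation
  act_id <- seq_len(n)[state0 == "growing"]
  act_parent <- rep(NA_integer_, length(act_id))
  act_birth <- rep(0, length(act_id))
  act_area <- rep(1, length(act_id))
  act_chamber <- act_id
  alive <- list()  # growing cells alive at exposure onset
  while (length(act_id)) {
    w <- if (r_div > 0) stats::rexp(length(act_id), r_div)
         else rep(Inf, length(act_id))
    t_div <- act_birth + w
    div <- t_div < t_pre
    if (any(!div)) {
      i <- which(!div)
      alive[[length(alive) + 1L]] <- data.frame(
        cell_id = act_id[i], parent_id = act_parent[i],
        chamber_id = act_chamber[i], birth_h = act_birth[i],
        area_birth_um2 = act_area[i], stringsAsFactors = FALSE)
    }
    if (any(div)) {
      i <- which(div)
      area_end <- act_area[i] * exp(g * (t_div[i] - act_birth[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = act_id[i], parent_id = act_parent[i],
        chamber_id = act_chamber[i], birth_h = act_birth[i],
        end_h = t_div[i], fate = "division", persister = FALSE,
        area_birth_um2 = act_area[i], area_end_um2 = area_end,
        stringsAsFactors = FALSE)
      nd <- length(i)
      child_id <- next_id + seq_len(2 * nd)
      next_id <- next_id + 2L * nd
      act_parent <- rep(act_id[i], each = 2)
      act_chamber <- rep(act_chamber[i], each = 2)
      act_birth <- rep(t_div[i], each = 2)
      act_area <- rep(area_end / 2, each = 2)
      act_id <- child_id
    } else break
  }
  grow_alive <- if (length(alive)) do.call(rbind, alive) else NULL
  # growing cells alive at onset
  if (!is.null(grow_alive) && nrow(grow_alive)) {
    ng <- nrow(grow_alive)
    fx <- .exposure_fates(ng, rep("growing", ng), cfg)
    area_on <- grow_alive$area_birth_um2 * exp(g * (t_pre - grow_alive$birth_h))
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = grow_alive$cell_id, parent_id = grow_alive$parent_id,
      chamber_id = grow_alive$chamber_id, birth_h = grow_alive$birth_h,
      end_h = fx$end_h, fate = fx$fate, persister = fx$persister,
      area_birth_um2 = grow_alive$area_birth_um2, area_end_um2 = area_on,
      stringsAsFactors = FALSE)
    pp <- which(fx$persister)
    if (length(pp)) {
      npp <- length(pp)
      child_id <- next_id + seq_len(2 * npp)
      next_id <- next_id + 2L * npp
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = child_id,
        parent_id = rep(grow_alive$cell_id[pp], each = 2),
        chamber_id = rep(grow_alive$chamber_id[pp], each = 2),
        birth_h = rep(fx$end_h[pp], each = 2),
        end_h = t_end, fate = "censored", persister = FALSE,
        area_birth_um2 = rep(area_on[pp] / 2, each = 2),
        area_end_um2 = rep(area_on[pp] / 2, each = 2),
        stringsAsFactors = FALSE)
    }
  }
  # non-growing founders: single cells spanning the pre-exposure period
  ngf <- which(state0 == "non_growing")
  if (length(ngf)) {
    nn <- length(ngf)
    fx <- .exposure_fates(nn, rep("non_growing", nn), cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = ngf, parent_id = NA_integer_, chamber_id = ngf,
      birth_h = 0, end_h = fx$end_h, fate = fx$fate,
      persister = fx$persister, area_birth_um2 = 1, area_end_um2 = 1,
      stringsAsFactors = FALSE)
    pp <- which(fx$persister)
    if (length(pp)) {
      npp <- length(pp)
      child_id <- next_id + seq_len(2 * npp)
      next_id <- next_id + 2L * npp
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = child_id, parent_id = rep(ngf[pp], each = 2),
        chamber_id = rep(ngf[pp], each = 2),
        birth_h = rep(fx$end_h[pp], each = 2),
        end_h = t_end, fate = "censored", persister = FALSE,
        area_birth_um2 = 0.5, area_end_um2 = 0.5, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$cell_id), ]
  rownames(tab) <- NULL
  # ground truth per founder
  pers_by_chamber <- tapply(tab$persister & !is.na(tab$persister),
                            tab$chamber_id, any)
  founders <- which(is.na(tab$parent_id))
  truth <- data.frame(
    founder_id = tab$cell_id[founders],
    true_state_at_exposure = state0[tab$chamber_id[founders]],
    true_persister = as.logical(pers_by_chamber[as.character(tab$chamber_id[founders])]),
    stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

# per-frame areas on the fixed frame interval; growth frozen at exposure
.emit_frames <- function(tab, cfg) {
  res <- lapply(seq_len(nrow(tab)), function(i) {
    ts <- seq(tab$birth_h[i], tab$end_h[i], by = cfg$frame_interval_h)
    if (!length(ts)) ts <- tab$birth_h[i]
    a0 <- tab$area_birth_um2[i]; a1 <- tab$area_end_um2[i]
    b <- tab$birth_h[i]; e <- tab$end_h[i]
    grow_until <- min(e, cfg$t_pre)
    frac <- if (grow_until > b) pmin(pmax(ts, b), grow_until) - b else 0
    span <- if (grow_until > b) grow_until - b else 1
    area <- a0 * (a1 / a0)^(frac / span)
    data.frame(cell_id = tab$cell_id[i], t_h = ts, area_um2 = area)
  })
  do.call(rbind, res)
}

#' @export
print.simulated_lineages <- function(x, ...) {
  cat(sprintf("Simulated lineage set: %d cells, %d founders, %d persister founder(s)\n",
              nrow(x$table), nrow(x$truth), sum(x$truth$true_persister)))
  invisible(x)
}

#' Polygonal spherocylinder outline with analytic area and perimeter
#'
#' Builds a closed, counter-clockwise polygon approximating a rod-shaped
#' cell: a rectangle of length `length - width` capped by two semicircles
#' of diameter `width`. The analytic area
#' `(length - width) * width + pi * (width / 2)^2` and perimeter
#' `2 * (length - width) + pi * width` are attached as attributes for use
#' as oracle values in shape-metric tests. `length == width` gives a
#' circle.
#'
#' @param length Total cell length, um, `>= width`.
#' @param width Cell width (diameter), um, `> 0`.
#' @param n_vertices Approximate number of vertices, `>= 8`.
#' @return Two-column matrix of vertices (closed: last vertex repeats the
#'   first) with attributes `area` and `perimeter`.
#' @export
simulate_cell_outline <- function(length, width, n_vertices = 64) {
  if (width <= 0 || length < width) stop("need length >= width > 0")
  if (n_vertices < 8) stop("n_vertices must be >= 8")
  r <- width / 2
  h <- (length - width) / 2   # half-length of the straight section
  m <- max(4L, ceiling(n_vertices / 2))
  # right cap: -pi/2 -> pi/2; left cap: pi/2 -> 3 pi/2 (counter-clockwise)
  th_r <- seq(-pi / 2, pi / 2, length.out = m)
  th_l <- seq(pi / 2, 3 * pi / 2, length.out = m)
  right <- cbind(h + r * cos(th_r), r * sin(th_r))
  left <- cbind(-h + r * cos(th_l), r * sin(th_l))
  poly <- rbind(right, left)
  poly <- .drop_dup_vertices(poly)
  poly <- rbind(poly, poly[1, ])   # close exactly
  attr(poly, "area") <- (length - width) * width + pi * r^2
  attr(poly, "perimeter") <- 2 * (length - width) + pi * width
  poly
}
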