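# Limiting-dilution (most probable number) viable-count estimation and
# killing-curve assembly.

#' Construct a limiting-dilution plate record
#'
#' One observation of a 96-well limiting-dilution assay: a diluted cell
#' suspension dispensed into `wells` wells of `volume_ml` each, of which
#' `non_turbid` showed no growth after incubation.
#'
#' @param dilution Dilution level d in (0, 1] (e.g. `1e-6` for a
#'   million-fold dilution).
#' @param wells Total wells dispensed W.
#' @param non_turbid Number of non-turbid wells k, `0 <= k <= W`.
#' @param volume_ml Volume per well y in mL (default 0.2, i.e. 200 uL).
#' @param time_h Hours since antibiotic exposure onset (optional, `NA` if
#'   the plate is not part of a time course).
#' @param replicate Replicate identifier (optional).
#' @return A one-row data frame of class `well_plate` with columns
#'   `replicate`, `time_h`, `dilution`, `wells`, `non_turbid`, `volume_ml`.
#' @export
well_plate <- function(dilution, wells, non_turbid, volume_ml = 0.2,
                       time_h = NA_real_, replicate = NA_character_) {
  stopifnot(length(dilution) == 1, length(wells) == 1, length(non_turbid) == 1)
  if (!is.finite(dilution) || dilution <= 0 || dilution > 1)
    stop("dilution must be in (0, 1]")
  if (wells < 1 || non_turbid < 0 || non_turbid > wells)
    stop("need 0 <= non_turbid <= wells, wells >= 1")
  if (volume_ml <= 0) stop("volume_ml must be positive")
  out <- data.frame(replicate = as.character(replicate), time_h = time_h,
                    dilution = dilution, wells = as.integer(wells),
                    non_turbid = as.integer(non_turbid),
                    volume_ml = volume_ml, stringsAsFactors = FALSE)
  class(out) <- c("well_plate", class(out))
  out
}

#' Estimate viable cell density from one limiting-dilution plate
#'
#' Under Poisson allocation of viable cells into wells, the probability that
#' a well receives no viable cell (and stays non-turbid) is
#' `exp(-d * y * Nv)`, so the density is estimated as
#' `Nv = ln(W / k) / (y * d)` cells/mL. With the standard 0.2 mL wells this
#' is the familiar `(5 / d) * ln(W / k)`.
#'
#' @param plate A `well_plate` (one row), or `NULL` if the scalar arguments
#'   are given directly.
#' @param dilution,wells,non_turbid,volume_ml Scalars used when `plate` is
#'   `NULL`.
#' @return Estimated viable density in cells/mL. `non_turbid == wells`
#'   (no growth anywhere) returns 0 with a warning; `non_turbid == 0` (all
#'   wells turbid) is an error of class `persistlab_all_turbid` because the
#'   estimate is unbounded and a higher dilution is needed.
#' @examples
#' estimate_viable_density(well_plate(1e-6, 12, 3))  # 6.93e6, ~7e6 at 1 s.f.
#' @export
estimate_viable_density <- function(plate = NULL, dilution = NULL,
                                    wells = NULL, non_turbid = NULL,
                                    volume_ml = 0.2) {
  if (!is.null(plate)) {
    stopifnot(inherits(plate, "well_plate") || is.data.frame(plate))
    stopifnot(nrow(plate) == 1)
    dilution <- plate$dilution; wells <- plate$wells
    non_turbid <- plate$non_turbid; volume_ml <- plate$volume_ml
  }
  if (dilution <= 0 || dilution > 1) stop("dilution must be in (0, 1]")
  if (volume_ml <= 0) stop("volume_ml must be positive")
  if (non_turbid < 0 || non_turbid > wells) stop("need 0 <= k <= W")
  if (non_turbid == 0)
    stop(structure(class = c("persistlab_all_turbid", "error", "condition"),
                   list(message = "all wells turbid: density estimate unbounded; use a higher dilution",
                        call = sys.call(-1))))
  if (non_turbid == wells) {
    warning("all wells non-turbid: estimated density is 0 cells/mL")
    return(0)
  }
  log(wells / non_turbid) / (volume_ml * dilution)
}

#' Reconcile density estimates from dilutions with mixed wells
#'
#' When turbid and non-turbid wells coexist at two adjacent dilutions, the
#' two density estimates are reconciled by their geometric mean; a single
#' estimate passes through unchanged.
#'
#' @param estimates Numeric vector of 1 or 2 positive density estimates
#'   (cells/mL).
#' @return A single density (cells/mL).
#' @export
combine_mixed_dilutions <- function(estimates) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 1 || length(estimates) > 2)
    stop("expected 1 or 2 estimates")
  if (any(!is.finite(estimates)) || any(estimates <= 0))
    stop("estimates must be positive and finite")
  if (length(estimates) == 1) estimates else sqrt(prod(estimates))
}

#' Assemble a killing curve from limiting-dilution plates
#'
#' For each (replicate, time) the plates showing both turbid and non-turbid
#' wells are converted to density estimates and reconciled by geometric mean
#' (when more than two dilutions are mixed, the two with the non-turbid count
#' closest to W/2 are used, with a warning). Per time point the mean and
#' standard error of log10 density across replicates are computed.
#'
#' Replicate/time combinations where every dilution shows only non-turbid
#' wells contribute density 0 and are excluded from the log-scale summary
#' with a flag; combinations with no usable plate at all are flagged missing.
#'
#' @param plates Data frame with columns `replicate`, `time_h`, `dilution`,
#'   `wells`, `non_turbid`, `volume_ml` (one row per plate).
#' @return An object of class `killing_curve`: a list with `curve`
#'   (replicate, time_h, density), `summary` (time_h, mean_log10, se_log10,
#'   n_replicates, n_zero), and `flags` (character messages).
#' @export
build_killing_curve <- function(plates) {
  req <- c("replicate", "time_h", "dilution", "wells", "non_turbid", "volume_ml")
  miss <- setdiff(req, names(plates))
  if (length(miss)) stop("missing plate columns: ", paste(miss, collapse = ", "))
  if (!nrow(plates)) stop("no plates supplied")
  flags <- character(0)
  keys <- unique(plates[, c("replicate", "time_h")])
  dens <- vapply(seq_len(nrow(keys)), function(i) {
    sub <- plates[plates$replicate == keys$replicate[i] &
                  plates$time_h == keys$time_h[i], , drop = FALSE]
    mixed <- sub[sub$non_turbid >= 1 & sub$non_turbid < sub$wells, , drop = FALSE]
    if (nrow(mixed) == 0) {
      if (all(sub$non_turbid == sub$wells)) {
        flags <<- c(flags, sprintf(
          "replicate %s, t=%g h: no growth at any dilution; density 0 excluded from log-mean",
          keys$replicate[i], keys$time_h[i]))
        return(0)
      }
      flags <<- c(flags, sprintf(
        "replicate %s, t=%g h: no dilution with mixed wells; point missing",
        keys$replicate[i], keys$time_h[i]))
      return(NA_real_)
    }
    if (nrow(mixed) > 2) {
      ord <- order(abs(mixed$non_turbid / mixed$wells - 0.5))
      mixed <- mixed[ord[1:2], , drop = FALSE]
      warning(sprintf("replicate %s, t=%g h: >2 mixed dilutions; using the two with k closest to W/2",
                      keys$replicate[i], keys$time_h[i]))
    }
    est <- vapply(seq_len(nrow(mixed)), function(j)
      estimate_viable_density(dilution = mixed$dilution[j],
                              wells = mixed$wells[j],
                              non_turbid = mixed$non_turbid[j],
                              volume_ml = mixed$volume_ml[j]), numeric(1))
    combine_mixed_dilutions(est)
  }, numeric(1))
  curve <- data.frame(replicate = keys$replicate, time_h = keys$time_h,
                      density = dens, stringsAsFactors = FALSE)
  summarize_killing_curve(curve, flags = flags)
}

#' Summarize a replicate-level killing curve on the log10 scale
#'
#' @param curve Data frame with columns `replicate`, `time_h`, `density`.
#' @param flags Optional character vector of messages carried through.
#' @return A `killing_curve` object (see [build_killing_curve()]).
#' @export
summarize_killing_curve <- function(curve, flags = character(0)) {
  stopifnot(all(c("replicate", "time_h", "density") %in% names(curve)))
  times <- sort(unique(curve$time_h[is.finite(curve$time_h)]))
  summ <- do.call(rbind, lapply(times, function(tt) {
    d <- curve$density[curve$time_h == tt & !is.na(curve$density)]
    nz <- sum(d == 0)
    d <- d[d > 0]
    n <- length(d)
    lg <- log10(d)
    data.frame(time_h = tt,
               mean_log10 = if (n) mean(lg) else NA_real_,
               se_log10 = if (n > 1) stats::sd(lg) / sqrt(n) else if (n == 1) 0 else NA_real_,
               n_replicates = n, n_zero = nz)
  }))
  structure(list(curve = curve, summary = summ, flags = flags),
            class = "killing_curve")
}

#' @export
print.killing_curve <- function(x, ...) {
  cat("Killing curve:", length(unique(x$curve$replicate)), "replicate(s),",
      nrow(x$summary), "time point(s)\n")
  print(x$summary, row.names = FALSE)
  if (length(x$flags)) cat("flags:\n ", paste(x$flags, collapse = "\n  "), "\n")
  invisible(x)
}

#' Surviving fraction at a time point, with a propagated log-scale range
#'
#' The fraction of cells surviving to time `t` relative to the onset of
#' exposure, `f = 10^(mean_log10(t) - mean_log10(0))`. The range is obtained
#' by propagating the standard errors of the two log-means,
#' `SE = sqrt(SE(t)^2 + SE(0)^2)`, as `f * 10^(+/- SE)`.
#'
#' @param curve A `killing_curve` object.
#' @param t Time in hours; the curve must have summaries at 0 and `t`.
#' @return A list of class `surviving_fraction` with elements `time_h`, `f`,
#'   `lower`, `upper`, `se_log10`.
#' @export
surviving_fraction <- function(curve, t) {
  stopifnot(inherits(curve, "killing_curve"))
  s <- curve$summary
  row0 <- s[s$time_h == 0, , drop = FALSE]
  rowt <- s[s$time_h == t, , drop = FALSE]
  if (!nrow(row0) || !is.finite(row0$mean_log10))
    stop("curve has no usable t = 0 point")
  if (!nrow(rowt) || !is.finite(rowt$mean_log10))
    stop("curve has no usable point at t = ", t)
  se <- sqrt(rowt$se_log10^2 + row0$se_log10^2)
  f <- 10^(rowt$mean_log10 - row0$mean_log10)
  structure(list(time_h = t, f = f, lower = f * 10^(-se),
                 upper = f * 10^(se), se_log10 = se),
            class = "surviving_fraction")
}

#' @export
print.surviving_fraction <- function(x, ...) {
  cat(sprintf("Surviving fraction at %g h: %.3g (%.3g-%.3g)\n",
              x$time_h, x$f, x$lower, x$upper))
  invisible(x)
}

#' Minimum inhibitory concentration from optical-density readings
#'
#' The MIC is the smallest tested concentration such that it and every
#' higher tested concentration have a geometric-mean OD below `threshold`
#' across replicates.
#'
#' @param od Data frame with a `concentration` column and an `od` column
#'   (long format, one row per replicate reading).
#' @param threshold Geometric-mean OD cutoff (default 0.001).
#' @return The MIC concentration; `Inf` (with a warning) if no tested
#'   concentration suppresses growth, meaning the MIC is above the tested
#'   range.
#' @export
mic_from_od <- function(od, threshold = 0.001) {
  stopifnot(all(c("concentration", "od") %in% names(od)))
  if (!nrow(od)) stop("empty OD table")
  if (any(od$od <= 0)) stop("OD values must be positive for geometric means")
  conc <- sort(unique(od$concentration))
  gm <- vapply(conc, function(cc)
    exp(mean(log(od$od[od$concentration == cc]))), numeric(1))
  below <- gm < threshold
  # smallest conc where this and all higher concentrations are suppressed
  ok <- rev(cumprod(rev(below))) == 1
  if (!any(ok)) {
    warning("no tested concentration suppressed growth: MIC above tested range")
    return(Inf)
  }
  conc[which(ok)[1]]
}
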