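#' Options for population-coupling computation
#'
#' @param kernel_half_width_ms population-rate smoothing sigma (12 ms).
#' @param unit_kernel_mode `"literal"` smooths the unit train with sigma
#'   `12/sqrt(2)` ms and the population with 12 ms; `"strict"` uses
#'   `12/sqrt(2)` for both, so the implied product of the two kernels matches
#'   a single 12 ms smoothing.
#' @param leakage_min_separation_um 150 (own contact excluded only) or 300
#'   (leakage control; adjacent contacts dropped too).
#' @param max_lag_ms widest diagnostic cross-correlation lag.
#' @return A named list.
#' @export
coupling_options <- function(kernel_half_width_ms = 12,
                             unit_kernel_mode = c("literal", "strict"),
                             leakage_min_separation_um = 150,
                             max_lag_ms = 500) {
  unit_kernel_mode <- match.arg(unit_kernel_mode)
  pop_hw <- if (unit_kernel_mode == "strict")
    kernel_half_width_ms / sqrt(2) else kernel_half_width_ms
  list(kernel_half_width_ms = kernel_half_width_ms,
       unit_kernel_mode = unit_kernel_mode,
       unit_half_width_ms = kernel_half_width_ms / sqrt(2),
       population_half_width_ms = pop_hw,
       leakage_min_separation_um = leakage_min_separation_um,
       max_lag_ms = max_lag_ms)
}

#' Spike-normalised cross-correlation
#'
#' `R_xy[k] = (1/||x||) * sum_n (x[n+k] - xbar) (y[n] - ybar)` with
#' out-of-range indices contributing zero; `||x||` is the unit's spike count
#' in the analysed window, supplied by the caller.
#'
#' @param x,y equal-length numeric signals (smoothed 1 ms series).
#' @param max_lag largest lag in bins; lags run `-max_lag..max_lag`.
#' @param spike_norm the normaliser `||x||`; 0 flags the result undefined
#'   (silent unit).
#' @return List of class `cross_correlation` with `lags`, `values`,
#'   `spike_norm`, `undefined`.
#' @export
cross_correlation <- function(x, y, max_lag = 500, spike_norm) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  xc <- x - mean(x); yc <- y - mean(y)
  lags <- seq(-max_lag, max_lag)
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(xc[(1 + k):n] * yc[1:(n - k)])
    else sum(xc[1:(n + k)] * yc[(1 - k):n])
  }, numeric(1))
  undefined <- spike_norm == 0
  structure(list(lags = lags,
                 values = if (undefined) rep(NA_real_, length(lags))
                          else vals / spike_norm,
                 spike_norm = spike_norm, undefined = undefined),
            class = "cross_correlation")
}

#' Raw population coupling at lag zero
#'
#' `C[0] = (1/||x||) * sum (x - xbar)(y - ybar)`.
#'
#' @inheritParams cross_correlation
#' @return Scalar `C[0]`; `NA` (with a warning) when `spike_norm` is 0.
#' @export
coupling_at_zero <- function(x, y, spike_norm) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (spike_norm == 0) {
    warning("spike_norm is zero: coupling undefined for a silent unit")
    return(NA_real_)
  }
  sum((x - mean(x)) * (y - mean(y))) / spike_norm
}

#' Normalised population coupling (Pearson correlation)
#'
#' The correlation-normalised coupling
#' `sum (x - xbar)(y - ybar) / sqrt(sum (x - xbar)^2 * sum (y - ybar)^2)`,
#' bounded in `[-1, 1]` and therefore the only version a Fisher z-transform
#' applies to.
#'
#' @param x,y equal-length numeric signals.
#' @return Scalar in `[-1, 1]`; `NA` (with a warning) when either signal has
#'   zero variance.
#' @export
normalized_coupling <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) {
    warning("zero variance: normalised coupling undefined")
    return(NA_real_)
  }
  sum(xc * yc) / sqrt(sxx * syy)
}

#' Fisher z-transform of a coupling coefficient
#'
#' @param c_norm correlation in (-1, 1); `NA` passes through.
#' @return `atanh(c_norm)`.
#' @export
fisher_z <- function(c_norm) {
  if (is.na(c_norm)) return(NA_real_)
  if (abs(c_norm) >= 1)
    stop("|C_norm| >= 1: Fisher z undefined for degenerate perfect correlation")
  atanh(c_norm)
}

new_coupling_result <- function(unit_id, window, condition, C0, C_norm, Z,
                                n_samples, spike_norm, leakage_mode) {
  structure(list(unit_id = unit_id, window = window, condition = condition,
                 C0 = C0, C_norm = C_norm, Z = Z, n_samples = n_samples,
                 spike_norm = spike_norm, leakage_mode = leakage_mode),
            class = "coupling_result")
}

#' Population coupling of session units
#'
#' For each requested single unit and each trial of the condition, resolves
#' the window, bins the unit train and its population rate (all other
#' included contacts) at 1 ms, smooths both (population sigma 12 ms, unit
#' sigma 12/sqrt(2) ms by default) and mean-subtracts per trial segment.
#' Cross-products are then accumulated across segments -- trials are
#' concatenated without smoothing across boundaries -- giving raw `C[0]`
#' (spike-count normalised), `C_norm` (Pearson) and `Z = atanh(C_norm)`.
#'
#' Population rates are computed once per contact and trial, so requesting
#' many units is no slower than requesting one.
#'
#' @param session a `spike_session`.
#' @param unit_ids single-unit ids (default: every single unit).
#' @param window an [analysis_window()] (default cue-to-dimming).
#' @param condition attention condition, or `NULL` to pool all trials.
#' @param options a [coupling_options()] list.
#' @return Named list of `coupling_result` objects, one per unit.
#' @export
session_population_coupling <- function(session, unit_ids = NULL,
                                        window = NULL, condition = NULL,
                                        options = coupling_options()) {
  if (is.null(window))
    window <- analysis_window("cue_to_dimming", session$monkey_profile)
  if (is.null(unit_ids))
    unit_ids <- vapply(Filter(function(tr) tr$kind == "single_unit",
                              session$spike_trains), `[[`, character(1),
                       "unit_id")
  trials <- session_trials(session, condition)
  if (!nrow(trials)) stop("no trials in the requested condition")
  units <- lapply(unit_ids, function(id) get_unit(session, id))
  keep_sets <- lapply(units, function(u)
    included_channels(session$n_channels, u$channel_index,
                      session$probe_spacing_um,
                      options$leakage_min_separation_um))
  if (any(!lengths(keep_sets))) stop("no channels remain for some unit")

  acc <- lapply(unit_ids, function(id)
    list(Sxy = 0, Sxx = 0, Syy = 0, nsp = 0, N = 0L))
  names(acc) <- unit_ids

  for (i in seq_len(nrow(trials))) {
    iv <- resolve_window(window, trials[i, ])
    counts <- channel_count_matrix(session, iv, 1)
    pooled_cache <- new.env(parent = emptyenv())
    for (k in seq_along(unit_ids)) {
      u <- units[[k]]
      key <- paste(keep_sets[[k]], collapse = ",")
      y <- if (exists(key, envir = pooled_cache, inherits = FALSE))
        get(key, envir = pooled_cache)
      else {
        pooled <- colSums(counts[keep_sets[[k]] + 1L, , drop = FALSE])
        sm <- as.numeric(gaussian_smooth(pooled,
                                         options$population_half_width_ms, 1,
                                         mean_subtract = TRUE))
        assign(key, sm, envir = pooled_cache)
        sm
      }
      xb <- bin_spikes(u$spike_times, iv, 1)
      nsp <- sum(xb)
      x <- as.numeric(gaussian_smooth(xb, options$unit_half_width_ms, 1,
                                      mean_subtract = TRUE))
      a <- acc[[u$unit_id]]
      a$Sxy <- a$Sxy + sum(x * y)
      a$Sxx <- a$Sxx + sum(x^2)
      a$Syy <- a$Syy + sum(y^2)
      a$nsp <- a$nsp + nsp
      a$N <- a$N + length(x)
      acc[[u$unit_id]] <- a
    }
  }

  out <- lapply(unit_ids, function(id) {
    a <- acc[[id]]
    C0 <- if (a$nsp > 0) a$Sxy / a$nsp else NA_real_
    C_norm <- if (a$Sxx > 0 && a$Syy > 0) a$Sxy / sqrt(a$Sxx * a$Syy)
              else NA_real_
    Z <- if (!is.na(C_norm) && abs(C_norm) < 1) atanh(C_norm) else NA_real_
    new_coupling_result(id, window$name,
                        if (is.null(condition)) "pooled" else condition,
                        C0, C_norm, Z, a$N, a$nsp,
                        options$leakage_min_separation_um)
  })
  names(out) <- unit_ids
  out
}

#' Population coupling of a single unit
#'
#' Convenience wrapper around [session_population_coupling()].
#'
#' @inheritParams session_population_coupling
#' @param unit_id the unit.
#' @return A `coupling_result`.
#' @export
unit_population_coupling <- function(session, unit_id, window = NULL,
                                     condition = NULL,
                                     options = coupling_options()) {
  session_population_coupling(session, unit_id, window, condition,
                              options)[[1L]]
}

#' Tabulate coupling results
#' @param results list of `coupling_result` objects.
#' @return data.frame with one row per unit.
#' @export
coupling_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(unit_id = r$unit_id, window = r$window, condition = r$condition,
               C0 = r$C0, C_norm = r$C_norm, Z = r$Z, n_samples = r$n_samples,
               spike_norm = r$spike_norm, leakage_mode = r$leakage_mode,
               stringsAsFactors = FALSE)))
}
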