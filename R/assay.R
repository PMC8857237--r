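# Droplet-freezing assay: cumulative INP spectra and detection calls.
#
# An assay table is a long data frame with one row per (strain, replicate,
# dilution, temperature): columns strain, replicate, dilution_factor,
# cfu_per_drop, temperature_c, n_drops, frozen. `frozen` is the cumulative
# number of frozen droplets at or above temperature_c (a frozen droplet
# stays frozen as the ramp cools), so it is non-decreasing as the
# temperature decreases within a series.

#' Cumulative ice-nucleating particles per CFU
#'
#' Converts droplet counts from one dilution of a droplet-freezing assay into
#' the cumulative INP concentration per colony-forming unit,
#' \eqn{K(\Theta) = [\ln N_0 - \ln N(\Theta)] / A}, where \eqn{N_0} is the
#' number of droplets tested, \eqn{N(\Theta)} the number still unfrozen at
#' temperature \eqn{\Theta}, and \eqn{A} the mean CFU per droplet.
#'
#' When every droplet has frozen, \eqn{\ln N(\Theta)} is undefined; the point
#' is then reported as a lower bound obtained by substituting
#' \eqn{N(\Theta) = 0.5}, and flagged `censored = TRUE`.
#'
#' @param n0 Integer vector, droplets tested per series (\eqn{N_0}).
#' @param n_unfrozen Integer vector, unfrozen droplets at the temperature of
#'   interest (\eqn{N(\Theta)}); `n0 - frozen`.
#' @param a Positive numeric vector, CFU per droplet (\eqn{A}).
#' @return A data frame with columns `k` (INP per CFU) and `censored`.
#' @examples
#' cumulative_inp_per_cfu(30, 15, 1e6)  # ln(2)/1e6
#' @export
cumulative_inp_per_cfu <- function(n0, n_unfrozen, a) {
  n <- max(length(n0), length(n_unfrozen), length(a))
  n0 <- rep_len(as.numeric(n0), n)
  n_unfrozen <- rep_len(as.numeric(n_unfrozen), n)
  a <- rep_len(as.numeric(a), n)
  if (any(!is.finite(n0)) || any(n0 < 1)) {
    stop("`n0` must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("`a` (CFU per droplet) must be positive", call. = FALSE)
  }
  if (any(n_unfrozen < 0) || any(n_unfrozen > n0)) {
    stop("`n_unfrozen` must lie in [0, n0]", call. = FALSE)
  }
  censored <- n_unfrozen == 0
  n_eff <- ifelse(censored, 0.5, n_unfrozen)
  data.frame(k = (log(n0) - log(n_eff)) / a, censored = censored)
}

validate_assay <- function(assay) {
  required <- c("strain", "replicate", "dilution_factor", "cfu_per_drop",
                "temperature_c", "n_drops", "frozen")
  missing <- setdiff(required, names(assay))
  if (length(missing) > 0) {
    stop("assay table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(assay) == 0) stop("assay table is empty", call. = FALSE)
  if (any(assay$frozen < 0) || any(assay$frozen > assay$n_drops)) {
    stop("frozen counts must lie in [0, n_drops]", call. = FALSE)
  }
  if (any(assay$cfu_per_drop <= 0)) {
    stop("cfu_per_drop must be positive", call. = FALSE)
  }
  # cumulative-frozen invariant within each physical series
  key <- interaction(assay$strain, assay$replicate, assay$dilution_factor,
                     drop = TRUE)
  for (k in levels(key)) {
    sub <- assay[key == k, ]
    sub <- sub[order(-sub$temperature_c), ]
    if (is.unsorted(sub$frozen)) {
      stop("frozen counts must be non-decreasing as temperature decreases ",
           "(series ", k, ")", call. = FALSE)
    }
  }
  invisible(assay)
}

#' Estimate a freezing spectrum from a dilution-series assay
#'
#' Pools replicate series of each dilution by summing droplet and frozen
#' counts, computes \eqn{K(\Theta)} per dilution with
#' [cumulative_inp_per_cfu()], and combines dilutions per temperature.
#' A dilution is *informative* at a temperature when some but not all of its
#' pooled droplets are frozen; only informative dilutions enter the combined
#' estimate. With `combine = "weighted"` (default) the per-dilution estimates
#' are averaged with pooled droplet number as weight; `"most_dilute"` keeps
#' the single informative dilution with the largest dilution factor.
#'
#' Temperatures with no informative dilution are reported as `k_per_cfu = 0`
#' when no droplet froze anywhere, and otherwise as a censored lower bound
#' (the largest all-frozen bound across dilutions). The finished spectrum is
#' forced non-decreasing along the cooling ramp with a running maximum, since
#' the switch of informative dilutions between adjacent temperatures can
#' otherwise produce small dips that a cumulative quantity cannot have.
#'
#' @param assay Assay data frame for a single strain (see package overview).
#' @param combine `"weighted"` or `"most_dilute"`.
#' @return A `freezing_spectrum` data frame: `strain`, `temperature_c`
#'   (decreasing), `k_per_cfu`, `censored`, `n_series_used`.
#' @export
spectrum_from_assay <- function(assay, combine = c("weighted", "most_dilute")) {
  combine <- match.arg(combine)
  validate_assay(assay)
  if (length(unique(assay$strain)) != 1) {
    stop("spectrum_from_assay() expects a single strain; got: ",
         paste(unique(assay$strain), collapse = ", "), call. = FALSE)
  }
  grids <- tapply(assay$temperature_c,
                  interaction(assay$replicate, assay$dilution_factor,
                              drop = TRUE),
                  function(x) paste(sort(x), collapse = ","))
  if (length(unique(grids)) != 1) {
    stop("all series must share one temperature grid", call. = FALSE)
  }
  temps <- sort(unique(assay$temperature_c), decreasing = TRUE)

  k_out <- numeric(length(temps))
  cens_out <- logical(length(temps))
  nser_out <- integer(length(temps))
  for (i in seq_along(temps)) {
    at <- assay[assay$temperature_c == temps[i], ]
    # pool replicates within dilution
    n0 <- tapply(at$n_drops, at$dilution_factor, sum)
    fr <- tapply(at$frozen, at$dilution_factor, sum)
    a <- tapply(at$cfu_per_drop, at$dilution_factor, function(x) {
      if (length(unique(x)) != 1) {
        stop("cfu_per_drop must be constant within a dilution", call. = FALSE)
      }
      x[1]
    })
    dil <- as.numeric(names(n0))
    informative <- fr > 0 & fr < n0
    if (any(informative)) {
      kk <- cumulative_inp_per_cfu(n0[informative], (n0 - fr)[informative],
                                   a[informative])$k
      if (combine == "weighted") {
        w <- n0[informative]
        k_out[i] <- sum(w * kk) / sum(w)
        nser_out[i] <- sum(informative)
      } else {
        pick <- which.max(dil[informative])
        k_out[i] <- kk[pick]
        nser_out[i] <- 1L
      }
    } else if (any(fr > 0)) {
      # every dilution either fully frozen or fully unfrozen: lower bound
      # from the sharpest (most dilute) all-frozen series
      full <- fr == n0
      bounds <- cumulative_inp_per_cfu(n0[full], 0, a[full])$k
      k_out[i] <- max(bounds)
      cens_out[i] <- TRUE
      nser_out[i] <- 0L
    } # else all counts zero: K = 0, uncensored
  }
  k_out <- cummax(k_out)
  structure(
    data.frame(strain = assay$strain[1], temperature_c = temps,
               k_per_cfu = k_out, censored = cens_out,
               n_series_used = nser_out),
    class = c("freezing_spectrum", "data.frame")
  )
}

#' @export
print.freezing_spectrum <- function(x, ...) {
  cat("Freezing spectrum for", x$strain[1], "--",
      nrow(x), "temperatures,",
      sum(x$censored), "censored\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a freezing spectrum
#'
#' Log-scale cumulative INP per CFU against the cooling ramp; censored points
#' (lower bounds) are drawn as open triangles.
#'
#' @param x A `freezing_spectrum`.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.freezing_spectrum <- function(x, ...) {
  pos <- x$k_per_cfu > 0
  plot(x$temperature_c[pos], x$k_per_cfu[pos], log = "y",
       xlim = rev(range(x$temperature_c)),
       xlab = "Temperature (°C)", ylab = "cumulative INP per CFU",
       pch = ifelse(x$censored[pos], 2, 19), type = "b", ...)
  invisible(x)
}

pool_by_temperature <- function(assay) {
  n0 <- tapply(assay$n_drops, assay$temperature_c, sum)
  fr <- tapply(assay$frozen, assay$temperature_c, sum)
  data.frame(temperature_c = as.numeric(names(n0)),
             n_drops = as.vector(n0), frozen = as.vector(fr))
}

one_sided_exact_test <- function(frozen1, total1, frozen0, total0) {
  stats::fisher.test(matrix(c(frozen1, total1 - frozen1,
                              frozen0, total0 - frozen0), nrow = 2),
                     alternative = "greater")$p.value
}

#' Call ice-nucleation activity against a control
#'
#' Declares a sample INA-positive when, at any shared temperature, its pooled
#' frozen fraction exceeds the control's by a one-sided exact test
#' (Fisher's exact test on the 2x2 frozen/unfrozen table) at level `alpha`.
#'
#' @param sample,control Assay data frames (replicates and dilutions are
#'   pooled per temperature before testing).
#' @param alpha One-sided significance level; default 0.05.
#' @return Logical scalar; attribute `"tests"` holds the per-temperature
#'   table of counts and p-values, and `"alpha"` records the level used.
#' @export
ina_detectable <- function(sample, control, alpha = 0.05) {
  validate_assay(sample)
  validate_assay(control)
  ps <- pool_by_temperature(sample)
  pc <- pool_by_temperature(control)
  shared <- intersect(ps$temperature_c, pc$temperature_c)
  if (length(shared) == 0) {
    stop("sample and control share no temperatures", call. = FALSE)
  }
  ps <- ps[match(shared, ps$temperature_c), ]
  pc <- pc[match(shared, pc$temperature_c), ]
  pv <- mapply(one_sided_exact_test, ps$frozen, ps$n_drops,
               pc$frozen, pc$n_drops)
  out <- any(pv < alpha)
  attr(out, "tests") <- data.frame(
    temperature_c = shared,
    sample_frozen = ps$frozen, sample_total = ps$n_drops,
    control_frozen = pc$frozen, control_total = pc$n_drops,
    p_value = pv)
  attr(out, "alpha") <- alpha
  out
}

#' Per-fraction INA detection for gradient ultracentrifugation profiles
#'
#' Tests each gradient fraction's frozen/total droplet counts, at one fixed
#' assay temperature, against a blank with the same one-sided exact rule as
#' [ina_detectable()].
#'
#' @param frozen,total Integer vectors, one entry per fraction (fraction ids
#'   are `seq_along(frozen)` unless `fraction_ids` is given).
#' @param blank_frozen,blank_total Counts for the blank (e.g. buffer-only
#'   droplets).
#' @param alpha One-sided level; default 0.05.
#' @param fraction_ids Optional fraction labels.
#' @return A `fraction_profile` data frame with columns `fraction`, `frozen`,
#'   `total`, `p_value`, `detectable`; attribute `"detectable"` is the vector
#'   of detectable fraction ids.
#' @export
fraction_profile <- function(frozen, total, blank_frozen, blank_total,
                             alpha = 0.05, fraction_ids = seq_along(frozen)) {
  if (length(total) == 1) total <- rep(total, length(frozen))
  stopifnot(length(frozen) == length(total),
            length(frozen) >= 1, length(frozen) <= 12)
  if (any(total < 1) || any(frozen < 0) || any(frozen > total)) {
    stop("need 0 <= frozen <= total and total >= 1", call. = FALSE)
  }
  pv <- mapply(one_sided_exact_test, frozen, total,
               MoreArgs = list(frozen0 = blank_frozen, total0 = blank_total))
  out <- structure(
    data.frame(fraction = fraction_ids, frozen = frozen, total = total,
               p_value = pv, detectable = pv < alpha),
    class = c("fraction_profile", "data.frame"))
  attr(out, "detectable") <- fraction_ids[pv < alpha]
  attr(out, "alpha") <- alpha
  out
}
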