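#' Summarize negative-control well areas
#'
#' Negative controls (PBS plus red blood cells, no lectin) define the
#' reference distribution of pellet areas against which sample wells are
#' judged. A well is later called positive when its area exceeds the
#' negative mean by more than `n_sd` standard deviations (default 3). The
#' standard deviation is the sample estimate (n - 1 denominator). Because
#' pellet areas drift with red-blood-cell age, controls must come from the
#' same run as the samples; there is deliberately no way to reuse a stored
#' threshold across runs.
#'
#' @param neg_areas Numeric vector of negative-control well areas (mm^2),
#'   at least 2 values, all non-negative.
#' @param n_sd Multiplier on the standard deviation (default 3).
#' @return An object of class `negative_control_stats` with fields
#'   `mean_area_mm2`, `sd_area_mm2`, `threshold_area_mm2`
#'   (`mean + n_sd * sd`), `n_wells`, `n_sd`.
#' @examples
#' negative_stats(c(1.0, 3.0)) # threshold = 2 + 3 * sqrt(2)
#' @export
negative_stats <- function(neg_areas, n_sd = 3) {
  if (!is.numeric(neg_areas) || length(neg_areas) < 2L)
    stop("insufficient negative controls: at least 2 negative-control wells are required per run",
         call. = FALSE)
  if (any(!is.finite(neg_areas)) || any(neg_areas < 0))
    stop("negative-control areas must be finite and >= 0", call. = FALSE)
  m <- mean(neg_areas)
  s <- stats::sd(neg_areas)
  structure(
    list(mean_area_mm2 = m, sd_area_mm2 = s,
         threshold_area_mm2 = m + n_sd * s,
         n_wells = length(neg_areas), n_sd = n_sd),
    class = "negative_control_stats")
}

#' @export
print.negative_control_stats <- function(x, ...) {
  cat(sprintf("negative controls (n = %d): mean %.4g mm^2, sd %.4g, positivity threshold %.4g mm^2 (mean + %g SD)\n",
              x$n_wells, x$mean_area_mm2, x$sd_area_mm2,
              x$threshold_area_mm2, x$n_sd))
  invisible(x)
}

#' Call the hemagglutination endpoint of one dilution series
#'
#' Wells are classified positive when their thresholded area strictly
#' exceeds the negative-control threshold (mean + 3 SD). The endpoint is
#' the last positive well: the rightmost supra-threshold well in the series;
#' the first negative well is the one after it. Any sub-threshold well
#' *before* the last positive well is the low-dilution edge-effect artifact
#' (the agglutinated mat rolled into small polygons, deceptively shrinking
#' its thresholded area); such wells are flagged in `artifact_wells` and can
#' never move the endpoint. The titer in hemagglutination units is
#' `dilution_factor^(last_positive - 1)`.
#'
#' A series spanning two physical plates is concatenated by well index
#' before calling; this function is agnostic to plate boundaries.
#'
#' @param areas Numeric vector of well areas (mm^2) ordered by dilution step
#'   (well 1 = least dilute), length >= 2.
#' @param stats A [negative_stats()] result from the same run.
#' @param dilution_factor Per-step dilution factor (default 2).
#' @return An object of class `endpoint_call`: `positivity` (logical per
#'   well), `artifact_wells` (integer indices), `last_positive` /
#'   `first_negative` (1-based index or `NA`), `hau` (numeric titer, `NA`
#'   when the series is entirely negative, in which case `censored` is
#'   `TRUE` and the titer is reported as below 1), `threshold_area_mm2`,
#'   `dilution_factor`.
#' @examples
#' st <- negative_stats(c(2, 2.1, 1.9, 2))
#' call_endpoint(c(12, 11, 10, 9, 2, 2), st)
#' @export
call_endpoint <- function(areas, stats, dilution_factor = 2) {
  stopifnot(inherits(stats, "negative_control_stats"))
  if (!is.numeric(areas) || length(areas) < 2L)
    stop("a dilution series needs at least 2 wells", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("well areas must be finite and >= 0", call. = FALSE)
  if (!is.numeric(dilution_factor) || dilution_factor <= 1)
    stop("`dilution_factor` must be > 1", call. = FALSE)
  thr <- stats$threshold_area_mm2
  pos <- areas > thr  # strict: a tie with the threshold calls negative
  n <- length(areas)
  if (!any(pos)) {
    last_pos <- NA_integer_
    first_neg <- 1L
    artifacts <- integer(0)
    hau <- NA_real_
    censored <- TRUE
  } else {
    last_pos <- max(which(pos))
    first_neg <- if (last_pos < n) last_pos + 1L else NA_integer_
    artifacts <- which(!pos & seq_len(n) < last_pos)
    hau <- dilution_factor^(last_pos - 1L)
    censored <- FALSE
  }
  structure(
    list(positivity = pos, artifact_wells = artifacts,
         last_positive = last_pos, first_negative = first_neg,
         hau = hau, censored = censored,
         threshold_area_mm2 = thr, dilution_factor = dilution_factor),
    class = "endpoint_call")
}

#' @export
print.endpoint_call <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("endpoint: negative series, HAU < %g (no well above %.4g mm^2)\n",
                x$dilution_factor^0, x$threshold_area_mm2))
  } else {
    cat(sprintf("endpoint: last positive well %d%s, HAU %g\n",
                x$last_positive,
                if (is.na(x$first_negative)) " (series fully positive)"
                else sprintf(", first negative well %d", x$first_negative),
                x$hau))
    if (length(x$artifact_wells))
      cat(sprintf("  edge-effect artifact wells ignored: %s\n",
                  paste(x$artifact_wells, collapse = ", ")))
  }
  invisible(x)
}

#' Check the positive control against its expected endpoint
#'
#' A run is acceptable only when the positive-control series ends where it
#' is known to end; a shifted control endpoint is the basis for repeating
#' the analysis.
#'
#' @param call An [call_endpoint()] result for the positive-control row.
#' @param expected_last_positive Expected 1-based last positive well.
#' @param tolerance_wells Allowed absolute deviation in wells (default 0).
#' @return An object of class `qc_result`: `pass` (logical), `observed`,
#'   `expected`, `reason`.
#' @export
qc_positive_control <- function(call, expected_last_positive,
                                tolerance_wells = 0L) {
  stopifnot(inherits(call, "endpoint_call"))
  if (!is.numeric(expected_last_positive) || expected_last_positive < 1)
    stop("`expected_last_positive` must be a well index >= 1", call. = FALSE)
  if (is.na(call$last_positive)) {
    res <- list(pass = FALSE, observed = NA_integer_,
                expected = as.integer(expected_last_positive),
                reason = "positive control has no positive wells")
  } else {
    ok <- abs(call$last_positive - expected_last_positive) <= tolerance_wells
    res <- list(pass = ok, observed = call$last_positive,
                expected = as.integer(expected_last_positive),
                reason = if (ok) "within tolerance"
                else sprintf("last positive well %d differs from expected %d by more than %d",
                             call$last_positive,
                             as.integer(expected_last_positive),
                             as.integer(tolerance_wells)))
  }
  structure(res, class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("positive-control QC: %s (%s)\n",
              if (x$pass) "PASS" else "FAIL", x$reason))
  invisible(x)
}
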