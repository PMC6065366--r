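#' Normalize a FRAP trace
#'
#' Two-step normalization of a fluorescence-recovery-after-photobleaching
#' trace. Acquisition photobleaching is first corrected by dividing by the
#' reference-region intensity rescaled to its own prebleach mean (skipped
#' when no `reference` column is present). The corrected trace is then
#' full-scale normalized, anchored at the first post-bleach point:
#' f(t) = (I(t) - I(0+)) / (I_pre - I(0+)), so f(0) = 0 and complete
#' recovery approaches 1.
#'
#' @param trace data.frame with columns `time` (s, bleach at 0; prebleach
#'   samples at negative times) and `intensity`, optionally `reference`.
#' @return A `frap_trace` data.frame with normalized `intensity`; prebleach
#'   rows are retained (normalized to ~1).
#' @export
normalize_trace <- function(trace) {
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  pre <- trace$time < 0
  if (sum(pre) < 1) stop("trace has no prebleach samples (time < 0)")
  intens <- trace$intensity
  if ("reference" %in% names(trace)) {
    ref <- trace$reference / mean(trace$reference[pre])
    intens <- intens / ref
  }
  i_pre <- mean(intens[pre])
  post <- which(!pre)
  i0 <- intens[post[1]]
  if (i_pre <= i0) stop("no bleach detected: prebleach mean <= first post-bleach point")
  out <- trace
  out$intensity <- (intens - i0) / (i_pre - i0)
  class(out) <- c("frap_trace", "data.frame")
  attr(out, "normalized") <- TRUE
  out
}

#' Fit single-exponential FRAP recovery
#'
#' Nonlinear least-squares fit of the post-bleach samples of a normalized
#' trace to f(t) = A * (1 - exp(-t / tau)). Initial values: A0 = last
#' observed value, tau0 = first time the trace exceeds 0.63 * A0 (falling
#' back to half the trace duration). A residual RMS above 0.1 flags the fit
#' as low confidence.
#'
#' @param trace Normalized `frap_trace` (see [normalize_trace()]); only rows
#'   with `time >= 0` are fit. At least 5 post-bleach points are required.
#' @return An object of class `frap_fit`: list with `A`, `tau` (s), `rms`,
#'   `low_confidence`, `n`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  post <- trace[trace$time >= 0, ]
  if (nrow(post) < 5) stop("need at least 5 post-bleach points")
  if (stats::sd(post$intensity) == 0 || max(post$intensity) <= 0)
    stop("FRAP fit did not converge: no recovery signal in trace")
  a0 <- tail(post$intensity, 1)
  if (!is.finite(a0) || a0 <= 0) a0 <- max(post$intensity, 0.1)
  idx <- which(post$intensity >= 0.63 * a0)
  tau0 <- if (length(idx) > 0 && post$time[idx[1]] > 0) post$time[idx[1]]
          else max(post$time) / 2
  fit <- try(minpack.lm::nlsLM(
    intensity ~ A * (1 - exp(-time / tau)), data = post,
    start = list(A = a0, tau = tau0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                         ftol = 1e-10)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("FRAP fit did not converge: ", attr(fit, "condition")$message)
  cf <- coef(fit)
  if (cf[["tau"]] <= 0) stop("FRAP fit produced non-positive tau")
  resid <- post$intensity - cf[["A"]] * (1 - exp(-post$time / cf[["tau"]]))
  rms <- sqrt(mean(resid^2))
  structure(list(A = unname(cf[["A"]]), tau = unname(cf[["tau"]]),
                 rms = rms, low_confidence = rms > 0.1 || cf[["A"]] > 1.2,
                 n = nrow(post)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: A = %.4g, tau = %.4g s, RMS = %.3g%s\n",
              x$A, x$tau, x$rms,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Diffusion coefficient from FRAP recovery timescale
#'
#' The half-bleach-spot approximation D = r^2 / tau, valid for partial
#' bleaching of a circular spot well inside a much larger droplet (droplet
#' diameter about 10x the bleach radius). For whole-droplet bleaching (e.g.
#' in cells) the recovery is exchange-limited and this conversion is not
#' interpretable; set `whole_droplet = TRUE` to have the value flagged.
#'
#' @param tau Recovery timescale, s, > 0.
#' @param r Bleach-spot radius, um, > 0 (typically 1.5-2 um).
#' @param whole_droplet Flag whole-droplet bleaching.
#' @return D in um^2/s, with attribute `interpretable = FALSE` when
#'   `whole_droplet` is set.
#' @export
diffusion_coefficient <- function(tau, r, whole_droplet = FALSE) {
  if (any(tau <= 0)) stop("tau must be > 0")
  if (any(r <= 0)) stop("bleach radius must be > 0")
  d <- r^2 / tau
  if (whole_droplet) attr(d, "interpretable") <- FALSE
  d
}
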