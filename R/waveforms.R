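#' Synthetic periodic inlet flow waveform
#'
#' Generates a physiological-looking pulsatile volume-flow waveform: a
#' systolic peak of `peak_ratio * mean_q`, an optional early-diastolic
#' reverse lobe, and small seeded zero-mean residual harmonics.  The sample
#' mean is exactly `mean_q` and the sample maximum exactly
#' `peak_ratio * mean_q`; the waveform is smooth and periodic when wrapped.
#' The generator is pure: identical arguments (including the seed) yield
#' bit-identical output.
#'
#' @param period Cardiac period (s), default 1.0.
#' @param mean_q Mean volumetric flow over one period (m^3/s); default
#'   5 L/min at the ascending-aorta inlet.
#' @param peak_ratio Systolic peak flow divided by mean flow (>= 1).
#' @param reverse_fraction Depth of the early-diastolic reverse lobe as a
#'   fraction of the systolic lobe amplitude, in `[0, 0.2)`.
#' @param n_samples Number of phase samples in `[0, period)`; at least 16.
#' @param seed Integer seed for the residual harmonics.
#'
#' @return An object of class `flow_waveform` with fields `period`, `times`,
#'   `q` and `mean_q`.
#' @examples
#' wf <- make_inlet_waveform(seed = 1)
#' max(wf$q) / mean(wf$q)   # = peak_ratio
#' @export
make_inlet_waveform <- function(period = 1.0, mean_q = 5 / 60000,
                                peak_ratio = 4, reverse_fraction = 0.05,
                                n_samples = 400, seed = 1) {
  if (period <= 0) stop("period must be positive")
  if (mean_q <= 0) stop("mean_q must be positive")
  if (peak_ratio < 1) stop("peak_ratio must be >= 1")
  if (reverse_fraction < 0 || reverse_fraction >= 0.2)
    stop("reverse_fraction must lie in [0, 0.2)")
  if (n_samples < 16) stop("n_samples must be at least 16")

  phi <- seq(0, 1, length.out = n_samples + 1)[seq_len(n_samples)]
  times <- phi * period

  # periodic (wrapped) Gaussian lobe centred at c with width w
  lobe <- function(centre, w) {
    d <- phi - centre
    d <- d - round(d)            # wrap to [-0.5, 0.5)
    exp(-(d / w)^2)
  }
  shape <- lobe(0.22, 0.08) - reverse_fraction * lobe(0.42, 0.05)

  # seeded zero-mean residual harmonics (1% of mean), deterministic per seed
  rng <- .hx_rng(seed)
  harm <- rep(0, n_samples)
  for (k in 3:6) {
    amp <- 0.01 * (0.5 + rng())
    pha <- 2 * pi * rng()
    harm <- harm + amp * sin(2 * pi * k * phi + pha)
  }
  dev <- shape + harm
  dev <- dev - mean(dev)
  # scale so max(q)/mean(q) = peak_ratio exactly at the sample points
  beta <- if (max(dev) > 0) (peak_ratio - 1) * mean_q / max(dev) else 0
  q <- mean_q + beta * dev

  structure(list(period = period, times = times, q = q, mean_q = mean(q)),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "flow_waveform: period %.3g s, %d samples, mean %.4g m^3/s (%.2f L/min), peak/mean %.3f\n",
    x$period, length(x$times), x$mean_q, x$mean_q * 60000,
    max(x$q) / x$mean_q))
  invisible(x)
}

# tiny deterministic LCG so waveform generation never touches .Random.seed
.hx_rng <- function(seed) {
  state <- as.numeric(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

#' Scale a waveform by the descending-aorta flow fraction
#'
#' The aortic-arch branches divert part of the inlet flow; the descending
#' aorta carries the remaining fraction.  The branch split is represented as
#' a single scalar: the flow samples are scaled pointwise, the period is
#' unchanged.
#'
#' @param waveform A [make_inlet_waveform()] object.
#' @param fraction Fraction of inlet flow reaching the descending aorta,
#'   in `(0, 1]`.
#' @return A `flow_waveform` with `q` and `mean_q` scaled.
#' @export
descending_fraction <- function(waveform, fraction) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a scalar in (0, 1]")
  waveform$q <- waveform$q * fraction
  waveform$mean_q <- waveform$mean_q * fraction
  waveform
}

#' Evaluate a waveform at arbitrary times (periodic linear interpolation)
#' @param waveform A `flow_waveform`.
#' @param t Times (s); wrapped into the period.
#' @return Flow values (m^3/s) at `t`.
#' @export
waveform_at <- function(waveform, t) {
  p <- waveform$period
  tt <- t %% p
  xs <- c(waveform$times, p)
  qs <- c(waveform$q, waveform$q[1])
  stats::approx(xs, qs, xout = tt, rule = 2)$y
}

#' Write / read a flow waveform as CSV plus JSON sidecar
#'
#' The CSV holds two columns `time_s, q_m3s`; the sidecar (same path with
#' `.json` appended) records the period, the mean flow, and provenance.
#'
#' @param waveform A `flow_waveform`.
#' @param path CSV file path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns the reconstructed `flow_waveform`.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  utils::write.csv(data.frame(time_s = waveform$times, q_m3s = waveform$q),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(period_s = waveform$period, mean_q_m3s = waveform$mean_q,
         n_samples = length(waveform$times), generator = "hemotherm"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(period = meta$period_s, times = d$time_s, q = d$q_m3s,
                 mean_q = mean(d$q_m3s)),
            class = "flow_waveform")
}
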