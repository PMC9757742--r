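#' Climatic niche axes
#'
#' A niche axis is an asymmetric, bell-shaped local-extinction-probability
#' curve over one climate variable (temperature or precipitation), built from
#' two logistic tails calibrated on the monthly values a species experienced
#' over its calibration window. By construction the extinction probability
#' equals `1 - p_thresh` (default 0.05) exactly at the most extreme values
#' recorded in the calibration samples (`v_min`, `v_max`), and is close to
#' zero at the sample mean `x_mean`.
#'
#' Convention: the curve returns the probability of LOCAL EXTINCTION, so
#' survival probability is `1 - p`. The persistence filter used elsewhere
#' (`p < 0.05`) follows the same convention.
#'
#' @name niche_axis
NULL

# Tail-fit termination tolerances: right logistic evaluated at x_mean must be
# <= RIGHT_TOL; left logistic (survival form) at x_mean must be >= 1 - LEFT_TOL.
.RIGHT_TOL <- 0.001
.LEFT_TOL <- 0.0002

new_niche_axis <- function(x_mean, v_min, v_max, a, b, c, d,
                           p_thresh = 0.95, degenerate = FALSE) {
  structure(
    list(x_mean = x_mean, v_min = v_min, v_max = v_max,
         a = a, b = b, c = c, d = d,
         p_thresh = p_thresh, degenerate = degenerate),
    class = "niche_axis")
}

#' @export
print.niche_axis <- function(x, ...) {
  cat(sprintf(
    "<niche_axis> x_mean=%.4g  [v_min=%.4g, v_max=%.4g]  a=%.4g c=%.4g%s\n",
    x$x_mean, x$v_min, x$v_max, x$a, x$c,
    if (x$degenerate) "  (degenerate: zero-width tolerance)" else ""))
  invisible(x)
}

#' Fit a niche axis to calibration samples
#'
#' Computes `x_mean`, `v_min`, `v_max` from the samples and calibrates the
#' two logistic tails. The right tail starts at `a = 1e-4` with
#' `b = (log(p_thresh / (1 - p_thresh)) + a * v_max) / a`, which pins the
#' extinction probability at `v_max` to `1 - p_thresh`; `a` is then
#' incremented by `step` (with `b` recomputed from the closed form at every
#' increment) until the right logistic evaluated at `x_mean` drops to
#' `<= 0.001`. The left tail is calibrated analogously from `c`, `d` and
#' `v_min`, iterating until the survival form at `x_mean` reaches
#' `>= 0.9998`.
#'
#' Constant samples (`v_min == v_max`) produce a degenerate, zero-width axis
#' flagged as such: the closed forms still pin the extinction probability to
#' `1 - p_thresh` exactly at that value, but no iteration is possible.
#'
#' @param samples numeric vector of monthly climate values (non-empty, finite).
#' @param p_thresh survival probability at the tolerance edges, in (0.5, 1).
#' @param step increment applied to `a` and `c` at each iteration.
#' @param max_iter hard cap on iterations; exceeded caps raise an error.
#' @return a `niche_axis` object.
#' @export
fit_axis <- function(samples, p_thresh = 0.95, step = 0.01, max_iter = 1e6) {
  if (length(samples) == 0) stop("`samples` must be non-empty")
  if (!all(is.finite(samples))) stop("`samples` must all be finite")
  if (!(p_thresh > 0.5 && p_thresh < 1)) stop("`p_thresh` must be in (0.5, 1)")
  fit_axis_params(mean(samples), min(samples), max(samples),
                  p_thresh = p_thresh, step = step, max_iter = max_iter)
}

#' Fit a niche axis from its summary statistics
#'
#' Same calibration as [fit_axis()] but starting from `x_mean`, `v_min`,
#' `v_max` directly (used when re-deriving a shifted niche, where the raw
#' samples no longer exist).
#'
#' @inheritParams fit_axis
#' @param x_mean,v_min,v_max axis summary statistics, `v_min <= x_mean <= v_max`.
#' @return a `niche_axis` object.
#' @export
fit_axis_params <- function(x_mean, v_min, v_max, p_thresh = 0.95,
                            step = 0.01, max_iter = 1e6) {
  if (!(v_min <= x_mean && x_mean <= v_max))
    stop("need v_min <= x_mean <= v_max")
  logit_p <- log(p_thresh / (1 - p_thresh))

  if (v_max - v_min <= .Machine$double.eps * max(1, abs(v_max))) {
    a <- 1e-4
    c <- 1e-4
    return(new_niche_axis(x_mean, v_min, v_max,
                          a = a, b = (logit_p + a * v_max) / a,
                          c = c, d = (-logit_p + c * v_min) / c,
                          p_thresh = p_thresh, degenerate = TRUE))
  }

  # right tail: extinction probability 1/(1+exp(-a(x-b)))
  a <- 1e-4
  b <- (logit_p + a * v_max) / a
  iter <- 0L
  while (stats::plogis(a * (x_mean - b)) > .RIGHT_TOL) {
    iter <- iter + 1L
    if (iter > max_iter) stop("right-tail calibration exceeded `max_iter`")
    a <- a + step
    b <- (logit_p + a * v_max) / a
  }

  # left tail: survival form 1/(1+exp(-c(x-d))), extinction is its complement
  c <- 1e-4
  d <- (-logit_p + c * v_min) / c
  iter <- 0L
  while (stats::plogis(c * (x_mean - d)) < 1 - .LEFT_TOL) {
    iter <- iter + 1L
    if (iter > max_iter) stop("left-tail calibration exceeded `max_iter`")
    c <- c + step
    d <- (-logit_p + c * v_min) / c
  }

  new_niche_axis(x_mean, v_min, v_max, a = a, b = b, c = c, d = d,
                 p_thresh = p_thresh, degenerate = FALSE)
}

#' Local extinction probability along one niche axis
#'
#' Evaluates the fitted curve at climate value(s) `x`:
#' `p = 1 - 1/(1 + exp(-c (x - d)))` for `x <= x_mean` (left tail) and
#' `p = 1/(1 + exp(-a (x - b)))` otherwise. Extrapolation beyond
#' `[v_min, v_max]` is allowed; `p` saturates towards 1 far outside the
#' tolerance range.
#'
#' @param axis a `niche_axis`.
#' @param x numeric vector of climate values.
#' @return extinction probabilities in `[0, 1]`, same length as `x`.
#' @export
axis_extinction_prob <- function(axis, x) {
  stopifnot(inherits(axis, "niche_axis"))
  ifelse(x <= axis$x_mean,
         1 - stats::plogis(axis$c * (x - axis$d)),
         stats::plogis(axis$a * (x - axis$b)))
}

#' Combined (bidimensional) extinction probability
#'
#' The two axes define a bidimensional niche: at any combination of
#' temperature and precipitation the survival probability is the minimum of
#' the two axis survival probabilities, i.e. the extinction probability is
#' the maximum of the two axis extinction probabilities.
#'
#' @param species a `virtual_species` (or any list with `niche_T`, `niche_P`).
#' @param temperature,precipitation climate values (vectors recycle).
#' @return extinction probabilities in `[0, 1]`.
#' @export
combined_extinction_prob <- function(species, temperature, precipitation) {
  pmax(axis_extinction_prob(species$niche_T, temperature),
       axis_extinction_prob(species$niche_P, precipitation))
}

#' Shift a species' niche towards local climate (adaptation)
#'
#' Moves the joint niche center (the pair of axis means, a point in the
#' temperature x precipitation plane) and both tolerance edges of each axis
#' along the segment from the current center to the local mean conditions,
#' by a length `C_adp * A * d_N`, where `A` is the species' adaptive
#' capacity and `d_N` the distance between center and local means computed
#' with each axis standardized by its world-wide standard deviation (so
#' degrees Celsius and millimetres are commensurable). Because the shift
#' length is proportional to `d_N`, the move is a fraction `C_adp * A` of
#' the remaining distance on every axis; the whole axis (center and both
#' edges) translates rigidly and the logistic parameters are re-derived by
#' the same calibration as [fit_axis_params()].
#'
#' @param species a `virtual_species`.
#' @param local_mean_T,local_mean_P local mean conditions to adapt towards.
#' @param C_adp overall adaptation factor (default 0.01).
#' @param sd_T,sd_P world-wide standard deviations used to standardize the
#'   two axes before measuring `d_N`.
#' @return the species with both niche axes shifted and refitted.
#' @export
shift_niche <- function(species, local_mean_T, local_mean_P, C_adp = 0.01,
                        sd_T = 1, sd_P = 1) {
  stopifnot(C_adp >= 0, species$adaptive_capacity >= 0,
            species$adaptive_capacity <= 1)
  frac <- C_adp * species$adaptive_capacity
  dT <- local_mean_T - species$niche_T$x_mean
  dP <- local_mean_P - species$niche_P$x_mean
  d_N <- sqrt((dT / sd_T)^2 + (dP / sd_P)^2)
  if (d_N == 0 || frac == 0) return(species)

  shift_one <- function(axis, delta) {
    fit_axis_params(axis$x_mean + delta, axis$v_min + delta,
                    axis$v_max + delta, p_thresh = axis$p_thresh)
  }
  species$niche_T <- shift_one(species$niche_T, frac * dT)
  species$niche_P <- shift_one(species$niche_P, frac * dP)
  species
}

# ---- vectorized parameter-matrix evaluation (used by the world simulator) ----

# Column layout of a niche parameter matrix (one row per species, both axes).
.NICHE_COLS <- c("T_xmean", "T_vmin", "T_vmax", "T_a", "T_b", "T_c", "T_d",
                 "P_xmean", "P_vmin", "P_vmax", "P_a", "P_b", "P_c", "P_d")

# Extinction probability for many species at one (T, P) condition.
# `np` is a matrix with the .NICHE_COLS columns; returns a vector.
ext_prob_matrix <- function(np, x_T, x_P) {
  pT <- stats::plogis(np[, "T_a"] * (x_T - np[, "T_b"]))
  left <- x_T <= np[, "T_xmean"]
  if (any(left))
    pT[left] <- 1 - stats::plogis(np[left, "T_c"] * (x_T - np[left, "T_d"]))
  pP <- stats::plogis(np[, "P_a"] * (x_P - np[, "P_b"]))
  left <- x_P <= np[, "P_xmean"]
  if (any(left))
    pP[left] <- 1 - stats::plogis(np[left, "P_c"] * (x_P - np[left, "P_d"]))
  pmax(pT, pP)
}

# Max combined extinction probability over a window of monthly (T, P) values,
# for many species at once. `x_T`, `x_P` are vectors over months.
max_ext_prob_matrix <- function(np, x_T, x_P) {
  out <- rep(0, nrow(np))
  for (m in seq_along(x_T)) {
    out <- pmax(out, ext_prob_matrix(np, x_T[m], x_P[m]))
  }
  out
}

axis_to_row <- function(axis, prefix) {
  v <- c(axis$x_mean, axis$v_min, axis$v_max, axis$a, axis$b, axis$c, axis$d)
  names(v) <- paste0(prefix, c("_xmean", "_vmin", "_vmax", "_a", "_b", "_c", "_d"))
  v
}

row_to_axis <- function(row, prefix, p_thresh = 0.95) {
  g <- function(s) unname(row[paste0(prefix, s)])
  new_niche_axis(g("_xmean"), g("_vmin"), g("_vmax"),
                 a = g("_a"), b = g("_b"), c = g("_c"), d = g("_d"),
                 p_thresh = p_thresh,
                 degenerate = g("_vmax") - g("_vmin") <=
                   .Machine$double.eps * max(1, abs(g("_vmax"))))
}
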