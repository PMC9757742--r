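#' Land-use change response
#'
#' Habitat loss translates into local diversity loss through a one-parameter
#' family of response curves. With `R_1 = 1 - |S_LUC|` and
#' `R_2 = sign(S_LUC)` the loss is `1 - (1 - P_LUC)^R_1` when `R_2 = -1` and
#' `P_LUC^R_1` otherwise; at `S_LUC = 0` both branches reduce to the linear
#' (identity) response used by default. `S_LUC = 1` means full diversity
#' loss even with negligible habitat loss; `S_LUC = -1` means diversity is
#' invariant even to full habitat loss. A second parameter `V_LUC` relaxes
#' the body-size bias of which species are lost.
#'
#' @name landuse_response
NULL

#' Fraction of local diversity lost to habitat loss
#'
#' @param P_LUC fraction of primary + secondary land lost this step relative
#'   to the previous step, in `[0, 1]`.
#' @param S_LUC response-curve shape in `[-1, 1]` (0 = linear).
#' @return fraction of local diversity lost, in `[0, 1]`.
#' @export
loss_fraction <- function(P_LUC, S_LUC = 0) {
  if (any(P_LUC < 0 | P_LUC > 1)) stop("P_LUC must be in [0, 1]")
  stopifnot(S_LUC >= -1, S_LUC <= 1)
  R1 <- 1 - abs(S_LUC)
  if (S_LUC < 0) 1 - (1 - P_LUC)^R1 else P_LUC^R1
}

#' Select which species die to land-use change
#'
#' Species are sorted by decreasing body mass, the ordering is perturbed by
#' `floor(V_LUC * S)` random transpositions, and the first `n_loss` entries
#' of the perturbed list are returned. With `V_LUC = 0` the largest species
#' always die; increasing `V_LUC` moves the selection towards random.
#'
#' @param ids species ids (length `S`).
#' @param body_mass masses parallel to `ids`.
#' @param n_loss number of casualties, `0 <= n_loss <= S`.
#' @param V_LUC body-size-bias relaxation in `[0, 1]`.
#' @return vector of `n_loss` casualty ids.
#' @export
select_landuse_casualties <- function(ids, body_mass, n_loss, V_LUC = 0) {
  S <- length(ids)
  stopifnot(length(body_mass) == S, n_loss >= 0, n_loss <= S,
            V_LUC >= 0, V_LUC <= 1)
  if (n_loss == 0) return(ids[0])
  ord <- ids[order(-body_mass)]
  n_swaps <- floor(V_LUC * S)
  for (k in seq_len(n_swaps)) {
    ij <- sample.int(S, 2L)
    ord[ij] <- ord[rev(ij)]
  }
  ord[seq_len(n_loss)]
}

#' Integer casualty count from a fractional loss
#'
#' Stochastic rounding of `loss * S`: the integer part is kept and the
#' fractional remainder becomes one extra casualty with probability equal to
#' the remainder, avoiding systematic bias in small communities.
#'
#' @param loss fraction in `[0, 1]`.
#' @param S community size.
#' @return integer in `[0, S]`.
#' @export
loss_count <- function(loss, S) {
  x <- loss * S
  n <- floor(x) + (stats::runif(1) < (x - floor(x)))
  as.integer(min(n, S))
}
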