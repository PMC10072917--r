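# run code under a local RNG state so envelopes are reproducible without
# clobbering the caller's stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# content-based key used to order two panels canonically (independent of
# argument position) when assigning RNG sub-streams
panel_stream_key <- function(panel) {
  paste(nrow(panel),
        format(sum(panel$rate * seq_len(nrow(panel))), digits = 17),
        format(sum(panel$rate^2), digits = 17),
        format(sum(panel$upper - panel$lower), digits = 17))
}

# one perturbed copy of the rate column, consuming nrow(panel) normals.
# Two-piece normal keyed to the asymmetric 95% interval:
#   sd_low = (val - lower)/1.96, sd_high = (upper - val)/1.96,
# draws truncated at 0. The symmetric alternative pools the two half-widths.
perturb_rates <- function(panel, dist = c("two_piece_normal", "normal")) {
  dist <- match.arg(dist)
  z <- stats::rnorm(nrow(panel))
  if (dist == "two_piece_normal") {
    sd_lo <- (panel$rate - panel$lower) / 1.96
    sd_hi <- (panel$upper - panel$rate) / 1.96
    x <- panel$rate + z * ifelse(z < 0, sd_lo, sd_hi)
  } else {
    x <- panel$rate + z * (panel$upper - panel$lower) / 3.92
  }
  pmax(x, 0)
}

#' Draw perturbed panels from the uncertainty intervals
#'
#' Monte-Carlo resampling of the rate surface: every cell is drawn
#' independently from a two-piece normal centred at the point estimate with
#' `sd_low = (val - lower)/1.96` below and `sd_high = (upper - val)/1.96`
#' above (so an asymmetric 95% interval is honoured), truncated at zero.
#' Degenerate intervals (`lower = val = upper`) reproduce the point estimate
#' exactly. Draw streams are deterministic given `seed`.
#'
#' @param panel a [mortality_panel()].
#' @param n_draws number of perturbed panels.
#' @param seed integer seed.
#' @param dist `"two_piece_normal"` (default) or `"normal"`
#'   (`sd = (upper - lower)/3.92`).
#' @return List of `n_draws` mortality panels (bounds carried over from the
#'   input). Intended for inspection at small scale; [mc_envelope()] streams
#'   the same draws without materialising them.
#' @export
sample_rates <- function(panel, n_draws, seed,
                         dist = c("two_piece_normal", "normal")) {
  dist <- match.arg(dist)
  with_local_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      out <- panel
      out$rate <- perturb_rates(panel, dist)
      out
    })
  })
}

#' Monte-Carlo uncertainty envelope of a panel statistic
#'
#' Applies `statistic_fn` to `n_draws` perturbed panels (drawn as in
#' [sample_rates()]) and reports the empirical 2.5th/97.5th percentiles
#' around the point estimate computed on the unperturbed panel.
#'
#' @param statistic_fn function mapping a mortality panel to a finite
#'   scalar.
#' @param panel a [mortality_panel()].
#' @param n_draws number of draws (default 1000).
#' @param seed integer seed.
#' @param dist draw distribution, see [sample_rates()].
#' @param keep_draws retain the draw statistics in the result? Default
#'   `FALSE`.
#' @return Object of class `uncertainty_envelope`: list with `point`,
#'   `lower`, `upper`, `n_draws`, `seed` (and `draws` if kept).
#' @export
mc_envelope <- function(statistic_fn, panel, n_draws = 1000L, seed,
                        dist = c("two_piece_normal", "normal"),
                        keep_draws = FALSE) {
  dist <- match.arg(dist)
  point <- statistic_fn(panel)
  draws <- with_local_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      pert <- panel
      pert$rate <- perturb_rates(panel, dist)
      val <- tryCatch(statistic_fn(pert), error = function(e)
        stop("statistic failed on draw ", i, ": ", conditionMessage(e)))
      if (!is.finite(val)) stop("statistic non-finite on draw ", i)
      val
    }, numeric(1))
  })
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  structure(list(point = point, lower = qs[1L], upper = qs[2L],
                 n_draws = n_draws, seed = seed,
                 draws = if (keep_draws) draws else NULL),
            class = "uncertainty_envelope")
}

#' @export
print.uncertainty_envelope <- function(x, ...) {
  cat("<uncertainty_envelope> ", format(x$point, digits = 4),
      " (", format(x$lower, digits = 4), " to ",
      format(x$upper, digits = 4), "); ", x$n_draws, " draws, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Significance of a difference between two panels' statistics
#'
#' Paired Monte-Carlo comparison: both panels are perturbed `n_draws` times
#' (independent draws, common pairing index) and the per-draw differences
#' `statistic_fn(panel_b) - statistic_fn(panel_a)` are summarised by their
#' `(level/2, 1 - level/2)` percentile interval. The difference is flagged
#' significant when that interval excludes zero.
#'
#' @param statistic_fn function mapping a mortality panel to a finite
#'   scalar.
#' @param panel_a,panel_b mortality panels.
#' @param n_draws number of paired draws (default 1000).
#' @param seed integer seed.
#' @param level two-sided uncertainty level (default 0.05).
#' @param dist draw distribution, see [sample_rates()].
#' @return List with `significant` (logical), `point` (difference of point
#'   estimates, b minus a), `lower`, `upper` (difference percentile
#'   interval), `level`, `n_draws`, `seed`.
#' @export
significant_difference <- function(statistic_fn, panel_a, panel_b,
                                   n_draws = 1000L, seed, level = 0.05,
                                   dist = c("two_piece_normal", "normal")) {
  dist <- match.arg(dist)
  point <- statistic_fn(panel_b) - statistic_fn(panel_a)
  # assign RNG sub-streams by a canonical panel ordering so the significance
  # flag is invariant under swapping panel_a and panel_b
  a_first <- panel_stream_key(panel_a) <= panel_stream_key(panel_b)
  diffs <- with_local_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      if (a_first) {
        ra <- perturb_rates(panel_a, dist)
        rb <- perturb_rates(panel_b, dist)
      } else {
        rb <- perturb_rates(panel_b, dist)
        ra <- perturb_rates(panel_a, dist)
      }
      pa <- panel_a; pa$rate <- ra
      pb <- panel_b; pb$rate <- rb
      va <- tryCatch(statistic_fn(pa), error = function(e)
        stop("statistic failed on draw ", i, " (panel_a): ",
             conditionMessage(e)))
      vb <- tryCatch(statistic_fn(pb), error = function(e)
        stop("statistic failed on draw ", i, " (panel_b): ",
             conditionMessage(e)))
      vb - va
    }, numeric(1))
  })
  qs <- stats::quantile(diffs, c(level / 2, 1 - level / 2), names = FALSE)
  # guard against floating-point ties: differences at rounding-error scale
  # must never exclude zero
  zero_tol <- 1e-12 * max(1, abs(point))
  list(significant = qs[1L] > zero_tol || qs[2L] < -zero_tol,
       point = point, lower = qs[1L], upper = qs[2L],
       level = level, n_draws = n_draws, seed = seed)
}
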