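#' Aggregate a country-level panel to regions
#'
#' Region-level cause-age-specific rates are population-weighted means of
#' the member countries' rates (weights: the age-specific populations);
#' uncertainty bounds are aggregated the same way and populations are
#' summed. Regions become the locations of the returned panel.
#'
#' @param panel a [mortality_panel()] whose `region` column groups its
#'   locations.
#' @return A [mortality_panel()] with one location per region.
#' @export
aggregate_regions <- function(panel) {
  cs <- attr(panel, "cause_scheme"); as_ <- attr(panel, "age_scheme")
  key <- interaction(panel$region, panel$sex, panel$year, panel$age_index,
                     panel$cause, drop = TRUE, sep = "\r")
  wsum <- function(v) tapply(v * panel$population, key, sum)
  psum <- tapply(panel$population, key, sum)
  agg <- do.call(rbind, strsplit(names(psum), "\r", fixed = TRUE))
  df <- data.frame(
    location = agg[, 1L], region = agg[, 1L], sex = agg[, 2L],
    year = as.integer(agg[, 3L]), age_index = as.integer(agg[, 4L]),
    cause = agg[, 5L],
    rate = as.numeric(wsum(panel$rate) / psum),
    lower = as.numeric(wsum(panel$lower) / psum),
    upper = as.numeric(wsum(panel$upper) / psum),
    population = as.numeric(psum),
    stringsAsFactors = FALSE)
  mortality_panel(df, cs, as_)
}

# F of a single-slice panel (location/sex/year unique), via the life-table
# pipeline; used as the statistic handed to the Monte-Carlo machinery
slice_F_statistic <- function(age_scheme, cause_scheme, infant_ax = TRUE) {
  function(panel) {
    mxc <- matrix(0, age_scheme$n_groups, cause_scheme$k)
    mxc[cbind(panel$age_index, match(panel$cause, cause_scheme$causes))] <-
      panel$rate
    f_index_from_rates(mxc, age_scheme, infant_ax = infant_ax)
  }
}

# materialize one slice as a standalone panel (for the MC machinery)
subset_slice <- function(panel, location, sex, year) {
  out <- panel[panel$location == location & panel$sex == sex &
                 panel$year == year, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Levels table: F by region, sex and year with uncertainty and change
#'
#' For each (region, sex) the fractionalization index is computed through
#' the life-table pipeline at the two analysis years, with Monte-Carlo
#' 95% envelopes, the 1990-to-2019-style difference, and a flag for whether
#' that difference is statistically significant at the given level.
#'
#' @param panel a [mortality_panel()] (country level; aggregated to regions
#'   internally unless `aggregate = FALSE`).
#' @param years length-2 vector of distinct analysis years.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed integer seed.
#' @param level significance level for the change flag (default 0.05).
#' @param aggregate aggregate countries to regions first? Default `TRUE`.
#' @param infant_ax passed to the life-table construction.
#' @return data.frame with one row per (region, sex, year): columns
#'   `region`, `sex`, `year`, `F`, `lower`, `upper`, and on each later-year
#'   row `diff` (F at the later year minus F at the earlier) and
#'   `significant`.
#' @export
run_levels <- function(panel, years = c(1990L, 2019L), n_draws = 1000L,
                       seed = 1L, level = 0.05, aggregate = TRUE,
                       infant_ax = TRUE) {
  if (length(years) != 2L || years[1L] == years[2L])
    stop("`years` must be two distinct analysis years")
  years <- sort(as.integer(years))
  reg_panel <- if (aggregate) aggregate_regions(panel) else panel
  cs <- attr(reg_panel, "cause_scheme"); as_ <- attr(reg_panel, "age_scheme")
  stat <- slice_F_statistic(as_, cs, infant_ax)

  combos <- unique(reg_panel[, c("location", "sex")])
  combos <- combos[order(combos$location, combos$sex), ]
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    reg <- combos$location[i]; sx <- combos$sex[i]
    s1 <- subset_slice(reg_panel, reg, sx, years[1L])
    s2 <- subset_slice(reg_panel, reg, sx, years[2L])
    env1 <- mc_envelope(stat, s1, n_draws, seed = seed + 2L * i)
    env2 <- mc_envelope(stat, s2, n_draws, seed = seed + 2L * i + 1L)
    sig <- significant_difference(stat, s1, s2, n_draws,
                                  seed = seed + 2L * i, level = level)
    rows[[i]] <- data.frame(
      region = reg, sex = sx, year = years,
      F = c(env1$point, env2$point),
      lower = c(env1$lower, env2$lower),
      upper = c(env1$upper, env2$upper),
      diff = c(NA_real_, env2$point - env1$point),
      significant = c(NA, sig$significant),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cause x age decomposition of the change in F for every region and sex
#'
#' Runs [decompose_F_change()] between the two analysis years within each
#' (region, sex) stratum of the region-aggregated panel.
#'
#' @inheritParams run_levels
#' @param n_steps Horiuchi integration steps (default 20).
#' @return List with `table` (long data.frame: region, sex, cause,
#'   age_lower, contribution), `by_cause` (wide per-cause marginals with a
#'   `total` column) and `decompositions` (named list of `f_decomposition`
#'   objects keyed `region|sex`).
#' @export
run_decomposition <- function(panel, years = c(1990L, 2019L), n_steps = 20L,
                              aggregate = TRUE, infant_ax = TRUE) {
  if (length(years) != 2L || years[1L] == years[2L])
    stop("`years` must be two distinct analysis years")
  years <- sort(as.integer(years))
  reg_panel <- if (aggregate) aggregate_regions(panel) else panel
  cs <- attr(reg_panel, "cause_scheme"); as_ <- attr(reg_panel, "age_scheme")

  combos <- unique(reg_panel[, c("location", "sex")])
  combos <- combos[order(combos$location, combos$sex), ]
  tabs <- list(); decs <- list(); marg <- list()
  for (i in seq_len(nrow(combos))) {
    reg <- combos$location[i]; sx <- combos$sex[i]
    r1 <- slice_rates(reg_panel, reg, sx, years[1L])
    r2 <- slice_rates(reg_panel, reg, sx, years[2L])
    dec <- decompose_F_change(r1, r2, as_, cs, n_steps = n_steps,
                              infant_ax = infant_ax)
    decs[[paste(reg, sx, sep = "|")]] <- dec
    tabs[[i]] <- decomposition_table(dec, region = reg, sex = sx)
    marg[[i]] <- data.frame(region = reg, sex = sx,
                            t(dec$by_cause), total = dec$total,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, tabs),
       by_cause = do.call(rbind, marg),
       decompositions = decs)
}

#' Country-level association of F with life expectancy and life disparity
#'
#' Computes F, e0 and e-dagger for every (country, sex, analysis year)
#' slice, fits population-weighted LOESS curves of F against each longevity
#' indicator separately per sex and year, and extracts region-level
#' year-ordered trajectories across all years of the panel.
#'
#' @inheritParams run_levels
#' @param span,degree LOESS parameters (defaults 0.75 and 1).
#' @param grid_points evaluation points per curve (default 50).
#' @return List with `points` (country-level indicator table), `curves`
#'   (long data.frame: predictor, sex, year, x, fitted, span, degree) and
#'   `trajectories` (region-level year paths of F, e0, e-dagger).
#' @export
run_association <- function(panel, years = c(1990L, 2019L), span = 0.75,
                            degree = 1L, grid_points = 50L,
                            infant_ax = TRUE) {
  years <- sort(as.integer(unique(years)))
  cs <- attr(panel, "cause_scheme"); as_ <- attr(panel, "age_scheme")

  slice_stats <- function(p) {
    combos <- unique(p[, c("location", "region", "sex", "year")])
    out <- combos
    out$F <- out$e0 <- out$edagger <- out$population <- NA_real_
    for (i in seq_len(nrow(combos))) {
      mxc <- slice_rates(p, combos$location[i], combos$sex[i],
                         combos$year[i])
      sm <- summaries_from_rates(mxc, as_, infant_ax = infant_ax)
      out$F[i] <- sm$F; out$e0[i] <- sm$e0; out$edagger[i] <- sm$edagger
      out$population[i] <- sum(slice_population(p, combos$location[i],
                                                combos$sex[i],
                                                combos$year[i]))
    }
    out
  }

  pts <- slice_stats(panel[panel$year %in% years, , drop = FALSE])
  curves <- list()
  for (sx in unique(pts$sex)) for (yr in years) {
    sub <- pts[pts$sex == sx & pts$year == yr, ]
    if (nrow(sub) < degree + 2L) next
    for (pred in c("e0", "edagger")) {
      cv <- weighted_loess(sub[[pred]], sub$F, sub$population,
                           span = span, degree = degree,
                           grid = seq(min(sub[[pred]]), max(sub[[pred]]),
                                      length.out = grid_points))
      curves[[length(curves) + 1L]] <- data.frame(
        predictor = pred, sex = sx, year = yr, x = cv$x, fitted = cv$fitted,
        span = span, degree = degree, stringsAsFactors = FALSE)
    }
  }

  reg_panel <- aggregate_regions(panel)
  traj_pts <- slice_stats(reg_panel)
  traj <- region_trajectory(traj_pts[, c("region", "sex", "year", "F",
                                         "e0", "edagger")])
  list(points = pts,
       curves = if (length(curves)) do.call(rbind, curves) else
         data.frame(predictor = character(0), sex = character(0),
                    year = integer(0), x = numeric(0), fitted = numeric(0),
                    span = numeric(0), degree = integer(0)),
       trajectories = traj)
}

#' Run the full analysis end to end
#'
#' Orchestrates levels, decomposition and association on a panel (read from
#' CSV or generated from a scenario) and optionally writes the result
#' tables. Configuration may be given as a list or as a YAML file with the
#' same field names.
#'
#' @param config list (or path to a YAML file) with fields: one of `input`
#'   (panel CSV path) or `scenario` (arguments for [scenario_config()]);
#'   optional `years` (two analysis years, default 1990 and 2019),
#'   `n_draws` (default 1000), `seed` (default 1), `n_steps` (default 20),
#'   `loess_span` (default 0.75), `loess_degree` (default 1), `out_dir`
#'   (write CSV tables there when present).
#' @return List with `levels`, `decomposition`, `association` and the
#'   `panel` used, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  years <- as.integer(config$years %||% c(1990L, 2019L))
  n_draws <- as.integer(config$n_draws %||% 1000L)
  seed <- as.integer(config$seed %||% 1L)
  n_steps <- as.integer(config$n_steps %||% 20L)
  span <- as.numeric(config$loess_span %||% 0.75)
  degree <- as.integer(config$loess_degree %||% 1L)

  if (!is.null(config$input)) {
    panel <- read_panel(config$input, gbd_cause_scheme(), gbd_age_scheme())
  } else if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!inherits(sc, "scenario_config"))
      sc <- do.call(scenario_config, as.list(sc))
    panel <- generate_panel(sc)$panel
  } else {
    stop("config needs either `input` (CSV path) or `scenario`")
  }

  message("levels: ", appendLF = FALSE)
  levels <- run_levels(panel, years = years, n_draws = n_draws, seed = seed)
  message(nrow(levels), " rows")
  message("decomposition (n_steps = ", n_steps, "): ", appendLF = FALSE)
  decomp <- run_decomposition(panel, years = years, n_steps = n_steps)
  message(nrow(decomp$table), " rows")
  message("association (span = ", span, ", degree = ", degree, ")")
  assoc <- run_association(panel, years = years, span = span,
                           degree = degree)

  if (!is.null(config$out_dir))
    write_results_tables(list(levels = levels, decomposition = decomp$table,
                              curves = assoc$curves), config$out_dir)
  invisible(list(levels = levels, decomposition = decomp,
                 association = assoc, panel = panel))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
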