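#' Scenario configuration for the synthetic GBD-like panel generator
#'
#' Defines a stylized epidemiological transition on a multi-region world:
#' communicable-cause hazards concentrated at young ages that decline over
#' calendar time, non-communicable hazards rising Gompertz-like with age
#' whose cardiovascular share follows a rise-and-fall trajectory, and
#' age-flat injury hazards with a male excess. Regions are phase-shifted
#' copies of the same transition (more advanced regions are further along),
#' countries within a region jitter around the regional schedule, and
#' populations are drawn log-uniformly so that population weighting is
#' exercised non-trivially.
#'
#' @param n_regions number of regions (default 7).
#' @param countries_per_region countries per region (default 3).
#' @param years analysis years (default 1990:2019).
#' @param age_scheme an [age_scheme()]; default [gbd_age_scheme()].
#' @param cause_scheme a [cause_scheme()]; default [gbd_cause_scheme()]
#'   (21 causes, 3 level-1 groups).
#' @param sexes sex labels (default female, male).
#' @param comm_level communicable hazard scale at transition time zero
#'   (deaths per person-year at birth-age shape value 1).
#' @param ncd_level non-communicable Gompertz scale (hazard at age 0).
#' @param gompertz_slope per-year log-slope of the non-communicable hazard.
#' @param inj_level injury hazard (age-flat, deaths per person-year).
#' @param comm_decline,ncd_decline,inj_decline per-year exponential decline
#'   rates of the three level-1 hazard blocks.
#' @param cvd_peak_year calendar year at which the cardiovascular share of
#'   non-communicable mortality peaks (for a region with zero offset).
#' @param cvd_amplitude peak extra multiplier on the cardiovascular weight
#'   (share hump height).
#' @param cvd_width width (years, Gaussian sd) of the cardiovascular hump.
#' @param injury_sex_multiplier male/female ratio of injury hazards.
#' @param region_offsets per-region phase shifts in years (positive =
#'   further along the transition); default evenly spread over +/- 12 years.
#' @param region_levels per-region overall mortality level multipliers.
#' @param country_jitter lognormal sd of country-specific multipliers.
#' @param uncertainty_width relative half-width of the 95% uncertainty
#'   interval attached to every cell (bounds = value * (1 -/+ width)).
#' @param population_range range of country population sizes (persons),
#'   sampled log-uniformly.
#' @param uniform_causes if `TRUE`, replace cause fractions by 1/k at every
#'   age (all-cause schedule kept), so the true F is (k-1)/k everywhere.
#' @param seed integer seed fixing country multipliers and populations.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_regions = 7L,
                            countries_per_region = 3L,
                            years = 1990:2019,
                            age_scheme = gbd_age_scheme(),
                            cause_scheme = gbd_cause_scheme(),
                            sexes = c("female", "male"),
                            comm_level = 0.06,
                            ncd_level = 9e-5,
                            gompertz_slope = 0.085,
                            inj_level = 5e-4,
                            comm_decline = 0.04,
                            ncd_decline = 0.005,
                            inj_decline = 0.01,
                            cvd_peak_year = 2000,
                            cvd_amplitude = 1.2,
                            cvd_width = 12,
                            injury_sex_multiplier = 2,
                            region_offsets = NULL,
                            region_levels = NULL,
                            country_jitter = 0.15,
                            uncertainty_width = 0.10,
                            population_range = c(1e6, 1e8),
                            uniform_causes = FALSE,
                            seed = 19901L) {
  if (is.null(region_offsets))
    region_offsets <- if (n_regions == 1L) 0 else
      seq(-12, 12, length.out = n_regions)
  if (is.null(region_levels))
    region_levels <- if (n_regions == 1L) 1 else
      seq(1.5, 0.7, length.out = n_regions)
  if (length(region_offsets) != n_regions ||
      length(region_levels) != n_regions)
    stop("region_offsets / region_levels must have one entry per region")
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("`years` must be contiguous")
  cfg <- list(
    n_regions = as.integer(n_regions),
    countries_per_region = as.integer(countries_per_region),
    years = years, age_scheme = age_scheme, cause_scheme = cause_scheme,
    sexes = sexes, comm_level = comm_level, ncd_level = ncd_level,
    gompertz_slope = gompertz_slope, inj_level = inj_level,
    comm_decline = comm_decline, ncd_decline = ncd_decline,
    inj_decline = inj_decline, cvd_peak_year = cvd_peak_year,
    cvd_amplitude = cvd_amplitude, cvd_width = cvd_width,
    injury_sex_multiplier = injury_sex_multiplier,
    region_offsets = region_offsets, region_levels = region_levels,
    country_jitter = country_jitter,
    uncertainty_width = uncertainty_width,
    population_range = population_range,
    uniform_causes = uniform_causes,
    seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$n_regions, " regions x ",
      x$countries_per_region, " countries x ", length(x$sexes),
      " sexes x ", length(x$years), " years (",
      min(x$years), "-", max(x$years), "); ",
      x$age_scheme$n_groups, " age groups x ", x$cause_scheme$k,
      " causes; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# cause-level metadata for the generator: per-cause base weight, age shape
# ("infant" steeply infancy-concentrated, "comm" generally declining with
# age, "gomp" Gompertz, "flat") and whether the cause is the cardiovascular
# hump carrier. Weights are within level-1 group and sum to 1 per group.
generator_cause_table <- function(cause_scheme) {
  cs <- cause_scheme
  lev <- cs$level1[cs$causes]
  groups <- unique(lev)
  if (identical(cs$causes, gbd_cause_scheme()$causes)) {
    shape <- c("comm", "comm", "infant", "infant", "comm", "infant",
               "infant",
               rep("gomp", 11L),
               rep("flat", 3L))
    w <- c(0.06, 0.30, 0.22, 0.12, 0.08, 0.18, 0.04,
           0.22, 0.34, 0.09, 0.06, 0.08, 0.02, 0.02, 0.08, 0.01, 0.02, 0.06,
           0.40, 0.40, 0.20)
    cvd <- cs$causes == "Cardiovascular diseases"
    group_of <- c(rep("comm", 7L), rep("ncd", 11L), rep("inj", 3L))
  } else {
    # generic scheme: spread weights evenly within each group; use the
    # group order to assign blocks comm/ncd/inj cyclically
    blocks <- c("comm", "ncd", "inj")
    group_block <- stats::setNames(blocks[(seq_along(groups) - 1L) %% 3L + 1L],
                                   groups)
    group_of <- unname(group_block[lev])
    shape <- c(comm = "comm", ncd = "gomp", inj = "flat")[group_of]
    w <- stats::ave(rep(1, cs$k), lev, FUN = function(v) v / length(v))
    # first cause of the ncd block carries the share hump
    cvd <- seq_len(cs$k) == match("ncd", group_of)
    cvd[is.na(cvd)] <- FALSE
  }
  data.frame(cause = cs$causes, level1 = unname(lev), block = group_of,
             shape = unname(shape), weight = w, cvd = cvd,
             stringsAsFactors = FALSE)
}

# age shapes evaluated at interval midpoints (open interval: lower + 2.5)
generator_age_shapes <- function(age_scheme, gompertz_slope) {
  mid <- age_scheme$lower + ifelse(is.finite(age_scheme$width),
                                   age_scheme$width / 2, 2.5)
  cbind(infant = exp(-mid / 0.8),
        comm = exp(-mid / 6) + 0.02,
        gomp = exp(gompertz_slope * mid),
        flat = rep(1, length(mid)))
}

# exact cause-by-age rate matrix for one (country, sex, year)
generator_slice_rates <- function(cfg, tab, shapes, level_mult, cause_mult,
                                  region_idx, sex, year) {
  t_eff <- (year - cfg$years[1L]) + cfg$region_offsets[region_idx]
  t_peak <- cfg$cvd_peak_year - cfg$years[1L]
  hump <- 1 + cfg$cvd_amplitude *
    exp(-0.5 * ((t_eff - t_peak) / cfg$cvd_width)^2)

  w <- tab$weight
  w[tab$cvd] <- w[tab$cvd] * hump
  # renormalize within the NCD block so the hump shifts shares, not the
  # block's total hazard
  ncd <- tab$block == "ncd"
  w[ncd] <- w[ncd] / sum(w[ncd]) * sum(tab$weight[ncd])

  block_scale <- c(
    comm = cfg$comm_level * exp(-cfg$comm_decline * t_eff),
    ncd = cfg$ncd_level * exp(-cfg$ncd_decline * t_eff),
    inj = cfg$inj_level * exp(-cfg$inj_decline * t_eff))
  sexmult <- ifelse(tab$block == "inj" & sex == "male",
                    cfg$injury_sex_multiplier, 1)

  colscale <- w * block_scale[tab$block] * sexmult * cause_mult *
    cfg$region_levels[region_idx] * level_mult
  mxc <- shapes[, tab$shape, drop = FALSE] *
    rep(colscale, each = nrow(shapes))
  colnames(mxc) <- tab$cause
  rownames(mxc) <- cfg$age_scheme$labels
  if (cfg$uniform_causes) {
    m_all <- rowSums(mxc)
    mxc <- outer(m_all, rep(1 / cfg$cause_scheme$k, cfg$cause_scheme$k))
    dimnames(mxc) <- list(cfg$age_scheme$labels, cfg$cause_scheme$causes)
  }
  mxc
}

#' Generate a synthetic GBD-like mortality panel with known ground truth
#'
#' Builds the full (location, sex, year, age, cause) grid of the scenario's
#' exact cause-age-specific rates, attaches relative uncertainty bounds
#' `value * (1 -/+ uncertainty_width)`, and returns alongside the panel the
#' exact rates and the noise-free F, e0 and e-dagger of every slice. With
#' `observation_noise = TRUE` the panel's point estimates are drawn around
#' the exact rates with relative standard deviation
#' `uncertainty_width / 1.96` (truncated at zero), emulating estimation
#' error consistent with the stated intervals.
#'
#' @param cfg a [scenario_config()].
#' @param observation_noise perturb the point estimates? Default `FALSE`.
#' @param noise_seed seed for the observation noise (only used when
#'   `observation_noise = TRUE`); default `cfg$seed + 1`.
#' @return List with elements `panel` (a [mortality_panel()]) and `truth`
#'   (list: `rates`, a named list of exact age x cause matrices keyed by
#'   `"location|sex|year"`, and `summaries`, a data.frame of exact
#'   F/e0/e-dagger per slice).
#' @export
generate_panel <- function(cfg, observation_noise = FALSE,
                           noise_seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  as_ <- cfg$age_scheme; cs <- cfg$cause_scheme
  ng <- as_$n_groups; k <- cs$k
  n_c <- cfg$n_regions * cfg$countries_per_region
  regions <- sprintf("region_%02d", seq_len(cfg$n_regions))
  countries <- sprintf("country_%02d_%02d",
                       rep(seq_len(cfg$n_regions),
                           each = cfg$countries_per_region),
                       rep(seq_len(cfg$countries_per_region),
                           times = cfg$n_regions))
  region_of <- rep(seq_len(cfg$n_regions), each = cfg$countries_per_region)

  tab <- generator_cause_table(cs)
  shapes <- generator_age_shapes(as_, cfg$gompertz_slope)

  draws <- with_local_seed(cfg$seed, list(
    level_mult = exp(stats::rnorm(n_c, 0, cfg$country_jitter)),
    cause_mult = matrix(exp(stats::rnorm(n_c * k, 0, cfg$country_jitter)),
                        n_c, k),
    pop = exp(stats::runif(n_c, log(cfg$population_range[1L]),
                           log(cfg$population_range[2L])))))

  # fixed pyramid shape: proportional to exp(-0.03 * midpoint) * width
  mid <- as_$lower + ifelse(is.finite(as_$width), as_$width / 2, 2.5)
  wdt <- ifelse(is.finite(as_$width), as_$width, 5)
  pshare <- exp(-0.03 * mid) * wdt
  pshare <- pshare / sum(pshare)

  n_slices <- n_c * length(cfg$sexes) * length(cfg$years)
  cells <- ng * k
  n_rows <- n_slices * cells
  loc_v <- reg_v <- sex_v <- character(n_rows)
  yr_v <- age_v <- integer(n_rows)
  cause_v <- character(n_rows)
  rate_v <- pop_v <- numeric(n_rows)

  rates <- vector("list", n_slices)
  keys <- character(n_slices)
  summaries <- data.frame(
    location = character(n_slices), region = character(n_slices),
    sex = character(n_slices), year = integer(n_slices),
    F = numeric(n_slices), e0 = numeric(n_slices),
    edagger = numeric(n_slices), stringsAsFactors = FALSE)

  age_idx <- rep(seq_len(ng), times = k)
  cause_lab <- rep(cs$causes, each = ng)
  s <- 0L
  for (ct in seq_len(n_c)) {
    pop_age_sex <- draws$pop[ct] * pshare / length(cfg$sexes)
    for (sx in cfg$sexes) for (yr in cfg$years) {
      s <- s + 1L
      mxc <- generator_slice_rates(cfg, tab, shapes, draws$level_mult[ct],
                                   draws$cause_mult[ct, ], region_of[ct],
                                   sx, yr)
      rates[[s]] <- mxc
      keys[s] <- paste(countries[ct], sx, yr, sep = "|")
      sm <- summaries_from_rates(mxc, as_)
      summaries[s, c("location", "region", "sex")] <-
        c(countries[ct], regions[region_of[ct]], sx)
      summaries$year[s] <- yr
      summaries$F[s] <- sm$F
      summaries$e0[s] <- sm$e0
      summaries$edagger[s] <- sm$edagger

      at <- (s - 1L) * cells + seq_len(cells)
      loc_v[at] <- countries[ct]
      reg_v[at] <- regions[region_of[ct]]
      sex_v[at] <- sx
      yr_v[at] <- yr
      age_v[at] <- age_idx
      cause_v[at] <- cause_lab
      rate_v[at] <- as.vector(mxc)
      pop_v[at] <- pop_age_sex[age_idx]
    }
  }

  val <- rate_v
  if (observation_noise) {
    val <- with_local_seed(noise_seed, {
      pmax(rate_v * (1 + stats::rnorm(n_rows, 0,
                                      cfg$uncertainty_width / 1.96)), 0)
    })
  }
  df <- data.frame(
    location = loc_v, region = reg_v, sex = sex_v, year = yr_v,
    age_index = age_v, cause = cause_v, rate = val,
    lower = val * (1 - cfg$uncertainty_width),
    upper = val * (1 + cfg$uncertainty_width),
    population = pop_v, stringsAsFactors = FALSE)
  panel <- mortality_panel(df, cs, as_)
  list(panel = panel,
       truth = list(rates = stats::setNames(rates, keys),
                    summaries = summaries))
}

#' Generate a null pair: identical truth, independent observation noise
#'
#' Two panels sharing the same exact underlying rates, each with its own
#' independent observation noise (relative sd `uncertainty_width / 1.96`,
#' truncated at zero). With `uncertainty_width = 0` the two panels are
#' identical and noise-free. Supports type-I-error calibration of
#' [significant_difference()].
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed for the two noise draws.
#' @return List with `panel_a`, `panel_b` (mortality panels) and `truth`
#'   (as in [generate_panel()]).
#' @export
generate_null_pair <- function(cfg, seed) {
  base <- generate_panel(cfg, observation_noise = FALSE)
  w <- cfg$uncertainty_width
  noisify <- function(panel) {
    val <- pmax(panel$rate *
                  (1 + stats::rnorm(nrow(panel), 0, w / 1.96)), 0)
    panel$rate <- val
    panel$lower <- val * (1 - w)
    panel$upper <- val * (1 + w)
    panel
  }
  pair <- with_local_seed(seed, list(a = noisify(base$panel),
                                     b = noisify(base$panel)))
  list(panel_a = pair$a, panel_b = pair$b, truth = base$truth)
}
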