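# small schemes and panel builders shared across test files

toy_cause_scheme <- function() {
  cause_scheme(c("infection", "heart disease", "injury"),
               c("communicable", "non-communicable", "injuries"))
}

toy_age_scheme <- function() {
  age_scheme(c(0, 1, 5, 25, 45, 65, 85))
}

# full-grid panel data.frame for arbitrary rate filler
toy_panel_df <- function(locations = "A", sexes = "female", years = 2000L,
                         cs = toy_cause_scheme(), as_ = toy_age_scheme(),
                         rate = 0.01, width = 0.1, population = 1e6,
                         region = NULL) {
  grid <- expand.grid(age_index = seq_len(as_$n_groups), cause = cs$causes,
                      location = locations, sex = sexes, year = years,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  r <- rep_len(rate, n)
  data.frame(location = grid$location,
             region = if (is.null(region)) grid$location else
               rep_len(region, n),
             sex = grid$sex, year = grid$year,
             age_index = grid$age_index, cause = grid$cause,
             rate = r, lower = r * (1 - width), upper = r * (1 + width),
             population = rep_len(population, n),
             stringsAsFactors = FALSE)
}

toy_panel <- function(..., cs = toy_cause_scheme(), as_ = toy_age_scheme()) {
  mortality_panel(toy_panel_df(..., cs = cs, as_ = as_), cs, as_)
}

# random full-grid rate matrix (ages x causes), strictly positive
random_rates <- function(cs = toy_cause_scheme(), as_ = toy_age_scheme()) {
  matrix(stats::runif(as_$n_groups * cs$k, 1e-4, 0.1),
         as_$n_groups, cs$k,
         dimnames = list(as_$labels, cs$causes))
}

# small transition scenario used by the Monte-Carlo calibration suites
calib_scenario <- function(width = 0.08, seed = 11L) {
  scenario_config(n_regions = 1L, countries_per_region = 1L, years = 1990L,
                  sexes = "female", age_scheme = toy_age_scheme(),
                  cause_scheme = cause_scheme(paste0("c", 1:6),
                                              rep(c("g1", "g2", "g3"),
                                                  each = 2)),
                  country_jitter = 0, uncertainty_width = width, seed = seed)
}

# recompute F for a rate matrix through the exported step-by-step API
# (independent of the internal fused statistic used on hot paths)
f_direct <- function(mxc, as_) {
  m <- rowSums(mxc)
  lt <- build_life_table(m, as_)
  frac <- sweep(mxc, 1, ifelse(m > 0, m, 1), "/")
  frac[m == 0, ] <- 0
  p <- cause_proportions_from_lifetable(partition_deaths_by_cause(lt, frac))
  fractionalization(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
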