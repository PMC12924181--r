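#' Closed-form storage trajectories
#'
#' The generator's building blocks. Substrate (fatty-acid) and antioxidant
#' (polyphenol) pools decay exponentially, `C(d) = C0 * exp(-rate * d)`:
#' the simplest monotone model consistent with pseudo-first-order oxidation
#' kinetics. Secondary oxidation volatiles stay at a baseline during the
#' induction lag, grow exponentially through the propagation phase
#' (`C(d) = baseline * exp(growth_rate * (d - lag_day))` for
#' `lag_day < d <= plateau_day`), then drift linearly with
#' `post_plateau_slope`, floored at 0.
#'
#' @param initial initial concentration (> 0), native units.
#' @param rate first-order decay rate, 1/day (>= 0).
#' @param days numeric vector of sampling days.
#' @return concentration vector, same length as `days`.
#' @export
fatty_acid_trajectory <- function(initial, rate, days) {
  stopifnot(initial > 0)
  if (rate < 0) stop("decay rate must be >= 0", call. = FALSE)
  initial * exp(-rate * days)
}

#' @rdname fatty_acid_trajectory
#' @param class polyphenol class label (metadata only; the kinetic form is
#'   shared, class-dependence lives in the profile's rates).
#' @export
polyphenol_trajectory <- function(initial, class, rate, days) {
  stopifnot(class %in% POLYPHENOL_CLASSES)
  fatty_acid_trajectory(initial, rate, days)
}

#' @rdname fatty_acid_trajectory
#' @param baseline pre-propagation concentration (> 0), ppm.
#' @param lag_day last day of the induction lag.
#' @param growth_rate propagation growth rate, 1/day.
#' @param plateau_day day the propagation phase ends; must exceed
#'   `lag_day`.
#' @param post_plateau_slope linear drift (ppm/day) after the plateau.
#' @export
volatile_trajectory <- function(baseline, lag_day, growth_rate, plateau_day,
                                post_plateau_slope = 0, days) {
  stopifnot(baseline > 0, growth_rate >= 0)
  if (plateau_day <= lag_day) {
    stop("plateau_day must exceed lag_day", call. = FALSE)
  }
  peak <- baseline * exp(growth_rate * (plateau_day - lag_day))
  out <- ifelse(
    days <= lag_day,
    baseline,
    ifelse(
      days <= plateau_day,
      baseline * exp(growth_rate * (days - lag_day)),
      pmax(0, peak + post_plateau_slope * (days - plateau_day))
    )
  )
  out
}

#' Solve a first-order rate from an observed decline
#'
#' `rate_from_decline(0.665)` returns the rate at which a pool loses 66.5%
#' of its initial level over `t` days; `rate_from_endpoints()` solves from
#' a printed start/end concentration pair.
#'
#' @param frac fractional decline in (0, 1).
#' @param t elapsed days.
#' @return rate in 1/day.
#' @export
rate_from_decline <- function(frac, t = 168) {
  stopifnot(frac > 0, frac < 1, t > 0)
  -log(1 - frac) / t
}

#' @rdname rate_from_decline
#' @param c0,c1 start and end concentrations, `c0 > c1 > 0`.
#' @export
rate_from_endpoints <- function(c0, c1, t = 168) {
  stopifnot(c0 > 0, c1 > 0, c1 <= c0, t > 0)
  log(c0 / c1) / t
}

#' Construct an oil profile for the synthetic generator
#'
#' A profile fixes, per oil type, the noiseless trajectories of its
#' compounds: fatty acids (mg/g oil), polyphenols (ug/g oil) and
#' volatiles (ppm).
#'
#' @param oil_type one of [OIL_TYPES].
#' @param fatty_acids tibble/data frame with columns `compound`,
#'   `initial` (mg/g), `rate` (1/day).
#' @param polyphenols tibble with `compound`, `class` (a polyphenol class),
#'   `initial` (ug/g), `rate` (1/day).
#' @param volatiles tibble with `compound`, `baseline` (ppm), `lag_day`,
#'   `growth_rate` (1/day), `plateau_day`, `post_plateau_slope` (ppm/day).
#' @return a list of class `"oil_profile"`.
#' @export
oil_profile <- function(oil_type, fatty_acids, polyphenols, volatiles) {
  stopifnot(oil_type %in% OIL_TYPES)
  fatty_acids <- tibble::as_tibble(fatty_acids)
  polyphenols <- tibble::as_tibble(polyphenols)
  volatiles <- tibble::as_tibble(volatiles)
  stopifnot(
    all(fatty_acids$initial > 0), all(fatty_acids$rate >= 0),
    all(polyphenols$initial > 0), all(polyphenols$rate >= 0),
    all(polyphenols$class %in% POLYPHENOL_CLASSES),
    all(volatiles$baseline > 0), all(volatiles$growth_rate >= 0)
  )
  if (sum(fatty_acids$initial) > 1000) {
    stop("fatty-acid initial levels exceed 1000 mg/g oil", call. = FALSE)
  }
  if (any(volatiles$plateau_day <= volatiles$lag_day)) {
    stop("every volatile needs lag_day < plateau_day", call. = FALSE)
  }
  structure(
    list(
      oil_type = oil_type, fatty_acids = fatty_acids,
      polyphenols = polyphenols, volatiles = volatiles
    ),
    class = "oil_profile"
  )
}

#' Default profiles for the six cold-pressed oils
#'
#' Illustrative profiles anchored to typical published day-0 compositions
#' and six-month declines for cold-pressed black cumin (BC), canola (CA),
#' sunflower (SF), high-oleic sunflower (HOSF), linseed (LS) and hempseed
#' (HS) oils: PUFA-rich oils carry the fastest fatty-acid decay, phenolic
#' acids deplete faster than flavonoids and lignans in every profile, and
#' hexanal propagates exponentially between days 14 and 42. These defaults
#' are anchors for simulation, not fitted estimates.
#'
#' @return named list of [oil_profile()] objects.
#' @export
default_oil_profiles <- function() {
  fa <- function(...) tibble::tribble(~compound, ~initial, ~rate, ...)
  pp <- function(...) tibble::tribble(~compound, ~class, ~initial, ~rate, ...)
  vol <- function(...) {
    tibble::tribble(
      ~compound, ~baseline, ~lag_day, ~growth_rate, ~plateau_day,
      ~post_plateau_slope, ...
    )
  }
  r <- rate_from_decline
  re <- rate_from_endpoints

  list(
    BC = oil_profile(
      "BC",
      fa(
        "linoleic acid", 645.0, r(0.665),
        "palmitic acid", 136.0, r(0.08),
        "oleic acid", 100.0, r(0.20),
        "stearic acid", 30.0, r(0.10)
      ),
      pp(
        "p-coumaric acid", "phenolic_acid", 538.2, re(538.2, 13.2),
        "quinic acid", "phenolic_acid", 25.3, re(25.3, 2.42),
        "kaempferol", "flavonoid", 40.0, r(0.55),
        "matairesinol", "lignan", 15.0, r(0.45)
      ),
      vol(
        "hexanal", 0.05, 14, log(1.45 / 0.05) / 98, 112, 0,
        "nonanal", 0.06, 14, log(10.3) / 154, 168, 0,
        "4,5-epoxy-(E)-2-decenal", 0.03, 14, log(13.9) / 154, 168, 0
      )
    ),
    CA = oil_profile(
      "CA",
      fa(
        "oleic acid", 526.0, r(0.282),
        "linoleic acid", 245.5, r(0.615),
        "alpha-linolenic acid", 107.2, r(0.559),
        "palmitic acid", 45.0, r(0.05)
      ),
      pp(
        "sinapic acid", "phenolic_acid", 60.0, r(0.80),
        "ferulic acid", "phenolic_acid", 20.0, r(0.75),
        "herbacetin", "flavone", 19.1, re(19.1, 1.41),
        "ellagic acid", "flavonoid", 12.0, r(0.70)
      ),
      vol(
        "hexanal", 0.06, 14, log(2.13 / 0.06) / 154, 168, 0,
        "2,4-decadienal", 0.04, 14, log(13) / 98, 112, -0.002,
        "2,4-heptadienal", 0.05, 14, log(6) / 98, 112, 0
      )
    ),
    SF = oil_profile(
      "SF",
      fa(
        "linoleic acid", 604.0, r(0.577),
        "oleic acid", 250.0, r(0.25),
        "palmitic acid", 60.0, r(0.05),
        "stearic acid", 35.0, r(0.05)
      ),
      pp(
        "ellagic acid", "phenolic_acid", 16.7, re(16.7, 0.45),
        "quercetin-3-O-glucoside", "flavonoid", 1.39, re(1.39, 0.13),
        "apigenin", "flavone", 8.0, r(0.50)
      ),
      vol(
        "hexanal", 0.10, 14, log(3.9 / 0.10) / 70, 84, -0.03,
        "2,4-decadienal", 0.05, 14, log(13.1) / 98, 112, -0.002,
        "(E)-2-nonenal", 0.04, 14, log(3.7) / 98, 112, 0
      )
    ),
    HOSF = oil_profile(
      "HOSF",
      fa(
        "oleic acid", 789.5, r(0.408),
        "linoleic acid", 70.0, r(0.30),
        "palmitic acid", 40.0, r(0.05),
        "stearic acid", 30.0, r(0.08)
      ),
      pp(
        "ellagic acid", "phenolic_acid", 10.4, re(10.4, 0.47),
        "caffeic acid", "phenolic_acid", 15.0, r(0.85),
        "quinic acid", "phenolic_acid", 12.0, r(0.70),
        "luteolin", "flavone", 6.0, r(0.45)
      ),
      vol(
        "hexanal", 0.05, 14, log(0.96 / 0.05) / 154, 168, 0,
        "decanal", 0.04, 14, log(9) / 70, 84, 0,
        "nonanal", 0.05, 14, log(4.8) / 28, 42, 0.001
      )
    ),
    LS = oil_profile(
      "LS",
      fa(
        "alpha-linolenic acid", 621.0, r(0.558),
        "linoleic acid", 150.0, r(0.536),
        "oleic acid", 170.0, r(0.12),
        "palmitic acid", 50.0, r(0.04)
      ),
      pp(
        "p-coumaric acid", "phenolic_acid", 6.07, re(6.07, 0.53),
        "secoisolariciresinol", "lignan", 30.0, r(0.80),
        "apigenin", "flavone", 25.0, r(0.50)
      ),
      vol(
        "hexanal", 0.08, 14, 0.15, 42, -0.03,
        "2-pentyl-furan", 0.05, 14, log(28.9) / 98, 112, -0.005,
        "2,4-heptadienal", 0.04, 14, log(8) / 98, 112, 0
      )
    ),
    HS = oil_profile(
      "HS",
      fa(
        "linoleic acid", 570.0, r(0.60),
        "alpha-linolenic acid", 209.0, r(0.55),
        "oleic acid", 110.0, r(0.05),
        "palmitic acid", 55.0, r(0.03)
      ),
      pp(
        "p-coumaric acid", "phenolic_acid", 7.2, re(7.2, 0.39),
        "chlorogenic acid", "phenolic_acid", 10.0, r(0.85),
        "kaempferol", "flavonoid", 12.0, r(0.50),
        "secoisolariciresinol", "lignan", 8.0, r(0.45)
      ),
      vol(
        "hexanal", 0.11, 14, 0.14, 42, -0.01,
        "(E)-2-heptenal", 0.03, 14, log(42.7) / 70, 84, 0,
        "2,4-decadienal", 0.04, 14, log(9) / 98, 112, 0
      )
    )
  )
}

#' Noise model for the synthetic generator
#'
#' Noise is multiplicative log-normal on both layers, so concentrations
#' stay positive and coefficients of variation are scale-proportional:
#' one factor per (supplier, compound) pair drawn once (batch effect) and
#' one independent factor per observation (bottle replicate scatter).
#' Values falling below the class LOQ are censored: flagged and removed.
#'
#' @param cv_within coefficient of variation across bottle replicates.
#' @param cv_supplier CV of the supplier (commercial batch) effect.
#' @param loq named per-class censoring thresholds in native units; any
#'   class not named keeps its default (fatty acids 0.5 mg/g, polyphenol
#'   classes 0.5 ug/g, volatiles 0.05 ppm — typical quantification limits
#'   for GC-FID, LC-MS/MS and SPME-GC-MS respectively), so deeply depleted
#'   polyphenols censor late in storage and low-baseline volatiles censor
#'   before the propagation phase.
#' @return a list of class `"noise_model"`.
#' @export
noise_model <- function(cv_within = 0.05, cv_supplier = 0.15, loq = NULL) {
  stopifnot(cv_within >= 0, cv_supplier >= 0)
  defaults <- c(
    fatty_acid = 0.5, volatile = 0.05,
    stats::setNames(rep(0.5, length(POLYPHENOL_CLASSES)), POLYPHENOL_CLASSES)
  )
  if (!is.null(loq)) {
    stopifnot(all(names(loq) %in% COMPOUND_CLASSES), all(loq >= 0))
    defaults[names(loq)] <- loq
  }
  structure(
    list(cv_within = cv_within, cv_supplier = cv_supplier, loq = defaults),
    class = "noise_model"
  )
}

# multiplicative log-normal factors with unit mean and the given CV
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

class_unit <- function(compound_class) {
  ifelse(compound_class == "fatty_acid", "mg/g",
    ifelse(compound_class == "volatile", "ppm", "ug/g")
  )
}

noiseless_profile_trajectories <- function(profile, schedule) {
  parts <- list()
  if (nrow(profile$fatty_acids) > 0) {
    parts$fa <- tibble::tibble(
      compound = rep(profile$fatty_acids$compound, each = length(schedule)),
      compound_class = "fatty_acid",
      day = rep(schedule, nrow(profile$fatty_acids)),
      value = unlist(Map(
        function(i, k) fatty_acid_trajectory(i, k, schedule),
        profile$fatty_acids$initial, profile$fatty_acids$rate
      ), use.names = FALSE)
    )
  }
  if (nrow(profile$polyphenols) > 0) {
    parts$pp <- tibble::tibble(
      compound = rep(profile$polyphenols$compound, each = length(schedule)),
      compound_class = rep(profile$polyphenols$class, each = length(schedule)),
      day = rep(schedule, nrow(profile$polyphenols)),
      value = unlist(Map(
        function(i, cl, k) polyphenol_trajectory(i, cl, k, schedule),
        profile$polyphenols$initial, profile$polyphenols$class,
        profile$polyphenols$rate
      ), use.names = FALSE)
    )
  }
  if (nrow(profile$volatiles) > 0) {
    v <- profile$volatiles
    parts$vol <- tibble::tibble(
      compound = rep(v$compound, each = length(schedule)),
      compound_class = "volatile",
      day = rep(schedule, nrow(v)),
      value = unlist(Map(
        function(b, l, g, p, s) {
          volatile_trajectory(b, l, g, p, s, days = schedule)
        },
        v$baseline, v$lag_day, v$growth_rate, v$plateau_day,
        v$post_plateau_slope
      ), use.names = FALSE)
    )
  }
  dplyr::bind_rows(parts)
}

#' Generate a synthetic storage-study dataset
#'
#' Emulates the standard storage design: each oil type sourced from
#' `n_suppliers` commercial batches with `n_replicates` bottles each
#' (default 3 x 3 = 9 observations per time point), sampled over
#' `schedule`. Each concentration is the profile's noiseless trajectory
#' times a fixed supplier factor (drawn once per supplier-compound pair)
#' times an independent bottle factor; values below the class LOQ are
#' flagged `below_loq` with the value removed. The same seed always
#' yields the identical record set.
#'
#' @param profiles list of [oil_profile()] objects.
#' @param noise a [noise_model()].
#' @param schedule sampling days.
#' @param n_suppliers,n_replicates design counts (>= 1).
#' @param seed integer seed.
#' @return tibble of concentration records (one row per
#'   profile x compound x supplier x replicate x day).
#' @export
generate_storage_dataset <- function(profiles,
                                     noise = noise_model(),
                                     schedule = DEFAULT_SCHEDULE,
                                     n_suppliers = 3L,
                                     n_replicates = 3L,
                                     seed) {
  if (inherits(profiles, "oil_profile")) profiles <- list(profiles)
  stopifnot(
    length(schedule) > 0, n_suppliers >= 1, n_replicates >= 1,
    inherits(noise, "noise_model")
  )
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))

  out <- lapply(profiles, function(profile) {
    traj <- noiseless_profile_trajectories(profile, schedule)
    compounds <- unique(traj$compound)
    supplier_ids <- sprintf("S%d", seq_len(n_suppliers))
    replicate_ids <- sprintf("R%d", seq_len(n_replicates))

    supplier_factor <- matrix(
      lognormal_factors(n_suppliers * length(compounds), noise$cv_supplier),
      nrow = n_suppliers,
      dimnames = list(supplier_ids, compounds)
    )

    grid <- tidyr::expand_grid(
      traj,
      supplier_id = supplier_ids,
      replicate_id = replicate_ids
    )
    value <- grid$value *
      supplier_factor[cbind(grid$supplier_id, grid$compound)] *
      lognormal_factors(nrow(grid), noise$cv_within)

    loq <- noise$loq[grid$compound_class]
    censored <- value < loq
    value[censored] <- NA_real_

    tibble::tibble(
      oil_type = profile$oil_type,
      supplier_id = grid$supplier_id,
      replicate_id = grid$replicate_id,
      day = as.integer(grid$day),
      compound = grid$compound,
      compound_class = grid$compound_class,
      value = value,
      unit = class_unit(grid$compound_class),
      below_loq = censored
    )
  })
  records <- dplyr::bind_rows(out)
  validate_records(records, schedule = NULL)
  records
}
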