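# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# minimal well-formed record set: 2 compounds x 2 days x 1 bottle
tiny_records <- function() {
  tibble::tibble(
    oil_type = "LS",
    supplier_id = "S1",
    replicate_id = "R1",
    day = rep(c(0L, 168L), each = 2),
    compound = rep(c("hexanal", "p-coumaric acid"), 2),
    compound_class = rep(c("volatile", "phenolic_acid"), 2),
    value = c(0.08, 6.07, 5.3, NA),
    unit = rep(c("ppm", "ug/g"), 2),
    below_loq = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# a single-oil profile with one fast-decaying marker among slow/constant
# compounds, used for recovery checks
toy_profile <- function() {
  oil_profile(
    "LS",
    fatty_acids = tibble::tibble(
      compound = c("fast acid", "slow acid", "stable acid"),
      initial = c(500, 300, 100),
      rate = c(0.01, 0.002, 0)
    ),
    polyphenols = tibble::tibble(
      compound = "phenolic marker", class = "phenolic_acid",
      initial = 50, rate = 0.008
    ),
    volatiles = tibble::tibble(
      compound = "hexanal", baseline = 0.08, lag_day = 14,
      growth_rate = 0.15, plateau_day = 42, post_plateau_slope = 0
    )
  )
}

# storage profile with well-separated decay rates in every block, so the
# steepest decliner is identifiable against its class
recovery_profile <- function() {
  oil_profile(
    "LS",
    fatty_acids = tibble::tibble(
      compound = c("steep acid", "mid acid", "slow acid", "stable acid"),
      initial = c(500, 300, 150, 50), rate = c(0.008, 0.002, 5e-4, 0)
    ),
    polyphenols = tibble::tibble(
      compound = c("fast phenolic", "slow flavonoid", "slow lignan"),
      class = c("phenolic_acid", "flavonoid", "lignan"),
      initial = c(100, 50, 30), rate = c(0.012, 0.002, 0.001)
    ),
    volatiles = tibble::tibble(
      compound = c("hexanal", "slow volatile"), baseline = c(0.08, 0.1),
      lag_day = c(14, 14), growth_rate = c(0.15, 0.02),
      plateau_day = c(42, 112), post_plateau_slope = c(0, 0)
    )
  )
}

# z-scored feature block: one monotone-in-day column among pure noise
noisy_block <- function(n_noise = 9, seed = 1, days = rep(DEFAULT_SCHEDULE, 3)) {
  set.seed(seed)
  signal <- 100 * exp(-0.01 * days) * exp(rnorm(length(days), 0, 0.02))
  noise <- matrix(rnorm(length(days) * n_noise),
    ncol = n_noise,
    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))
  )
  x <- cbind(signal = signal, noise)
  list(features = scale(x)[, , drop = FALSE], response = as.numeric(days))
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
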