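# Shared fixtures built in code.

toy_records <- function() {
  as_screening_records(data.frame(
    year = c(2014, 2014, 2014, 2015, 2015),
    direction = c("E", "E", "W", "E", "W"),
    distance_m = c(0.5, 10, 10, 0.5, 10),
    n_screened = c(300, 200, 200, 250, 150),
    n_resistant = c(180, 40, 30, 120, 20)))
}

# Distance-only double-exponential coefficients (the published reference
# level) used when an arm-free kernel is enough.
ref5 <- function() reference_coefficients(full = FALSE)

winner_spec <- function() model_spec(2, "direction:year", "direction:year")
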