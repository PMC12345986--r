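# Independent oracles used across tests.

# central finite difference of the logistic closed form (not growth_rate)
fd_rate <- function(A, B, K, t, h = 1e-4) {
  f <- function(t) A / (1 + B * exp(-K * t))
  (f(t + h) - f(t - h)) / (2 * h)
}

# brute-force Pearson correlation from the defining formula
brute_cor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# noise-free logistic records
exact_records <- function(A, B, K, ages = seq(50, 300, by = 10)) {
  data.frame(animal_id = "a1", breed = "X", age_days = ages,
             weight_kg = A / (1 + B * exp(-K * ages)))
}

yp_params  <- function() logistic_params(160.493, 16.901, 0.022)
qyp_params <- function() logistic_params(137.948, 20.059, 0.016)
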