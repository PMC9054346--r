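# shared fixtures built in code

gt_noiseless <- function(...) {
  ground_truth(F_opt = 300, L_opt = 15, L_slack = 11, noise_sd = 0, ...)
}

# study-condition truth: adult soleus scale, noise 2% of F_opt
gt_study <- function(noise_frac = 0.02) {
  ground_truth(F_opt = 294, L_opt = 15.2, L_slack = 11.1,
               noise_sd = noise_frac * 294)
}

fit_series <- function(series, ...) {
  pts <- length_force_points(series$muscle_length_mm,
                             series$total_force_mN,
                             series$passive_force_mN)
  fit_length_force(pts, ...)
}

# independent polynomial evaluation (plain power sum, not the package's)
poly_eval_for_tests <- function(coefs, x) {
  vapply(x, function(xi) sum(coefs * xi^(seq_along(coefs) - 1)), numeric(1))
}

# trace with two twitches and a tetanus over a given baseline function
passive_protocol_trace <- function(baseline_fun, sampling_hz = 1000) {
  t <- seq(0, 1000, by = 1000 / sampling_hz)
  f <- baseline_fun(t)
  f[t >= 100 & t <= 150] <- f[t >= 100 & t <= 150] + 40  # twitch 1
  f[t >= 300 & t <= 350] <- f[t >= 300 & t <= 350] + 40  # twitch 2
  f[t >= 800] <- f[t >= 800] + 250                       # tetanus
  list(trace = force_trace(t, f),
       events = stim_events(c("twitch", "twitch", "tetanus"),
                            onset_ms = c(100, 300, 800),
                            offset_ms = c(150, 350, 1000),
                            frequency_hz = c(NA, NA, 150)))
}
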