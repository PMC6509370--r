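# shared fixtures: all data are built in code at test time

quick_mcmc <- function(seed = 1L, chains = 2L, iterations = 1000L,
                       burnin = 500L) {
  mcmc_settings(chains = chains, iterations = iterations, burnin = burnin,
                seed = seed)
}

write_temp_csv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  write.csv(df, path, row.names = FALSE)
  path
}

gosling_csv <- function(env = parent.frame()) {
  write_temp_csv(data.frame(
    id = c("a", "b", "c", "d"),
    year = c(1990, 1990, 1991, 1991),
    age_days = c(25, 50, 30, 44),
    mass_g = c(500, 700, 610, 820)), env = env)
}

bout_row <- function(year, group, duration, total, foraging = 0, alert = 0,
                     walking = 0, aggression = 0, resting = 0) {
  data.frame(year = year, group = group, duration_min = duration,
             total_scans = total, foraging = foraging, alert = alert,
             walking = walking, aggression = aggression, resting = resting)
}
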