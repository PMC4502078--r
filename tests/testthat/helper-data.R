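# shared builders for small deterministic respondent data sets

# two respondents rating a 3-design-state task plus anchors
tiny_records <- function() {
  states <- c("21111", "22222", "33333", "11111", "DEAD")
  data.frame(
    respondent_id = rep(c("r1", "r2"), each = length(states)),
    set = "Green",
    state = rep(states, 2),
    vas_raw = c(80, 55, 10, 100, 0,
                60, 45, 20, 90, 10),
    stringsAsFactors = FALSE
  )
}

# a noise-free study: ratings are exactly 100 x latent value
noiseless_config <- function(...) {
  sim_config(noise_sd = 0, heterogeneity_sd = 0,
             full_anchor = c(mean = 100, sd = 0),
             dead_anchor = c(mean = 0, sd = 0),
             round_vas = FALSE, ...)
}

fixture_table <- function() suppressMessages(table2_means())
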