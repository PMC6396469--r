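# Shared fixtures: tiny life tables and fast parameter sets.

# Immortal population (all q5 = 0 except the mandatory terminal band).
immortal_life_table <- function(max_age = 110) {
  x <- seq(0, max_age - 5, by = 5)
  life_table(c(x, max_age), c(x + 5, Inf), c(rep(0, length(x)), 1),
             country = "immortal")
}

# Flat-hazard table: same q5 in every band, with certain death from
# `absorb_age` so traces terminate cleanly before the model's age cap.
flat_life_table <- function(q5 = 0.05, absorb_age = 100) {
  x <- seq(0, absorb_age - 5, by = 5)
  life_table(c(x, absorb_age), c(x + 5, Inf), c(rep(q5, length(x)), 1),
             country = "flat")
}

# Parameters for a short, fast model run (10-year horizon).
fast_params <- function(...) {
  model_params(start_age = 45, max_age = 55, ...)
}

# A disease-free parameter set: no transitions at all.
no_disease_params <- function(...) {
  model_params(p_R_LR = 0, p_R_DR = 0, p_LR_R = 0, p_LR_DR = 0,
               p_DR_BCD = 0, ...)
}
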