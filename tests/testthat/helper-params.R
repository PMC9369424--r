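# Published single-drug potency parameters used as canonical fixtures:
# (emax %MPE, ed50 nmol, hill) with standard errors, per assay.
mech_thc <- function() hill_params(85, 14, 2.6,
                                   se = c(emax = 2, ed50 = 0.8, hill = 0.3),
                                   dof = 45, drug = "THC", assay = "mechanical_pwt")
mech_cbd <- function() hill_params(79, 20, 1.5,
                                   se = c(emax = 2, ed50 = 0.6, hill = 0.1),
                                   dof = 45, drug = "CBD", assay = "mechanical_pwt")
acet_thc <- function() hill_params(52, 21, 1.7,
                                   se = c(emax = 3, ed50 = 3.6, hill = 0.4),
                                   dof = 45, drug = "THC", assay = "acetone")
acet_cbd <- function() hill_params(27, 11, 2.2,
                                   se = c(emax = 1, ed50 = 1.0, hill = 0.4),
                                   dof = 45, drug = "CBD", assay = "acetone")

mech_surface <- function() additive_surface(mech_cbd(), mech_thc())
acet_surface <- function() additive_surface(acet_cbd(), acet_thc())

# noiseless per-animal dose-response table from a Hill truth
noiseless_dr <- function(emax, ed50, hill,
                         doses = c(1, 3.2, 10, 18, 32, 56, 100, 178),
                         n = 2) {
  d <- tibble::tibble(dose = rep(doses, each = n))
  d$effect <- hill_effect(d$dose, emax, ed50, hill)
  d$animal_id <- sprintf("A%02d", seq_len(nrow(d)))
  d
}
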