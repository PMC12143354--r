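# Shared fixtures: the canonical drug list, the screening design, and a
# couple of small constructors used across test files.

std_drugs <- c("H1152", "irosustat", "losartan", "LY294002",
               "SB203580", "SD208", "TM5441", "Y27632")

# 59-run OACD plus the 16 monotherapy runs, as used for fitting
screen_design <- function(drugs = std_drugs) {
  bind_designs(build_oacd(8, drugs = drugs),
               monotherapy_runs(8, drugs = drugs))
}

# A simple reference 4PL curve object without going through fit_4pl
ref_curve <- function(top = 100, ec50 = 1, hill = 1) {
  list(top = top, ec50 = ec50, hill = hill, flat = FALSE)
}
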