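# Generate the synthetic single-cell interval study and write it in the
# study CSV schemas (conditions/intervals; empty upper bound = interval
# still open at the end of the observation window).

source("analysis/00_study_setup.R")

message("simulating lac/ara-promoter study (3 schemes x 6 temperatures) ...")
placlara <- generate_study(placlara_design, schemes = placlara_schemes,
                           temperatures = placlara_temps, seed = study_seed)
write_study(placlara,
            file.path(synthetic_dir, "placlara_conditions.csv"),
            file.path(synthetic_dir, "placlara_intervals.csv"))
print(placlara)

message("simulating tetA-promoter study (2 temperatures) ...")
ptet <- generate_study(ptet_design, schemes = ptet_schemes,
                       temperatures = ptet_temps, seed = study_seed + 1L)
write_study(ptet,
            file.path(synthetic_dir, "ptet_conditions.csv"),
            file.path(synthetic_dir, "ptet_intervals.csv"))
print(ptet)

cens <- function(s) round(100 * mean(!is.finite(s$intervals$ub_s)), 1)
message("right-censored fraction: lac/ara ", cens(placlara),
        "%, tetA ", cens(ptet), "%")
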