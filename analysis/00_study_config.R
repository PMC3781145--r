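# Shared configuration for the synthetic two-stage thyroid-cancer-style
# interaction study driven by the numbered analysis scripts. Sourced, not
# run. Sizes mirror the two series the pipeline is designed around:
# discovery 609 cases / 525 controls, replication 969 / 1040.

library(epistage)

STUDY_SEED <- 20260928L

study_mafs <- local({
  set.seed(STUDY_SEED)
  m <- setNames(runif(50, 0.1, 0.5), sprintf("SNP%03d", 1:50))
  m[c("SNP001", "SNP002")] <- 0.3
  m
})

# purely epistatic pair planted in classic-PTC cases only: carrier-corner
# pattern, cell log-OR 1.2, marginal per-SNP OR exactly 1
planted_pair <- c("SNP001", "SNP002")
planted_model <- pure_epistasis_model(planted_pair, 1.2, "corner", study_mafs)
null_model <- penetrance_model()

make_discovery <- function()
  simulate_case_control(sim_config(
    609, 525, mafs = study_mafs, model = null_model,
    subtype_models = list(cPTC = planted_model),
    seed = STUDY_SEED + 1L))

make_replication <- function()
  simulate_case_control(sim_config(
    969, 1040, mafs = study_mafs, model = null_model,
    subtype_models = list(cPTC = planted_model),
    country_levels = c("ES", "IT"), country_probs = c(0.5, 0.5),
    seed = STUDY_SEED + 2L))

dir.create("results", showWarnings = FALSE)
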