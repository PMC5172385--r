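# Shared setup for the analysis scripts: one seeded synthetic cohort at the
# study scale (5,455 raw -> 3,513 analysed). Sourced by the numbered drivers.
suppressMessages(library(dediffwm))

SEED <- 7L
MEASURES <- c("FA", "MD", "ICVF", "ISOVF", "OD")
dir.create("results", showWarnings = FALSE)

make_cohort <- function() {
  gm <- generating_model()
  exclude_cohort(generate_cohort(gm, 5455, seed = SEED))
}
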