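# Shared settings for the analysis workflow. Source()d by every step.
#
# The study bundle (synthetic, with known ground truth) lives under
# scratch/ -- regenerate it any time with 01_simulate_data.R; the summary
# tables each step derives from it go under results/.

library(fluorisk)

STUDY_SEED <- 20230601          # one master seed for the whole workflow
BUNDLE_DIR <- "scratch/study_bundle"
RESULTS_DIR <- "results"
MC_ITER <- 10000                # iterations, matching the study convention

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

load_bundle <- function() {
  if (!file.exists(file.path(BUNDLE_DIR, "foods.csv"))) {
    stop("no study bundle found; run analysis/01_simulate_data.R first",
         call. = FALSE)
  }
  list(foods = read_foods_csv(file.path(BUNDLE_DIR, "foods.csv")),
       assays = read_assays_csv(file.path(BUNDLE_DIR, "assays.csv")),
       survey = read_intake_survey_csv(file.path(BUNDLE_DIR, "intake_survey.csv")),
       truth = jsonlite::read_json(file.path(BUNDLE_DIR, "ground_truth.json")))
}
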