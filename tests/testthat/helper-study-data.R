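# The deposited study data (subject properties plus timed straight-bout and
# circle trials) is not redistributed with the package; to run the
# data-dependent checks, convert the supplement to the two-CSV schema (see
# README) and point WALKOPT_DATA_DIR at it, or place the files under
# inst/extdata/s1_data/.
real_study_cohort <- function() {
  dir <- Sys.getenv("WALKOPT_DATA_DIR", "")
  if (!nzchar(dir))
    dir <- system.file("extdata", "s1_data", package = "walkopt")
  sp <- file.path(dir, "subjects.csv")
  tp <- file.path(dir, "trials.csv")
  if (!nzchar(dir) || !file.exists(sp) || !file.exists(tp))
    stop("deposited study dataset not available (expected subjects.csv and ",
         "trials.csv under $WALKOPT_DATA_DIR or inst/extdata/s1_data; ",
         "the supplement must be obtained and converted by the user - ",
         "see README)", call. = FALSE)
  read_cohort(sp, tp)
}
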