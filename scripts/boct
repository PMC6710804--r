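#!/usr/bin/env Rscript
# Thin command-line wrapper over the boct package.
#
#   boct simulate  --phantom spec.json --out DIR [--seed N] [--format tiff|json]
#   boct measure   --phantom spec.json --out DIR [--seed N] [--shots N]
#   boct stats precision  --csv measurements.csv --out DIR
#   boct stats agreement  --csv pairs.csv --out DIR
#   boct study repeatability --out DIR [--seed N] [--subjects N] [--observers N] [--replicates N] [--cohort healthy|cataract]
#   boct study agreement     --out DIR [--seed N] [--subjects N] [--cohort healthy|cataract]

suppressMessages({
  library(boct)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[[1]] else ""
sub <- if (cmd %in% c("stats", "study") && length(args) >= 2) args[[2]] else NULL
rest <- args[-seq_len(1 + !is.null(sub))]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--phantom", type = "character", default = NULL),
  make_option("--csv", type = "character", default = NULL),
  make_option("--out", type = "character", default = "boct-out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--shots", type = "integer", default = 10L),
  make_option("--subjects", type = "integer", default = 50L),
  make_option("--observers", type = "integer", default = 2L),
  make_option("--replicates", type = "integer", default = 3L),
  make_option("--cohort", type = "character", default = "healthy"),
  make_option("--format", type = "character", default = "json")
)), args = rest)

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config()
load_phantom <- function() {
  if (is.null(opts$phantom)) build_phantom() else read_phantom_spec(opts$phantom)
}

if (cmd == "simulate") {
  shot <- acquire_measurement(load_phantom(), cfg, seed = opts$seed)
  if (opts$format == "tiff") {
    write_windows_tiff(shot, file.path(opts$out, "windows.tiff"))
  }
  for (o in c("horizontal", "vertical"))
    write_boundary_json(segment_shot(shot, o, cfg),
                        file.path(opts$out, paste0("boundaries_", o, ".json")))
  write_manifest(file.path(opts$out, "manifest.json"), cfg, opts$seed)
} else if (cmd == "measure") {
  res <- measure_biometry(load_phantom(), cfg, n_shots = opts$shots, seed = opts$seed)
  print(res)
  append_biometry_csv(res, file.path(opts$out, "biometry.csv"))
  write_manifest(file.path(opts$out, "manifest.json"), cfg, opts$seed)
} else if (cmd == "stats" && identical(sub, "precision")) {
  study <- read_measurements_csv(opts$csv)
  for (p in unique(study$parameter)) print(precision_report(study, p))
} else if (cmd == "stats" && identical(sub, "agreement")) {
  d <- utils::read.csv(opts$csv)
  for (p in unique(d$parameter)) {
    cat("==", p, "==\n")
    print(bland_altman(d$device_a[d$parameter == p], d$device_b[d$parameter == p]))
  }
} else if (cmd == "study" && identical(sub, "repeatability")) {
  pr <- study_protocol(n_subjects = opts$subjects, observers = opts$observers,
                       replicates = opts$replicates, cohort = opts$cohort,
                       seed = opts$seed)
  run_repeatability_study(pr, cfg, out_dir = opts$out)
  cat("wrote", opts$out, "\n")
} else if (cmd == "study" && identical(sub, "agreement")) {
  pr <- study_protocol(n_subjects = opts$subjects, cohort = opts$cohort,
                       seed = opts$seed)
  run_agreement_study(pr, out_dir = opts$out)
  cat("wrote", opts$out, "\n")
} else {
  cat("usage: boct <simulate|measure|stats precision|stats agreement|study repeatability|study agreement> [options]\n")
  quit(status = if (cmd == "") 0 else 1)
}
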