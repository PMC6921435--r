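#!/usr/bin/env Rscript
# Thin command-line front end over the ecgdelta package.
#
#   Rscript scripts/ecg_pipeline.R simulate --out DIR [--config FILE]
#       [--participants N] [--seed S] [--no-signal]
#   Rscript scripts/ecg_pipeline.R analyze --out DIR
#       (--segments FILE | --ecg-dir DIR) [--quiet]
#
# A config file is flat key = value text mirroring session_config() /
# glucose_effect() fields; command-line flags override it.

suppressMessages(library(ecgdelta))
suppressMessages(library(optparse))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1 || !argv[1] %in% c("simulate", "analyze")) {
  message("usage: ecg_pipeline.R <simulate|analyze> [options]")
  quit(status = 2)
}
cmd <- argv[1]

die <- function(...) { message("error: ", ...); quit(status = 1) }

opts <- list(
  make_option("--out", type = "character", help = "output directory"),
  make_option("--config", type = "character", default = NULL,
              help = "flat key=value config file"),
  make_option("--participants", type = "integer", default = 16),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--no-signal", action = "store_true", default = FALSE,
              dest = "no_signal", help = "write ground truth only"),
  make_option("--segments", type = "character", default = NULL,
              help = "long segment-series CSV input"),
  make_option("--ecg-dir", type = "character", default = NULL,
              dest = "ecg_dir",
              help = "directory of ecg_pNN_G.csv / ecg_pNN_NG.csv files"),
  make_option("--frame-length", type = "integer", default = 256,
              dest = "frame_length", help = "Welch frame length M"),
  make_option("--quiet", action = "store_true", default = FALSE)
)
opt <- parse_args(OptionParser(option_list = opts), args = argv[-1])
if (is.null(opt$out)) die("--out is required")

cfg_file <- if (!is.null(opt$config)) read_config_file(opt$config) else list()
pick <- function(defaults, overrides) {
  keep <- intersect(names(overrides), names(defaults))
  utils::modifyList(defaults, overrides[keep])
}

result <- tryCatch({
  if (cmd == "simulate") {
    cfg_args <- pick(as.list(formals(session_config)), cfg_file)
    cfg_args$random_seed <- opt$seed
    eff_args <- pick(as.list(formals(glucose_effect)), cfg_file)
    t0 <- Sys.time()
    files <- run_simulate(opt$out, n_participants = opt$participants,
                          config = do.call(session_config, cfg_args),
                          effect = do.call(glucose_effect, eff_args),
                          signal = !opt$no_signal)
    if (!opt$quiet)
      message(sprintf("simulate: %d files in %.1f s", nrow(files) * 2,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  } else {
    welch <- welch_config(frame_length = opt$frame_length)
    if (!is.null(opt$segments)) {
      fit <- run_analyze(opt$segments, mode = "segment-series",
                         out_dir = opt$out, welch = welch)
    } else if (!is.null(opt$ecg_dir)) {
      paths <- list.files(opt$ecg_dir, "^ecg_p[0-9]+_(G|NG)\\.csv$",
                          full.names = TRUE)
      if (!length(paths)) die("no ecg_pNN_<session>.csv files in ",
                              opt$ecg_dir)
      m <- regmatches(basename(paths),
                      regexec("^ecg_p([0-9]+)_(G|NG)\\.csv$",
                              basename(paths)))
      layout <- tibble::tibble(
        participant = as.integer(vapply(m, `[`, "", 2)),
        session = vapply(m, `[`, "", 3),
        path = paths)
      fit <- run_analyze(layout, mode = "raw-ecg", out_dir = opt$out,
                         welch = welch)
    } else die("analyze needs --segments or --ecg-dir")
    if (!opt$quiet) print(tidy(fit), n = Inf)
  }
  0L
}, error = function(e) { message("error: ", conditionMessage(e)); 1L })

quit(status = result)
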