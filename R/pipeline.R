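#' Run the full surveillance pipeline on quarter bundles
#'
#' Orchestrates parse -> preprocess -> disproportionality screen ->
#' time-to-onset analysis -> descriptives and writes four delimiter-
#' separated tables plus a provenance log of per-stage case counts. Rerun
#' on identical inputs, the outputs are byte-identical.
#'
#' @param input A `quarter_bundle`, a list of bundles, or a directory path
#'   (passed to [read_quarter()]).
#' @param out_dir Output directory (created if needed).
#' @param target_pts Target preferred-term set (default
#'   [target_pts_hyponatremia()]).
#' @param synonym_map Drug-name synonym map (see [normalize_drug_name()]).
#' @param drug_window Optional per-drug receipt-date window table.
#' @param min_cases Minimum target-event case count for the screen
#'   (default 3).
#' @param level Confidence level (default 0.95).
#' @param top_k Screen rows and TTO drugs to keep (default 50, mirroring a
#'   top-50 reporting convention); `NULL` keeps everything.
#' @param sep Output delimiter (default tab, for readable tables).
#' @param verbose Log stage progress to standard error.
#' @return Invisibly, a list with the four result tables (`signals`, `tto`,
#'   `descriptives`, `severity`), the `case_set`, and the named output
#'   `files`.
#' @export
run_pipeline <- function(input, out_dir,
                         target_pts = target_pts_hyponatremia(),
                         synonym_map = character(0), drug_window = NULL,
                         min_cases = 3, level = 0.95, top_k = 50,
                         sep = "\t", verbose = FALSE) {
  say <- function(...) if (verbose) message("[faerssignal] ", ...)
  if (is.character(input)) {
    say("reading quarter tables from ", input)
    input <- read_quarter(input)
  }
  say("building case set")
  cs <- build_case_set(input, target_pts = target_pts,
                       synonym_map = synonym_map, drug_window = drug_window)
  say("screening ", length(unique(cs$ps_drugs$drug)), " drugs")
  signals <- screen_signals(cs, min_cases = min_cases, level = level,
                            top_k = top_k)
  say("time-to-onset analysis for ", nrow(signals), " screened drugs")
  tto <- tto_table(cs, drugs = signals$drug, level = level)
  say("descriptive tabulations")
  desc <- describe_cases(cs, drugs = if (nrow(signals)) signals$drug)
  sev <- outcome_severity_table(cs, drugs = signals$drug)

  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory ", out_dir, call. = FALSE)
  prov <- data.table(stage = names(cs$provenance),
                     count = unlist(cs$provenance))
  files <- c(signals = file.path(out_dir, "signals.tsv"),
             tto = file.path(out_dir, "tto.tsv"),
             descriptives = file.path(out_dir, "descriptives.tsv"),
             severity = file.path(out_dir, "severity.tsv"),
             provenance = file.path(out_dir, "provenance.tsv"))
  fwrite(signals, files["signals"], sep = sep, quote = FALSE)
  fwrite(tto, files["tto"], sep = sep, quote = FALSE)
  fwrite(desc, files["descriptives"], sep = sep, quote = FALSE)
  fwrite(sev, files["severity"], sep = sep, quote = FALSE)
  fwrite(prov, files["provenance"], sep = sep, quote = FALSE)
  say("wrote ", length(files), " tables to ", out_dir)
  invisible(list(signals = signals, tto = tto, descriptives = desc,
                 severity = sev, case_set = cs, files = files))
}
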