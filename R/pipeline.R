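# Shared front half of both pipeline stages: read replicate Ct tables,
# aggregate, drop globally undetected targets.
load_ct <- function(ct_paths, cycle_limit, undetected_token) {
  mats <- lapply(ct_paths, read_ct_table, cycle_limit = cycle_limit,
                 undetected_token = undetected_token)
  filter_globally_undetected(aggregate_replicates(mats))
}

write_manifest <- function(path, stage, inputs, params) {
  manifest <- list(
    stage = stage,
    package = "diffpairs",
    version = as.character(utils::packageVersion("diffpairs")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    params = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the training-phase diffpair screen
#'
#' End-to-end discovery stage: read the replicate Ct tables and metadata,
#' aggregate replicates, drop globally undetected miRNAs, form all diffpairs,
#' screen them on the training split, and write the candidate table
#' (integer percentages alongside raw proportions), the locked rules for
#' the candidates, and a JSON run manifest (input checksums and parameters)
#' sufficient to reproduce the run bit-for-bit.
#'
#' @param ct_paths character vector of replicate Ct CSV paths (>= 1).
#' @param meta_path metadata CSV path.
#' @param out_dir output directory.
#' @param cycle_limit censoring limit (cycles).
#' @param sens_min,spec_min training candidate gate (default 0.80 each).
#' @param undetected_token token marking non-detection in the Ct tables.
#' @return the \code{\link{screen_all}} result, invisibly.
#' @export
run_screen <- function(ct_paths, meta_path, out_dir,
                       cycle_limit = 40, sens_min = 0.80, spec_min = 0.80,
                       undetected_token = "Undetermined") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- load_ct(ct_paths, cycle_limit, undetected_token)
  meta <- read_cohort_metadata(meta_path)
  dp <- compute_diffpairs(ct)
  screen <- screen_all(dp, meta, sens_min = sens_min, spec_min = spec_min)

  cand <- data.frame(
    diffpair = screen$pair, cutoff = screen$cutoff,
    direction = screen$direction,
    PPV = round_half_up(100 * screen$ppv), NPV = round_half_up(100 * screen$npv),
    SENS = round_half_up(100 * screen$sens), SPEC = round_half_up(100 * screen$spec),
    p_value = screen$p_value, AUC = screen$auc,
    is_candidate = screen$is_candidate,
    ppv = screen$ppv, npv = screen$npv, sens = screen$sens, spec = screen$spec,
    stringsAsFactors = FALSE)
  utils::write.csv(cand, file.path(out_dir, "screen_table.csv"),
                   row.names = FALSE)

  rules <- screen[screen$is_candidate,
                  c("mirna_a", "mirna_b", "cutoff", "direction")]
  utils::write.csv(rules, file.path(out_dir, "rules.csv"), row.names = FALSE)

  write_manifest(file.path(out_dir, "screen_manifest.json"), "screen",
                 c(ct_paths, meta_path),
                 list(cycle_limit = cycle_limit, sens_min = sens_min,
                      spec_min = spec_min, undetected_token = undetected_token))
  invisible(screen)
}

read_rules_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mirna_a", "mirna_b", "cutoff", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("rules file lacks column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    diffpair_rule(df$mirna_a[i], df$mirna_b[i], df$cutoff[i], df$direction[i]))
}

#' Validate locked rules on the test cohort
#'
#' End-to-end validation stage: read the rules written by
#' \code{\link{run_screen}} (schema-checked), the test-phase replicate Ct
#' tables and metadata; apply every rule with its training cutoff unchanged
#' to the test split; write the metrics table with exact confidence
#' intervals, per-pair ROC point files, and a run manifest.
#'
#' @param rules_path rules CSV path (columns
#'   \code{mirna_a,mirna_b,cutoff,direction}).
#' @param ct_paths character vector of replicate Ct CSV paths.
#' @param meta_path metadata CSV path.
#' @param out_dir output directory.
#' @param cycle_limit censoring limit (cycles).
#' @param sens_min,spec_min validation gate (default 0.75 each).
#' @param undetected_token token marking non-detection.
#' @return the \code{\link{validate_candidates}} table, invisibly.
#' @export
run_validate <- function(rules_path, ct_paths, meta_path, out_dir,
                         cycle_limit = 40, sens_min = 0.75, spec_min = 0.75,
                         undetected_token = "Undetermined") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- read_rules_csv(rules_path)
  ct <- load_ct(ct_paths, cycle_limit, undetected_token)
  meta <- read_cohort_metadata(meta_path)
  needed <- unique(c(vapply(rules, `[[`, "", "mirna_a"),
                     vapply(rules, `[[`, "", "mirna_b")))
  absent <- setdiff(needed, ct$mirna_ids)
  if (length(absent))
    stop2("rule miRNAs absent from Ct table: ", paste(absent, collapse = ", "))
  dp <- compute_diffpairs(ct[, ct$mirna_ids %in% needed])
  res <- validate_candidates(rules, dp, meta,
                             sens_min = sens_min, spec_min = spec_min)

  out <- data.frame(
    diffpair = res$pair,
    PPV = round_half_up(100 * res$ppv), NPV = round_half_up(100 * res$npv),
    SENS = round_half_up(100 * res$sens), SPEC = round_half_up(100 * res$spec),
    p_value = res$p_value,
    sens_ci_lo = res$sens_ci_lo, sens_ci_hi = res$sens_ci_hi,
    spec_ci_lo = res$spec_ci_lo, spec_ci_hi = res$spec_ci_hi,
    passed_gate = res$passed_gate,
    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(out_dir, "validation_table.csv"),
                   row.names = FALSE)

  mm <- meta_for_samples(meta, dp$sample_ids)
  test <- mm$split == "test"
  roc_dir <- file.path(out_dir, "roc")
  dir.create(roc_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(res))) {
    hit <- find_pair(dp, res$mirna_a[i], res$mirna_b[i])
    pts <- roc_points((hit$sign * dp$delta_ct[, hit$col])[test],
                      mm$group[test])
    safe <- gsub("[^A-Za-z0-9._-]", "_", res$pair[i])
    utils::write.csv(pts, file.path(roc_dir, paste0(safe, ".csv")),
                     row.names = FALSE)
  }

  write_manifest(file.path(out_dir, "validate_manifest.json"), "validate",
                 c(rules_path, ct_paths, meta_path),
                 list(cycle_limit = cycle_limit, sens_min = sens_min,
                      spec_min = spec_min, undetected_token = undetected_token))
  invisible(res)
}
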