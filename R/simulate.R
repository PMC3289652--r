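# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic serum qPCR cohort
#'
#' Defines the generative model for a two-phase (train/test) case-control
#' serum RT-qPCR study:
#' \deqn{Ct(s, m, r) = \beta_m + \gamma_s + \delta_m 1[s\ cancer] + \epsilon_{s,m,r}}
#' where \eqn{\beta_m} is the per-miRNA baseline abundance level (a uniform
#' draw on \code{baseline_ct_mean_range} jittered with
#' \eqn{N(0, \code{baseline_sd}^2)}), \eqn{\gamma_s \sim N(0,
#' \code{sample_shift_sd}^2)} a per-sample global Ct offset (serum input and
#' extraction-yield variability -- exactly the nuisance the diffpair
#' construction cancels), \eqn{\delta_m} the
#' planted additive disease effect in cycles (a k-cycle Ct shift is about a
#' 2^k fold-change), and \eqn{\epsilon} per-replicate measurement noise.
#' Values exceeding the cycle limit are right-censored at the limit. A
#' \code{censor_fraction_null} proportion of miRNAs have their baseline
#' pushed past the limit, emulating targets below the detection limit.
#'
#' @param n_mirnas number of miRNA targets.
#' @param n_cancer_train,n_control_train,n_cancer_test,n_control_test
#'   cohort sizes per group and split.
#' @param baseline_ct_mean_range \code{c(lo, hi)} cycles for per-miRNA
#'   baseline means.
#' @param baseline_sd SD of the per-miRNA jitter around the uniform baseline
#'   draw (cycles).
#' @param sample_shift_sd SD of the per-sample global Ct offset (cycles).
#' @param effects data.frame with columns \code{mirna} (index) and
#'   \code{effect} (cycles added in cancers); empty for a null cohort.
#' @param noise_sd per-replicate measurement noise SD (cycles).
#' @param noise_df degrees of freedom for t-distributed replicate noise;
#'   \code{Inf} (default) gives Gaussian noise.
#' @param n_replicates independent RT reactions per sample.
#' @param cycle_limit censoring limit (cycles).
#' @param censor_fraction_null proportion of miRNAs placed past the
#'   detection limit.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return a \code{sim_config} list.
#' @export
simulation_config <- function(n_mirnas = 40,
                              n_cancer_train = 30, n_control_train = 20,
                              n_cancer_test = 55, n_control_test = 75,
                              baseline_ct_mean_range = c(22, 36),
                              baseline_sd = 0.8,
                              sample_shift_sd = 1.5,
                              effects = data.frame(mirna = integer(),
                                                   effect = numeric()),
                              noise_sd = 0.5, noise_df = Inf,
                              n_replicates = 2, cycle_limit = 40,
                              censor_fraction_null = 0, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_mirnas >= 2, n_replicates >= 1,
            baseline_sd >= 0, sample_shift_sd >= 0, noise_sd >= 0,
            censor_fraction_null >= 0, censor_fraction_null <= 1,
            all(c("mirna", "effect") %in% names(effects)))
  if (nrow(effects) && (any(effects$mirna < 1) || any(effects$mirna > n_mirnas)))
    stop2("effect miRNA indices must lie in 1..n_mirnas")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-phase serum qPCR cohort
#'
#' Draws replicate Ct matrices, cohort metadata and a ground-truth manifest
#' from the model in \code{\link{simulation_config}}. Demographics (age,
#' sex, smoking, stage, histology) are generated with a cancer-enriched
#' smoking rate so that the cohort-association test has something to find.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{replicates} (list of \code{ct_matrix}, one per RT
#'   reaction), \code{metadata} (data.frame), and \code{truth} (planted
#'   effects, baselines, seed, config echo).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_per <- c(cfg$n_cancer_train, cfg$n_control_train,
             cfg$n_cancer_test, cfg$n_control_test)
  if (any(n_per == 0))
    stop2("every group x split cell needs at least one sample")
  ns <- sum(n_per)
  group <- rep(c("cancer", "control", "cancer", "control"), n_per)
  split <- rep(c("train", "train", "test", "test"), n_per)
  sample_ids <- sprintf("S%03d", seq_len(ns))
  mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))

  with_seed(cfg$seed, {
    mu <- stats::runif(cfg$n_mirnas, cfg$baseline_ct_mean_range[1L],
                       cfg$baseline_ct_mean_range[2L]) +
      stats::rnorm(cfg$n_mirnas, 0, cfg$baseline_sd)
    n_null <- round(cfg$censor_fraction_null * cfg$n_mirnas)
    null_idx <- if (n_null > 0) sample.int(cfg$n_mirnas, n_null) else integer()
    mu[null_idx] <- cfg$cycle_limit + 2  # past the detection limit

    delta <- numeric(cfg$n_mirnas)
    delta[cfg$effects$mirna] <- cfg$effects$effect

    shift <- stats::rnorm(ns, 0, cfg$sample_shift_sd)
    is_cancer <- group == "cancer"
    expect <- matrix(mu, ns, cfg$n_mirnas, byrow = TRUE) + shift +
      outer(is_cancer, delta)

    rnoise <- function(n) {
      if (is.infinite(cfg$noise_df)) stats::rnorm(n, 0, cfg$noise_sd)
      else cfg$noise_sd * stats::rt(n, cfg$noise_df)
    }
    replicates <- lapply(seq_len(cfg$n_replicates), function(r) {
      ct <- expect + matrix(rnoise(ns * cfg$n_mirnas), ns, cfg$n_mirnas)
      cen <- ct > cfg$cycle_limit
      ct[cen] <- cfg$cycle_limit
      ct <- pmax(ct, 1)  # Ct must stay positive; unreachable at defaults
      dimnames(ct) <- dimnames(cen) <- list(sample_ids, mirna_ids)
      ct_matrix(ct, cen, cycle_limit = cfg$cycle_limit)
    })

    age <- round(ifelse(is_cancer, stats::rnorm(ns, 67, 8),
                        stats::rnorm(ns, 60, 10)))
    meta <- data.frame(
      sample_id = sample_ids, group = group, split = split,
      age = pmin(pmax(age, 20), 90),
      sex = sample(c("F", "M"), ns, replace = TRUE, prob = c(0.4, 0.6)),
      smoker = stats::rbinom(ns, 1, ifelse(is_cancer, 0.8, 0.5)) == 1,
      stage = ifelse(is_cancer,
                     sample(c("I", "II", "III", "IV"), ns, replace = TRUE,
                            prob = c(0.5, 0.25, 0.2, 0.05)), NA),
      histology = ifelse(is_cancer,
                         sample(c("adenocarcinoma", "squamous"), ns,
                                replace = TRUE, prob = c(0.6, 0.4)), NA),
      stringsAsFactors = FALSE)

    truth <- list(
      seed = cfg$seed,
      config = unclass(cfg),
      baseline_ct = stats::setNames(mu, mirna_ids),
      effects = data.frame(mirna = mirna_ids[cfg$effects$mirna],
                           effect = cfg$effects$effect,
                           stringsAsFactors = FALSE),
      undetectable = mirna_ids[sort(null_idx)])

    list(replicates = replicates, metadata = meta, truth = truth)
  })
}

#' Paper-shaped cohort preset
#'
#' Convenience wrapper for a cohort with the geometry of a two-phase serum
#' miRNA study: 181 miRNAs (hence 16290 diffpairs), 30 cancers / 20 controls
#' in training, 55 cancers / 75 controls in the test phase, two RT
#' replicates per sample, censoring at 40 cycles. By default two miRNAs
#' carry opposite disease effects of 2.5 cycles each, so their mutual
#' diffpair separates the groups by about 5 cycles while every pair with a
#' neutral partner separates by 2.5.
#'
#' @param seed integer RNG seed.
#' @param effects planted effects; default
#'   \code{data.frame(mirna = c(1, 2), effect = c(-2.5, 2.5))}.
#' @param ... further overrides passed to \code{\link{simulation_config}}.
#' @return as \code{\link{simulate_cohort}}.
#' @export
paper_shaped_cohort <- function(seed = 1L,
                                effects = data.frame(mirna = c(1, 2),
                                                     effect = c(-2.5, 2.5)),
                                ...) {
  cfg <- simulation_config(
    n_mirnas = 181,
    n_cancer_train = 30, n_control_train = 20,
    n_cancer_test = 55, n_control_test = 75,
    effects = effects, n_replicates = 2, seed = seed, ...)
  simulate_cohort(cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits one Ct CSV per replicate (\code{ct_replicate<k>.csv}),
#' \code{metadata.csv}, and \code{truth_manifest.json} in the dialects the
#' readers expect.
#'
#' @param sim result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(sim$replicates), function(r) {
    p <- file.path(dir, sprintf("ct_replicate%d.csv", r))
    write_ct_table(sim$replicates[[r]], p)
    p
  }, character(1))
  mp <- file.path(dir, "metadata.csv")
  utils::write.csv(sim$metadata, mp, row.names = FALSE)
  tp <- file.path(dir, "truth_manifest.json")
  jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp, tp))
}
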