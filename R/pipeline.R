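# End-to-end pipeline: synthetic condition -> round detection -> subperiod
# slopes -> concurrent-cycles pH fit, reported per condition.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Analyse one generated condition
#'
#' Runs detection, slope estimation over the G, I and C+D subperiods, and
#' the fixed- or free-zeta_H concurrent-cycles fit for a single generated
#' condition, returning one summary row.
#'
#' @param cond Output of [generate_condition()].
#' @param fit_mode Passed to [fit_ph()].
#' @param ancestry_min Minimum number of recorded ancestors for a cell to
#'   enter the statistics (default 4).
#' @param QCDprime Growth factor assumed for the replication/segregation
#'   process (default 1.8).
#' @return A one-row tibble: condition, cell and detection counts, detected
#'   mean C and D, the three coupling constants with standard errors, and
#'   the fitted pH (standard error by first-order propagation of the CD
#'   slope's error in fixed mode).
#' @export
analyse_condition <- function(cond, fit_mode = "fixed_zetaH",
                              ancestry_min = 4, QCDprime = 1.8) {
  preset <- cond$preset
  rounds <- stage("detect", detect_rounds(cond$frames, cond$lineages,
                                          preset$frame_interval))
  slopes <- stage("slopes", {
    lapply(c("G", "I", "CD"), function(per) {
      adder_slope(subperiod_samples(cond$lineages, rounds, per,
                                    ancestry_min = ancestry_min))
    })
  })
  names(slopes) <- c("G", "I", "CD")
  gf <- stage("growth-factors",
              measure_growth_factors(cond$lineages, rounds,
                                     ancestry_min = ancestry_min,
                                     QCDprime = QCDprime))
  obs <- tibble::tibble(
    period = c("G", "I", "CD"),
    zeta = vapply(slopes, function(s) s$zeta, numeric(1)),
    se = vapply(slopes, function(s) s$se, numeric(1))
  )
  fit <- stage("fit", fit_ph(obs, gf, mode = fit_mode))
  det <- rounds[rounds$detected, ]
  tibble::tibble(
    condition = preset$name,
    n_cells = sum(!cond$lineages$burn_in),
    n_detected = nrow(det),
    detection_rate = attr(rounds, "detection_rate"),
    C_mean_min = mean(det$C_min),
    D_mean_min = mean(det$D_min),
    zeta_G = slopes$G$zeta, se_G = slopes$G$se,
    zeta_I = slopes$I$zeta, se_I = slopes$I$se,
    zeta_CD = slopes$CD$zeta, se_CD = slopes$CD$se,
    pH = fit$pH,
    pH_se = fit$pH_se
  )
}

#' Reproduce the per-condition coupling-constant and pH report
#'
#' Chains synthetic-data generation, replication-round detection, robust
#' slope estimation and pH fitting over a list of condition presets and
#' returns the per-condition report table (one row per condition, sorted as
#' given). All randomness derives from the seeds stored in the presets.
#'
#' @param presets A non-empty list of [condition_preset()] objects.
#' @param fit_mode,ancestry_min,QCDprime Passed to [analyse_condition()].
#' @param out_path Optional TSV path for the report.
#' @return A tibble with one row per condition.
#' @export
reproduce_conditions <- function(presets, fit_mode = "fixed_zetaH",
                                 ancestry_min = 4, QCDprime = 1.8,
                                 out_path = NULL) {
  if (length(presets) == 0) {
    stop("stage input: no condition presets supplied", call. = FALSE)
  }
  rows <- lapply(presets, function(ps) {
    cond <- stage("synth", generate_condition(ps))
    analyse_condition(cond, fit_mode = fit_mode,
                      ancestry_min = ancestry_min, QCDprime = QCDprime)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_path)) write_tsv_plain(as.data.frame(report), out_path)
  report
}
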