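# Condition presets: bundles of simulator parameters plus trace-synthesis
# settings that stand in for a mother-machine imaging condition. The
# unperturbed preset is anchored to slow growth in minimal medium: 6-min
# frames, ~90-min doubling time, mean C period 51 min and mean D period
# 22 min, ~5% division asymmetry, and balanced concurrent cycles
# (pH ~ 0.5).

#' Define a synthetic imaging-condition preset
#'
#' @param name Condition label (written to `condition_id`).
#' @param params An [icd_params()] or [concurrent_params()] object.
#' @param frame_interval Imaging interval (min); 6 or 8.
#' @param C_mean,C_cv Mean and CV of the per-cell C period (min) used to
#'   place replication termination inside the simulated cycle.
#' @param itot_mean Mean replication-phase excess intensity Itot (a.u.).
#' @param itot_sd_frac Gaussian noise SD on Itot as a fraction of
#'   `itot_mean` (default 0.10).
#' @return A list of class `condition_preset`.
#' @export
condition_preset <- function(name, params, frame_interval = 6,
                             C_mean = 51, C_cv = 0.08,
                             itot_mean = 100, itot_sd_frac = 0.10) {
  if (!frame_interval %in% c(6, 8)) {
    stop("frame_interval must be 6 or 8 min", call. = FALSE)
  }
  if (C_mean <= 0) stop("C_mean must be positive", call. = FALSE)
  stopifnot(inherits(params, "sim_params"))
  structure(
    list(name = name, params = params, frame_interval = frame_interval,
         C_mean = C_mean, C_cv = C_cv,
         itot_mean = itot_mean, itot_sd_frac = itot_sd_frac),
    class = "condition_preset"
  )
}

# Frozen calibration of the unperturbed balanced preset: tau_CDprime and
# mean_dH are set so that, at balance (emergent pH ~ 0.5), the emergent
# mean C and D periods equal the measured 51 and 22 min; the noise is
# split between the inter-initiation adder (CV 0.15) and the two division
# processes (CV 0.10 each) so that the initiation-size/birth-size variance
# ratio and the near-adder inter-division slope resemble the measured
# inputs. See the methods vignette for the calibration rationale.
UNPERT_TAU_CDPRIME <- 67.0
UNPERT_MEAN_DH <- 1.59

#' The unperturbed slow-growth condition preset
#'
#' Balanced concurrent-cycles condition: exponential growth with a ~90-min
#' doubling time, per-origin inter-initiation adder of 1 um, division
#' asymmetry 5%, 6-min frames, and replication/segregation vs
#' inter-division processes balanced so that each limits division with
#' roughly equal probability. The mean emergent C and D periods are 51 and
#' 22 min.
#'
#' @param seed Integer RNG seed.
#' @param n_lineages Number of simulated channels (default 40).
#' @param n_generations Post-burn-in generations per channel (default 30).
#' @return A [condition_preset()].
#' @export
unperturbed_preset <- function(seed = 1L, n_lineages = 40,
                               n_generations = 30) {
  condition_preset(
    name = "unperturbed",
    params = concurrent_params(
      mean_dH = UNPERT_MEAN_DH, cv_dH = 0.10,
      mean_dI = 1.0, cv_dI = 0.15,
      tau_CDprime = UNPERT_TAU_CDPRIME, cv_CDprime = 0.10,
      alpha = 0.05,
      growth_rate_mean = log(2) / 90, growth_rate_cv = 0.07,
      n_cells = n_lineages * n_generations, n_lineages = n_lineages,
      seed = seed, burn_in = 10L
    ),
    frame_interval = 6, C_mean = 51, C_cv = 0.08
  )
}

#' Generate a complete synthetic condition (lineages plus traces)
#'
#' Simulates lineages under the preset's model, places replication
#' termination at `t_init + C` with per-cell log-normal C periods
#' (truncated at division), and emits per-frame traces on the global
#' imaging grid: length by exponential interpolation, `Itot` drawn around
#' `itot_mean` during replication and around `-itot_mean/2` otherwise, and
#' two replisome foci migrating from mid-cell toward the quarter positions
#' over the course of replication. Deterministic given the preset seed.
#'
#' @param preset A [condition_preset()].
#' @param out_dir Optional directory; if given, `<name>_lineages.tsv` and
#'   `<name>_frames.tsv` are written there.
#' @return A list with `lineages` (including `t_term_min` and
#'   `condition_id`), `frames`, and `preset`.
#' @export
generate_condition <- function(preset, out_dir = NULL) {
  stopifnot(inherits(preset, "condition_preset"))
  p <- preset$params
  sim <- if (identical(p$model, "concurrent")) {
    simulate_concurrent(p)
  } else {
    simulate_icd(p)
  }
  n <- nrow(sim)
  C_i <- rlnorm_mean_cv(n, preset$C_mean, preset$C_cv)
  sim$t_term_min <- pmin(sim$t_init_min + C_i, sim$t_div_min)
  sim$condition_id <- preset$name

  dt <- preset$frame_interval
  first <- ceiling(sim$t_birth_min / dt)
  last <- ceiling(sim$t_div_min / dt) - 1
  nf <- pmax(0L, last - first + 1L)
  idx <- rep(seq_len(n), nf)
  k <- sequence(nf) - 1L + rep(first, nf)
  t <- k * dt

  rate <- log(sim$Ld_um / sim$L0_um) / (sim$t_div_min - sim$t_birth_min)
  L <- sim$L0_um[idx] * exp(rate[idx] * (t - sim$t_birth_min[idx]))
  # a cell's frames can show its own round (which may have initiated in the
  # mother) and the early portion of the daughter's round
  di <- match(paste(sim$lineage, sim$generation + 1L),
              paste(sim$lineage, sim$generation))
  t_init_next <- sim$t_init_min[di]
  t_term_next <- sim$t_term_min[di]
  in_own <- t >= sim$t_init_min[idx] & t <= sim$t_term_min[idx]
  in_next <- !is.na(t_init_next[idx]) & t >= t_init_next[idx] &
    t <= t_term_next[idx]
  repl <- in_own | in_next
  A <- preset$itot_mean
  itot <- stats::rnorm(length(t),
                       mean = ifelse(repl, A, -A / 2),
                       sd = preset$itot_sd_frac * A)

  q_own <- (t - sim$t_init_min[idx]) /
    pmax(sim$t_term_min[idx] - sim$t_init_min[idx], 1e-9)
  q_next <- (t - t_init_next[idx]) /
    pmax(t_term_next[idx] - t_init_next[idx], 1e-9)
  q <- ifelse(in_own, q_own, q_next)
  y1 <- pmin(pmax(0.5 - 0.25 * q + stats::rnorm(length(t), 0, 0.02),
                  0.02), 0.98)
  y2 <- pmin(pmax(0.5 + 0.25 * q + stats::rnorm(length(t), 0, 0.02),
                  0.02), 0.98)
  focus <- ifelse(repl, paste0(formatC(y1, digits = 4, format = "f"), ";",
                               formatC(y2, digits = 4, format = "f")), "")

  frames <- tibble::tibble(
    cell_id = sim$cell_id[idx],
    t_min = t,
    L_um = L,
    Itot = itot,
    focus_rel_positions = focus
  )

  out <- list(lineages = sim, frames = frames, preset = preset)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_lineages(sim, file.path(out_dir,
                                  paste0(preset$name, "_lineages.tsv")))
    write_frames(frames, file.path(out_dir,
                                   paste0(preset$name, "_frames.tsv")))
  }
  out
}

#' Generate the in-silico width-perturbation (A22) series
#'
#' A sequence of conditions that differ only in the mean added size of the
#' inter-division process: the C period, the replication/segregation timer
#' and the inter-initiation adder stay fixed while the inter-division
#' process becomes progressively more limiting, which raises the emergent
#' mean D period — the model's account of the A22 width perturbation.
#'
#' @param base A [condition_preset()] with a concurrent-cycles parameter
#'   set (e.g. [unperturbed_preset()]).
#' @param dH_values Non-decreasing mean inter-division added sizes (um).
#' @param out_dir Optional output directory, passed to
#'   [generate_condition()].
#' @return A named list of generated conditions (one per value).
#' @export
generate_a22_series <- function(base, dH_values, out_dir = NULL) {
  stopifnot(inherits(base, "condition_preset"),
            inherits(base$params, "concurrent_params"))
  if (is.unsorted(dH_values)) {
    stop("dH_values must be non-decreasing", call. = FALSE)
  }
  out <- lapply(seq_along(dH_values), function(i) {
    p <- base
    p$params$mean_dH <- dH_values[i]
    p$name <- sprintf("%s_dH%.2f", base$name, dH_values[i])
    generate_condition(p, out_dir = out_dir)
  })
  names(out) <- sprintf("dH%.2f", dH_values)
  out
}
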