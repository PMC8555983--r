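# Shared fixtures: small parameter sets, hand-built chains and traces.

small_icd <- function(seed = 1L, alpha = 0, cv = 0.05, n_cells = 4000,
                      burn_in = 10L) {
  icd_params(mean_dI = 1, cv_dI = cv, mean_dCD = 1.6, cv_dCD = cv,
             alpha = alpha, growth_rate_mean = log(2) / 90,
             growth_rate_cv = min(cv, 0.05),
             n_cells = n_cells, n_lineages = 50, seed = seed,
             burn_in = burn_in)
}

small_concurrent <- function(seed = 1L, alpha = 0, n_cells = 4000, ...) {
  concurrent_params(mean_dH = 1.59, cv_dH = 0.10, mean_dI = 1, cv_dI = 0.15,
                    tau_CDprime = 67, cv_CDprime = 0.10, alpha = alpha,
                    growth_rate_mean = log(2) / 90, growth_rate_cv = 0.07,
                    n_cells = n_cells, n_lineages = 50, seed = seed,
                    burn_in = 10L, ...)
}

# exponentially growing grandmother-mother-cell chain, each cycle doubling
# from 1 to 2 um over 60 min, symmetric divisions
toy_lineages <- function() {
  tibble::tibble(
    cell_id = c("gm", "mo", "ce"),
    parent_id = c(NA, "gm", "mo"),
    t_birth_min = c(0, 60, 120),
    t_div_min = c(60, 120, 180),
    L0_um = c(1, 1, 1),
    Ld_um = c(2, 2, 2),
    L0_sibling_um = c(1, 1, 1)
  )
}

# mother-daughter frame pair on a 6-min grid: the daughter's round has
# Itot > 0 exactly on its frames 5..15 (absolute frames 23..33), division
# at daughter frame 18 (t = 216)
toy_detection_fixture <- function(blip_only = FALSE) {
  dt <- 6
  tM <- seq(0, 102, by = dt)
  tD <- seq(108, 210, by = dt)
  pos_frames <- if (blip_only) {
    tD >= 108 + 5 * dt & tD <= 108 + 7 * dt       # 3 frames: 12-min blip
  } else {
    tD >= 108 + 5 * dt & tD <= 108 + 15 * dt
  }
  frames <- tibble::tibble(
    cell_id = c(rep("M", length(tM)), rep("D", length(tD))),
    t_min = c(tM, tD),
    L_um = 1.5,
    Itot = c(rep(-50, length(tM)), ifelse(pos_frames, 100, -50)),
    focus_rel_positions = ""
  )
  lineages <- tibble::tibble(
    cell_id = c("M", "D"),
    parent_id = c(NA, "M"),
    t_birth_min = c(0, 108),
    t_div_min = c(108, 216),
    L0_um = c(1, 1),
    Ld_um = c(2, 2),
    L0_sibling_um = c(1, 1)
  )
  wide <- list(init = c(-120, -40), term = c(-40, 40))
  list(frames = frames, lineages = lineages, windows = wide, dt = dt)
}

# samples on a normalized-axes line: added = slope * initial + b with
# mean(initial) = mean(added) = 1 so normalization is the identity; a tiny
# deterministic ripple keeps the residual scale finite for the robust fit
line_samples <- function(n = 200, slope = 0.5, ripple = 1e-3) {
  initial <- seq(0.6, 1.4, length.out = n)
  initial <- initial / mean(initial)
  wig <- ripple * sin(seq_len(n))
  tibble::tibble(period = "G", initial = initial,
                 added = slope * initial + (1 - slope) + wig - mean(wig))
}

raw_ols_slope <- function(samples) {
  fit <- stats::lm(added ~ initial, data = samples)
  c(slope = unname(stats::coef(fit)[2]),
    se = unname(sqrt(diag(stats::vcov(fit)))[2]))
}

# B-period samples (birth size vs size added up to initiation) from a
# simulated lineage table, using the latent initiation sizes
b_period_samples <- function(sim) {
  keep <- !sim$burn_in
  tibble::tibble(period = "B", initial = sim$L0_um[keep],
                 added = sim$L_init_um[keep] - sim$L0_um[keep])
}
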