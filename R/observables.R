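# Observables: ori-normalized lengths on grandmother-mother-cell triplets,
# added sizes over the G, I and C+D subperiods, growth factors, single-cell
# growth rates, and robust adder-plot slopes.

#' Assemble a grandmother-mother-cell triplet chain
#'
#' Triplets allow replication rounds that initiate up to two generations
#' before the division they control to be expressed on a single
#' ori-normalized length trajectory.
#'
#' @param lineages A lineage tibble.
#' @param cell_id Id of the focal (youngest) cell; its mother and
#'   grandmother must be present in `lineages`.
#' @return A list of class `triplet_chain` with one-row records `cell`,
#'   `mother`, `grandmother`.
#' @export
triplet_chain <- function(lineages, cell_id) {
  row <- function(id) {
    i <- match(id, lineages$cell_id)
    if (is.na(i)) stop("cell ", id, " not found in lineage table",
                       call. = FALSE)
    as.list(lineages[i, ])
  }
  cell <- row(cell_id)
  if (is.na(cell$parent_id)) stop("cell has no recorded mother", call. = FALSE)
  mother <- row(cell$parent_id)
  if (is.na(mother$parent_id)) stop("cell has no recorded grandmother",
                                    call. = FALSE)
  grandmother <- row(mother$parent_id)
  structure(list(cell = cell, mother = mother, grandmother = grandmother),
            class = "triplet_chain")
}

interp_length <- function(rec, t) {
  rate <- log(rec$Ld_um / rec$L0_um) / (rec$t_div_min - rec$t_birth_min)
  rec$L0_um * exp(rate * (t - rec$t_birth_min))
}

#' Ori-normalized length along a triplet chain
#'
#' Evaluates the per-origin length trajectory `L*` at time `t`, anchored at
#' the focal cell: the length of the cell itself, the mother's length
#' divided by two, or the grandmother's length divided by four. Lengths
#' between recorded birth and division are obtained by exponential
#' interpolation. With `asym_correct = TRUE` each crossed division
#' contributes an additive offset `L0_child - Ld_parent / 2`
#' (equivalently `alpha * Ld_parent / 2` with asymmetry
#' `alpha = (L0_sib - L0)/(L0_sib + L0)`), which makes the trajectory
#' exactly continuous across asymmetric divisions and recovers the
#' generative added sizes of an asymmetric-division adder model.
#'
#' @param chain A [triplet_chain()].
#' @param t Time (min), within the grandmother-to-cell time span.
#' @param asym_correct Apply the measured division-asymmetry offsets
#'   (default `FALSE`).
#' @return Ori-normalized length (um).
#' @export
per_ori_length <- function(chain, t, asym_correct = FALSE) {
  stopifnot(inherits(chain, "triplet_chain"))
  cl <- chain$cell; mo <- chain$mother; gm <- chain$grandmother
  off_cm <- if (asym_correct) cl$L0_um - mo$Ld_um / 2 else 0
  off_mg <- if (asym_correct) mo$L0_um - gm$Ld_um / 2 else 0
  if (t >= cl$t_birth_min && t <= cl$t_div_min) {
    interp_length(cl, t)
  } else if (t >= mo$t_birth_min && t < cl$t_birth_min) {
    interp_length(mo, t) / 2 + off_cm
  } else if (t >= gm$t_birth_min && t < mo$t_birth_min) {
    interp_length(gm, t) / 4 + off_mg / 2 + off_cm
  } else {
    stop("time ", t, " outside the span of the triplet chain", call. = FALSE)
  }
}

#' Added ori-normalized size over a subperiod of one triplet chain
#'
#' Computes the added size for the inter-division (`"G"`), inter-initiation
#' (`"I"`) or initiation-to-division (`"CD"`) subperiod:
#' `Delta_I = L*(tB_cell) - L*(tB_mother)`,
#' `Delta_CD = L*(td_cell) - L*(tB_cell)`, and
#' `Delta_G = Ld - L0` of the focal cell; `tB` denotes replication
#' initiation times taken from `round` (the focal cell's round) and
#' `mother_round`.
#'
#' @param chain A [triplet_chain()].
#' @param round A one-row list/data frame with the focal cell's replication
#'   round (`t_init_min` at least); required for `"I"` and `"CD"`.
#' @param period `"G"`, `"I"` or `"CD"`.
#' @param mother_round The mother's replication round; required for `"I"`.
#' @param asym_correct Propagated to [per_ori_length()].
#' @return A list with `period`, `initial` and `added` (um), or `NULL` with
#'   a message if a required initiation event is missing.
#' @export
added_size <- function(chain, round = NULL,
                       period = c("G", "I", "CD"),
                       mother_round = NULL, asym_correct = FALSE) {
  period <- match.arg(period)
  stopifnot(inherits(chain, "triplet_chain"))
  if (period == "G") {
    cl <- chain$cell
    return(list(period = "G", initial = cl$L0_um,
                added = cl$Ld_um - cl$L0_um))
  }
  if (is.null(round) || is.na(round$t_init_min)) {
    message("skipping chain ", chain$cell$cell_id,
            ": no replication round for the focal cell")
    return(NULL)
  }
  if (period == "CD") {
    t1 <- round$t_init_min
    t2 <- chain$cell$t_div_min
    l1 <- per_ori_length(chain, t1, asym_correct)
    return(list(period = "CD", initial = l1,
                added = per_ori_length(chain, t2, asym_correct) - l1))
  }
  if (is.null(mother_round) || is.na(mother_round$t_init_min)) {
    message("skipping chain ", chain$cell$cell_id,
            ": no replication round for the mother")
    return(NULL)
  }
  t1 <- mother_round$t_init_min
  t2 <- round$t_init_min
  l1 <- per_ori_length(chain, t1, asym_correct)
  list(period = "I", initial = l1,
       added = per_ori_length(chain, t2, asym_correct) - l1)
}

#' Added size with explicit division-asymmetry correction
#'
#' Convenience wrapper for [added_size()] with `asym_correct = TRUE`: the
#' ori-normalized trajectory gains an additive offset `alpha * Ld/2` at
#' every division the subperiod spans, with division asymmetry
#' `alpha = (L0_sibling - L0)/(L0_sibling + L0)`, correcting the added
#' size for unequal partitioning between the daughters.
#'
#' @inheritParams added_size
#' @return As [added_size()].
#' @export
asymmetry_corrected_added_size <- function(chain, round = NULL,
                                           period = c("G", "I", "CD"),
                                           mother_round = NULL) {
  added_size(chain, round, period, mother_round, asym_correct = TRUE)
}

ancestry_depth <- function(lineages) {
  idx <- match(lineages$parent_id, lineages$cell_id)
  depth <- rep(0L, nrow(lineages))
  # iterate: depth = parent's depth + 1; lineage tables are shallow enough
  repeat {
    new <- ifelse(is.na(idx), 0L, depth[idx] + 1L)
    new[is.na(new)] <- 0L
    if (identical(new, depth)) break
    depth <- new
  }
  depth
}

#' Replication rounds from simulator latent initiation times
#'
#' Builds a rounds table directly from the latent `t_init_min` column of a
#' simulated lineage table, bypassing trace-based detection. Termination
#' times are unset (`NA`).
#'
#' @param sim A simulated lineage tibble.
#' @return A rounds tibble (`cell_id`, `t_init_min`, `t_term_min`, `C_min`,
#'   `D_min`, `n_span`).
#' @export
latent_rounds <- function(sim) {
  tibble::tibble(
    cell_id = sim$cell_id,
    t_init_min = sim$t_init_min,
    t_term_min = NA_real_,
    C_min = NA_real_,
    D_min = NA_real_,
    n_span = 1L
  )
}

#' Subperiod adder-plot samples for a whole condition
#'
#' Vectorized assembly of (initial size, added size) pairs over all triplet
#' chains of a condition, for one subperiod. Only cells with at least
#' `ancestry_min` recorded ancestors enter; burn-in rows of simulated tables
#' are excluded. Initial and added sizes are also returned mean-normalized
#' (`initial_norm`, `added_norm`), the form in which adder slopes are
#' estimated.
#'
#' @param lineages Lineage tibble (simulated or read from file).
#' @param rounds Rounds tibble ([detect_rounds()] output or
#'   [latent_rounds()]); required for periods `"I"` and `"CD"`.
#' @param period `"G"`, `"I"` or `"CD"`.
#' @param ancestry_min Minimum number of recorded ancestors (default 4).
#' @param asym_correct Use measured division asymmetries in the ori
#'   normalization (default `FALSE`).
#' @return A tibble with columns `cell_id`, `period`, `initial`, `added`,
#'   `initial_norm`, `added_norm`.
#' @export
subperiod_samples <- function(lineages, rounds = NULL,
                              period = c("G", "I", "CD"),
                              ancestry_min = 4, asym_correct = FALSE) {
  period <- match.arg(period)
  ln <- as.data.frame(lineages)
  keep <- ancestry_depth(ln) >= ancestry_min
  if ("burn_in" %in% names(ln)) keep <- keep & !ln$burn_in

  if (period == "G") {
    out <- tibble::tibble(
      cell_id = ln$cell_id[keep],
      period = "G",
      initial = ln$L0_um[keep],
      added = ln$Ld_um[keep] - ln$L0_um[keep]
    )
    return(normalize_samples(out))
  }

  if (is.null(rounds)) {
    stop("periods I and CD require a rounds table", call. = FALSE)
  }
  rd <- as.data.frame(rounds)
  mi <- match(ln$parent_id, ln$cell_id)       # mother row index
  gi <- match(ln$parent_id[ifelse(is.na(mi), 1L, mi)], ln$cell_id)
  gi[is.na(mi)] <- NA
  ri <- match(ln$cell_id, rd$cell_id)         # focal round
  rmi <- match(ln$parent_id, rd$cell_id)      # mother's round

  t_init <- rd$t_init_min[ri]
  t_init_mother <- rd$t_init_min[rmi]

  ok <- keep & !is.na(mi) & !is.na(gi) & !is.na(t_init)
  if (period == "I") ok <- ok & !is.na(t_init_mother)
  idx <- which(ok)
  if (length(idx) == 0) {
    stop("no usable triplet chains for period ", period, call. = FALSE)
  }

  lstar <- function(i, t) {
    chain_lstar_vec(ln, i, mi[i], gi[i], t, asym_correct)
  }
  if (period == "CD") {
    l1 <- lstar(idx, t_init[idx])
    l2 <- lstar(idx, ln$t_div_min[idx])
  } else {
    l1 <- lstar(idx, t_init_mother[idx])
    l2 <- lstar(idx, t_init[idx])
  }
  out <- tibble::tibble(
    cell_id = ln$cell_id[idx],
    period = period,
    initial = l1,
    added = l2 - l1
  )
  out <- out[is.finite(out$initial) & is.finite(out$added) & out$initial > 0, ]
  normalize_samples(out)
}

# vectorized L* over rows i (cell), mothers m, grandmothers g at times t;
# with asym_correct each crossed division adds L0(child) - Ld(parent)/2
chain_lstar_vec <- function(ln, i, m, g, t, asym_correct) {
  off_cm <- if (asym_correct) ln$L0_um[i] - ln$Ld_um[m] / 2 else
    rep(0, length(i))
  off_mg <- if (asym_correct) ln$L0_um[m] - ln$Ld_um[g] / 2 else
    rep(0, length(i))
  seg_len <- function(rows, t) {
    rate <- log(ln$Ld_um[rows] / ln$L0_um[rows]) /
      (ln$t_div_min[rows] - ln$t_birth_min[rows])
    ln$L0_um[rows] * exp(rate * (t - ln$t_birth_min[rows]))
  }
  in_cell <- t >= ln$t_birth_min[i]
  in_mother <- !in_cell & t >= ln$t_birth_min[m]
  out <- rep(NA_real_, length(i))
  if (any(in_cell)) out[in_cell] <- seg_len(i[in_cell], t[in_cell])
  if (any(in_mother)) {
    out[in_mother] <- seg_len(m[in_mother], t[in_mother]) / 2 +
      off_cm[in_mother]
  }
  rest <- !in_cell & !in_mother
  if (any(rest)) {
    out[rest] <- seg_len(g[rest], t[rest]) / 4 + off_mg[rest] / 2 +
      off_cm[rest]
  }
  out
}

normalize_samples <- function(samples) {
  samples$initial_norm <- samples$initial / mean(samples$initial)
  samples$added_norm <- samples$added / mean(samples$added)
  samples
}

#' Robust adder-plot slope (coupling constant)
#'
#' Estimates the coupling constant `zeta` of a subperiod as the slope of the
#' mean-normalized added size against the mean-normalized initial size,
#' using iteratively re-weighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, tolerance 1e-8, at most 50 iterations) to
#' suppress occasional gross outliers.
#'
#' @param samples A tibble from [subperiod_samples()] (at least `initial`
#'   and `added`; re-normalized internally).
#' @param Q Optional growth factor of the period; if given, the equivalent
#'   size-growth slope `lambda` is filled in via [lambda_from_zeta()].
#' @param normalize Fit on mean-normalized axes (default `TRUE`, the adder-
#'   plot convention). With `FALSE` the raw-unit slope is returned, the
#'   quantity that enters the linear-response covariance relations; the two
#'   differ by the factor `mean(initial)/mean(added)`, which is 1 for the
#'   inter-division and inter-initiation periods but not for B or C+D.
#' @return An object of class `coupling_estimate`: list with `period`,
#'   `zeta`, `se`, `lam`, `n_samples`.
#' @export
adder_slope <- function(samples, Q = NULL, normalize = TRUE) {
  samples <- as.data.frame(samples)
  if (nrow(samples) < 10) {
    stop("need at least 10 samples for a slope estimate", call. = FALSE)
  }
  if (stats::var(samples$initial) <= 0 ||
      stats::sd(samples$initial) / mean(samples$initial) < 1e-10) {
    stop("degenerate initial-size variance", call. = FALSE)
  }
  samples <- normalize_samples(samples)
  if (!normalize) {
    samples$initial_norm <- samples$initial
    samples$added_norm <- samples$added
  }
  fit <- MASS::rlm(added_norm ~ initial_norm, data = samples,
                   psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 50, acc = 1e-8)
  co <- summary(fit)$coefficients
  zeta <- unname(co["initial_norm", "Value"])
  se <- unname(co["initial_norm", "Std. Error"])
  period <- if ("period" %in% names(samples)) samples$period[1] else NA_character_
  structure(
    list(period = period, zeta = zeta, se = se,
         lam = if (is.null(Q)) NA_real_ else lambda_from_zeta(zeta, Q),
         n_samples = nrow(samples)),
    class = "coupling_estimate"
  )
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf("zeta_%s = %+.4f +/- %.4f  (n = %d", x$period, x$zeta, x$se,
              x$n_samples))
  if (is.finite(x$lam)) cat(sprintf(", lambda = %.4f", x$lam))
  cat(")\n")
  invisible(x)
}

#' Single-cell growth rate from an exponential fit
#'
#' Fits `log(L) ~ t` by least squares and returns the growth rate. Cells
#' with fewer than 4 frames, non-positive fitted rate, or coefficient of
#' determination at or below 0.8 are rejected.
#'
#' @param trace A data frame with columns `t_min` and `L_um` for one cell.
#' @return A list with `mu` (1/min), `r_squared`, `accepted` (logical) and
#'   `reason` (`NA` if accepted).
#' @export
growth_rate <- function(trace) {
  trace <- as.data.frame(trace)
  if (nrow(trace) < 4) {
    return(list(mu = NA_real_, r_squared = NA_real_, accepted = FALSE,
                reason = "fewer than 4 frames"))
  }
  fit <- stats::lm(log(L_um) ~ t_min, data = trace)
  mu <- unname(stats::coef(fit)["t_min"])
  # noiseless traces fit exactly; the perfect-fit warning is meaningless here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(mu) || mu <= 0) {
    return(list(mu = mu, r_squared = r2, accepted = FALSE,
                reason = "non-positive growth rate"))
  }
  if (!is.finite(r2) || r2 <= 0.8) {
    return(list(mu = mu, r_squared = r2, accepted = FALSE,
                reason = "R-squared at or below 0.8"))
  }
  list(mu = mu, r_squared = r2, accepted = TRUE, reason = NA_character_)
}

#' Growth factors and population parameters measured from data
#'
#' Computes the subperiod growth factors (QG, QI, QB, QCD), the
#' initiation/birth size-variance ratio and the generations spanned by C+D
#' from a lineage table with replication rounds, using the ori-normalized
#' length trajectory on triplet chains.
#'
#' @inheritParams subperiod_samples
#' @return A [growth_factors()] object, with `QCDprime` left at its default.
#' @export
measure_growth_factors <- function(lineages, rounds,
                                   ancestry_min = 4, QCDprime = 1.8) {
  ln <- as.data.frame(lineages)
  rd <- as.data.frame(rounds)
  keep <- ancestry_depth(ln) >= ancestry_min
  if ("burn_in" %in% names(ln)) keep <- keep & !ln$burn_in
  mi <- match(ln$parent_id, ln$cell_id)
  gi <- match(ln$parent_id[ifelse(is.na(mi), 1L, mi)], ln$cell_id)
  gi[is.na(mi)] <- NA
  ri <- match(ln$cell_id, rd$cell_id)
  rmi <- match(ln$parent_id, rd$cell_id)
  t_init <- rd$t_init_min[ri]
  t_init_mother <- rd$t_init_min[rmi]
  ok <- keep & !is.na(mi) & !is.na(gi) & !is.na(t_init) & !is.na(t_init_mother)
  idx <- which(ok)
  if (length(idx) < 10) stop("too few complete chains with rounds",
                             call. = FALSE)
  lB <- chain_lstar_vec(ln, idx, mi[idx], gi[idx], t_init[idx], FALSE)
  lB_mother <- chain_lstar_vec(ln, idx, mi[idx], gi[idx],
                               t_init_mother[idx], FALSE)
  L0 <- ln$L0_um[idx]
  Ld <- ln$Ld_um[idx]
  tau_CD <- mean(ln$t_div_min[idx] - t_init[idx])
  tau <- mean(ln$t_div_min[idx] - ln$t_birth_min[idx])
  growth_factors(
    QG = exp(mean(log(Ld / L0))),
    QI = exp(mean(log(lB / lB_mother))),
    QB = exp(mean(log(lB / L0))),
    QCD = exp(mean(log(Ld / lB))),
    QCDprime = QCDprime,
    var_ratio = stats::var(lB) / stats::var(L0),
    n_span = generations_spanned(tau_CD, tau)
  )
}
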