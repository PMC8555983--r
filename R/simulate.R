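# Stochastic forward simulation of single-cell lineages (mother-machine
# style: one daughter followed per division, independent channels in
# parallel). Growth is exponential within a cycle; added sizes are
# log-normal; division asymmetry is Gaussian on the inherited fraction.

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Parameters for the replication-limited (ICD) lineage simulator
#'
#' The ICD simulator implements the adder-input variant of
#' replication-limited division control: at each initiation the origins
#' double and two log-normal added lengths are drawn, one per origin for the
#' inter-initiation process (`mean_dI`, `cv_dI`) and one for the C+D process
#' (`mean_dCD`, `cv_dCD`); the cell divides when it has added `dCD` since
#' initiation. Newborn size is Gaussian with mean `Vd/2` and standard
#' deviation `alpha * Vd / 2`.
#'
#' @param mean_dI Mean added length per origin between initiations (um).
#' @param cv_dI CV of the inter-initiation added length.
#' @param mean_dCD Mean added length between initiation and division (um).
#' @param cv_dCD CV of the C+D added length.
#' @param alpha Division-asymmetry standard deviation (dimensionless,
#'   0 <= alpha < 0.5); the measured asymmetry
#'   (L0_sib - L0)/(L0_sib + L0) then has standard deviation `alpha`.
#' @param growth_rate_mean Mean single-cell growth rate (1/min).
#' @param growth_rate_cv CV of the per-cell growth rate (default 0.07).
#' @param n_cells Target number of recorded (post burn-in) cell cycles.
#' @param n_lineages Number of independent lineages (channels).
#' @param seed Integer RNG seed.
#' @param burn_in Generations discarded from all statistics (default 10).
#' @return A list of class `icd_params`.
#' @export
icd_params <- function(mean_dI = 1.0, cv_dI = 0.10,
                       mean_dCD = 1.6, cv_dCD = 0.10,
                       alpha = 0.05,
                       growth_rate_mean = log(2) / 90, growth_rate_cv = 0.07,
                       n_cells = 5000, n_lineages = 50,
                       seed = 1L, burn_in = 10L) {
  p <- list(model = "icd", mean_dI = mean_dI, cv_dI = cv_dI,
            mean_dCD = mean_dCD, cv_dCD = cv_dCD, alpha = alpha,
            growth_rate_mean = growth_rate_mean,
            growth_rate_cv = growth_rate_cv,
            n_cells = n_cells, n_lineages = n_lineages,
            seed = as.integer(seed), burn_in = as.integer(burn_in))
  validate_sim_params(p)
  structure(p, class = c("icd_params", "sim_params"))
}

#' Parameters for the concurrent-cycles (AND-gate) lineage simulator
#'
#' Each cycle computes two division candidates: the inter-division (H)
#' process completes when the cell has added `dH` (log-normal) since birth,
#' and the replication/segregation (C+D') process completes a log-normal
#' timer `tau_CDprime` after replication initiation. The cell divides at the
#' later of the two completion times (AND gate) and the limiting process is
#' recorded. Initiation follows the per-origin inter-initiation adder as in
#' [icd_params()].
#'
#' @inheritParams icd_params
#' @param mean_dH Mean added length of the inter-division process (um).
#' @param cv_dH CV of the inter-division added length.
#' @param tau_CDprime Mean duration of the replication/segregation timer
#'   (min), measured from initiation.
#' @param cv_CDprime CV of the timer duration (default 0.15).
#' @param gate How the two completed processes set division. `"and"`
#'   (default): the mechanistic AND gate — division at the later of the two
#'   completion times, so the limiting process co-fluctuates with cell
#'   sizes. `"lottery"`: the effective coupling scheme underlying the
#'   closed-form predictions — each division follows the H candidate with
#'   fixed probability `p_H` and the C+D' candidate otherwise,
#'   independently of the cell's fluctuations. The closed-form relations
#'   (see [predict_concurrent()]) are exact (small-noise) for the lottery
#'   scheme and only approximate for the AND gate near balance.
#' @param p_H Limiting probability used when `gate = "lottery"`.
#' @return A list of class `concurrent_params`.
#' @export
concurrent_params <- function(mean_dH = 1.75, cv_dH = 0.15,
                              mean_dI = 1.0, cv_dI = 0.10,
                              tau_CDprime = 67, cv_CDprime = 0.15,
                              alpha = 0.05,
                              growth_rate_mean = log(2) / 90,
                              growth_rate_cv = 0.07,
                              n_cells = 5000, n_lineages = 50,
                              seed = 1L, burn_in = 10L,
                              gate = c("and", "lottery"), p_H = NA_real_) {
  gate <- match.arg(gate)
  if (gate == "lottery" && (!is.finite(p_H) || p_H < 0 || p_H > 1)) {
    stop("gate = 'lottery' requires p_H in [0, 1]", call. = FALSE)
  }
  p <- list(model = "concurrent", mean_dH = mean_dH, cv_dH = cv_dH,
            mean_dI = mean_dI, cv_dI = cv_dI,
            tau_CDprime = tau_CDprime, cv_CDprime = cv_CDprime,
            alpha = alpha, gate = gate, p_H = p_H,
            growth_rate_mean = growth_rate_mean,
            growth_rate_cv = growth_rate_cv,
            n_cells = n_cells, n_lineages = n_lineages,
            seed = as.integer(seed), burn_in = as.integer(burn_in))
  validate_sim_params(p)
  structure(p, class = c("concurrent_params", "sim_params"))
}

validate_sim_params <- function(p) {
  means <- c(p$mean_dI, p$growth_rate_mean,
             p$mean_dCD, p$mean_dH)           # NULLs drop out
  if (any(means <= 0)) stop("mean parameters must be positive", call. = FALSE)
  if (!is.null(p$tau_CDprime) && p$tau_CDprime < 0) {
    stop("tau_CDprime must be non-negative", call. = FALSE)
  }
  cvs <- c(p$cv_dI, p$growth_rate_cv, p$cv_dCD, p$cv_dH, p$cv_CDprime)
  if (any(cvs < 0)) stop("CVs must be non-negative", call. = FALSE)
  if (p$alpha < 0 || p$alpha >= 0.5) {
    stop("alpha must lie in [0, 0.5)", call. = FALSE)
  }
  if (p$n_cells < 1 || p$n_lineages < 1) {
    stop("n_cells and n_lineages must be positive", call. = FALSE)
  }
  invisible(p)
}

#' Simulate lineages under the replication-limited (ICD) model
#'
#' @param params An [icd_params()] object.
#' @return A tibble of cell-cycle records (one row per cell) with columns
#'   `cell_id`, `parent_id`, `lineage`, `generation`, `burn_in` (logical),
#'   `t_birth_min`, `t_div_min`, `L0_um`, `Ld_um`, `L0_sibling_um`,
#'   `mu_per_min`, `t_init_min`, `L_init_um` (length at initiation, frame of
#'   the initiating cell), `d_I_um` (latent inter-initiation draw),
#'   `n_ori_init` and `limiting_process` (`NA` for ICD). The attribute
#'   `params` stores the generating parameters.
#' @export
simulate_icd <- function(params) {
  stopifnot(inherits(params, "icd_params"))
  simulate_lineages(params)
}

#' Simulate lineages under the concurrent-cycles (AND-gate) model
#'
#' @param params A [concurrent_params()] object.
#' @return As [simulate_icd()], with `limiting_process` set to `"H"` or
#'   `"CD"` for every division and the latent `d_H_um` draw recorded.
#' @export
simulate_concurrent <- function(params) {
  stopifnot(inherits(params, "concurrent_params"))
  simulate_lineages(params)
}

simulate_lineages <- function(p) {
  set.seed(p$seed)
  L <- p$n_lineages
  n_gen <- p$burn_in + ceiling(p$n_cells / L)
  concurrent <- identical(p$model, "concurrent")

  # steady-state-informed initial condition; burn-in removes the transient
  TH <- rep(2 * p$mean_dI, L)  # next initiation threshold, current frame
  if (concurrent) {
    V0 <- rep(p$mean_dH, L)
  } else {
    V0 <- rep(p$mean_dI + p$mean_dCD / 2, L)
  }
  tb <- rep(0, L)
  parent <- rep(NA_character_, L)
  sib <- rep(NA_real_, L)        # birth size of this cell's sibling
  pend <- rep(FALSE, L)          # round initiated in the mother, not yet
  pend_T <- rep(NA_real_, L)     # consumed by a division
  pend_VB <- rep(NA_real_, L)    # anchored (current-frame) initiation size
  scale0 <- 2 * p$mean_dI + if (concurrent) p$mean_dH else p$mean_dCD

  rows <- vector("list", n_gen)
  for (g in seq_len(n_gen)) {
    mu <- rlnorm_mean_cv(L, p$growth_rate_mean, p$growth_rate_cv)
    dI <- rlnorm_mean_cv(L, p$mean_dI, p$cv_dI)

    if (concurrent) {
      # round gating this division: carried from the mother, or initiated
      # here when the lineage reaches the per-origin adder threshold
      t_init <- pend_T
      Vinit <- pend_VB
      new_round <- !pend
      if (any(new_round)) {
        Vn <- pmax(TH[new_round], V0[new_round])   # clamp: init at birth
        t_init[new_round] <- tb[new_round] +
          log(Vn / V0[new_round]) / mu[new_round]
        Vinit[new_round] <- Vn
        # threshold for the following round, set at initiation
        TH[new_round] <- Vn + 2 * dI[new_round]
      }
      init_in_mother <- pend

      dH <- rlnorm_mean_cv(L, p$mean_dH, p$cv_dH)
      tH <- tb + log((V0 + dH) / V0) / mu
      tCD <- t_init + rlnorm_mean_cv(L, p$tau_CDprime, p$cv_CDprime)
      if (identical(p$gate, "lottery")) {
        h_wins <- stats::runif(L) < p$p_H
        t_div <- pmax(ifelse(h_wins, tH, tCD), t_init + 1e-9)
      } else {
        t_div <- pmax(tH, tCD)
        h_wins <- tH >= tCD
      }
      limiting <- ifelse(h_wins, "H", "CD")
      Vd <- V0 * exp(mu * (t_div - tb))

      # does the next round initiate before this division? (it then fires
      # on two origins: the threshold increment doubles so that the
      # anchored per-origin added size between initiations stays dI)
      S <- pmax(TH, V0)
      t_next <- tb + log(S / V0) / mu
      starts_here <- t_next < t_div
      dI2 <- rlnorm_mean_cv(L, p$mean_dI, p$cv_dI)
      pend <- starts_here
      pend_T <- ifelse(starts_here, t_next, NA_real_)
      pend_VB_cur <- ifelse(starts_here, S, NA_real_)
      TH[starts_here] <- S[starts_here] + 4 * dI2[starts_here]
    } else {
      Vinit <- pmax(TH, V0)
      t_init <- tb + log(Vinit / V0) / mu
      TH <- Vinit + 2 * dI
      init_in_mother <- rep(FALSE, L)
      dH <- rep(NA_real_, L)
      dCD <- rlnorm_mean_cv(L, p$mean_dCD, p$cv_dCD)
      Vd <- Vinit + dCD
      t_div <- tb + log(Vd / V0) / mu
      limiting <- rep(NA_character_, L)
      pend_VB_cur <- rep(NA_real_, L)
    }

    f <- if (p$alpha > 0) {
      pmin(pmax(stats::rnorm(L, 0.5, p$alpha / 2), 0.2), 0.8)
    } else {
      rep(0.5, L)
    }
    V0_next <- f * Vd
    V0_sib <- Vd - V0_next

    if (any(!is.finite(Vd)) || any(Vd <= 0) ||
        any(Vd > 1e4 * scale0) || any(V0_next < 1e-4 * scale0)) {
      stop("simulation diverged: no steady state for these parameters",
           call. = FALSE)
    }

    id <- sprintf("L%03d_G%03d", seq_len(L), g)
    rows[[g]] <- tibble::tibble(
      cell_id = id,
      parent_id = parent,
      lineage = seq_len(L),
      generation = g,
      burn_in = g <= p$burn_in,
      t_birth_min = tb,
      t_div_min = t_div,
      L0_um = V0,
      Ld_um = Vd,
      L0_sibling_um = sib,
      mu_per_min = mu,
      t_init_min = t_init,
      L_init_um = Vinit,
      d_I_um = dI,
      d_H_um = dH,
      init_in_mother = init_in_mother,
      n_ori_init = ifelse(init_in_mother, 4L, 2L),   # post-firing count
      limiting_process = limiting
    )

    # transform thresholds and pending anchored sizes to the daughter frame
    shift <- Vd / 2 - V0_next
    TH <- TH / 2 - shift
    pend_VB <- pend_VB_cur / 2 - shift
    if (any(!is.finite(TH)) || any(TH <= 0) ||
        any(pend & (!is.finite(pend_VB) | pend_VB <= 0))) {
      stop("simulation diverged: initiation threshold collapsed",
           call. = FALSE)
    }
    V0 <- V0_next
    sib <- V0_sib
    tb <- t_div
    parent <- id
  }

  out <- do.call(rbind, rows)
  attr(out, "params") <- p
  out
}

#' Fraction of divisions limited by the inter-division process
#'
#' Empirical counterpart of the concurrent-cycles parameter `pH`: the
#' fraction of post-burn-in divisions for which the recorded limiting
#' process is `"H"`.
#'
#' @param sim A lineage table from [simulate_concurrent()].
#' @return A probability in \[0, 1\].
#' @export
emergent_ph <- function(sim) {
  keep <- !sim$burn_in & !is.na(sim$limiting_process)
  if (!any(keep)) {
    stop("no post-burn-in divisions with a recorded limiting process",
         call. = FALSE)
  }
  mean(sim$limiting_process[keep] == "H")
}

#' Simulate a series of increasing mean D period
#'
#' In-silico analogue of the width-perturbation (A22) series: the C period,
#' the replication/segregation timer and the inter-initiation adder are held
#' fixed while the inter-division process is made progressively more
#' limiting by increasing its mean added size `mean_dH`. The emergent mean D
#' period (division lagging replication termination) then increases along
#' the series, the limiting probability pH is non-decreasing, and the
#' measured `zeta_CD` drops toward -1.
#'
#' @param base A [concurrent_params()] object; all parameters except
#'   `mean_dH` are shared across the series.
#' @param dH_values Non-decreasing vector of mean inter-division added sizes
#'   (um).
#' @return A list of lineage tables, one per value, named by `dH_values`.
#' @export
increase_d_series <- function(base, dH_values) {
  stopifnot(inherits(base, "concurrent_params"))
  if (is.unsorted(dH_values)) {
    stop("dH_values must be non-decreasing", call. = FALSE)
  }
  out <- lapply(dH_values, function(dh) {
    p <- base
    p$mean_dH <- dh
    simulate_concurrent(p)
  })
  names(out) <- format(dH_values)
  out
}
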