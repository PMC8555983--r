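#' Convert a size-growth-plot slope to an adder-plot coupling constant
#'
#' Single-cell size control over a cell-cycle subperiod can be quantified
#' either on the size-growth plot (slope `lambda`, log final size vs log
#' initial size) or on the adder plot (slope `zeta`, added size vs initial
#' size, both mean-normalized). For small fluctuations the two are in 1:1
#' correspondence through the mean multiplicative growth factor `Q` of the
#' subperiod:
#'
#'   zeta = (1 - lambda) * Q - 1
#'
#' For a symmetrically dividing cell over the full cycle Q is close to 2, so
#' an adder (`zeta = 0`) corresponds to `lambda = 0.5`, a timer (`lambda = 0`)
#' to `zeta = Q - 1`, and a sizer (`lambda = 1`) to `zeta = -1`.
#'
#' @param lam Size-growth-plot slope (dimensionless).
#' @param Q Mean multiplicative growth factor over the subperiod; must be
#'   positive.
#' @return The adder-plot coupling constant (dimensionless).
#' @seealso [lambda_from_zeta()], [growth_factor()]
#' @export
zeta_from_lambda <- function(lam, Q) {
  check_positive_q(Q)
  (1 - lam) * Q - 1
}

#' Convert an adder-plot coupling constant to a size-growth-plot slope
#'
#' Inverse of [zeta_from_lambda()]: `lambda = 1 - (zeta + 1) / Q`. The two
#' conversions round-trip to machine precision.
#'
#' @param zeta Adder-plot coupling constant (dimensionless).
#' @param Q Mean multiplicative growth factor over the subperiod; positive.
#' @return The size-growth-plot slope (dimensionless).
#' @export
lambda_from_zeta <- function(zeta, Q) {
  check_positive_q(Q)
  1 - (zeta + 1) / Q
}

check_positive_q <- function(Q) {
  if (any(!is.finite(Q)) || any(Q <= 0)) {
    stop("growth factor Q must be positive and finite", call. = FALSE)
  }
  invisible(Q)
}

#' Mean multiplicative growth factor over a subperiod
#'
#' Computes `Q = exp(mean(log(ori_factor * final / initial)))`, the geometric
#' mean fold-change in size over a subperiod. `ori_factor` carries the
#' origin-number correction (a power of two) used when the subperiod spans
#' division or initiation events, e.g. `Q_CD = exp <log 2^n V0 / VB>` for a
#' C+D period spanning `n` divisions.
#'
#' @param initial_sizes,final_sizes Equal-length vectors of positive sizes
#'   (um).
#' @param ori_factor Integer power of 2 correcting for origin multiplicity
#'   (default 1).
#' @return The growth factor (dimensionless, > 0).
#' @export
growth_factor <- function(initial_sizes, final_sizes, ori_factor = 1) {
  if (length(initial_sizes) != length(final_sizes)) {
    stop("initial and final size vectors must have equal length", call. = FALSE)
  }
  if (any(initial_sizes <= 0) || any(final_sizes <= 0)) {
    stop("sizes must be positive", call. = FALSE)
  }
  exp(mean(log(ori_factor * final_sizes / initial_sizes)))
}

#' Number of generations spanned by the C+D period
#'
#' `n = floor(tau_CD / tau) + 1`: the number of cell cycles between
#' replication initiation and the division it controls. `n = 1` means
#' initiation and division happen in the same cycle (non-overlapping rounds).
#'
#' @param tau_CD Mean C+D duration (min), non-negative.
#' @param tau Mean interdivision time (min), positive.
#' @return Integer number of generations (>= 1).
#' @export
generations_spanned <- function(tau_CD, tau) {
  stopifnot(tau > 0, tau_CD >= 0)
  as.integer(floor(tau_CD / tau) + 1)
}

#' Bundle of growth factors and population parameters for model predictions
#'
#' Container for the multiplicative growth factors of the cell-cycle
#' subperiods, the variance ratio of initiation to birth size, and the number
#' of generations spanned by C+D. `QCDprime` is the growth factor of the
#' (non-measurable) replication/segregation C+D' process; following the
#' approximation that it equals the measured unperturbed Q_CD, it defaults
#' to 1.8.
#'
#' @param QG,QI,QB,QCD Growth factors of the G (inter-division), I
#'   (inter-initiation), B (birth-to-initiation) and C+D subperiods. For
#'   symmetrically dividing cells QG and QI are close to 2.
#' @param QCDprime Growth factor of the C+D' process (default 1.8).
#' @param var_ratio Variance ratio sigma^2_VB / sigma^2_V0 of (per-origin)
#'   initiation size to birth size; positive.
#' @param n_span Generations spanned by C+D (see [generations_spanned()]).
#' @return An object of class `growth_factors` (a list).
#' @export
growth_factors <- function(QG = 2, QI = 2, QB = NA_real_, QCD = NA_real_,
                           QCDprime = 1.8, var_ratio = 1, n_span = 1L) {
  for (q in list(QG, QI, QCDprime)) check_positive_q(q)
  if (!is.finite(var_ratio) || var_ratio <= 0) {
    stop("var_ratio must be positive", call. = FALSE)
  }
  if (n_span < 1) stop("n_span must be >= 1", call. = FALSE)
  structure(
    list(QG = QG, QI = QI, QB = QB, QCD = QCD, QCDprime = QCDprime,
         var_ratio = var_ratio, n_span = as.integer(n_span)),
    class = "growth_factors"
  )
}

#' @export
print.growth_factors <- function(x, ...) {
  cat("Growth factors: QG =", format(x$QG, digits = 4),
      " QI =", format(x$QI, digits = 4),
      " QCD =", format(x$QCD, digits = 4),
      " QCD' =", format(x$QCDprime, digits = 4), "\n")
  cat("  var(VB)/var(V0) =", format(x$var_ratio, digits = 4),
      "  n_span =", x$n_span, "\n")
  invisible(x)
}

new_model_prediction <- function(model, zeta_G, zeta_B, zeta_CD,
                                 approximate = FALSE) {
  structure(
    list(model = model, zeta_G = zeta_G, zeta_B = zeta_B, zeta_CD = zeta_CD,
         approximate = approximate),
    class = "model_prediction"
  )
}

#' @export
print.model_prediction <- function(x, ...) {
  cat(sprintf("%s model prediction:%s\n", x$model,
              if (isTRUE(x$approximate)) " (approximate, n_span > 1)" else ""))
  cat(sprintf("  zeta_G  = %+.4f\n  zeta_B  = %+.4f\n  zeta_CD = %+.4f\n",
              x$zeta_G, x$zeta_B, x$zeta_CD))
  invisible(x)
}

#' Predicted coupling constants for replication-limited (ICD) models
#'
#' In ICD models, replication initiation is controlled by an inter-initiation
#' process with coupling constant `zeta_I`, and cell division is set by a
#' process coupling division size to size at initiation with coupling
#' constant `zeta_CD`; division has no influence on replication. The
#' inter-division slope `zeta_G` and birth-to-initiation slope `zeta_B` are
#' then emergent correlations:
#'
#'   (zeta_G + 1) = (zeta_CD + 1)^2 (zeta_I + 1)   var_ratio / 2^(2n)
#'   (zeta_B + 1) = (zeta_CD + 1)   (zeta_I + 1)^n var_ratio / 2^(2n)
#'
#' with `n` the number of generations spanned by C+D and `var_ratio`
#' the ratio of initiation-size to birth-size variance. Predictions with
#' `n > 1` are flagged approximate; they are validated by simulation.
#'
#' @param zeta_I,zeta_CD Input coupling constants (dimensionless).
#' @param gf A [growth_factors()] object supplying `var_ratio` and `n_span`.
#' @return A `model_prediction` with fields `zeta_G`, `zeta_B`, `zeta_CD`.
#' @export
predict_icd <- function(zeta_I, zeta_CD, gf) {
  stopifnot(inherits(gf, "growth_factors"))
  n <- gf$n_span
  vr <- gf$var_ratio
  zg <- (zeta_CD + 1)^2 * (zeta_I + 1) * vr / 4^n - 1
  zb <- (zeta_CD + 1) * (zeta_I + 1)^n * vr / 4^n - 1
  new_model_prediction("ICD", zg, zb, zeta_CD, approximate = n > 1L)
}

#' Predicted coupling constants for the Witz-type double-adder model
#'
#' The double-adder model is the ICD special case in which both the
#' inter-initiation and the C+D processes are perfect adders
#' (`zeta_I = zeta_CD = 0`):
#'
#'   (zeta_G + 1) = (zeta_B + 1) = var_ratio / 2^(2n)
#'
#' @inheritParams predict_icd
#' @return A `model_prediction`.
#' @export
predict_witz <- function(gf) {
  out <- predict_icd(0, 0, gf)
  out$model <- "WITZ"
  out
}

#' Predicted coupling constants for the concurrent-cycles model
#'
#' Two processes must both complete before division (an AND gate): an
#' inter-division process anchored at birth with coupling `zeta_H`, and a
#' replication/segregation process (C+D') anchored at initiation, assumed a
#' pure timer. `pH` is the probability that the inter-division process is
#' the later (limiting) one. The emergent adder-plot slopes are
#'
#'   (zeta_CD + 1) = (1 - pH) QCD' / (1 - pH (zeta_H+1)(zeta_I+1) / 4)
#'   (zeta_B  + 1) = (zeta_CD + 1)(zeta_I + 1) var_ratio / 4
#'   (zeta_G  + 1) = pH (zeta_H + 1) + (1 - pH) QCD' (zeta_B + 1)
#'
#' valid for initiation and division in the same cycle (`n_span = 1`); for
#' `n_span > 1` the returned prediction is flagged approximate and should be
#' checked by simulation.
#'
#' @param pH Probability that the inter-division process is limiting, in
#'   \[0, 1\].
#' @param zeta_H Coupling constant of the inter-division process.
#' @param zeta_I Coupling constant of the inter-initiation process.
#' @param gf A [growth_factors()] object supplying `QCDprime` and
#'   `var_ratio`.
#' @return A `model_prediction`.
#' @export
predict_concurrent <- function(pH, zeta_H, zeta_I, gf) {
  stopifnot(inherits(gf, "growth_factors"))
  if (pH < 0 || pH > 1) stop("pH must lie in [0, 1]", call. = FALSE)
  Q <- gf$QCDprime
  denom <- 1 - pH * (zeta_H + 1) * (zeta_I + 1) / 4
  if (abs(denom) < 1e-12) {
    stop("singular concurrent-cycles prediction: pH (zeta_H+1)(zeta_I+1) = 4",
         call. = FALSE)
  }
  zcd <- (1 - pH) * Q / denom - 1
  zb <- (zcd + 1) * (zeta_I + 1) * gf$var_ratio / 4 - 1
  zg <- pH * (zeta_H + 1) + (1 - pH) * Q * (zb + 1) - 1
  new_model_prediction("CONCURRENT", zg, zb, zcd,
                       approximate = gf$n_span > 1L)
}

#' Predicted coupling constants for the adder-adder concurrent-cycles model
#'
#' Concurrent-cycles prediction with both the inter-initiation and the
#' inter-division processes set to adders (`zeta_I = zeta_H = 0`). As `pH`
#' goes from 0 (replication always limiting) to 1 (inter-division process
#' always limiting), `zeta_CD` interpolates monotonically from `QCD' - 1`
#' down to -1.
#'
#' @inheritParams predict_concurrent
#' @return A `model_prediction`.
#' @export
predict_concurrent_adder_adder <- function(pH, gf) {
  out <- predict_concurrent(pH, 0, 0, gf)
  out$model <- "CONCURRENT_ADDER_ADDER"
  out
}

#' Fit the limiting probability pH of the inter-division process
#'
#' Inverts the concurrent-cycles relations to estimate `pH`, the probability
#' that the replication-independent inter-division process is the limiting
#' one, from measured adder-plot slopes.
#'
#' In `"fixed_zetaH"` mode (inter-division process assumed an adder,
#' `zeta_H = 0`), `pH` follows in closed form from the C+D relation of the
#' adder-adder scheme:
#'
#'   pH = (QCD' - (zeta_CD + 1)) / (QCD' - (zeta_CD + 1) / 4)
#'
#' clipped to \[0, 1\] with a warning if sampling noise pushes it outside.
#'
#' In `"free_zetaH"` mode, `(pH, zeta_H)` jointly minimize the weighted
#' squared residuals of the inter-division and C+D relations (with
#' `zeta_I = 0`), weights being inverse squared standard errors of the
#' observed slopes.
#'
#' @param observed A data frame (or tibble) of observed slopes with columns
#'   `period` (`"G"`, `"I"` or `"CD"`), `zeta`, and `se`. `"fixed_zetaH"`
#'   mode requires at least the CD row; `"free_zetaH"` also requires the G
#'   row.
#' @param gf A [growth_factors()] object (`QCDprime`, `var_ratio`).
#' @param mode `"fixed_zetaH"` (default) or `"free_zetaH"`.
#' @return An object of class `concurrent_fit`: list with `pH`, `zeta_H`,
#'   `residual`, `mode`, and `pH_se` (delta-method propagation of the CD
#'   slope's standard error in fixed mode; `NA` otherwise).
#' @export
fit_ph <- function(observed, gf, mode = c("fixed_zetaH", "free_zetaH")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gf, "growth_factors"))
  observed <- as.data.frame(observed)
  if (!all(c("period", "zeta") %in% names(observed))) {
    stop("observed must have columns period and zeta", call. = FALSE)
  }
  if (!"se" %in% names(observed)) observed$se <- NA_real_
  get_row <- function(p) {
    i <- which(observed$period == p)
    if (length(i) == 0) return(NULL)
    observed[i[1], ]
  }
  cd <- get_row("CD")
  if (is.null(cd)) stop("observed slopes must include the CD period", call. = FALSE)
  Q <- gf$QCDprime

  if (mode == "fixed_zetaH") {
    x <- cd$zeta + 1
    if (x > Q) {
      warning("observed zeta_CD + 1 exceeds QCDprime; pH clipped to 0")
      ph <- 0
      ph_se <- NA_real_
    } else {
      ph <- (Q - x) / (Q - x / 4)
      if (ph < 0 || ph > 1) {
        warning("closed-form pH outside [0, 1]; clipped")
        ph <- min(max(ph, 0), 1)
      }
      # d pH / d zeta_CD = -(3/4) Q / (Q - x/4)^2
      ph_se <- if (is.finite(cd$se)) abs(-0.75 * Q / (Q - x / 4)^2) * cd$se else NA_real_
    }
    resid <- predict_concurrent_adder_adder(ph, gf)$zeta_CD - cd$zeta
    return(structure(
      list(pH = ph, zeta_H = 0, residual = resid, mode = mode, pH_se = ph_se),
      class = "concurrent_fit"
    ))
  }

  g <- get_row("G")
  if (is.null(g)) {
    stop("free_zetaH mode requires both G and CD observed slopes", call. = FALSE)
  }
  w <- function(se) if (is.finite(se) && se > 0) 1 / se^2 else 1
  obj <- function(par) {
    pred <- tryCatch(predict_concurrent(par[1], par[2], 0, gf),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e12)
    w(g$se) * (pred$zeta_G - g$zeta)^2 + w(cd$se) * (pred$zeta_CD - cd$zeta)^2
  }
  fit <- stats::optim(c(0.5, 0), obj, method = "L-BFGS-B",
                      lower = c(0, -1), upper = c(1, 1))
  structure(
    list(pH = fit$par[1], zeta_H = fit$par[2], residual = fit$value,
         mode = mode, pH_se = NA_real_),
    class = "concurrent_fit"
  )
}

#' @export
print.concurrent_fit <- function(x, ...) {
  cat(sprintf("Concurrent-cycles fit (%s): pH = %.3f", x$mode, x$pH))
  if (is.finite(x$pH_se)) cat(sprintf(" +/- %.3f", x$pH_se))
  if (x$mode == "free_zetaH") cat(sprintf(", zeta_H = %+.3f", x$zeta_H))
  cat(sprintf("  (residual %.2e)\n", x$residual))
  invisible(x)
}
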