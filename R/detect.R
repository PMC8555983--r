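# Replication-round detection on per-frame replisome-signal traces.
# The replisome signal is summarized per frame as Itot (median-subtracted
# summed excess intensity): Itot > 0 marks ongoing replication. Rounds are
# maximal positive runs of at least 25 min whose endpoints fall inside
# population-derived windows around the average initiation and termination
# times; the analysis works on mother-daughter trace pairs so that rounds
# initiated in the mother are captured.

#' Replisome-position density map aligned to division
#'
#' Builds the conditional probability map `p(y | t - td)` of finding a
#' replisome focus at relative cell position `y = z/L` at time `t - td`
#' before division, and the per-column occupancy (fraction of frames with at
#' least one focus), used to locate average initiation/termination times.
#'
#' @param frames Frames tibble (see [read_frames()]).
#' @param lineages Lineage tibble supplying division times.
#' @param frame_interval Frame interval (min), also the time-bin width.
#' @param n_pos_bins Number of relative-position bins (default 20).
#' @return An object of class `density_map`: list with `t_centers` (min,
#'   relative to division), `y_centers`, `p` (position x time matrix, each
#'   occupied column summing to 1), `occupancy`, `n_frames`.
#' @export
density_map <- function(frames, lineages, frame_interval, n_pos_bins = 20) {
  fr <- as.data.frame(frames)
  ln <- as.data.frame(lineages)
  ci <- match(fr$cell_id, ln$cell_id)
  td <- ln$t_div_min[ci]
  if (all(is.na(td))) stop("no frames match the lineage table", call. = FALSE)
  # pair alignment: each cell contributes its own frames and its mother's
  # frames, both aligned to the cell's division, so that rounds initiated
  # in the mother appear at their true time before division
  ch <- match(ln$cell_id, ln$parent_id)       # a daughter of each cell
  td_child <- ln$t_div_min[ch][ci]
  t_rel <- c(fr$t_min - td, (fr$t_min - td_child)[!is.na(td_child)])
  fr <- rbind(fr, fr[!is.na(td_child), ])
  keep <- !is.na(t_rel)
  fr <- fr[keep, ]; t_rel <- t_rel[keep]

  bin <- floor(t_rel / frame_interval + 0.5)
  bins <- seq(min(bin), max(bin))
  t_centers <- bins * frame_interval
  foci <- parse_focus_positions(fr$focus_rel_positions)
  nfoci <- lengths(foci)

  y_breaks <- seq(0, 1, length.out = n_pos_bins + 1)
  y_centers <- (y_breaks[-1] + y_breaks[-length(y_breaks)]) / 2
  p <- matrix(0, nrow = n_pos_bins, ncol = length(bins))
  occ_num <- integer(length(bins))
  tot <- integer(length(bins))
  col_of <- match(bin, bins)
  for (j in seq_along(bins)) {
    rows <- which(col_of == j)
    tot[j] <- length(rows)
    if (length(rows) == 0) next
    occ_num[j] <- sum(nfoci[rows] > 0)
    ys <- unlist(foci[rows])
    ys <- ys[is.finite(ys) & ys >= 0 & ys <= 1]
    if (length(ys) > 0) {
      h <- graphics::hist(ys, breaks = y_breaks, plot = FALSE)$counts
      p[, j] <- h / sum(h)
    }
  }
  occupancy <- ifelse(tot > 0, occ_num / tot, NA_real_)
  structure(
    list(t_centers = t_centers, y_centers = y_centers, p = p,
         occupancy = occupancy, n_frames = tot,
         frame_interval = frame_interval),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "Replisome density map: %d position bins x %d time bins (%g-min frames)\n",
    length(x$y_centers), length(x$t_centers), x$frame_interval))
  invisible(x)
}

#' Average initiation and termination times from a density map
#'
#' Locates the average replication initiation and termination times
#' (relative to division) as the points of steepest rise and fall of the
#' column-wise occupancy profile, after a 3-bin moving-average smoothing.
#' These population-level estimates seed the per-cell detection windows;
#' like the inflection points of the printed maps, they need not coincide
#' exactly with the mean of per-cell event times.
#'
#' @param map A [density_map()].
#' @return Named numeric vector `c(t_init = , t_term = )`, minutes relative
#'   to division (negative values).
#' @export
average_event_times <- function(map) {
  stopifnot(inherits(map, "density_map"))
  occ <- map$occupancy
  occ[is.na(occ)] <- 0
  # restrict to the contiguous well-sampled part of the aligned window:
  # sparsely covered columns at the ends are data boundaries, not signal
  valid <- which(map$n_frames >= 0.5 * max(map$n_frames))
  lo <- min(valid); hi <- max(valid)
  occ <- occ[lo:hi]
  tc <- map$t_centers[lo:hi]
  if (max(occ) <= 0) stop("no occupied band in the density map", call. = FALSE)
  sm <- stats::filter(occ, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- occ[is.na(sm)]
  d <- diff(as.numeric(sm))
  # termination of the round most recently completed before division: the
  # latest comparably steep fall (the pair-aligned profile also contains
  # the mother's own round one generation earlier); initiation: the latest
  # comparably steep rise preceding that fall. The outermost bins are
  # excluded as boundary artifacts.
  K <- length(d)
  if (K < 6) stop("occupancy profile too short for inflection detection",
                  call. = FALSE)
  ok_fall <- 3:(K - 2)
  dmin <- min(d[ok_fall])
  if (dmin >= 0) stop("no falling edge in the occupancy profile",
                      call. = FALSE)
  falls <- ok_fall[d[ok_fall] <= 0.6 * dmin]
  fall <- falls[length(falls)]
  if (fall < 4) stop("no occupied band before the steepest fall",
                     call. = FALSE)
  dr <- d[3:(fall - 1)]
  rises <- which(dr >= 0.6 * max(dr)) + 2L
  rise <- rises[length(rises)]
  mid <- function(j) (tc[j] + tc[j + 1]) / 2
  c(t_init = mid(rise), t_term = mid(fall))
}

positive_runs <- function(t, pos) {
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(first = t[starts[keep]], last = t[ends[keep]],
             n = r$lengths[keep])
}

#' Detect replication rounds from mother-daughter trace pairs
#'
#' For every cell whose mother is present, the mother and cell traces are
#' concatenated and maximal runs with `Itot > 0` of duration at least
#' `min_duration` are candidate rounds. Run endpoints are corrected for
#' frame-grid censoring by half a frame interval at each end (a signal
#' observed on frames `[f, l]` is taken to start at `f - dt/2` and end at
#' `l + dt/2`), which makes the recovered C and D durations unbiased.
#' Candidates must start and end within `window_frames` frames of the
#' population-average initiation and termination times (obtained from the
#' occupancy profile of the division-aligned density map unless `windows`
#' is supplied); the largest admissible run is selected, ties broken toward
#' the later run. The C period is the corrected run duration and the D
#' period is the (non-negative) lag from corrected termination to division;
#' a round whose signal reaches the cell's last frame terminates at
#' division and gets `D = 0`.
#'
#' @param frames Frames tibble covering mothers and daughters.
#' @param lineages Lineage tibble (parent links and division times).
#' @param frame_interval Frame interval (min; 6 or 8 in the supported
#'   acquisition settings).
#' @param min_duration Minimum corrected run duration (min; default 25).
#' @param window_frames Half-width of the admissible-endpoint windows, in
#'   frames (default 11).
#' @param windows Optional list with numeric `init` and `term` (each
#'   `c(lo, hi)`, min relative to division) overriding the two-pass
#'   bootstrap.
#' @return A rounds tibble: `cell_id`, `detected`, `t_init_min`,
#'   `t_term_min`, `C_min`, `D_min`, `n_span`; the attribute
#'   `detection_rate` gives the fraction of eligible pairs with a detected
#'   round, and `windows` the windows used.
#' @export
detect_rounds <- function(frames, lineages, frame_interval,
                          min_duration = 25, window_frames = 11,
                          windows = NULL) {
  fr <- as.data.frame(frames)
  ln <- as.data.frame(lineages)
  dt <- frame_interval

  if (is.null(windows)) {
    ev <- average_event_times(density_map(fr, ln, dt))
    windows <- list(
      init = c(ev[["t_init"]] - window_frames * dt,
               ev[["t_init"]] + window_frames * dt),
      term = c(ev[["t_term"]] - window_frames * dt,
               ev[["t_term"]] + window_frames * dt)
    )
  }

  by_cell <- split(seq_len(nrow(fr)), fr$cell_id)
  has_mother <- !is.na(ln$parent_id) & ln$parent_id %in% ln$cell_id
  eligible <- which(has_mother & ln$cell_id %in% names(by_cell) &
                      ln$parent_id %in% names(by_cell))
  # process pairs in division order so that a round already assigned to the
  # mother is not assigned again to the daughter (each division consumes
  # one replication round)
  eligible <- eligible[order(ln$t_div_min[eligible])]
  assigned_init <- new.env(parent = emptyenv())

  res <- vector("list", length(eligible))
  for (k in seq_along(eligible)) {
    i <- eligible[k]
    rows <- c(by_cell[[ln$parent_id[i]]], by_cell[[ln$cell_id[i]]])
    tt <- fr$t_min[rows]
    o <- order(tt)
    tt <- tt[o]
    pos <- fr$Itot[rows][o] > 0
    td <- ln$t_div_min[i]
    tb <- ln$t_birth_min[i]
    last_frame <- max(fr$t_min[by_cell[[ln$cell_id[i]]]])

    runs <- positive_runs(tt, pos)
    if (nrow(runs) > 0) {
      t0 <- runs$first - dt / 2
      t1 <- runs$last + dt / 2
      dur <- t1 - t0
      adm <- dur >= min_duration &
        runs$first > tt[1] + 1e-9 &   # truncated at trace start: no
                                      # observable initiation point
        (t0 - td) >= windows$init[1] & (t0 - td) <= windows$init[2] &
        (t1 - td) >= windows$term[1] & (t1 - td) <= windows$term[2]
      mother_init <- get0(ln$parent_id[i], envir = assigned_init,
                          ifnotfound = NA_real_)
      if (is.finite(mother_init)) {
        adm <- adm & abs(t0 - mother_init) > dt / 2
      }
      cand <- which(adm)
    } else cand <- integer(0)

    if (length(cand) == 0) {
      res[[k]] <- list(cell_id = ln$cell_id[i], detected = FALSE,
                       t_init_min = NA_real_, t_term_min = NA_real_,
                       C_min = NA_real_, D_min = NA_real_, n_span = NA_integer_)
      next
    }
    best <- cand[order(dur[cand], t1[cand])]   # largest, ties -> later
    best <- best[length(best)]
    t_init <- t0[best]
    t_term <- t1[best]
    # signal running into the last observed frame: terminates at division
    if (runs$last[best] >= last_frame - 1e-9) t_term <- td
    t_term <- min(t_term, td)
    assign(ln$cell_id[i], t_init, envir = assigned_init)
    res[[k]] <- list(
      cell_id = ln$cell_id[i], detected = TRUE,
      t_init_min = t_init,
      t_term_min = t_term,
      C_min = t_term - t_init,
      D_min = max(0, td - t_term),
      n_span = if (t_init < tb) 2L else 1L
    )
  }
  out <- tibble::as_tibble(do.call(rbind, lapply(res, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })))
  attr(out, "detection_rate") <- mean(out$detected)
  attr(out, "windows") <- windows
  out
}
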