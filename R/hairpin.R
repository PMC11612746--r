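# Hairpin analysis: scoring, detection, counting statistics, track linking
# across frames, and hairpin diffusivity along the backbone.
#
# A hairpin is a localized back-fold of the chain in the nematic
# background: two well-aligned arms pointing in opposite directions along
# the director, joined by a sudden turn.  Its polarity is +1/2 when it
# opens toward +n and -1/2 when it opens toward -n; polarity can only
# change through chain-end events or pair creation/annihilation.

#' Per-monomer hairpin scores
#'
#' For monomer j, let `P-` be the mean director projection `t . n` of the
#' `w` bonds before j and `P+` that of the `w` bonds after.  The score is
#' `(|P-| + |P+|)/2` when the two arms point in opposite directions along
#' the director (`sign(P-) != sign(P+)`) and 0 otherwise: close to 1 at
#' the apex of an ideal U-turn, 0 everywhere on a straight rod.  End
#' monomers without a full window on both sides score 0.
#'
#' @param pos N x 3 unwrapped bead positions.
#' @param nhat unit director.
#' @param w arm window in bonds (default 3).
#' @return list with `score` (length N), `P_minus`, `P_plus`.
#' @export
hairpin_scores <- function(pos, nhat = c(0, 0, 1), w = 3) {
  N <- nrow(pos)
  if (N < 2 * w + 1) stop("chain too short for the scoring window")
  nhat <- nhat / sqrt(sum(nhat^2))
  proj <- drop(bond_tangents(pos) %*% nhat) # length N - 1
  score <- Pm <- Pp <- rep(0, N)
  for (j in (w + 1):(N - w)) {
    pm <- mean(proj[(j - w):(j - 1)])
    pp <- mean(proj[j:(j + w - 1)])
    Pm[j] <- pm
    Pp[j] <- pp
    if (sign(pm) != sign(pp) && pm != 0 && pp != 0) {
      score[j] <- (abs(pm) + abs(pp)) / 2
    }
  }
  list(score = score, P_minus = Pm, P_plus = Pp)
}

#' Detect hairpins in one conformation
#'
#' Local maxima of the hairpin score above a threshold, with non-maximum
#' suppression within a minimum contour separation.  Polarity is read off
#' the arm signs: a fold whose arms extend toward `+n` from the apex
#' (`P- < 0 < P+`) is a +1/2 hairpin.
#'
#' @param pos N x 3 unwrapped positions.
#' @param nhat unit director.
#' @param w arm window (bonds).
#' @param threshold minimum score (default 0.5).
#' @param min_sep minimum separation between detections, in bonds
#'   (default `w`).
#' @return data.frame with one row per hairpin: `s` (monomer index),
#'   `score`, `polarity` (+0.5/-0.5); zero rows when none.
#' @export
detect_hairpins <- function(pos, nhat = c(0, 0, 1), w = 3, threshold = 0.5,
                            min_sep = w) {
  hs <- hairpin_scores(pos, nhat, w)
  sc <- hs$score
  cand <- which(sc >= threshold)
  # local maxima only (plateaus keep their first index)
  cand <- cand[vapply(cand, function(j) {
    left <- if (j > 1) sc[j - 1] else -Inf
    right <- if (j < length(sc)) sc[j + 1] else -Inf
    sc[j] > left && sc[j] >= right
  }, logical(1))]
  cand <- cand[order(-sc[cand], cand)]
  keep <- integer(0)
  for (j in cand) {
    if (all(abs(j - keep) > min_sep)) keep <- c(keep, j)
  }
  keep <- sort(keep)
  data.frame(s = keep,
             score = sc[keep],
             polarity = ifelse(hs$P_plus[keep] > 0, 0.5, -0.5))
}

#' Hairpin counting statistics
#'
#' Empirical distribution of the number of hairpins per frame and its
#' maximum-likelihood Poisson fit (`lambda = mean count`).
#'
#' @param counts integer vector of per-frame hairpin counts.
#' @return list with `mean`, `lambda` (MLE, equal to the mean), `sd`,
#'   and `pdf`, a data.frame with `n`, `p_emp`, `p_pois`.
#' @export
hairpin_count_statistics <- function(counts) {
  lam <- mean(counts)
  nmax <- max(counts, 0)
  tab <- tabulate(counts + 1, nbins = nmax + 1)
  list(mean = lam, lambda = lam, sd = stats::sd(counts),
       pdf = data.frame(n = 0:nmax,
                        p_emp = tab / length(counts),
                        p_pois = stats::dpois(0:nmax, lam)))
}

#' Link per-frame hairpin detections into tracks
#'
#' Greedy nearest-neighbour matching of detections between consecutive
#' frames with cost `|delta s|` along the contour, rejecting jumps beyond
#' `max_jump`; matches must preserve polarity.  Ties in cost are resolved
#' in favour of the lower monomer index.  Unmatched detections open new
#' tracks, classified `end_entry` when within `w` monomers of a chain end
#' and otherwise `pair_creation` (paired with the nearest simultaneous
#' birth of opposite polarity when one exists); track terminations are
#' classified symmetrically (`end_exit` / `pair_annihilation`).
#'
#' @param records data.frame of detections with columns `frame`, `s`,
#'   `polarity` (e.g. rows accumulated from [detect_hairpins()]).
#' @param N chain length (for end classification).
#' @param max_jump maximum contour jump between consecutive frames
#'   (bonds, default 4).
#' @param w end window for birth/death classification (default 3).
#' @return list with `points` (data.frame `track`, `frame`, `s`,
#'   `polarity`) and `tracks` (one row per track: `track`, `polarity`,
#'   `birth_frame`, `death_frame`, `lifetime`, `birth_type`,
#'   `death_type`).
#' @export
link_hairpin_tracks <- function(records, N, max_jump = 4, w = 3) {
  if (nrow(records) == 0) {
    return(list(points = data.frame(track = integer(0), frame = integer(0),
                                    s = integer(0), polarity = numeric(0)),
                tracks = data.frame(track = integer(0), polarity = numeric(0),
                                    birth_frame = integer(0),
                                    death_frame = integer(0),
                                    lifetime = integer(0),
                                    birth_type = character(0),
                                    death_type = character(0))))
  }
  records <- records[order(records$frame, records$s), ]
  frames <- sort(unique(records$frame))
  next_id <- 1L
  # active: data.frame(track, s, polarity)
  active <- data.frame(track = integer(0), s = integer(0),
                       polarity = numeric(0))
  points <- list()
  births <- list()
  deaths <- list()
  classify_end <- function(s) s <= w || s >= N - w + 1
  prev_frame <- NULL
  for (fr in frames) {
    det <- records[records$frame == fr, ]
    contiguous <- !is.null(prev_frame) && any(frames == prev_frame) &&
      (fr - prev_frame) == min(diff(frames))
    matched_det <- rep(FALSE, nrow(det))
    new_active <- data.frame(track = integer(0), s = integer(0),
                             polarity = numeric(0))
    if (nrow(active) > 0 && nrow(det) > 0) {
      # all candidate pairs within max_jump and same polarity
      cand <- expand.grid(ai = seq_len(nrow(active)), di = seq_len(nrow(det)))
      cand$cost <- abs(active$s[cand$ai] - det$s[cand$di])
      cand <- cand[cand$cost <= max_jump &
                     active$polarity[cand$ai] == det$polarity[cand$di], ]
      cand <- cand[order(cand$cost, det$s[cand$di]), ]
      used_a <- rep(FALSE, nrow(active))
      for (ri in seq_len(nrow(cand))) {
        ai <- cand$ai[ri]; di <- cand$di[ri]
        if (used_a[ai] || matched_det[di]) next
        used_a[ai] <- TRUE
        matched_det[di] <- TRUE
        new_active <- rbind(new_active,
                            data.frame(track = active$track[ai],
                                       s = det$s[di],
                                       polarity = det$polarity[di]))
      }
      # unmatched active tracks die at this frame
      for (ai in which(!used_a)) {
        deaths[[length(deaths) + 1]] <- data.frame(
          track = active$track[ai], frame = fr, s = active$s[ai],
          polarity = active$polarity[ai])
      }
    } else if (nrow(active) > 0) {
      for (ai in seq_len(nrow(active))) {
        deaths[[length(deaths) + 1]] <- data.frame(
          track = active$track[ai], frame = fr, s = active$s[ai],
          polarity = active$polarity[ai])
      }
    }
    # unmatched detections open tracks
    for (di in which(!matched_det)) {
      id <- next_id
      next_id <- next_id + 1L
      births[[length(births) + 1]] <- data.frame(
        track = id, frame = fr, s = det$s[di], polarity = det$polarity[di])
      new_active <- rbind(new_active,
                          data.frame(track = id, s = det$s[di],
                                     polarity = det$polarity[di]))
    }
    active <- new_active
    if (nrow(det) > 0) {
      points[[length(points) + 1]] <- data.frame(
        track = active$track[match(det$s, active$s)],
        frame = fr, s = det$s, polarity = det$polarity)
    }
    prev_frame <- fr
  }
  for (ai in seq_len(nrow(active))) { # survivors die at the end
    deaths[[length(deaths) + 1]] <- data.frame(
      track = active$track[ai], frame = max(frames) + 1L, s = active$s[ai],
      polarity = active$polarity[ai])
  }
  births <- do.call(rbind, births)
  deaths <- do.call(rbind, deaths)
  points <- do.call(rbind, points)
  points <- points[order(points$track, points$frame), ]
  # classify births and deaths
  btype <- character(nrow(births))
  for (i in seq_len(nrow(births))) {
    if (classify_end(births$s[i])) {
      btype[i] <- "end_entry"
    } else {
      sib <- births[births$frame == births$frame[i] &
                      births$polarity == -births$polarity[i], ]
      btype[i] <- if (nrow(sib) > 0) "pair_creation" else "interior"
    }
  }
  dtype <- character(nrow(deaths))
  for (i in seq_len(nrow(deaths))) {
    if (classify_end(deaths$s[i]) || deaths$frame[i] > max(frames)) {
      dtype[i] <- if (deaths$frame[i] > max(frames)) "censored" else "end_exit"
    } else {
      sib <- deaths[deaths$frame == deaths$frame[i] &
                      deaths$polarity == -deaths$polarity[i], ]
      dtype[i] <- if (nrow(sib) > 0) "pair_annihilation" else "interior"
    }
  }
  dord <- match(births$track, deaths$track)
  tracks <- data.frame(
    track = births$track,
    polarity = births$polarity,
    birth_frame = births$frame,
    death_frame = deaths$frame[dord],
    lifetime = deaths$frame[dord] - births$frame,
    birth_type = btype,
    death_type = dtype[dord])
  list(points = points, tracks = tracks)
}

#' Hairpin diffusivity along the backbone
#'
#' Arc-length mean squared displacement of linked hairpin tracks,
#' averaged over tracks and time origins, fit to `<ds^2> = 2 D_H dt` over
#' the requested lag window.  Short-lived tracks are excluded.
#'
#' @param points track points (`track`, `frame`, `s`) from
#'   [link_hairpin_tracks()].
#' @param b bond length (converts contour index to arc length).
#' @param dt_frame time between frames.
#' @param lags integer frame lags to evaluate (default 1:10).
#' @param min_lifetime minimum track length in frames (default
#'   `max(lags) + 1`).
#' @return list with `D_H`, `msd` (data.frame `lag_frames`, `lag_time`,
#'   `msd`, `n`), `n_tracks`; `D_H` is `NA` (flagged) when no track
#'   survives the lifetime cut.
#' @export
hairpin_diffusivity <- function(points, b = 0.89, dt_frame = 1,
                                lags = 1:10, min_lifetime = max(lags) + 1) {
  acc <- setNames(numeric(length(lags)), lags)
  cnt <- setNames(numeric(length(lags)), lags)
  n_used <- 0
  for (id in unique(points$track)) {
    tp <- points[points$track == id, ]
    tp <- tp[order(tp$frame), ]
    if (nrow(tp) < min_lifetime) next
    n_used <- n_used + 1
    # contiguous frame series assumed; index by frame offset
    f0 <- tp$frame - min(tp$frame) + 1
    x <- rep(NA_real_, max(f0))
    x[f0] <- tp$s * b
    for (li in seq_along(lags)) {
      L <- lags[li]
      if (length(x) <= L) next
      d2 <- (x[(1 + L):length(x)] - x[1:(length(x) - L)])^2
      d2 <- d2[!is.na(d2)]
      acc[li] <- acc[li] + sum(d2)
      cnt[li] <- cnt[li] + length(d2)
    }
  }
  if (n_used == 0 || all(cnt == 0)) {
    return(list(D_H = NA_real_, msd = NULL, n_tracks = 0))
  }
  ok <- cnt > 0
  msd_tab <- data.frame(lag_frames = lags[ok],
                        lag_time = lags[ok] * dt_frame,
                        msd = (acc / cnt)[ok],
                        n = cnt[ok])
  fit <- stats::lm(msd ~ 0 + lag_time, data = msd_tab, weights = n)
  list(D_H = unname(coef(fit)[1] / 2), msd = msd_tab, n_tracks = n_used)
}

#' Hairpin detection and tracking over a whole run
#'
#' @param run a `nemapoly_run`.
#' @param nhat global director.
#' @param w,threshold,min_sep detection parameters (see
#'   [detect_hairpins()]).
#' @param max_jump linking parameter (see [link_hairpin_tracks()]).
#' @return list with `counts` (per-frame N_H), `records` (all
#'   detections), `tracking` (output of [link_hairpin_tracks()]), and
#'   `statistics` ([hairpin_count_statistics()]).
#' @export
analyze_hairpins <- function(run, nhat = c(0, 0, 1), w = 3, threshold = 0.5,
                             min_sep = w, max_jump = 4) {
  frames <- run$frames
  nf <- dim(frames)[3]
  N <- dim(frames)[1]
  recs <- vector("list", nf)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    det <- detect_hairpins(frames[, , f], nhat, w, threshold, min_sep)
    counts[f] <- nrow(det)
    if (nrow(det) > 0) {
      det$frame <- f
      recs[[f]] <- det
    }
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records)) {
    records <- data.frame(s = integer(0), score = numeric(0),
                          polarity = numeric(0), frame = integer(0))
  }
  list(counts = counts, records = records,
       tracking = link_hairpin_tracks(records, N = N, max_jump = max_jump,
                                      w = w),
       statistics = hairpin_count_statistics(counts))
}
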