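#' Anchor positions of the generalized Labeled Magnitude Scale
#'
#' Verbal descriptors and their numerical positions on the 0-100 gLMS used
#' for rating itch, pricking/stinging, and burning: quasi-logarithmically
#' spaced from "no sensation" (0) through "barely detectable" (1), "weak"
#' (6), "moderate" (17), "strong" (35), "very strong" (53), up to
#' "strongest imaginable sensation of any kind" (100).
#'
#' @format Named numeric vector of length 7, strictly increasing.
#' @export
glms_anchors <- c(
  "no sensation" = 0, "barely detectable" = 1, "weak" = 6,
  "moderate" = 17, "strong" = 35, "very strong" = 53,
  "strongest imaginable" = 100
)

#' Construct a gLMS rating series
#'
#' Magnitude ratings of one sensory quality reported by one subject every
#' 30 s after one pruritogen injection, on the 0-100 gLMS. The first
#' rating falls at 0.5 min (the first 30 s interval after injection) and
#' successive ratings step by 0.5 min.
#'
#' @param subject_id Subject identifier.
#' @param stimulus Stimulus label, e.g. `"ALA"`, `"BAM"`, `"HIS"`,
#'   `"BAM+ALA"`, `"BAM+ALA+HIS"`.
#' @param quality Sensory quality: `"itch"`, `"pricking_stinging"`, or
#'   `"burning"`.
#' @param time_min Rating times in minutes: `0.5, 1.0, 1.5, ...`.
#' @param rating Magnitudes in `[0, 100]`, same length as `time_min`.
#' @return An object of class `rating_series`.
#' @export
rating_series <- function(subject_id, stimulus, quality, time_min, rating) {
  time_min <- as.numeric(time_min)
  rating <- as.numeric(rating)
  if (length(time_min) != length(rating)) stop("time and rating lengths differ")
  if (length(time_min) == 0) stop("empty rating series")
  grid <- seq(0.5, by = 0.5, length.out = length(time_min))
  if (max(abs(time_min - grid)) > 1e-8) {
    stop("ratings must lie on the 0.5-min grid starting at 0.5 min")
  }
  if (any(rating < 0 | rating > 100)) stop("ratings must be in [0, 100]")
  structure(
    list(subject_id = subject_id, stimulus = stimulus, quality = quality,
         time_min = time_min, rating = rating),
    class = "rating_series"
  )
}

#' @export
print.rating_series <- function(x, ...) {
  cat(sprintf("<rating_series> subject %s, %s, %s: %d samples over %.1f min, peak %.1f\n",
              x$subject_id, x$stimulus, x$quality, length(x$time_min),
              max(x$time_min), max(x$rating)))
  invisible(x)
}

#' Validate a rating session against the protocol
#'
#' Subjects rated every 30 s for at least 5 and at most 20 min, or until
#' every sensory quality had received three successive zero ratings.
#' Checks that the three quality series of one subject x stimulus session
#' share a common grid, that the session is not shorter than the minimum,
#' and that an early stop (before the 20 min cap) is justified by three
#' trailing zeros on every quality. A session still non-zero at 20 min is
#' valid but censored.
#'
#' @param series_list List of three [rating_series()] for one subject and
#'   stimulus (one per sensory quality).
#' @param min_min,max_min Protocol bounds in minutes.
#' @return A list with `valid` (logical), `censored` (logical), and
#'   `flags` (character vector of protocol violations, empty when valid).
#' @export
validate_session <- function(series_list, min_min = 5, max_min = 20) {
  flags <- character(0)
  lens <- vapply(series_list, function(s) length(s$time_min), integer(1))
  if (length(unique(lens)) != 1) {
    flags <- c(flags, "qualities have different session lengths")
  }
  end <- max(vapply(series_list, function(s) max(s$time_min), numeric(1)))
  if (end < min_min) {
    flags <- c(flags, sprintf("session ended at %.1f min, before the %g-min minimum",
                              end, min_min))
  }
  if (end > max_min) {
    flags <- c(flags, sprintf("session exceeds the %g-min maximum", max_min))
  }
  censored <- FALSE
  if (end < max_min && end >= min_min) {
    three_zero <- vapply(series_list, function(s) {
      n <- length(s$rating)
      n >= 3 && all(s$rating[(n - 2):n] == 0)
    }, logical(1))
    if (!all(three_zero)) {
      flags <- c(flags,
                 "stopped before 20 min without three successive zeros on every quality")
    }
  } else if (end >= max_min) {
    censored <- any(vapply(series_list,
                           function(s) s$rating[length(s$rating)] > 0,
                           logical(1)))
  }
  list(valid = length(flags) == 0, censored = censored, flags = flags)
}

#' Peak rating of a series
#'
#' @param series A [rating_series()].
#' @return The highest magnitude rating of the session (gLMS units).
#' @export
peak_rating <- function(series) max(series$rating)

#' Duration of a sensation
#'
#' The elapsed time between the onset of non-zero ratings and the first
#' zero rating after the sensation disappeared (i.e. the first zero after
#' the last non-zero sample). Intermediate zeros in a waxing and waning
#' series do not terminate the sensation. If no zero follows the last
#' non-zero sample the sensation outlasted the session: the duration runs
#' to the session end and is flagged censored.
#'
#' @param series A [rating_series()] with at least one non-zero rating.
#' @return List with `duration` (minutes) and `censored` (logical).
#' @export
sensation_duration <- function(series) {
  m <- series$rating
  t <- series$time_min
  nz <- which(m > 0)
  if (length(nz) == 0) stop("no sensation: all ratings are zero")
  t_on <- t[nz[1]]
  last_nz <- nz[length(nz)]
  zero_after <- which(m == 0 & seq_along(m) > last_nz)
  if (length(zero_after) == 0) {
    list(duration = t[length(t)] - t_on, censored = TRUE)
  } else {
    list(duration = t[zero_after[1]] - t_on, censored = FALSE)
  }
}

#' Area under the rating curve
#'
#' Trapezoidal integral of magnitude over time for the duration of the
#' sensation, in gLMS x min. Ratings are interval samples of a continuous
#' percept, so the curve is anchored with an implicit zero half a minute
#' before the first non-zero rating (the sensation was absent at the
#' previous report) and runs to the first zero after the last non-zero
#' sample, or to the session end when censored.
#'
#' @param series A [rating_series()] with at least one non-zero rating.
#' @return AUC in gLMS x min.
#' @export
rating_auc <- function(series) {
  m <- series$rating
  t <- series$time_min
  nz <- which(m > 0)
  if (length(nz) == 0) stop("no sensation: all ratings are zero")
  t_on <- t[nz[1]]
  last_nz <- nz[length(nz)]
  zero_after <- which(m == 0 & seq_along(m) > last_nz)
  i_off <- if (length(zero_after) == 0) length(t) else zero_after[1]
  sel <- which(t >= t_on & seq_along(t) <= i_off)
  tt <- c(t_on - 0.5, t[sel])
  mm <- c(0, m[sel])
  sum(diff(tt) * (utils::head(mm, -1) + utils::tail(mm, -1)) / 2)
}

#' Peak, duration, and AUC of one rating series
#'
#' A series with zero peak has no definable duration or AUC (there was no
#' sensation); both are returned as `NA` and such cells are excluded from
#' the duration/AUC analyses.
#'
#' @param series A [rating_series()].
#' @return List with `peak`, `duration`, `censored`, `auc`.
#' @export
sensation_metrics <- function(series) {
  pk <- peak_rating(series)
  if (pk == 0) {
    return(list(peak = 0, duration = NA_real_, censored = NA, auc = NA_real_))
  }
  d <- sensation_duration(series)
  list(peak = pk, duration = d$duration, censored = d$censored,
       auc = rating_auc(series))
}

#' Compute rating metrics for a tidy ratings table
#'
#' @param ratings Data frame with columns `subject_id`, `stimulus`,
#'   `quality`, `time_min`, `rating` (the ratings.csv schema).
#' @return Tidy data frame with one row per subject x stimulus x quality:
#'   `subject_id`, `stimulus`, `quality`, `peak`, `duration_min`,
#'   `censored`, `auc`.
#' @export
compute_metrics <- function(ratings) {
  req <- c("subject_id", "stimulus", "quality", "time_min", "rating")
  stopifnot(all(req %in% names(ratings)))
  key <- interaction(ratings$subject_id, ratings$stimulus, ratings$quality,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(ratings, key), function(d) {
    d <- d[order(d$time_min), ]
    s <- rating_series(d$subject_id[1], d$stimulus[1], d$quality[1],
                       d$time_min, d$rating)
    m <- sensation_metrics(s)
    data.frame(subject_id = d$subject_id[1], stimulus = d$stimulus[1],
               quality = d$quality[1], peak = m$peak,
               duration_min = m$duration, censored = m$censored,
               auc = m$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subjects with non-zero ratings in every cell
#'
#' The duration and AUC analyses require a sensation to have occurred:
#' only subjects whose peak rating exceeded zero for every sensory quality
#' and every stimulus are retained. Subjects with incomplete cells are
#' excluded with a warning.
#'
#' @param metrics Metrics table from [compute_metrics()].
#' @return Character vector of qualifying subject ids.
#' @export
filter_all_nonzero <- function(metrics) {
  n_cells <- length(unique(metrics$stimulus)) * length(unique(metrics$quality))
  by_sub <- split(metrics, metrics$subject_id)
  complete <- vapply(by_sub, function(d) nrow(d) == n_cells, logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) with incomplete cells excluded")
  }
  ok <- vapply(by_sub, function(d) {
    nrow(d) == n_cells && all(d$peak > 0)
  }, logical(1))
  names(by_sub)[ok]
}

#' Subjects with balanced itch responses across single pruritogens
#'
#' Retains subjects in whom the lowest maximum peak itch rating to any
#' single pruritogen was at least `ratio` (default 50%) of the highest
#' maximum peak itch rating to any single pruritogen, i.e. subjects in
#' whom no single pruritogen dominated the itch response. The boundary is
#' inclusive.
#'
#' @param metrics Metrics table from [compute_metrics()].
#' @param ratio Minimum allowed min/max peak-itch ratio.
#' @param single_stimuli Labels of the three single-pruritogen stimuli.
#' @param itch_quality Label of the itch quality.
#' @return Character vector of qualifying subject ids.
#' @export
filter_balanced_itch <- function(metrics, ratio = 0.5,
                                 single_stimuli = c("ALA", "BAM", "HIS"),
                                 itch_quality = "itch") {
  it <- metrics[metrics$quality == itch_quality &
                  metrics$stimulus %in% single_stimuli, ]
  by_sub <- split(it$peak, it$subject_id)
  ok <- vapply(by_sub, function(p) {
    length(p) == length(single_stimuli) && min(p) >= ratio * max(p)
  }, logical(1))
  names(by_sub)[ok]
}

#' Repeated-measures analysis of dysesthesia, wheal and flare areas
#'
#' One RM-ANOVA (within-subject factor: stimulus) with Greenhouse-Geisser
#' correction per area measure (alloknesis, hyperalgesia, hyperknesis,
#' wheal, flare), each followed by Bonferroni-adjusted pairwise post hoc
#' comparisons between stimuli.
#'
#' @param areas Data frame with columns `subject_id`, `stimulus`,
#'   `measure`, `area_cm2` (the areas.csv schema).
#' @param posthoc Run the Bonferroni post hoc per measure (default TRUE).
#' @return Named list (one element per measure), each with `anova` (from
#'   [rmanova_gg()]) and `posthoc` (from [bonferroni_posthoc()] or NULL).
#' @export
area_analysis <- function(areas, posthoc = TRUE) {
  req <- c("subject_id", "stimulus", "measure", "area_cm2")
  stopifnot(all(req %in% names(areas)))
  lapply(split(areas, areas$measure), function(d) {
    an <- rmanova_gg(d, dv = "area_cm2", subject = "subject_id",
                     within = "stimulus")
    ph <- if (posthoc) {
      bonferroni_posthoc(d, dv = "area_cm2", subject = "subject_id",
                         factor_name = "stimulus")
    }
    list(anova = an, posthoc = ph)
  })
}
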