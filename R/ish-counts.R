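#' Puncta positivity thresholds per species
#'
#' A neuron is called positive for a marker only when strictly more than
#' the threshold number of RNAscope/BaseScope puncta are present in the
#' cell: more than 5 puncta for human sections, more than 3 for macaque.
#'
#' @param species `"human"` or `"macaque"`.
#' @return Integer threshold.
#' @export
puncta_threshold <- function(species = c("human", "macaque")) {
  species <- match.arg(species)
  c(human = 5L, macaque = 3L)[[species]]
}

#' Call a neuron positive for a marker
#'
#' Strict inequality: a neuron is positive only when the puncta count
#' exceeds the threshold (a count equal to the threshold is negative).
#'
#' @param puncta Non-negative puncta count(s).
#' @param threshold Positivity threshold (default: human, 5).
#' @return Logical vector.
#' @examples
#' call_positive(6, 5)  # TRUE
#' call_positive(5, 5)  # FALSE
#' call_positive(4, 3)  # TRUE (macaque threshold)
#' @export
call_positive <- function(puncta, threshold = puncta_threshold("human")) {
  if (any(puncta < 0)) stop("puncta counts must be non-negative")
  puncta > threshold
}

# Pivot a tidy puncta table (species, donor_id, section_id, neuron_id,
# marker, puncta) into one row per neuron with a logical call per marker.
# Neurons are keyed by donor x section x neuron id; each counted neuron is
# assumed unique.
puncta_calls <- function(records, markers, threshold = NULL) {
  req <- c("donor_id", "neuron_id", "marker", "puncta")
  stopifnot(all(req %in% names(records)))
  if (is.null(threshold)) {
    sp <- unique(as.character(records$species))
    if (length(sp) != 1) {
      stop("records span multiple species; pass an explicit threshold")
    }
    threshold <- puncta_threshold(sp)
  }
  section <- if ("section_id" %in% names(records)) records$section_id else ""
  neuron_key <- paste(records$donor_id, section, records$neuron_id, sep = "\r")
  recs <- records[records$marker %in% markers, ]
  key <- paste(recs$donor_id,
               if ("section_id" %in% names(recs)) recs$section_id else "",
               recs$neuron_id, sep = "\r")
  puncta_by <- tapply(recs$puncta, list(key, factor(recs$marker, markers)),
                      function(z) {
                        if (length(z) > 1) stop("duplicate marker record for a neuron")
                        z
                      })
  if (anyNA(puncta_by)) {
    stop("neuron(s) missing a marker record for the requested panel")
  }
  calls <- call_positive(puncta_by, threshold)
  donor <- vapply(strsplit(rownames(puncta_by), "\r", fixed = TRUE),
                  `[[`, character(1), 1)
  list(calls = calls, donor = donor)
}

#' Pairwise co-expression summary
#'
#' Of the neurons positive for marker A, what fraction is also positive
#' for marker B? Reported two ways, as in standard double-ISH practice:
#' the mean and SEM of the per-donor percentages (SEM across donors with
#' the n-1 denominator), and the aggregated fraction pooling neurons from
#' all donors. Donors with no A-positive neuron contribute no per-donor
#' percentage and are dropped from the mean with a message.
#'
#' @param records Tidy puncta table: columns `species`, `donor_id`,
#'   `section_id`, `neuron_id`, `marker`, `puncta`.
#' @param marker_a,marker_b Marker names (e.g. `"MRGPRD"`, `"MRGPRX1"`).
#' @param threshold Positivity threshold; defaults to the species rule.
#' @return A list of class `coexpression_summary`: `marker_a`, `marker_b`,
#'   `per_donor_percent` (named), `mean_percent`, `sem_percent` (`NA` with
#'   fewer than two contributing donors), `n_double_positive`,
#'   `n_a_positive`, `aggregated_percent`.
#' @export
coexpression_summary <- function(records, marker_a, marker_b,
                                 threshold = NULL) {
  pc <- puncta_calls(records, c(marker_a, marker_b), threshold)
  a <- pc$calls[, marker_a]
  b <- pc$calls[, marker_b]
  if (!any(a)) stop("no neuron positive for ", marker_a)
  donors <- unique(pc$donor)
  per_donor <- vapply(donors, function(d) {
    sel <- pc$donor == d
    na <- sum(a[sel])
    if (na == 0) NA_real_ else 100 * sum(a[sel] & b[sel]) / na
  }, numeric(1))
  names(per_donor) <- donors
  dropped <- names(per_donor)[is.na(per_donor)]
  if (length(dropped)) {
    message("donor(s) with zero ", marker_a, "-positive neurons excluded ",
            "from the per-donor mean: ", paste(dropped, collapse = ", "))
  }
  pd <- per_donor[!is.na(per_donor)]
  structure(
    list(marker_a = marker_a, marker_b = marker_b,
         per_donor_percent = pd,
         mean_percent = mean(pd),
         sem_percent = if (length(pd) > 1) stats::sd(pd) / sqrt(length(pd))
                       else NA_real_,
         n_double_positive = sum(a & b), n_a_positive = sum(a),
         aggregated_percent = 100 * sum(a & b) / sum(a)),
    class = "coexpression_summary"
  )
}

#' @export
print.coexpression_summary <- function(x, ...) {
  sem <- if (is.na(x$sem_percent)) "NA" else sprintf("%.1f", x$sem_percent)
  cat(sprintf("%s+ neurons also %s+: %.1f +/- %s%% across %d donor(s); aggregated %d/%d (%.1f%%)\n",
              x$marker_a, x$marker_b, x$mean_percent, sem,
              length(x$per_donor_percent), x$n_double_positive,
              x$n_a_positive, x$aggregated_percent))
  invisible(x)
}

#' Three-marker Venn summary
#'
#' Counts neurons in each of the seven non-empty regions of the
#' three-marker Venn diagram plus the triple-negative outside region.
#' Region counts sum to the total number of neurons. Every neuron must
#' carry a puncta record for all three markers.
#'
#' @param records Tidy puncta table (see [coexpression_summary()]).
#' @param panel Character vector of exactly three marker names.
#' @param threshold Positivity threshold; defaults to the species rule.
#' @return A list of class `venn_summary` with `panel`, `counts` (named
#'   integer vector over the 8 regions, names like `"MRGPRD+MRGPRX1"` and
#'   `"none"`), and `n_total`.
#' @export
venn_summary <- function(records, panel = c("MRGPRD", "MRGPRX1", "TRPV1"),
                         threshold = NULL) {
  stopifnot(length(panel) == 3)
  pc <- puncta_calls(records, panel, threshold)
  calls <- pc$calls
  state <- apply(calls, 1, function(z) {
    if (!any(z)) "none" else paste(panel[z], collapse = "+")
  })
  regions <- c(
    "none", panel,
    apply(utils::combn(panel, 2), 2, paste, collapse = "+"),
    paste(panel, collapse = "+")
  )
  counts <- vapply(regions, function(r) sum(state == r), integer(1))
  structure(
    list(panel = panel, counts = counts, n_total = nrow(calls)),
    class = "venn_summary"
  )
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("<venn_summary>", x$n_total, "neurons; panel:",
      paste(x$panel, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

#' Marker-positive count from a Venn summary
#'
#' Total neurons positive for one marker (sum of the four regions that
#' include it), convenient for checking consistency with
#' [coexpression_summary()].
#'
#' @param venn A [venn_summary()].
#' @param marker One marker of the panel.
#' @return Integer count.
#' @export
venn_marker_total <- function(venn, marker) {
  stopifnot(marker %in% venn$panel)
  hit <- vapply(names(venn$counts), function(r) {
    r != "none" && marker %in% strsplit(r, "+", fixed = TRUE)[[1]]
  }, logical(1))
  sum(venn$counts[hit])
}
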