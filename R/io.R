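# CSV schemas for the pipeline interchange files. All files are UTF-8
# comma-separated with a header row and '.' decimal separator.
.schemas <- list(
  spikes = c(recording_id = "character", fiber_id = "character",
             event = "character", t_s = "numeric"),
  stimuli = c(recording_id = "character", event = "character",
              baseline_temp_c = "numeric", target_temp_c = "numeric",
              rise_s = "numeric", plateau_s = "numeric",
              conduction_latency_s = "numeric"),
  injections = c(fiber_id = "character", compound = "character",
                 baseline_aps_60s = "numeric", inj_start_s = "numeric",
                 inj_end_s = "numeric", observation_s = "numeric"),
  ratings = c(subject_id = "character", stimulus = "character",
              quality = "character", time_min = "numeric",
              rating = "numeric"),
  areas = c(subject_id = "character", stimulus = "character",
            measure = "character", area_cm2 = "numeric"),
  puncta = c(species = "character", donor_id = "character",
             section_id = "character", neuron_id = "character",
             marker = "character", puncta = "numeric")
)

#' Read and validate a pipeline CSV
#'
#' Reads one of the pipeline interchange tables and validates it against
#' its schema: all required columns must be present, and numeric columns
#' must parse; rows with unparseable numbers are reported with their file
#' line numbers in a single error.
#'
#' @param path Path to the CSV file.
#' @param schema One of `"spikes"`, `"stimuli"`, `"injections"`,
#'   `"ratings"`, `"areas"`, `"puncta"`.
#' @return A validated data frame.
#' @export
read_table_checked <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  spec <- .schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  problems <- character(0)
  for (col in names(spec)) {
    if (spec[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "%s: unparseable numeric '%s' at line %d", col,
          df[[col]][bad], bad + 1L))  # +1 for the header row
      }
      df[[col]] <- v
    }
  }
  if (length(problems)) {
    stop("validation errors in ", basename(path), ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  df
}

#' Write a pipeline CSV
#'
#' @param df Data frame to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#'
#' @param seed RNG seed for the simulated cohorts.
#' @param out_dir Output directory for the report bundle.
#' @param n_qc,n_sc Fibers per CMH subtype.
#' @param n_subjects Psychophysics cohort size.
#' @param n_donors,neurons_per_donor ISH cohort size.
#' @param tolerance Line-of-equality tolerance, s (see
#'   [classify_heat_response()]).
#' @param response_window Net-response scoring window, s.
#' @param response_threshold Responsiveness threshold, net APs.
#' @param stages Character vector of stages to run, a subset of
#'   `c("classify", "score", "psychophysics", "ish")`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("pruriphys_run_"),
                            n_qc = 29, n_sc = 31, n_subjects = 29,
                            n_donors = 4, neurons_per_donor = 150,
                            tolerance = 0.1, response_window = 300,
                            response_threshold = 10,
                            stages = c("classify", "score", "psychophysics",
                                       "ish")) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(tolerance >= 0, response_window > 0, response_threshold > 0,
            n_qc >= 1, n_sc >= 1, n_subjects >= 2, n_donors >= 1)
  structure(
    list(seed = seed, out_dir = out_dir, n_qc = n_qc, n_sc = n_sc,
         n_subjects = n_subjects, n_donors = n_donors,
         neurons_per_donor = neurons_per_donor, tolerance = tolerance,
         response_window = response_window,
         response_threshold = response_threshold, stages = stages),
    class = "pipeline_config"
  )
}

#' Run the simulate-then-analyze pipeline
#'
#' Generates a full synthetic study with the configured seed and runs
#' every enabled analysis stage: heat-response classification, pruritogen
#' response scoring with the electrophysiology statistics (paired t,
#' chi-squared association, mixed ANOVA with Scheffe post hoc), gLMS
#' psychophysics (metrics, subject filters, GG-corrected RM-ANOVAs, area
#' analyses), and ISH co-expression summaries. Tidy CSV outputs and a run
#' log (seed, configuration hash, package version) are written to
#' `config$out_dir`. The same configuration and seed reproduce the bundle
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with the stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  results <- list()
  stats_rows <- list()
  add_stat <- function(family, effect, statistic, df1, df2, p) {
    stats_rows[[length(stats_rows) + 1]] <<- data.frame(
      family = family, effect = effect, statistic = statistic,
      df1 = df1, df2 = df2, p = p, stringsAsFactors = FALSE)
  }

  if ("classify" %in% config$stages) {
    cohort <- generate_heat_cohort(config$n_qc, config$n_sc)
    cls <- classify_heat_cohort(cohort, tolerance = config$tolerance)
    write_tidy_csv(cls, file.path(config$out_dir, "classifications.csv"))
    results$classification <- cls
  }

  if ("score" %in% config$stages) {
    net <- generate_injection_cohort(config$n_qc, config$n_sc,
                                     window = config$response_window,
                                     threshold = config$response_threshold)
    write_tidy_csv(net, file.path(config$out_dir, "net_responses.csv"))
    summ <- summarize_net_table(net)
    add_stat("net_response", "ALA_vs_BAM8_22_paired_t",
             summ$paired_t$statistic, summ$paired_t$df, NA,
             summ$paired_t$p.value)
    chi <- tryCatch(association_chi_square(responsiveness_table(net)),
                    error = function(e) NULL)
    if (!is.null(chi)) {
      add_stat("responsiveness", "ALA_x_BAM8_22_chi_square",
               chi$statistic, chi$df, NA, chi$p.value)
    } else {
      message("responsiveness table degenerate at this cohort size; ",
              "chi-squared association skipped")
    }
    aov_tab <- mixed_anova_fiber_pruritogen(net)
    for (i in seq_len(nrow(aov_tab))) {
      add_stat("mixed_anova", aov_tab$effect[i], aov_tab$statistic[i],
               aov_tab$df1[i], aov_tab$df2[i], aov_tab$p_gg[i])
    }
    sch <- scheffe_posthoc(net)
    for (i in seq_len(nrow(sch))) {
      add_stat("scheffe", paste(sch$cell_1[i], "vs", sch$cell_2[i]),
               sch$F_scheffe[i], sch$df1[i], sch$df2[i], sch$p[i])
    }
    results$net_responses <- net
    results$net_summary <- summ
    results$scheffe <- sch
  }

  if ("psychophysics" %in% config$stages) {
    ratings <- generate_rating_cohort(config$n_subjects)
    metrics <- compute_metrics(ratings)
    write_tidy_csv(metrics, file.path(config$out_dir, "metrics.csv"))
    peaks_an <- rmanova_gg(metrics, dv = "peak", subject = "subject_id",
                           within = c("stimulus", "quality"))
    for (i in seq_len(nrow(peaks_an))) {
      add_stat("peak_rmanova", peaks_an$effect[i], peaks_an$statistic[i],
               peaks_an$df1_gg[i], peaks_an$df2_gg[i], peaks_an$p_gg[i])
    }
    keep <- filter_all_nonzero(metrics)
    sub_m <- metrics[metrics$subject_id %in% keep, ]
    if (length(keep) >= 3) {
      for (dv in c("auc", "duration_min")) {
        an <- rmanova_gg(sub_m, dv = dv, subject = "subject_id",
                         within = c("stimulus", "quality"))
        for (i in seq_len(nrow(an))) {
          add_stat(paste0(dv, "_rmanova"), an$effect[i], an$statistic[i],
                   an$df1_gg[i], an$df2_gg[i], an$p_gg[i])
        }
      }
    }
    areas <- generate_area_cohort(config$n_subjects)
    area_res <- area_analysis(areas, posthoc = FALSE)
    for (m in names(area_res)) {
      an <- area_res[[m]]$anova
      add_stat("area_rmanova", paste(m, an$effect), an$statistic,
               an$df1_gg, an$df2_gg, an$p_gg)
    }
    results$metrics <- metrics
    results$all_nonzero_subjects <- keep
    results$areas <- areas
  }

  if ("ish" %in% config$stages) {
    puncta <- generate_puncta_cohort(config$n_donors,
                                     config$neurons_per_donor)
    co <- coexpression_summary(puncta, "MRGPRX1", "MRGPRD")
    co_rows <- data.frame(
      marker_a = co$marker_a, marker_b = co$marker_b,
      mean_percent = co$mean_percent, sem_percent = co$sem_percent,
      n_double_positive = co$n_double_positive,
      n_a_positive = co$n_a_positive,
      aggregated_percent = co$aggregated_percent, stringsAsFactors = FALSE)
    write_tidy_csv(co_rows, file.path(config$out_dir, "coexpression.csv"))
    venn <- venn_summary(puncta)
    write_tidy_csv(data.frame(region = names(venn$counts),
                              count = unname(venn$counts)),
                   file.path(config$out_dir, "venn.csv"))
    results$coexpression <- co
    results$venn <- venn
  }

  if (length(stats_rows)) {
    stats_df <- do.call(rbind, stats_rows)
    write_tidy_csv(stats_df, file.path(config$out_dir, "stats.csv"))
    results$stats <- stats_df
  }

  # run log: seed, config hash, versions
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  writeLines(c(
    sprintf("pruriphys %s", as.character(utils::packageVersion("pruriphys"))),
    sprintf("R %s", getRversion()),
    sprintf("seed %d", config$seed),
    sprintf("config_md5 %s", cfg_hash),
    sprintf("stages %s", paste(config$stages, collapse = ","))
  ), file.path(config$out_dir, "run_log.txt"))

  invisible(results)
}
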