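# End-to-end orchestration: simulate -> preprocess -> classify -> spectral
# -> metrics -> compare, with CSV outputs and a run manifest.

#' Map classifier labels and sex to analysis categories
#'
#' Males are analysed as one category regardless of their (rarely cyclic)
#' classifier label; females split into cyclic and acyclic by the
#' classifier.
#'
#' @param participants Participant table with pid, sex.
#' @param labels Classifier output with pid, label.
#' @return data.table: pid, category.
#' @export
assign_categories <- function(participants, labels) {
  pt <- data.table::as.data.table(participants)
  lb <- data.table::as.data.table(labels)
  m <- lb[, c("pid", "label")][pt, on = "pid"]
  m[, category := data.table::fifelse(
    sex == "male", "male",
    data.table::fifelse(label == "cyclic", "cyclic_female", "acyclic_female"))]
  m[, c("pid", "category"), with = FALSE]
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort from `cfg`, preprocesses the minute streams, filters
#' for completeness, classifies cyclicity from nightly summaries, computes
#' wavelet band power, per-state variability metrics, group comparisons
#' (rank tests, Cohen's d, age-bin contrasts) and cumulative-error
#' trajectories at several resolutions, writing every table as CSV plus a
#' JSON manifest into `out_dir`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created).
#' @param q_low,q_high Preprocessing quantile band.
#' @param theta Cyclicity peak threshold (ACF units).
#' @param signal Nightly signal for classification.
#' @param band Wavelet band in days.
#' @param se_form Cumulative-error form (see [cumulative_error()]).
#' @param make_plots Write ggplot2 figures (requires ggplot2).
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir, q_low = 0.05, q_high = 0.95,
                         theta = 0.3, signal = "temp_trend_dev",
                         band = c(26, 32), se_form = "printed",
                         make_plots = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("simulate", generate_cohort(cfg, resolution = "minute"))
  participants <- cohort$participants

  clean <- stage("preprocess", {
    nights <- select_nightly_rows(cohort$nightly)
    preprocess_series(cohort$minute, nights, q_low, q_high)
  })
  kept <- stage("completeness", completeness_filter(
    clean, cfg$sample_minutes, threshold = 0.70, required_months = NA))
  clean$data <- clean$data[pid %in% kept]
  nightly <- cohort$nightly[pid %in% kept]
  participants <- participants[pid %in% kept]

  labels <- stage("classify", classify_cyclicity(
    nightly, signal = signal, theta = theta))
  categories <- assign_categories(participants, labels)

  bp <- stage("spectral", cohort_band_power(nightly, band[1], band[2]))
  band_summary <- stage("spectral", group_band_summary(bp, categories))

  metrics <- stage("metrics", state_metrics(clean))
  metrics <- categories[metrics, on = "pid"]

  comparisons <- stage("compare", {
    out <- list()
    for (met in c("mean", "variance", "cv", "pv", "d")) {
      for (st in unique(metrics$state)) {
        sub <- metrics[state == st]
        vals <- split(sub[[met]], sub$category)
        vals <- vals[vapply(vals, length, integer(1)) >= 2]
        if (length(vals) < 2) next
        r <- mwu_bonferroni(vals, n_comparisons = 9,
                            metric = paste(met, st, sep = "_"))
        out[[paste(met, st)]] <- r
      }
    }
    data.table::rbindlist(out)
  })

  effect_sizes <- stage("compare", {
    out <- list()
    for (met in c("mean", "variance")) {
      for (st in unique(metrics$state)) {
        sub <- metrics[state == st]
        vals <- split(sub[[met]], sub$category)
        prs <- utils::combn(names(vals), 2, simplify = FALSE)
        for (pr in prs) {
          out[[paste(met, st, pr[1], pr[2])]] <- data.table::data.table(
            group_a = pr[1], group_b = pr[2],
            metric = paste(met, st, sep = "_"),
            cohens_d = cohens_d(vals[[pr[1]]], vals[[pr[2]]]))
        }
      }
    }
    data.table::rbindlist(out)
  })

  age_contrasts <- stage("compare", {
    med <- nightly[, list(median_temp_max = stats::median(temp_max)),
                   by = "pid"]
    med <- participants[, c("pid", "sex", "age_bin")][med, on = "pid"]
    age_bin_contrasts(med[sex == "female"])
  })

  cumerr <- stage("cumerr", {
    vals <- split(nightly$temp_max, nightly$pid)
    n60 <- min(60, min(vapply(vals, length, integer(1))))
    vals60 <- lapply(vals, function(v) v[seq_len(n60)])
    traj <- cumulative_error_table(vals60, categories, form = se_form)
    finals <- traj[, list(final = cum[.N]), by = c("pid", "category")]
    kt <- kruskal_cumerr(split(finals$final, finals$category))
    list(trajectories = traj, finals = finals,
         kruskal = data.table::data.table(comparison = "nightly_60d",
                                          H = kt$H, p = kt$p,
                                          significant = kt$significant))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermovar")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = list(
      simulate = list(participants = nrow(cohort$participants),
                      minute_rows = nrow(cohort$minute),
                      nightly_rows = nrow(cohort$nightly)),
      preprocess = list(retained = nrow(clean$data),
                        dropped = nrow(clean$dropped)),
      completeness = list(retained_pids = length(kept)),
      classify = list(cyclic = sum(labels$label == "cyclic"),
                      overrides = sum(labels$override_applied)),
      spectral = list(participants = nrow(bp)),
      metrics = list(rows = nrow(metrics)),
      compare = list(tests = nrow(comparisons))))

  fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f))
  fw(participants, "participants.csv")
  fw(labels, "labels.csv")
  fw(categories, "categories.csv")
  fw(bp, "band_power.csv")
  fw(band_summary, "band_summary.csv")
  fw(metrics, "metrics.csv")
  fw(comparisons, "comparisons.csv")
  fw(effect_sizes, "effect_sizes.csv")
  fw(age_contrasts, "age_contrasts.csv")
  fw(cumerr$trajectories, "cumerr_trajectories.csv")
  fw(cumerr$finals, "cumerr_final.csv")
  fw(cumerr$kruskal, "cumerr_kruskal.csv")
  fw(dropped_samples(clean)[, list(n = .N), by = c("pid", "reason")],
     "drop_audit.csv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config_json(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  if (make_plots) write_pipeline_plots(out_dir, band_summary, metrics,
                                       cumerr$trajectories)

  invisible(list(participants = participants, labels = labels,
                 categories = categories, band_power = bp,
                 band_summary = band_summary, metrics = metrics,
                 comparisons = comparisons, effect_sizes = effect_sizes,
                 age_contrasts = age_contrasts, cumerr = cumerr,
                 clean = clean, nightly = nightly, manifest = manifest))
}

config_json <- function(cfg) {
  x <- unclass(cfg)
  x$start_date <- format(x$start_date)
  x$age_bins <- as.list(x$age_bins)
  x
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config_json(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

write_pipeline_plots <- function(out_dir, band_summary, metrics, traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping figures", call. = FALSE)
    return(invisible(NULL))
  }
  gg <- ggplot2::ggplot
  p1 <- gg(band_summary,
           ggplot2::aes(x = category, y = mean, fill = category)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           width = 0.2) +
    ggplot2::labs(y = "mean 26-32 d wavelet power", x = NULL)
  ggplot2::ggsave(file.path(out_dir, "fig_band_power.pdf"), p1,
                  width = 5, height = 4)
  p2 <- gg(metrics, ggplot2::aes(x = category, y = mean, fill = category)) +
    ggplot2::geom_violin() + ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(y = "mean temperature (deg C)", x = NULL)
  ggplot2::ggsave(file.path(out_dir, "fig_state_means.pdf"), p2,
                  width = 8, height = 4)
  p3 <- gg(traj, ggplot2::aes(x = t, y = cum, group = pid,
                              colour = category)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "night", y = "cumulative error")
  ggplot2::ggsave(file.path(out_dir, "fig_cumerr.pdf"), p3,
                  width = 6, height = 4)
  invisible(NULL)
}
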