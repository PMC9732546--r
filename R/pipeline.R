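# End-to-end efficacy pipeline: RTV -> TGI series -> optimal TGI ->
# Mann-Whitney on individual RTVs at the optimal day -> RTVV/ORR responder
# classification with Fisher comparison between treatments -> RTV x 2 / x 4
# progression events with Kaplan-Meier and log-rank versus control.

#' Efficacy analysis configuration
#'
#' One place for the analysis conventions: the volume formula, the
#' end-of-treatment evaluation day for RTVV (default: last day shared with
#' the control arm), the minimum number of measured mice per arm for a TGI
#' day to be evaluable, the exact-test switchover and the RTV-fold
#' progression thresholds.
#'
#' @param volume_convention passed to [volume_from_diameters()].
#' @param evaluation_day fixed RTVV evaluation day, or `NULL` for the last
#'   common day per arm.
#' @param min_n_per_day minimum measured mice per arm per TGI day.
#' @param exact_max_n combined-sample switchover for exact tests.
#' @param folds RTV progression thresholds.
#' @param enrollment_window,enrollment_filter see [read_measurements()].
#' @return list of class `efficacy_config`.
#' @export
efficacy_config <- function(volume_convention = c("as-printed", "conventional"),
                            evaluation_day = NULL,
                            min_n_per_day = 2L,
                            exact_max_n = 20L,
                            folds = c(2, 4),
                            enrollment_window = c(60, 150),
                            enrollment_filter = FALSE) {
  structure(list(volume_convention = match.arg(volume_convention),
                 evaluation_day = evaluation_day,
                 min_n_per_day = as.integer(min_n_per_day),
                 exact_max_n = as.integer(exact_max_n),
                 folds = folds,
                 enrollment_window = enrollment_window,
                 enrollment_filter = enrollment_filter),
            class = "efficacy_config")
}

# stable fingerprint of the study's measurements (md5 of their canonical
# CSV rendering), for the report provenance block
study_fingerprint <- function(study) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_measurements(study, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full efficacy analysis
#'
#' For every treated arm against the control arm: the TGI series and its
#' optimal (maximal) day with the >= 50% meaningful flag; a two-tailed
#' Mann-Whitney test on the individual RTVs at the optimal day; per-mouse
#' RTVV/ORR responder records; and RTV-fold progression analysis
#' (Kaplan-Meier estimate per arm plus Mantel-Cox log-rank versus control
#' at each fold). Responder counts are compared between treated arms by
#' Fisher's exact test. Every number in the report equals what the stage
#' functions return when called individually.
#'
#' @param study a [pdx_study()] with one control and >= 1 treated arm.
#' @param config an [efficacy_config()].
#' @param seed optional seed recorded in the provenance block (the analysis
#'   itself is deterministic).
#' @return object of class `efficacy_report`; see [write_report()].
#' @export
run_efficacy <- function(study, config = efficacy_config(), seed = NULL) {
  stopifnot(inherits(study, "pdx_study"))
  control <- study$arms[[study$control]]
  treated_names <- setdiff(names(study$arms), study$control)
  if (length(treated_names) == 0L)
    pdx_validation_error("study has no treated arm")

  tgi <- list(); rtv_tests <- list(); km <- list(); logrank <- list()
  for (a in treated_names) {
    arm <- study$arms[[a]]
    ser <- tgi_series(arm, control, min_n = config$min_n_per_day)
    opt <- ser[which.max(ser$tgi_percent), , drop = FALSE]
    tgi[[a]] <- list(series = cbind(arm = a, ser),
                     optimal = cbind(arm = a, opt))
    rt <- vapply(arm$curves, rtv_at, 0, day = opt$day)
    rc <- vapply(control$curves, rtv_at, 0, day = opt$day)
    mw <- mann_whitney(rt[!is.na(rt)], rc[!is.na(rc)],
                       exact_max_n = config$exact_max_n)
    rtv_tests[[a]] <- data.frame(arm = a, day = opt$day,
                                 statistic_U = mw$statistic,
                                 p_two_sided = mw$p_two_sided,
                                 method = mw$method)
  }

  orr <- orr_table(study$arms[treated_names], control,
                   evaluation_day = config$evaluation_day)
  responses <- attr(orr, "responses")
  orr_tests <- NULL
  if (length(treated_names) >= 2L) {
    pairs <- utils::combn(treated_names, 2L)
    orr_tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      ft <- compare_orr(orr_matrix(orr, pairs[1, i], pairs[2, i]))
      data.frame(arm_a = pairs[1, i], arm_b = pairs[2, i],
                 odds_ratio = ft$statistic, p_two_sided = ft$p_two_sided)
    }))
  }

  surv_tab <- fold_event_table(study, folds = config$folds)
  for (f in config$folds) {
    key <- sprintf("fold%g", f)
    for (a in names(study$arms)) {
      ta <- surv_tab[surv_tab$fold == f & surv_tab$arm == a, , drop = FALSE]
      km[[key]][[a]] <- km_estimate(ta$time_days, ta$event)
    }
    for (a in treated_names) {
      lt <- logrank_fold(study$arms[[a]], control, fold = f)
      logrank[[length(logrank) + 1L]] <-
        data.frame(arm = a, fold = f, chi_square = lt$statistic,
                   p_two_sided = lt$p_two_sided)
    }
  }

  structure(list(
    control = study$control,
    treated = treated_names,
    tgi = tgi,
    rtv_tests = do.call(rbind, unname(rtv_tests)),
    responses = responses,
    orr = orr,
    orr_tests = orr_tests,
    survival = surv_tab,
    km = km,
    logrank = do.call(rbind, logrank),
    provenance = list(
      input_md5 = study_fingerprint(study),
      seed = seed,
      config = unclass(config),
      package_version = as.character(packageVersion("pdxefficacy"))
    )
  ), class = "efficacy_report")
}

# 3-significant-figure p-value rendering for the plain-text summary
fmt_p <- function(p) formatC(signif(p, 3), format = "g", digits = 3)

#' @export
print.efficacy_report <- function(x, ...) {
  cat(format_report_summary(x), sep = "\n")
  invisible(x)
}

format_report_summary <- function(report) {
  lines <- c("PDX efficacy report",
             sprintf("control arm: %s", report$control), "")
  for (a in report$treated) {
    opt <- report$tgi[[a]]$optimal
    mw <- report$rtv_tests[report$rtv_tests$arm == a, ]
    lines <- c(lines,
      sprintf("arm %s:", a),
      sprintf("  optimal TGI = %.1f%% at day %d (%s; meaningful effect = TGI >= 50%%)",
              opt$tgi_percent, opt$day,
              if (opt$meaningful) "meaningful" else "not meaningful"),
      sprintf("  Mann-Whitney on individual RTVs at day %d: U = %g, p = %s (%s)",
              mw$day, mw$statistic_U, fmt_p(mw$p_two_sided), mw$method))
    o <- report$orr[report$orr$arm == a, ]
    lines <- c(lines,
      sprintf("  responders (ORR < -0.5): %d/%d (%.1f%%)",
              o$responders, o$n, o$responder_pct))
    lr <- report$logrank[report$logrank$arm == a, ]
    for (i in seq_len(nrow(lr)))
      lines <- c(lines,
        sprintf("  log-rank vs control, RTV x %g: chi-square = %.3f, p = %s",
                lr$fold[i], lr$chi_square[i], fmt_p(lr$p_two_sided[i])))
    lines <- c(lines, "")
  }
  if (!is.null(report$orr_tests)) {
    for (i in seq_len(nrow(report$orr_tests)))
      lines <- c(lines,
        sprintf("Fisher exact, responder rate %s vs %s: p = %s",
                report$orr_tests$arm_a[i], report$orr_tests$arm_b[i],
                fmt_p(report$orr_tests$p_two_sided[i])))
  }
  lines <- c(lines,
             sprintf("input md5: %s", report$provenance$input_md5),
             sprintf("pdxefficacy version %s", report$provenance$package_version))
  lines
}

#' Write an efficacy report to disk
#'
#' Writes deterministic, losslessly round-trippable CSV tables
#' (`tgi_series.csv`, `tgi_optimal.csv`, `rtv_tests.csv`, `responses.csv`,
#' `orr_table.csv`, `orr_tests.csv`, `survival_records.csv`,
#' `km_curves.csv`, `logrank_tests.csv`) plus a plain-text `summary.txt`.
#' Identical reports produce byte-identical files.
#'
#' @param report an [run_efficacy()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "efficacy_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tgi_series_all <- do.call(rbind, lapply(report$tgi, `[[`, "series"))
  tgi_opt_all <- do.call(rbind, lapply(report$tgi, `[[`, "optimal"))
  rownames(tgi_series_all) <- rownames(tgi_opt_all) <- NULL
  km_all <- do.call(rbind, lapply(names(report$km), function(key)
    do.call(rbind, lapply(names(report$km[[key]]), function(a)
      cbind(fold = as.numeric(sub("fold", "", key)), arm = a,
            as.data.frame(report$km[[key]][[a]]))))))
  rownames(km_all) <- NULL
  write_table_exact(tgi_series_all, file.path(dir, "tgi_series.csv"))
  write_table_exact(tgi_opt_all, file.path(dir, "tgi_optimal.csv"))
  write_table_exact(report$rtv_tests, file.path(dir, "rtv_tests.csv"))
  write_table_exact(report$responses, file.path(dir, "responses.csv"))
  orr <- report$orr; attr(orr, "responses") <- NULL
  write_table_exact(orr, file.path(dir, "orr_table.csv"))
  if (!is.null(report$orr_tests))
    write_table_exact(report$orr_tests, file.path(dir, "orr_tests.csv"))
  write_table_exact(report$survival, file.path(dir, "survival_records.csv"))
  write_table_exact(km_all, file.path(dir, "km_curves.csv"))
  write_table_exact(report$logrank, file.path(dir, "logrank_tests.csv"))
  con <- file(file.path(dir, "summary.txt"), open = "wb")
  writeLines(format_report_summary(report), con, sep = "\n")
  close(con)
  invisible(dir)
}

#' Read back the tabular parts of a written report
#'
#' @param dir directory written by [write_report()].
#' @return named list of data.frames, one per CSV file present.
#' @export
read_report <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, read.csv, stringsAsFactors = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
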