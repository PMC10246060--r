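# Evaluation machinery: run-timing summaries, the independent-samples t-test,
# and recomputation of the packaged visualization-speed benchmark table
# (10 subjects x 2 machines x 2 tools).

#' Summarize per-run pipeline timings
#'
#' Mean and sample standard deviation per component (prediction and
#' visualization) over exactly `runs` records, the protocol used for the
#' timing tables (50-run averages).
#'
#' @param session a SessionStats (from [runServerLoop()]) or a data.frame with
#'   columns `cnn_seconds` and `vis_seconds`.
#' @param runs number of records to summarize (default 50); fewer available
#'   records is an error.
#' @return data.frame with columns component, mean_seconds, sd_seconds, n_runs.
#' @export
timePipeline <- function(session, runs = 50L) {
  if (runs < 1L) stop("runs must be >= 1")
  df <- if (inherits(session, "SessionStats")) session$runs else session
  if (!all(c("cnn_seconds", "vis_seconds") %in% names(df)))
    stop("session must carry cnn_seconds and vis_seconds per run")
  if (nrow(df) < runs)
    stop(sprintf("only %d run records available, %d requested", nrow(df), runs))
  df <- df[seq_len(runs), , drop = FALSE]
  data.frame(
    component = c("cnn", "vis"),
    mean_seconds = c(mean(df$cnn_seconds), mean(df$vis_seconds)),
    sd_seconds = c(sd(df$cnn_seconds), sd(df$vis_seconds)),
    n_runs = runs)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided independent-samples Student t-test with pooled variance and
#' df = n1 + n2 - 2 (the form consistent with the benchmark's reported
#' degrees of freedom). Degenerate inputs (zero pooled variance) are flagged:
#' equal means give t = 0, p = 1; unequal means an infinite t with p = 0.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `infinite` (logical flag).
#' @export
twoSampleTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  out <- list(df = df, mean_a = mean(a), mean_b = mean(b),
              sd_a = sd(a), sd_b = sd(b), infinite = FALSE)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      out$t <- 0; out$p <- 1
    } else {
      out$t <- sign(mean(a) - mean(b)) * Inf; out$p <- 0; out$infinite <- TRUE
    }
    return(out)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  out$t <- unname(ht$statistic)
  out$p <- ht$p.value
  out
}

#' Load the packaged visualization-speed benchmark fixture
#'
#' Transcription of a published 10-subject benchmark comparing E-field
#' visualization times of a conventional FEM pipeline ("simnibs") against the
#' real-time deep-learning pipeline ("slicertms") on two CPU machines. The
#' printed per-subject summary columns (including their idiosyncrasies, e.g.
#' the real-time tool's per-subject "mean" column repeating its second-machine
#' cell) are kept verbatim in a separate table.
#'
#' @return list with `timings` (subject, machine, tool, seconds; 40 rows) and
#'   `printed` (per-subject printed means and improvement factors).
#' @export
table2Fixture <- function() {
  timings <- read.csv(system.file("extdata", "table2_timings.csv",
                                  package = "tmsfield"))
  printed <- read.csv(system.file("extdata", "table2_printed_summary.csv",
                                  package = "tmsfield"))
  if (nrow(timings) != 40L || any(timings$seconds <= 0))
    stop("benchmark fixture must hold the complete 40-cell grid of positive times")
  list(timings = timings, printed = printed)
}

#' Recompute the benchmark comparison from the fixture
#'
#' Pools the 20 printed cells per tool into mean +/- sample sd, recomputes
#' per-subject improvement factors (both from the printed per-subject means
#' and from recomputed two-machine means), and runs the pooled two-sample
#' t-test on the 20-vs-20 visualization times.
#'
#' @param fixture as returned by [table2Fixture()].
#' @return list with `pooled` (per-tool mean/sd data.frame), `per_subject`
#'   (improvement factors, printed and recomputed), `mean_improvement_printed`,
#'   `mean_improvement_recomputed`, and `ttest`.
#' @export
reproduceTable2 <- function(fixture = table2Fixture()) {
  tm <- fixture$timings
  pr <- fixture$printed
  need <- expand.grid(subject = 1:10, machine = unique(tm$machine),
                      tool = unique(tm$tool))
  if (nrow(tm) != nrow(need) ||
      nrow(unique(tm[, c("subject", "machine", "tool")])) != nrow(need))
    stop("incomplete benchmark fixture")

  sim <- tm$seconds[tm$tool == "simnibs"]
  sli <- tm$seconds[tm$tool == "slicertms"]
  pooled <- data.frame(
    tool = c("simnibs", "slicertms"),
    mean_seconds = c(mean(sim), mean(sli)),
    sd_seconds = c(sd(sim), sd(sli)),
    n = c(length(sim), length(sli)))

  sub_mean <- function(tool) vapply(1:10, function(s)
    mean(tm$seconds[tm$tool == tool & tm$subject == s]), numeric(1))
  recomputed <- sub_mean("simnibs") / sub_mean("slicertms")
  per_subject <- data.frame(
    subject = 1:10,
    improvement_printed = pr$improvement_printed,
    improvement_from_printed_means = pr$simnibs_mean_printed / pr$slicertms_mean_printed,
    improvement_recomputed = recomputed)

  list(pooled = pooled,
       per_subject = per_subject,
       mean_improvement_printed = mean(pr$improvement_printed),
       mean_improvement_recomputed = mean(recomputed),
       ttest = twoSampleTTest(sim, sli))
}

#' Write the benchmark report as CSV + text
#'
#' @param report as returned by [reproduceTable2()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTable2Report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$pooled, file.path(dir, "pooled_times.csv"), row.names = FALSE)
  write.csv(report$per_subject, file.path(dir, "per_subject_improvement.csv"),
            row.names = FALSE)
  tt <- report$ttest
  txt <- c(
    sprintf("Pooled visualization times (20 cells per tool):"),
    sprintf("  simnibs   %.5f +/- %.5f s", report$pooled$mean_seconds[1],
            report$pooled$sd_seconds[1]),
    sprintf("  slicertms %.5f +/- %.5f s", report$pooled$mean_seconds[2],
            report$pooled$sd_seconds[2]),
    sprintf("Mean improvement: %.2fx (printed column), %.2fx (recomputed)",
            report$mean_improvement_printed, report$mean_improvement_recomputed),
    sprintf("Independent-samples t-test (pooled variance): t(%d) = %.1f, p = %.3g",
            tt$df, tt$t, tt$p))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
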