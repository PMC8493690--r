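#' Render a run report
#'
#' Reads a completed run directory and produces a bar plot (group mean as
#' percent of control +/- SD, significance stars from the statistics
#' table) plus a plain-text summary per endpoint.
#'
#' @param run_dir directory written by [run_pipeline]
#' @return invisibly, paths of the report files
#' @export
write_report <- function(run_dir) {
  gp <- file.path(run_dir, "groups.csv")
  sp <- file.path(run_dir, "stats.csv")
  wp <- file.path(run_dir, "wells.csv")
  if (!file.exists(gp) || !file.exists(sp) || !file.exists(wp)) {
    stop("incomplete run directory: ", run_dir)
  }
  groups <- utils::read.csv(gp, stringsAsFactors = FALSE)
  stats_tab <- utils::read.csv(sp, stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  ctrl_label <- manifest$control_label
  ctrl_mean <- groups$mean[groups$group_label == ctrl_label]
  groups$sd_pct <- 100 * groups$sd / ctrl_mean
  stars <- stats_tab$stars[match(groups$group_label, stats_tab$dose)]
  groups$stars <- ifelse(is.na(stars), "", stars)
  groups$group_label <- factor(groups$group_label,
                               levels = groups$group_label)
  p <- ggplot2::ggplot(groups, ggplot2::aes(
    x = group_label, y = percent_of_control)) +
    ggplot2::geom_col(fill = "grey35", width = 0.65) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = percent_of_control - sd_pct,
      ymax = percent_of_control + sd_pct), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      y = percent_of_control + sd_pct + 5, label = stars), size = 6) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s (%% of %s)", toupper(manifest$metric),
                              ctrl_label)) +
    ggplot2::theme_classic()
  fig_path <- file.path(run_dir, "report_figure.pdf")
  grDevices::pdf(fig_path, width = 5, height = 4)
  print(p)
  grDevices::dev.off()
  txt <- c(
    sprintf("Endpoint: %s (mode %s)", manifest$metric, manifest$mode),
    sprintf("Control group: %s; trend alpha = %s (one-sided, %s)",
            ctrl_label, manifest$alpha_trend, manifest$direction),
    sprintf("Wells per group: %s",
            paste(sprintf("%s n=%d", groups$group_label, groups$n_wells),
                  collapse = ", ")),
    "",
    "Group means (% of control):",
    sprintf("  %-16s %7.1f%%  (mean %.4f, SD %s) %s",
            groups$group_label, groups$percent_of_control, groups$mean,
            ifelse(is.na(groups$sd), "NA", sprintf("%.4f", groups$sd)),
            groups$stars),
    "",
    "Trend test decisions:",
    sprintf("  %-16s stat %7.3f  crit %6.3f  %s [%s vs %s] %s",
            stats_tab$dose, stats_tab$statistic, stats_tab$critical,
            ifelse(stats_tab$significant, "significant", "ns"),
            stats_tab$test, stats_tab$baseline, stats_tab$stars))
  txt_path <- file.path(run_dir, "report.txt")
  writeLines(txt, txt_path)
  invisible(c(figure = fig_path, summary = txt_path))
}
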