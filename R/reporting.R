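#' Render a masked log2-ratio heatmap
#'
#' Masked cells (negligible changes) are drawn white; the color scale is
#' symmetric around 0 in log2 units.
#'
#' @param h A `mirpetri_heatmap`.
#' @param path Output PNG path.
#' @param main Plot title.
#' @return The path, invisibly.
#' @export
render_heatmap <- function(h, path, main = "log2 ratio vs control") {
  vals <- h$values
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list("experiment",
                                                         names(vals)))
  vals[as.logical(h$mask)] <- NA
  lim <- max(abs(vals), 1e-3, na.rm = TRUE)
  grDevices::png(path, width = 1200, height = 200 + 40 * nrow(vals),
                 res = 120)
  on.exit(grDevices::dev.off())
  if (all(is.na(vals))) {
    graphics::plot.new()
    graphics::title(main = paste(main, "(all changes below mask)"))
  } else {
    ph <- pheatmap::pheatmap(vals, cluster_rows = FALSE,
                             cluster_cols = FALSE, na_col = "white",
                             breaks = seq(-lim, lim, length.out = 101),
                             color = grDevices::colorRampPalette(
                               c("blue", "white", "red"))(100),
                             main = main, silent = TRUE)
    grid::grid.newpage()
    grid::grid.draw(ph$gtable)
  }
  invisible(path)
}

#' Render dose-response curves
#'
#' @param table A [dose_scan()] data frame (`level` + readout columns).
#' @param path Output PNG path.
#' @param log_x Log-scale the dose axis (zero doses are offset to the
#'   smallest positive dose / 10).
#' @return The path, invisibly.
#' @export
render_dose_curves <- function(table, path, log_x = TRUE) {
  long <- stats::reshape(table, direction = "long",
                         varying = setdiff(names(table), "level"),
                         v.names = "value", timevar = "readout",
                         times = setdiff(names(table), "level"))
  if (log_x) {
    pos <- table$level[table$level > 0]
    floor_lv <- if (length(pos)) min(pos) / 10 else 1e-3
    long$level <- pmax(long$level, floor_lv)
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$level, y = .data$value, color = .data$readout)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dose (nM)", y = "steady state (nM)") +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 120)
  invisible(path)
}

#' Export an anti-miRNA ranking table
#'
#' Columns ordered anti-miRNA then P-value, p-values in scientific
#' notation with 3 significant digits.
#'
#' @param ranking A [rank_anti_mirnas()] data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
export_ranking <- function(ranking, path) {
  out <- data.frame(
    `anti-miRNA` = ranking$anti_mirna,
    `P-value` = sprintf("%.2e", ranking$p_value),
    `P-value (BH)` = sprintf("%.2e", ranking$p_bh),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest with config and output checksums
#'
#' @param outputs Character vector of produced file paths.
#' @param config A list describing the run (seeds, parameters, fixture
#'   version); hashed into `config_hash`.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(outputs, config, path) {
  tf <- tempfile()
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "miRpetri",
    version = as.character(utils::packageVersion("miRpetri")),
    config = config,
    config_hash = unname(tools::md5sum(tf)),
    outputs = lapply(outputs, function(f) list(
      file = f, md5 = unname(tools::md5sum(f)))))
  unlink(tf)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
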