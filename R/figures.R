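#' Figures for a pipeline run
#'
#' Best-effort diagnostic figures from a [run_pipeline()] bundle: the
#' neutral-model occurrence-frequency scatter per group (fitted curve,
#' prediction band, above/neutral/below in orange/gray/green), the AVD bar
#' chart per stratum, and the PCoA scatter colored by group. Stages absent
#' from the bundle are skipped.
#'
#' @param bundle return value of [run_pipeline()].
#' @param out_dir output directory (defaults to the run's out_dir).
#' @return Invisibly, the paths of the figures written.
#' @export
make_figures <- function(bundle, out_dir = bundle$config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  part_cols <- c(above = "#E69F00", neutral = "#999999", below = "#009E73")

  if (length(bundle$fits)) {
    pts <- do.call(rbind, lapply(names(bundle$fits), function(g) {
      z <- bundle$fits[[g]]$zotu
      z$group <- g
      z
    }))
    curves <- do.call(rbind, lapply(names(bundle$fits), function(g) {
      fit <- bundle$fits[[g]]
      pr <- exp(seq(log(max(min(fit$zotu$p), 1e-7)), log(max(fit$zotu$p)),
                    length.out = 200))
      cv <- predict(fit, pr)
      cv$group <- g
      cv
    }))
    pl <- ggplot2::ggplot(pts, ggplot2::aes(x = log10(.data$p))) +
      ggplot2::geom_point(ggplot2::aes(y = .data$f_obs, color = .data$partition),
                          size = 0.6, alpha = 0.7) +
      ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$f_pred)) +
      ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$f_lower),
                         linetype = "dashed", color = "#27408B") +
      ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$f_upper),
                         linetype = "dashed", color = "#27408B") +
      ggplot2::scale_color_manual(values = part_cols, drop = TRUE) +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(x = "log10 mean relative abundance",
                    y = "occurrence frequency") +
      ggplot2::theme_bw()
    paths <- c(paths, fig_save(pl, file.path(out_dir, "ncm.png"), 8, 6))
  }

  if (!is.null(bundle$avd$strata)) {
    av <- bundle$avd$strata
    pl <- ggplot2::ggplot(av, ggplot2::aes(x = .data$stratum, y = .data$avd)) +
      ggplot2::geom_col(fill = "#4682B4") +
      ggplot2::labs(x = NULL, y = "AVD (lower = more stable)") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    paths <- c(paths, fig_save(pl, file.path(out_dir, "avd.png"), 6, 4))
  }

  if (!is.null(bundle$ordination) && ncol(bundle$ordination$coordinates) >= 2L) {
    co <- as.data.frame(bundle$ordination$coordinates[, 1:2])
    names(co) <- c("PCo1", "PCo2")
    co$sample_id <- rownames(bundle$ordination$coordinates)
    meta <- as.data.frame(bundle$samples)
    co <- merge(co, meta, by = "sample_id")
    prop <- bundle$ordination$proportion
    pl <- ggplot2::ggplot(co, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                           color = .data$group,
                                           shape = .data$lifestyle)) +
      ggplot2::geom_point(size = 1.6, alpha = 0.85) +
      ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", 100 * prop[1L]),
                    y = sprintf("PCo2 (%.1f%%)", 100 * prop[2L])) +
      ggplot2::theme_bw()
    paths <- c(paths, fig_save(pl, file.path(out_dir, "pcoa.png"), 6, 5))
  }
  invisible(paths)
}

fig_save <- function(plot, path, width, height) {
  ok <- tryCatch({
    suppressWarnings(ggplot2::ggsave(path, plot, width = width,
                                     height = height, dpi = 150))
    TRUE
  }, error = function(e) FALSE)
  if (ok) path else character(0)
}
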