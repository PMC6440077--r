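#' @import ggplot2
NULL

#' Two-panel distribution plot: raw fractions and enrichment
#'
#' Renders the package's signature figure: the top panel shows each
#' sample's raw fraction of nucleotides per feature, the bottom panel the
#' genome-size-normalized enrichment score on the same feature order
#' (1 = no enrichment, drawn as a reference line), with grouped bars per
#' sample. Categories are ordered by hierarchy level then fixed name order;
#' biotypes by descending mean raw fraction across samples. The plotted
#' numbers are also written to a sidecar TSV (`<outPath>.plotdata.tsv`),
#' which is the machine-readable (and testable) surface of the figure.
#'
#' @param tables list of summary tables from [summarizeCounts] (one per
#'   sample), all on the same axis.
#' @param axis `"categories"` or `"biotypes"`.
#' @param outPath output path prefix; the image is written to
#'   `<outPath>.<axis>.<format>`.
#' @param thresholds optional numeric pair capping the y-axis of the raw
#'   panel and of the enrichment panel respectively.
#' @param formats image format(s), any of `"png"`, `"svg"`, `"pdf"`.
#' @param dpi raster resolution, default 150.
#' @return Character vector of written file paths (images then sidecar),
#'   invisibly.
#' @export
plotFeatureDistribution <- function(tables, axis = c("categories",
                                                     "biotypes"),
                                    outPath, thresholds = NULL,
                                    formats = "png", dpi = 150) {
    axis <- match.arg(axis)
    if (is.data.frame(tables)) tables <- list(tables)
    if (!length(tables)) stop("no summary tables to plot")
    bad <- setdiff(formats, c("png", "svg", "pdf"))
    if (length(bad))
        stop("unknown image format(s): ", paste(bad, collapse = ", "))
    if (!is.null(thresholds) &&
        (length(thresholds) != 2 || !is.numeric(thresholds)))
        stop("thresholds must be a numeric pair (raw cap, enrichment cap)")
    df <- do.call(rbind, tables)
    samples <- unique(df$sample)
    if (length(samples) > 12)
        stop(length(samples), " samples is too many for one figure; ",
             "split the batch")
    if (!nrow(df)) stop("empty feature set")

    if (axis == "categories") {
        featOrder <- unique(df$feature[order(.categoryRank(df$feature))])
    } else {
        meanFrac <- rowsum(df$raw_fraction, df$feature) /
            as.numeric(table(df$feature)[sort(unique(df$feature))])
        featOrder <- rownames(meanFrac)[order(-meanFrac[, 1],
                                              rownames(meanFrac))]
    }
    df$feature <- factor(df$feature, levels = featOrder)
    df$sample <- factor(df$sample, levels = samples)
    df <- df[order(df$sample, df$feature), , drop = FALSE]

    sidecar <- paste0(outPath, ".", axis, ".plotdata.tsv")
    utils::write.table(df, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    pRaw <- ggplot(df, aes(x = .data$feature, y = .data$raw_fraction,
                           fill = .data$sample)) +
        geom_col(position = position_dodge2(preserve = "single"),
                 width = 0.8) +
        labs(y = "fraction of nucleotides", x = NULL,
             title = paste("Read distribution by", axis)) +
        theme_bw() +
        theme(axis.text.x = element_blank(),
              axis.ticks.x = element_blank(),
              legend.position = "none")
    pEnr <- ggplot(df, aes(x = .data$feature, y = .data$enrichment,
                           fill = .data$sample)) +
        geom_col(position = position_dodge2(preserve = "single"),
                 width = 0.8) +
        geom_hline(yintercept = 1, linetype = "dashed", linewidth = 0.3) +
        labs(y = "enrichment (sample / genome)", x = NULL, fill = NULL) +
        theme_bw() +
        theme(axis.text.x = element_text(angle = 45, hjust = 1),
              legend.position = "bottom")
    if (!is.null(thresholds)) {
        pRaw <- pRaw + coord_cartesian(ylim = c(0, thresholds[1]))
        pEnr <- pEnr + coord_cartesian(ylim = c(0, thresholds[2]))
    }
    fig <- patchwork::wrap_plots(pRaw, pEnr, ncol = 1, heights = c(1, 1.2))

    paths <- character()
    for (fmt in formats) {
        p <- paste0(outPath, ".", axis, ".", fmt)
        suppressMessages(ggplot2::ggsave(p, fig, width = 9, height = 7,
                                         dpi = dpi))
        paths <- c(paths, p)
    }
    invisible(c(paths, sidecar))
}
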