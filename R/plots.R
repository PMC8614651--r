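# Optional PNG figures written by run_pipeline(make_plots = TRUE): the
# ENC-ratio histogram, the PR2 scatter, per-group neutrality plots and the
# per-group CA ordinations. Base graphics, one file per figure.

group_palette <- function(groups) {
  stats::setNames(grDevices::hcl.colors(max(length(groups), 2L), "Dark 3"),
                  groups)[groups]
}

pipeline_plots <- function(outdir, hist_df, pr2, comp, neut, coa_rows) {
  paths <- character(0)
  save_png <- function(name, expr) {
    p <- file.path(outdir, name)
    grDevices::png(p, width = 1200, height = 900, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    paths <<- c(paths, p)
  }

  if (nrow(hist_df) > 0L) {
    save_png("enc_ratio_hist.png", {
      graphics::barplot(hist_df$count,
                        names.arg = sprintf("[%.2f,%.2f)", hist_df$bin_lo,
                                            hist_df$bin_hi),
                        las = 2, cex.names = 0.7,
                        ylab = "sequences",
                        main = "ENC ratio (expected - observed) / expected")
    })
  }

  ok <- pr2[pr2$defined, , drop = FALSE]
  if (nrow(ok) > 0L) {
    save_png("pr2.png", {
      cols <- group_palette(unique(ok$group))
      graphics::plot(ok$gc_bias, ok$at_bias, col = cols[ok$group], pch = 19,
                     xlim = c(0, 1), ylim = c(0, 1),
                     xlab = "G3 / (G3 + C3)", ylab = "A3 / (A3 + T3)",
                     main = "Parity rule 2")
      graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey50")
      graphics::legend("topright", legend = names(cols), col = cols,
                       pch = 19, bty = "n")
    })
  }

  if (nrow(neut) > 0L) {
    save_png("neutrality.png", {
      ng <- nrow(neut)
      graphics::par(mfrow = c(ceiling(ng / 2), min(ng, 2L)))
      for (i in seq_len(ng)) {
        g <- neut$group[i]
        sub <- comp[comp$group == g, ]
        graphics::plot(sub$p3, sub$p12, pch = 19,
                       xlab = "P3 (GC3)", ylab = "P12",
                       main = sprintf("%s: slope %.3f", g, neut$slope[i]))
        graphics::abline(neut$intercept[i], neut$slope[i], col = "red3")
      }
    })
  }

  coa_df <- do.call(rbind, coa_rows)
  if (!is.null(coa_df) && nrow(coa_df) > 0L) {
    save_png("coa.png", {
      cols <- group_palette(unique(coa_df$group))
      graphics::plot(coa_df$f1, coa_df$f2, col = cols[coa_df$group],
                     pch = 19, xlab = "f1", ylab = "f2",
                     main = "Correspondence analysis of RSCU")
      graphics::abline(h = 0, v = 0, lty = 2, col = "grey50")
      graphics::legend("topright", legend = names(cols), col = cols,
                       pch = 19, bty = "n")
    })
  }
  paths
}
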