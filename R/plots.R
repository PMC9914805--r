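#' Plot cluster condition profiles
#'
#' Line plot of per-cluster mean z-score archetype shapes across the six
#' conditions, the line-graph companion of a cluster heatmap.
#'
#' @param profiles Matrix from [cluster_condition_profile()] (clusters x
#'   conditions).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `profiles`.
#' @export
plot_cluster_profiles <- function(profiles, ...) {
  graphics::matplot(t(profiles), type = "b", lty = 1, pch = 16,
                    xaxt = "n", xlab = "condition",
                    ylab = "mean z-score", ...)
  graphics::axis(1, at = seq_len(ncol(profiles)), labels = colnames(profiles),
                 las = 2, cex.axis = 0.8)
  graphics::legend("topright", legend = rownames(profiles),
                   col = seq_len(nrow(profiles)), lty = 1, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(profiles)
}

#' Plot TSS metaprofiles by expression quintile
#'
#' One line per expression quintile (Q1 = highest) of mean accessibility
#' signal around the TSS, for one condition.
#'
#' @param profiles Output of [tss_quintile_profiles()].
#' @param condition Condition to plot (default the first).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_quintile_profiles <- function(profiles, condition = names(profiles)[1L],
                                   ...) {
  m <- profiles[[condition]]
  pos <- attr(profiles, "positions")
  graphics::matplot(pos, t(m), type = "l", lty = 1,
                    xlab = "distance from TSS (bp)",
                    ylab = "mean signal", main = condition, ...)
  graphics::legend("topright", legend = rownames(m),
                   col = seq_len(nrow(m)), lty = 1, cex = 0.7, bty = "n")
  invisible(m)
}
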