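## Clinical displays of classifier output: the per-score probability
## heatmap ("hot" color scale) and the unidimensional Background Trend
## (BT) — the probability-weighted average score with an uncertainty
## band, smoothed by a 3-epoch moving average.

#' Background Trend from posterior probabilities
#'
#' `bt_raw[t] = sum_c value(c) * p[t,c]`; bt is its centered moving
#' average (window 3 epochs, shrunk at the edges). The uncertainty is
#' the probability-weighted standard deviation of the class values
#' around bt_raw, `sqrt(sum_c p[t,c] * (value(c) - bt_raw[t])^2)` — zero
#' exactly when the posterior is one-hot.
#'
#' @param ps a [ProbSeries-class].
#' @param window moving-average window in epochs (default 3).
#' @return a [BTrend-class].
#' @export
#' @examples
#' p <- probSeries(matrix(rep(0.2, 10), 2, 5), classValues = 0:4)
#' trendValues(btFromProbs(p))       # 2, 2
#' trendUncertainty(btFromProbs(p))  # sqrt(2), sqrt(2)
btFromProbs <- function(ps, window = 3) {
  stopifnot(is(ps, "ProbSeries"))
  P <- probMatrix(ps)
  if (nrow(P) == 0) stop("empty probability series")
  v <- classValues(ps)
  btRaw <- as.numeric(P %*% v)
  unc <- sqrt(pmax(as.numeric(P %*% v^2) - btRaw^2, 0))
  half <- (window - 1) %/% 2
  n <- length(btRaw)
  bt <- vapply(seq_len(n), function(i) {
    mean(btRaw[max(1, i - half):min(n, i + half)])
  }, 0)
  new("BTrend", bt = bt, btRaw = btRaw, uncertainty = unc,
      time = ps@time, window = as.integer(window))
}

#' Heatmap matrix and color mapping from posterior probabilities
#'
#' Returns the K x T image matrix (classes in severity order, one column
#' per 5-min epoch) together with a monotone "hot"-style color scale
#' (black -> red -> yellow -> white with increasing probability). Columns
#' can be renormalized per epoch (`normalize = TRUE`); raw posteriors
#' already sum to 1 per epoch. Epochs flagged in `reject` are rendered in
#' a neutral grey.
#'
#' @param ps a [ProbSeries-class].
#' @param normalize renormalize each column to sum to 1.
#' @param reject optional logical per epoch (REJECT epochs).
#' @param nColors colors in the ramp.
#' @return list with `matrix` (K x T), `colors` (the ramp),
#'   `breaks`, `classValues`, `rejectColor`, `reject`.
#' @export
heatmapMatrix <- function(ps, normalize = FALSE, reject = NULL,
                          nColors = 64) {
  stopifnot(is(ps, "ProbSeries"))
  M <- t(probMatrix(ps))
  if (normalize) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
  }
  rownames(M) <- classValues(ps)
  ramp <- grDevices::colorRampPalette(
    c("black", "#7F0000", "red", "orange", "yellow", "white"))(nColors)
  list(matrix = M, colors = ramp,
       breaks = seq(0, 1, length.out = nColors + 1),
       classValues = classValues(ps),
       rejectColor = "grey70",
       reject = if (is.null(reject)) rep(FALSE, ncol(M)) else reject)
}

#' Render the two-panel clinical report figure
#'
#' Heatmap of score probabilities (top) over the Background Trend with
#' its shaded uncertainty band (bottom), on an hour-scale time axis, with
#' optional expert-score overlays. Output format follows the file
#' extension (pdf, svg or png).
#'
#' @param ps a [ProbSeries-class].
#' @param file output file path (".pdf", ".svg" or ".png").
#' @param references optional named list of [ScoreSeries-class] (or label
#'   vectors) overlaid on the BT panel.
#' @param normalize passed to [heatmapMatrix()].
#' @param title figure title.
#' @return the computed list(heatmap, bt), invisibly.
#' @export
renderReport <- function(ps, file, references = NULL, normalize = FALSE,
                         title = "EEG background classification") {
  stopifnot(is(ps, "ProbSeries"))
  hm <- heatmapMatrix(ps, normalize = normalize)
  bt <- btFromProbs(ps)
  if (!is.null(references)) {
    for (r in references) {
      len <- if (is(r, "ScoreSeries")) nEpochs(r) else length(r)
      if (len != nEpochs(ps)) stop("reference series length mismatch")
    }
  }
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         pdf = grDevices::pdf(file, width = 10, height = 6),
         svg = grDevices::svg(file, width = 10, height = 6),
         png = grDevices::png(file, width = 1200, height = 720, res = 120),
         stop("unsupported output format: ", ext))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  tHours <- ps@time
  v <- classValues(ps)
  graphics::image(x = tHours, y = seq_along(v), z = t(hm$matrix),
                  col = hm$colors, breaks = hm$breaks,
                  xlab = "", ylab = "score", axes = FALSE, main = title)
  graphics::axis(2, at = seq_along(v), labels = v, las = 1)
  graphics::axis(1)
  graphics::box()
  graphics::par(mar = c(4, 4, 1, 1))
  ylim <- range(v)
  graphics::plot(tHours, trendValues(bt), type = "n", ylim = ylim,
                 xlab = "time (h)", ylab = "background trend")
  graphics::polygon(c(tHours, rev(tHours)),
                    c(pmin(bt@btRaw + trendUncertainty(bt), ylim[2]),
                      rev(pmax(bt@btRaw - trendUncertainty(bt), ylim[1]))),
                    col = "grey85", border = NA)
  if (!is.null(references)) {
    cols <- c("blue", "darkgreen", "purple")
    i <- 0
    for (nm in names(references)) {
      i <- i + 1
      r <- references[[nm]]
      rv <- if (is(r, "ScoreSeries")) scores(r) else r
      graphics::lines(tHours, rv, col = cols[((i - 1) %% 3) + 1], lwd = 1,
                      lty = 2)
    }
    graphics::legend("topright", legend = names(references),
                     col = cols[seq_along(references)], lty = 2, bty = "n")
  }
  graphics::lines(tHours, trendValues(bt), lwd = 2)
  invisible(list(heatmap = hm, bt = bt))
}
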