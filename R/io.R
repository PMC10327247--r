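# Serialization helpers: flow checkpoints, training triples and the
# bound-trace figure.

#' Save / load a flow checkpoint
#'
#' The whole estimator (architecture, weights, standardizer) in a single
#' file via R serialization.
#'
#' @param flow an `lfpce_flow`.
#' @param path checkpoint file path.
#' @export
flow_save <- function(flow, path) {
  stopifnot(inherits(flow, "lfpce_flow"))
  saveRDS(flow, path)
  invisible(path)
}

#' @rdname flow_save
#' @export
flow_load <- function(path) {
  flow <- readRDS(path)
  if (!inherits(flow, "lfpce_flow")) {
    stop("checkpoint does not contain a flow estimator", call. = FALSE)
  }
  flow
}

#' Write / read simulation triples
#'
#' Flat-table serialization of `(theta, xi, y)` training triples:
#' columns `theta1..thetaP`, `xi1..xiD`, `y1..yD`.  CSV for portability;
#' `format = "rds"` gives a compact columnar binary alternative.
#'
#' @param theta `n x p` parameter matrix.
#' @param xi `n x D` per-sample design matrix (or one shared design).
#' @param y `n x D` response matrix.
#' @param path output file.
#' @param format `"csv"` or `"rds"`.
#' @export
write_triples <- function(theta, xi, y, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  theta <- as.matrix(theta); y <- as.matrix(y)
  if (inherits(xi, "lfpce_design") || is.null(dim(xi))) {
    xiv <- if (inherits(xi, "lfpce_design")) xi$values else as.numeric(xi)
    xi <- matrix(xiv, nrow(y), length(xiv), byrow = TRUE)
  }
  df <- data.frame(theta, xi, y)
  names(df) <- c(paste0("theta", seq_len(ncol(theta))),
                 paste0("xi", seq_len(ncol(xi))),
                 paste0("y", seq_len(ncol(y))))
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
  else saveRDS(df, path)
  invisible(path)
}

#' @rdname write_triples
#' @param p parameter dimension used to split the columns back out.
#' @export
read_triples <- function(path, p = 2L) {
  df <- if (grepl("\\.rds$", path)) readRDS(path)
  else utils::read.csv(path)
  D <- (ncol(df) - p) / 2L
  list(theta = as.matrix(df[, seq_len(p), drop = FALSE]),
       xi = as.matrix(df[, p + seq_len(D), drop = FALSE]),
       y = as.matrix(df[, p + D + seq_len(D), drop = FALSE]))
}

#' Plot smoothed bound traces to a vector-graphics file
#'
#' @param traces as in [report_fig1_analogue()].
#' @param file output PDF path (`NULL` draws on the current device).
#' @param window moving-average window.
#' @export
plot_eig_traces <- function(traces, file = NULL, window = 10L) {
  sm <- report_fig1_analogue(traces, window = window)
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 4)
    on.exit(grDevices::dev.off())
  }
  runs <- unique(sm$run)
  cols <- grDevices::hcl.colors(max(length(runs), 2L), "Dark 3")
  plot(NULL, xlim = range(sm$step), ylim = range(sm$bound_smoothed),
       xlab = "gradient step", ylab = "EIG lower bound (nats)",
       main = sprintf("LF-PCE bound, window-%d moving average", window))
  for (i in seq_along(runs)) {
    s <- sm[sm$run == runs[i], ]
    graphics::lines(s$step, s$bound_smoothed, col = cols[i], lwd = 1.5)
  }
  graphics::legend("bottomright", legend = runs, col = cols[seq_along(runs)],
                   lwd = 1.5, bty = "n", cex = 0.8)
  invisible(sm)
}
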