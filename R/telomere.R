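# qPCR T/S-ratio arithmetic: standard curves, triplicate handling,
# interplate normalization via a shared control sample, and linear batch
# adjustment. Also the sequencing-run correction applied to WGS-based
# telomere-length estimates.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of \code{Cq = slope * log10(conc) + intercept} over a
#' dilution series (default design: threefold dilutions 109.0, 36.3, 12.1,
#' 4.0, 1.3 ng/uL). Amplification efficiency is \code{10^(-1/slope) - 1};
#' an ideal doubling assay has slope -3.3219 and efficiency 1.
#'
#' @param conc Standard concentrations (ng/uL); at least 3 distinct values.
#' @param cq Observed quantification cycles, same length.
#' @return An object of class \code{standard_curve}: \code{slope},
#'   \code{intercept}, \code{efficiency}, \code{r_squared}, \code{n}.
#' @export
fit_standard_curve <- function(conc, cq) {
  if (length(conc) != length(cq)) stop("conc and cq lengths differ")
  ok <- stats::complete.cases(conc, cq)
  conc <- conc[ok]; cq <- cq[ok]
  if (length(unique(conc)) < 3L) {
    stop("standard curve needs at least 3 distinct concentrations")
  }
  if (any(conc <= 0)) stop("standard concentrations must be positive")
  fit <- stats::lm(cq ~ log10(conc))
  slope <- unname(stats::coef(fit)[2L])
  # suppressWarnings: a noise-free dilution series is a legitimate perfect fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         efficiency = 10^(-1 / slope) - 1,
         r_squared = r2,
         n = length(conc)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve (", x$n, " points)\n", sep = "")
  cat(sprintf("  Cq = %.4f * log10(conc) + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  efficiency = %.3f, r^2 = %.4f\n", x$efficiency, x$r_squared))
  invisible(x)
}

#' Interpolate concentrations from a standard curve
#'
#' @param object A \code{standard_curve}.
#' @param cq Quantification cycles to interpolate.
#' @param ... Unused.
#' @return Concentrations in the standards' units.
#' @export
predict.standard_curve <- function(object, cq, ...) {
  10^((cq - object$intercept) / object$slope)
}

# Triplicate collapse: drop the single well farthest from the median Cq if
# it deviates by more than max_dev cycles, then flag the sample for repeat
# if the concentration CV of the remaining wells still exceeds cv_threshold.
.collapse_triplicate <- function(cq, conc, max_dev = 0.5, cv_threshold = 0.15) {
  keep <- rep(TRUE, length(cq))
  if (length(cq) >= 3L) {
    dev <- abs(cq - stats::median(cq))
    worst <- which.max(dev)
    if (dev[worst] > max_dev) keep[worst] <- FALSE
  }
  m <- mean(conc[keep])
  cv <- if (sum(keep) > 1L) stats::sd(conc[keep]) / m else 0
  list(conc = m, cv = cv, flag_repeat = cv > cv_threshold, n_used = sum(keep))
}

#' Compute T/S ratios from qPCR plate data
#'
#' Full plate-to-ratio arithmetic: per-plate standard curves are fitted from
#' the standard wells; sample and control Cq values are interpolated to
#' concentrations; triplicates are collapsed with single-outlier removal;
#' each plate's concentrations are multiplied by a normalization factor
#' (reference control concentration divided by that plate's mean control
#' concentration) to remove inter-plate shifts; T and S concentrations are
#' optionally batch-adjusted by linear regression; and the T/S ratio is the
#' normalized telomere concentration over the normalized single-copy-gene
#' (36B4) concentration.
#'
#' The normalization reference defaults to the control sample's nominal
#' concentration: a data-independent reference makes normalization exactly
#' scale-equivariant (rescaling all concentrations of one plate leaves every
#' T/S ratio unchanged). Set \code{reference = "grand_mean"} to use the
#' control's grand mean concentration across plates instead, which fixes
#' the output scale from the data itself.
#'
#' @param plates Long data frame of wells with columns \code{plate_id},
#'   \code{assay} ("T" or "S"), \code{sample_id}, \code{role} ("sample",
#'   "standard" or "control"), \code{cq}, \code{conc} (known concentration,
#'   standards only) and optionally \code{batch}.
#' @param reference \code{"nominal"} (default) or \code{"grand_mean"}.
#' @param control_nominal Nominal control concentration in ng/uL used when
#'   \code{reference = "nominal"} (default 35).
#' @param outlier_max_dev_cq Triplicate outlier threshold in cycles
#'   (default 0.5).
#' @param cv_threshold Concentration CV above which a sample is flagged for
#'   repeat (default 0.15).
#' @param adjust_batch Batch-adjust T and S concentrations before the final
#'   ratio when at least two batches are present (default TRUE).
#' @return Data frame with one row per sample: \code{sample_id},
#'   \code{t_conc}, \code{s_conc} (normalized), \code{ts_ratio},
#'   \code{batch}, \code{ts_ratio_adjusted}, \code{flag_repeat}. Fitted
#'   curves are attached as the \code{"curves"} attribute.
#' @export
compute_ts <- function(plates, reference = c("nominal", "grand_mean"),
                       control_nominal = 35, outlier_max_dev_cq = 0.5,
                       cv_threshold = 0.15, adjust_batch = TRUE) {
  reference <- match.arg(reference)
  need <- c("plate_id", "assay", "sample_id", "role", "cq")
  miss <- setdiff(need, names(plates))
  if (length(miss) > 0L) stop("plate table missing column '", miss[1L], "'")
  if (!all(plates$assay %in% c("T", "S"))) stop("assay must be 'T' or 'S'")
  if (is.null(plates$batch)) plates$batch <- "batch1"

  plate_ids <- unique(plates$plate_id)
  curves <- list()
  per_plate <- list()
  for (pid in plate_ids) {
    pw <- plates[plates$plate_id == pid, , drop = FALSE]
    std <- pw[pw$role == "standard", , drop = FALSE]
    if (nrow(std) < 3L) stop("plate '", pid, "' lacks a usable standard series")
    curve <- fit_standard_curve(std$conc, std$cq)
    curves[[as.character(pid)]] <- curve
    ctrl <- pw[pw$role == "control", , drop = FALSE]
    if (nrow(ctrl) == 0L) stop("control sample missing on plate '", pid, "'")
    wells <- pw[pw$role %in% c("sample", "control"), , drop = FALSE]
    wells$conc_interp <- predict(curve, wells$cq)
    collapsed <- lapply(split(wells, wells$sample_id), function(w) {
      tri <- .collapse_triplicate(w$cq, w$conc_interp,
                                  max_dev = outlier_max_dev_cq,
                                  cv_threshold = cv_threshold)
      data.frame(plate_id = pid, assay = w$assay[1L], sample_id = w$sample_id[1L],
                 role = w$role[1L], batch = w$batch[1L], conc = tri$conc,
                 flag_repeat = tri$flag_repeat, stringsAsFactors = FALSE)
    })
    per_plate[[as.character(pid)]] <- do.call(rbind, collapsed)
  }
  conc_tab <- do.call(rbind, per_plate)
  rownames(conc_tab) <- NULL

  # per-plate normalization factor from the shared control sample
  ctrl_tab <- conc_tab[conc_tab$role == "control", , drop = FALSE]
  for (assay in unique(conc_tab$assay)) {
    ctrl_a <- ctrl_tab[ctrl_tab$assay == assay, , drop = FALSE]
    ref <- switch(reference,
                  nominal = control_nominal,
                  grand_mean = mean(ctrl_a$conc))
    for (pid in unique(conc_tab$plate_id[conc_tab$assay == assay])) {
      ctrl_p <- ctrl_a$conc[ctrl_a$plate_id == pid]
      if (length(ctrl_p) == 0L) stop("control sample missing on plate '", pid, "'")
      sel <- conc_tab$plate_id == pid & conc_tab$assay == assay
      conc_tab$conc[sel] <- conc_tab$conc[sel] * ref / mean(ctrl_p)
    }
  }
  samples <- conc_tab[conc_tab$role == "sample", , drop = FALSE]

  # optional batch adjustment of T and S concentrations before the ratio
  samples$conc_adj <- samples$conc
  if (adjust_batch && length(unique(samples$batch)) >= 2L) {
    for (assay in unique(samples$assay)) {
      sel <- samples$assay == assay
      samples$conc_adj[sel] <- batch_adjust(samples$conc[sel], samples$batch[sel])
    }
  }

  tw <- samples[samples$assay == "T", , drop = FALSE]
  sw <- samples[samples$assay == "S", , drop = FALSE]
  common <- intersect(tw$sample_id, sw$sample_id)
  tw <- tw[match(common, tw$sample_id), , drop = FALSE]
  sw <- sw[match(common, sw$sample_id), , drop = FALSE]
  out <- data.frame(
    sample_id = common,
    t_conc = tw$conc,
    s_conc = sw$conc,
    ts_ratio = tw$conc / sw$conc,
    batch = tw$batch,
    ts_ratio_adjusted = tw$conc_adj / sw$conc_adj,
    flag_repeat = tw$flag_repeat | sw$flag_repeat,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

#' Remove batch effects by linear regression
#'
#' Regresses the values on the batch indicator and returns residuals plus
#' the grand mean, so batch main effects are removed exactly while the
#' overall mean is preserved. Used for qPCR T and S concentrations across
#' experimental batches and for WGS telomere-length estimates across
#' sequencing runs.
#'
#' @param values Numeric vector.
#' @param batch Batch / sequencing-run labels, same length.
#' @return Adjusted numeric vector. A single batch returns the input
#'   unchanged, with a warning.
#' @export
batch_adjust <- function(values, batch) {
  if (length(values) != length(batch)) stop("values and batch lengths differ")
  b <- factor(batch)
  if (nlevels(b) < 2L) {
    warning("single batch: returning values unchanged")
    return(values)
  }
  counts <- table(b[!is.na(values)])
  if (any(counts < 2L)) {
    stop("each batch needs at least 2 observations; too small: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  fit <- stats::lm(values ~ b, na.action = stats::na.exclude)
  unname(stats::residuals(fit) + mean(values, na.rm = TRUE))
}
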