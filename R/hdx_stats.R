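#' Relative deuterium uptake as a percentage
#'
#' Expresses a raw uptake (deuterons) relative to the theoretical maximum
#' under the labeling conditions, \code{labeling_fraction * n_exch}.
#'
#' @param uptake deuterons (numeric vector).
#' @param n_exch maximum exchangeable amides (see \code{\link{max_exchangeable}}).
#' @param labeling_fraction deuterium fraction of the labeling buffer; 0.9 for
#'   a 10-fold dilution into deuterated buffer (default).
#' @return percentage (0 = no uptake; 100 = saturated).
#' @export
relative_uptake <- function(uptake, n_exch, labeling_fraction = 0.9) {
  if (any(n_exch < 1)) stop("n_exch must be >= 1")
  stopifnot(labeling_fraction > 0, labeling_fraction <= 1)
  100 * uptake / (labeling_fraction * n_exch)
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, the per-cell test of the hybrid significance criteria. Degenerate
#' inputs follow explicit conventions rather than producing NaN: both samples
#' with zero variance and equal means give p = 1; zero variance with unequal
#' means gives p = .Machine$double.xmin and a \code{degenerate} flag.
#'
#' @param xs,ys numeric samples (each of size >= 2).
#' @return list with \code{t_stat}, \code{dof}, \code{p_value},
#'   \code{degenerate}.
#' @export
welch_t_test <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 2L || length(ys) < 2L)
    stop("each sample must have >= 2 observations")
  nx <- length(xs); ny <- length(ys)
  vx <- stats::var(xs); vy <- stats::var(ys)
  dm <- mean(xs) - mean(ys)
  if (vx == 0 && vy == 0) {
    if (dm == 0)
      return(list(t_stat = 0, dof = nx + ny - 2, p_value = 1,
                  degenerate = TRUE))
    return(list(t_stat = sign(dm) * Inf, dof = nx + ny - 2,
                p_value = .Machine$double.xmin, degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t_stat <- dm / sqrt(se2)
  dof <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = dof)
  list(t_stat = t_stat, dof = dof, p_value = max(p, .Machine$double.xmin),
       degenerate = FALSE)
}

#' Differential deuterium uptake between two states
#'
#' For every (peptide, timepoint) present in both states, computes
#' \code{delta_d = mean(D_holo) - mean(D_apo)}, the replicate statistics, and
#' the Welch test. Cells with fewer than 2 replicates in either state are
#' emitted with test fields \code{NA} and \code{test_available = FALSE}.
#'
#' @param ds an \code{hdx_dataset}.
#' @param holo_state,apo_state state labels in \code{ds$states}.
#' @param log_transform apply the Welch test to log-uptake instead of raw
#'   uptake (conventional for relative-uptake time courses; default FALSE
#'   for delta-D testing). \code{delta_d} and the SDs stay on the raw scale.
#' @return data frame of class \code{hdx_differential}, one row per peptide x
#'   timepoint: peptide identity, \code{delta_d}, \code{sd_holo},
#'   \code{sd_apo}, \code{n_holo}, \code{n_apo}, \code{t_stat}, \code{dof},
#'   \code{p_value}; ordered by peptide start, end, timepoint. Carries the
#'   state pair as attributes.
#' @export
delta_uptake <- function(ds, holo_state, apo_state, log_transform = FALSE) {
  stopifnot(inherits(ds, "hdx_dataset"))
  for (s in c(holo_state, apo_state))
    if (!s %in% ds$states) stop("state not present in dataset: ", s)
  rec <- ds$records
  cell_stats <- function(state) {
    sub <- rec[rec$state == state, ]
    agg <- stats::aggregate(uptake ~ sequence + start + end + timepoint,
                            data = sub,
                            FUN = function(v) c(m = mean(v),
                                                s = stats::sd(v),
                                                n = length(v)))
    cbind(agg[c("sequence", "start", "end", "timepoint")],
          as.data.frame(agg$uptake))
  }
  h <- cell_stats(holo_state); a <- cell_stats(apo_state)
  m <- merge(h, a, by = c("sequence", "start", "end", "timepoint"),
             suffixes = c("_holo", "_apo"))
  if (nrow(m) == 0L)
    stop("no shared (peptide, timepoint) cells between states")
  out <- data.frame(
    sequence = m$sequence, start = m$start, end = m$end,
    timepoint = m$timepoint,
    delta_d = m$m_holo - m$m_apo,
    sd_holo = m$s_holo, sd_apo = m$s_apo,
    n_holo = as.integer(m$n_holo), n_apo = as.integer(m$n_apo),
    stringsAsFactors = FALSE)
  out$test_available <- out$n_holo >= 2L & out$n_apo >= 2L
  out$t_stat <- out$dof <- out$p_value <- NA_real_
  for (i in which(out$test_available)) {
    xs <- rec$uptake[rec$state == holo_state & rec$sequence == out$sequence[i] &
                     rec$start == out$start[i] & rec$end == out$end[i] &
                     rec$timepoint == out$timepoint[i]]
    ys <- rec$uptake[rec$state == apo_state & rec$sequence == out$sequence[i] &
                     rec$start == out$start[i] & rec$end == out$end[i] &
                     rec$timepoint == out$timepoint[i]]
    if (log_transform) {
      eps <- 1e-6
      w <- welch_t_test(log(pmax(xs, eps)), log(pmax(ys, eps)))
    } else {
      w <- welch_t_test(xs, ys)
    }
    out$t_stat[i] <- w$t_stat; out$dof[i] <- w$dof
    out$p_value[i] <- w$p_value
  }
  out <- out[order(out$start, out$end, out$timepoint), ]
  rownames(out) <- NULL
  attr(out, "holo_state") <- holo_state
  attr(out, "apo_state") <- apo_state
  class(out) <- c("hdx_differential", "data.frame")
  out
}

#' Global significance threshold from the pooled standard deviation
#'
#' The magnitude arm of the hybrid criteria. The replicate standard deviation
#' is pooled over every peptide-timepoint cell of both states of the pair
#' (the per-dataset "global" scope), and converted into a threshold on
#' \code{|delta_d|} via the two-sided Student-t confidence bound
#' \deqn{thr = t_{1-\alpha/2, dof} \; s_p \sqrt{1/n_{holo} + 1/n_{apo}}}
#' with the pooled degrees of freedom \code{sum(n_cell - 1)} and the modal
#' per-cell replicate counts.
#'
#' @param ds an \code{hdx_dataset}.
#' @param holo_state,apo_state the state pair.
#' @param alpha significance level (default 0.05).
#' @return list of class \code{hdx_threshold}: \code{pooled_sd}, \code{dof},
#'   \code{alpha}, \code{n_holo}, \code{n_apo}, \code{threshold},
#'   \code{label}.
#' @export
global_threshold <- function(ds, holo_state, apo_state, alpha = 0.05) {
  stopifnot(inherits(ds, "hdx_dataset"), alpha > 0, alpha < 1)
  rec <- ds$records[ds$records$state %in% c(holo_state, apo_state), ]
  if (nrow(rec) == 0L) stop("states not present: ", holo_state, ", ", apo_state)
  cells <- stats::aggregate(
    uptake ~ sequence + start + end + timepoint + state, data = rec,
    FUN = function(v) c(ss = sum((v - mean(v))^2), n = length(v)))
  ss <- cells$uptake[, "ss"]; n <- cells$uptake[, "n"]
  keep <- n >= 2
  dof <- sum(n[keep] - 1)
  if (dof == 0) stop("no cell has >= 2 replicates; cannot pool variance")
  pooled_sd <- sqrt(sum(ss[keep]) / dof)
  mode_n <- function(state) {
    ns <- n[cells$state == state & keep]
    as.integer(names(which.max(table(ns))))
  }
  n_holo <- mode_n(holo_state); n_apo <- mode_n(apo_state)
  thr <- stats::qt(1 - alpha / 2, df = dof) * pooled_sd *
    sqrt(1 / n_holo + 1 / n_apo)
  if (pooled_sd == 0)
    warning("all-zero replicate variance; threshold is 0")
  structure(list(pooled_sd = pooled_sd, dof = dof, alpha = alpha,
                 n_holo = n_holo, n_apo = n_apo, threshold = thr,
                 label = paste0(holo_state, "-", apo_state)),
            class = "hdx_threshold")
}

#' @export
print.hdx_threshold <- function(x, ...) {
  cat(sprintf(
    "<hdx_threshold> %s: pooled SD %.4g (dof %d), alpha %.3g -> |dD| > %.4g\n",
    x$label, x$pooled_sd, x$dof, x$alpha, x$threshold))
  invisible(x)
}

#' Apply the hybrid significance criteria
#'
#' A peptide-timepoint cell is significant only if BOTH arms hold:
#' \code{|delta_d| > threshold} and \code{p_value < alpha}. Direction is
#' protected (\code{delta_d < 0}, less uptake when ligand-bound) or
#' deprotected (\code{delta_d > 0}). Cells without an available test are
#' never significant.
#'
#' @param diffs an \code{hdx_differential} from \code{\link{delta_uptake}}.
#' @param thr an \code{hdx_threshold} from \code{\link{global_threshold}}.
#' @param p_adjust \code{"none"} (default, matching the hybrid criteria) or
#'   \code{"BH"} for an additional Benjamini-Hochberg layer on the p values
#'   before the alpha comparison.
#' @return \code{diffs} with \code{significant} (logical) and
#'   \code{direction} (\code{"protected"}, \code{"deprotected"},
#'   \code{"none"}) columns filled.
#' @export
hybrid_classify <- function(diffs, thr, p_adjust = c("none", "BH")) {
  stopifnot(inherits(diffs, "hdx_differential"), inherits(thr, "hdx_threshold"))
  p_adjust <- match.arg(p_adjust)
  p <- if (p_adjust == "BH") stats::p.adjust(diffs$p_value, "BH")
       else diffs$p_value
  sig <- diffs$test_available &
    abs(diffs$delta_d) > thr$threshold &
    !is.na(p) & p < thr$alpha
  diffs$significant <- sig
  diffs$direction <- ifelse(!sig, "none",
                            ifelse(diffs$delta_d < 0, "protected",
                                   "deprotected"))
  attr(diffs, "threshold") <- thr
  diffs
}

#' Per-peptide residual curves
#'
#' The residual-plot summary: per peptide, the differential uptake at each
#' timepoint plus their sum (the total differential uptake), ordered by
#' peptide start then end.
#'
#' @param diffs an \code{hdx_differential}.
#' @return data frame: peptide identity, one \code{dD_<t>} column per
#'   timepoint, and \code{total}.
#' @export
residual_curves <- function(diffs) {
  stopifnot(inherits(diffs, "hdx_differential"))
  tps <- sort(unique(diffs$timepoint))
  wide <- stats::reshape(
    as.data.frame(diffs)[c("sequence", "start", "end", "timepoint", "delta_d")],
    idvar = c("sequence", "start", "end"), timevar = "timepoint",
    direction = "wide")
  dcols <- paste0("delta_d.", tps)
  names(wide)[match(dcols, names(wide))] <- paste0("dD_", tps)
  wide$total <- rowSums(wide[paste0("dD_", tps)], na.rm = TRUE)
  wide <- wide[order(wide$start, wide$end), ]
  rownames(wide) <- NULL
  wide
}
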