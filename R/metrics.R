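# The three conversion-QC metrics ---------------------------------------

#' Bisulfite conversion efficiency (percent)
#'
#' The fraction of the short amplicon present as converted template:
#' `100 * q_short_t / (q_short_c + q_short_t)`.  Complete conversion gives
#' 100 (no unconverted short-C signal); equal converted and unconverted
#' amounts give 50.  When both quantities are zero the efficiency is
#' undefined (`NA`): nothing amplified.
#'
#' @param q_short_c Unconverted short amplicon amount (short-C channel).
#' @param q_short_t Converted short amplicon amount (short-T channel, on the
#'   short-C scale).
#' @return Percent in \[0, 100\]; `NA` where both inputs are zero.
#' @export
#' @examples
#' conversion_efficiency(0, 1)    # 100
#' conversion_efficiency(2, 2)    # 50
conversion_efficiency <- function(q_short_c, q_short_t) {
  stopifnot(all(q_short_c >= 0, na.rm = TRUE),
            all(q_short_t >= 0, na.rm = TRUE))
  tot <- q_short_c + q_short_t
  out <- 100 * q_short_t / tot
  out[tot == 0] <- NA_real_
  out
}

#' Degradation level of a converted sample relative to its source gDNA
#'
#' The short/long amplicon quantity ratio of the converted sample divided by
#' the same ratio in its paired genomic DNA:
#' `[(bs_short_c + bs_short_t) / bs_long] / [g_short_c / g_long]`.
#' A value of 1 means the conversion step preserved the size distribution;
#' values above 1 mean the long amplicon was preferentially lost (size-
#' dependent degradation).  Pairing with the sample's own gDNA normalises
#' individual copy-number variation of the two loci, so scaling all
#' quantities of either sample by a constant leaves the result unchanged.
#' The gDNA short amount uses the short-C channel only (gDNA has no short-T
#' signal).
#'
#' @param bs_short_c,bs_short_t,bs_long Converted-sample amounts.
#' @param g_short_c,g_long Paired gDNA amounts; must be > 0.
#' @return Dimensionless ratio > 0; `Inf` when `bs_long` is 0 while the
#'   short signal is present (severe degradation, a finding rather than
#'   missing data); `NA` when the converted sample has no signal at all.
#' @export
#' @examples
#' degradation_level(1, 1, 1, 2, 1)   # (2/1)/(2/1) = 1
degradation_level <- function(bs_short_c, bs_short_t, bs_long,
                              g_short_c, g_long) {
  if (any(g_short_c <= 0) || any(g_long <= 0)) {
    stop("invalid gDNA pair: gDNA short-C and long amounts must be > 0",
         call. = FALSE)
  }
  bs_short <- bs_short_c + bs_short_t
  g_ratio <- g_short_c / g_long
  out <- (bs_short / bs_long) / g_ratio
  out[bs_long == 0 & bs_short > 0] <- Inf
  out[bs_long == 0 & bs_short == 0] <- NA_real_
  out
}

#' Recovery of amplifiable DNA through the conversion step (percent)
#'
#' The short amplicon content of the converted sample over the short-C
#' content of its paired gDNA, times two because only the sense strand of
#' bisulfite-converted DNA is amplifiable while both gDNA strands are, and
#' times an elution-volume correction `elution_volume / baseline_volume`
#' because a sample eluted in a larger volume is more dilute per ul of
#' template:
#' `100 * 2 * (bs_short_c + bs_short_t) / g_short_c * elution/baseline`.
#'
#' @param bs_short_c,bs_short_t Converted-sample short amounts.
#' @param g_short_c Paired gDNA short-C amount; must be > 0.
#' @param elution_volume Elution volume of the converted sample (ul).
#' @param baseline_volume Reference elution volume (ul, default 10).
#' @return Percent >= 0.
#' @export
#' @examples
#' recovery(0.25, 0, 1)                       # 50
#' recovery(0.25, 0.25, 1, elution_volume = 20)  # 200
recovery <- function(bs_short_c, bs_short_t, g_short_c,
                     elution_volume = 10, baseline_volume = 10) {
  if (any(g_short_c <= 0)) {
    stop("invalid gDNA pair: gDNA short-C amount must be > 0", call. = FALSE)
  }
  100 * 2 * (bs_short_c + bs_short_t) / g_short_c *
    (elution_volume / baseline_volume)
}

# IPC inhibition QC ------------------------------------------------------

#' Flag PCR inhibition from internal positive control Cts
#'
#' Every well carries a fixed number of copies of an exogenous synthetic
#' template (the IPC), so its Ct should be constant across a run.  A sample
#' whose IPC Ct exceeds the run median by more than `threshold` cycles is
#' flagged as inhibited.
#'
#' @param ipc_ct Named or unnamed numeric vector of per-sample IPC Cts
#'   (undetermined = `NA`, always flagged: total inhibition).
#' @param threshold Cycles above the run median that trigger a flag
#'   (default 2).
#' @return Tibble with `sample_id` (if names given), `ipc_ct`, `run_median`
#'   and logical `inhibited`.
#' @export
ipc_qc <- function(ipc_ct, threshold = 2) {
  if (length(ipc_ct) == 0) {
    stop("IPC channel missing: no IPC Ct values supplied", call. = FALSE)
  }
  med <- stats::median(ipc_ct, na.rm = TRUE)
  flag <- is.na(ipc_ct) | (ipc_ct - med) > threshold
  tibble::tibble(
    sample_id = if (is.null(names(ipc_ct))) NA_character_ else names(ipc_ct),
    ipc_ct = unname(ipc_ct),
    run_median = med,
    inhibited = unname(flag)
  )
}

# Kit-level summary ------------------------------------------------------

#' Summarise per-sample metrics by conversion kit
#'
#' Per-kit location (mean by default, median optionally) of conversion
#' efficiency, degradation level and recovery, with a rank per metric
#' (efficiency and recovery ranked descending: higher is better; degradation
#' level ranked ascending: lower is better).  If a per-sample fluorometric
#' (Qubit) recovery column is present, the Pearson correlation between the
#' qPCR and fluorometric recovery across all samples is attached as an
#' attribute `recovery_correlation`.
#'
#' @param results Tibble with columns `sample_id`, `kit`,
#'   `conversion_efficiency`, `degradation_level`, `recovery`, and
#'   optionally `qubit_recovery`.
#' @param stat `"mean"` or `"median"`.
#' @return Tibble with one row per kit: the summary of each metric and
#'   `conversion_rank`, `dl_rank`, `recovery_rank` columns.
#' @export
summarize_kits <- function(results, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") {
    function(x) mean(x[is.finite(x)])
  } else {
    function(x) stats::median(x[is.finite(x)])
  }
  if (nrow(results) == 0) stop("no results to summarise", call. = FALSE)
  g <- dplyr::group_by(results, .data$kit)
  out <- dplyr::summarise(
    g,
    n = dplyr::n(),
    conversion_efficiency = f(.data$conversion_efficiency),
    degradation_level = f(.data$degradation_level),
    recovery = f(.data$recovery),
    qubit_recovery = if ("qubit_recovery" %in% names(results))
      f(.data$qubit_recovery) else NA_real_,
    .groups = "drop"
  )
  out$conversion_rank <- rank(-out$conversion_efficiency, ties.method = "min")
  out$dl_rank <- rank(out$degradation_level, ties.method = "min")
  out$recovery_rank <- rank(-out$recovery, ties.method = "min")
  if ("qubit_recovery" %in% names(results)) {
    ok <- is.finite(results$recovery) & is.finite(results$qubit_recovery)
    if (sum(ok) >= 3) {
      attr(out, "recovery_correlation") <-
        stats::cor(results$recovery[ok], results$qubit_recovery[ok],
                   method = "pearson")
    }
  }
  out
}
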