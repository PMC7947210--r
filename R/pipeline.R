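# End-to-end run evaluation ---------------------------------------------

channel_ct <- function(wells, sample, chan) {
  ct <- wells$ct[wells$sample_id == sample & wells$channel == chan]
  if (length(ct) == 0) NA_real_ else ct[1]
}

#' Evaluate a full run: curves, transform, quantities and metrics
#'
#' The complete analysis of one multiplex qPCR run:
#' \enumerate{
#'   \item collapse replicate wells;
#'   \item fit the short-C and long-Cfree standard curves on the genomic
#'     standard dilution series;
#'   \item fit the short-T to short-C transforming equation on the C/T
#'     indicator dilutions (run flagged unreliable if its R-squared < 0.99);
#'   \item quantify every gDNA and converted (BS-DNA) sample on the three
#'     quantification channels;
#'   \item compute conversion efficiency, degradation level and recovery for
#'     every converted sample against its paired gDNA, plus IPC inhibition
#'     flags.
#' }
#'
#' @param plate A [bisque_plate()] containing `STANDARD`, `CT_INDICATOR`,
#'   `GDNA` and `BSDNA` wells.
#' @param sample_sheet Tibble pairing converted samples to their source:
#'   columns `sample_id` (the BSDNA sample), `gdna_id`, `kit`, and
#'   optionally `elution_volume` (ul, default 10) and `qubit_recovery`.
#' @param ipc_threshold Cycles above the run-median IPC Ct that flag
#'   inhibition.
#' @param r2_min Reliability threshold for the transforming equation.
#' @param discordance_cycles Replicate discordance threshold, see
#'   [collapse_replicates()].
#' @return An object of class `bisque_run` with elements `curves` (named
#'   list of `standard_curve`), `transform` (`ct_transform`), `quantities`
#'   (per-sample amounts tibble), `results` (per converted sample: the three
#'   metrics plus QC flags), `ipc` (IPC QC table), `reliable` (logical).
#' @export
evaluate_run <- function(plate, sample_sheet, ipc_threshold = 2,
                         r2_min = 0.99, discordance_cycles = 0.5) {
  stopifnot(inherits(plate, "bisque_plate"))
  sample_sheet <- tibble::as_tibble(sample_sheet)
  if (!"elution_volume" %in% names(sample_sheet)) {
    sample_sheet$elution_volume <- 10
  }
  flat <- collapse_replicates(plate, discordance_cycles = discordance_cycles)
  w <- flat$wells

  std <- w[w$role == "STANDARD", ]
  if (nrow(std) == 0) {
    stop("no STANDARD wells on the plate: cannot fit standard curves",
         call. = FALSE)
  }
  ind <- w[w$role == "CT_INDICATOR", ]
  if (nrow(ind) == 0) {
    stop("no CT_INDICATOR wells on the plate: cannot fit the short-T ",
         "transforming equation", call. = FALSE)
  }

  # a standard dilution with no signal cannot enter the fit
  std_c <- std[std$channel == "SHORT_C" & !is.na(std$ct), ]
  std_l <- std[std$channel == "LONG_CFREE" & !is.na(std$ct), ]
  curves <- list(
    SHORT_C = fit_standard_curve(std_c$known_amount, std_c$ct,
                                 channel = "SHORT_C", unit = "ng"),
    LONG_CFREE = fit_standard_curve(std_l$known_amount, std_l$ct,
                                    channel = "LONG_CFREE", unit = "ng")
  )

  ind_wide <- tidyr::pivot_wider(
    ind[, c("sample_id", "known_amount", "channel", "ct")],
    names_from = "channel", values_from = "ct")
  transform <- fit_ct_transform(ind_wide$SHORT_C, ind_wide$SHORT_T,
                                copies = ind_wide$known_amount,
                                r2_min = r2_min)

  # Quantification works on the raw replicate wells, not the Ct means:
  # each well's Ct is converted to an amount (undetermined = 0, i.e. no
  # detectable template) and replicate amounts are averaged on the linear
  # scale.  Near the detection limit this is unbiased, whereas averaging
  # Cts and discarding undetermined replicates overestimates low-copy
  # targets.  The collapsed plate is still used for replicate QC flags,
  # curve fitting and IPC.
  w0 <- plate$wells
  rep_amount <- function(s, chan, f) {
    ct <- w0$ct[w0$sample_id == s & w0$channel == chan]
    if (length(ct) == 0) return(0)
    mean(f(ct))
  }
  quant_roles <- c("GDNA", "BSDNA", "CONTROL_M", "CONTROL_U")
  samples <- unique(w$sample_id[w$role %in% quant_roles])
  quantities <- dplyr::bind_rows(lapply(samples, function(s) {
    role <- w$role[w$sample_id == s][1]
    tibble::tibble(
      sample_id = s, role = role,
      q_short_c = rep_amount(s, "SHORT_C",
                             function(ct) quantify(ct, curves$SHORT_C)),
      q_short_t = rep_amount(s, "SHORT_T", function(ct)
        quantify_short_t(ct, transform, curves$SHORT_C)),
      q_long = rep_amount(s, "LONG_CFREE",
                          function(ct) quantify(ct, curves$LONG_CFREE)),
      ipc_ct = channel_ct(w, s, "IPC"),
      flag_discordant = any(w$flag_discordant[w$sample_id == s &
                                                w$channel != "IPC"]),
      flag_dropout = any(w$flag_dropout[w$sample_id == s &
                                          w$channel != "IPC"])
    )
  }))

  ipc_vec <- setNames(quantities$ipc_ct, quantities$sample_id)
  ipc <- ipc_qc(ipc_vec, threshold = ipc_threshold)

  res <- NULL
  if (nrow(sample_sheet) > 0) {
    missing_bs <- setdiff(sample_sheet$sample_id, quantities$sample_id)
    missing_g <- setdiff(sample_sheet$gdna_id, quantities$sample_id)
    if (length(missing_bs) || length(missing_g)) {
      stop("sample sheet refers to samples absent from the plate: ",
           paste(c(missing_bs, missing_g), collapse = ", "), call. = FALSE)
    }
    res <- dplyr::bind_rows(lapply(seq_len(nrow(sample_sheet)), function(i) {
      sh <- sample_sheet[i, ]
      bs <- quantities[quantities$sample_id == sh$sample_id, ]
      g <- quantities[quantities$sample_id == sh$gdna_id, ]
      tibble::tibble(
        sample_id = sh$sample_id,
        gdna_id = sh$gdna_id,
        kit = if ("kit" %in% names(sh)) sh$kit else NA_character_,
        conversion_efficiency = conversion_efficiency(bs$q_short_c,
                                                      bs$q_short_t),
        degradation_level = degradation_level(bs$q_short_c, bs$q_short_t,
                                              bs$q_long, g$q_short_c,
                                              g$q_long),
        recovery = recovery(bs$q_short_c, bs$q_short_t, g$q_short_c,
                            elution_volume = sh$elution_volume),
        qubit_recovery = if ("qubit_recovery" %in% names(sh))
          sh$qubit_recovery else NA_real_,
        ipc_inhibited = ipc$inhibited[match(sh$sample_id, ipc$sample_id)] |
          ipc$inhibited[match(sh$gdna_id, ipc$sample_id)],
        flag_discordant = bs$flag_discordant | g$flag_discordant,
        flag_dropout = bs$flag_dropout | g$flag_dropout,
        flag_no_long = bs$q_long == 0,
        flag_unreliable_transform = !transform$reliable
      )
    }))
  }

  structure(list(curves = curves, transform = transform,
                 quantities = quantities, results = res, ipc = ipc,
                 reliable = transform$reliable,
                 metadata = plate$metadata),
            class = "bisque_run")
}

#' @export
print.bisque_run <- function(x, ...) {
  cat("<bisque_run>\n")
  print(x$curves$SHORT_C)
  print(x$curves$LONG_CFREE)
  print(x$transform)
  if (!is.null(x$results)) {
    cat(sprintf("  %d converted sample(s) evaluated\n", nrow(x$results)))
  }
  invisible(x)
}

#' Write per-sample results and fits of an evaluated run
#'
#' Writes `<prefix>_results.tsv` (per converted sample: metrics + QC flags),
#' `<prefix>_quantities.tsv` (per-sample channel amounts), `<prefix>_fits.json`
#' (curves and transform) and, when kit labels are present,
#' `<prefix>_kits.tsv` (per-kit summary).
#'
#' @param run A `bisque_run` from [evaluate_run()].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_run <- function(run, prefix) {
  stopifnot(inherits(run, "bisque_run"))
  files <- character(0)
  f <- paste0(prefix, "_quantities.tsv")
  readr::write_tsv(run$quantities, f)
  files <- c(files, f)
  f <- paste0(prefix, "_fits.json")
  write_fits_json(run$curves, run$transform, f)
  files <- c(files, f)
  if (!is.null(run$results)) {
    f <- paste0(prefix, "_results.tsv")
    readr::write_tsv(run$results, f)
    files <- c(files, f)
    if (!all(is.na(run$results$kit))) {
      f <- paste0(prefix, "_kits.tsv")
      readr::write_tsv(summarize_kits(run$results), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
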