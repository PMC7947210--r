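# Molecule-level simulator of conversion + multiplex qPCR ---------------

#' Simulation configuration
#'
#' Parameters of the generative model of a bisulfite-conversion experiment
#' read out by multiplex qPCR.  The defaults emulate the nominal study
#' design: 20 samples converted from 50 ng of gDNA (measured at 5 ng per
#' 1 ul reaction), a five-point genomic standard dilution series of 10, 2,
#' 0.4, 0.08 and 0.016 ng/ul, four C/T indicator dilutions of 1e6..1e3
#' copies/ul with a 50/50 C/T degenerate site, duplicate wells, 40 cycles,
#' and an IPC in every well.
#'
#' The conversion chemistry is modelled per molecule: a genome copy of a
#' locus survives fragmentation iff no break falls inside the amplicon span
#' (independent per-nucleotide breakage, survival `(1-b)^(L-1)`), survives
#' purification with probability `retention_prob`, contributes only one
#' amplifiable strand (factor 1/2), and is converted at the probe's
#' discrimination site with probability `true_conversion_prob`.  Template
#' copies are Poisson-sampled into each 1 ul reaction aliquot, so
#' low-input stochastic effects are representable.  Channel Cts are
#' generated from per-channel copy-scale curves plus Gaussian noise; zero
#' copies, or a Ct beyond `max_cycles`, yields an undetermined well.
#'
#' @param seed Integer seed; a fixed seed makes [simulate_run()] output
#'   bit-identical.
#' @param n_samples Number of gDNA/BS-DNA sample pairs.
#' @param gdna_input_ng gDNA mass put into the conversion reaction (ng).
#' @param gdna_well_ng gDNA mass per 1 ul qPCR reaction (ng; the sample
#'   diluted to `gdna_well_ng` ng/ul).
#' @param locus_copies_per_ng Amplifiable copies of each multicopy target
#'   locus per ng of gDNA.
#' @param copy_cv Lognormal coefficient of variation of per-individual locus
#'   copy number (shared by both loci of a sample, which is exactly what the
#'   gDNA pairing normalises away).
#' @param true_conversion_prob Per-molecule probability that the
#'   discrimination-site C is converted.
#' @param breakage_prob_per_nt Per-nucleotide breakage probability during
#'   conversion.
#' @param retention_prob Per-molecule survival through purification.
#' @param elution_volume Elution volume of converted samples (ul).
#' @param short_len,long_len Amplicon lengths (nt; defaults 104 and 238).
#' @param curve_params Per-channel true Ct-generating curves on the
#'   log10(copies) scale: named list with `slope` and `intercept` for
#'   `SHORT_C`, `SHORT_T`, `LONG_CFREE`.  The short-T channel deliberately
#'   differs from short-C so the C-T transforming equation is non-trivial.
#' @param ct_noise_sd Gaussian Ct noise (cycles).
#' @param indicator_c_fraction Fraction of indicator molecules carrying C at
#'   the degenerate Y site (0.5 = the synthesis assumption).
#' @param indicator_copies Indicator dilution series (copies/ul).
#' @param standard_ng Genomic standard dilution series (ng/ul).
#' @param ipc_ct Expected IPC Ct (500 copies/reaction).
#' @param n_replicates Wells per sample and channel.
#' @param max_cycles Protocol length; Cts beyond it are undetermined.
#' @param kit_label Kit name written into the sample sheet.
#' @param poisson_sampling If `TRUE` (default), template copies are
#'   Poisson-sampled into each reaction aliquot and the conversion split is
#'   binomial; if `FALSE` the expectations are used directly, giving the
#'   exact noiseless limit (useful with `ct_noise_sd = 0` to check that the
#'   pipeline reproduces [expected_metrics()] to float precision).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 20L,
                              gdna_input_ng = 50,
                              gdna_well_ng = 5,
                              locus_copies_per_ng = 3300,
                              copy_cv = 0.15,
                              true_conversion_prob = 0.995,
                              breakage_prob_per_nt = 0.00302,
                              retention_prob = 0.45,
                              elution_volume = 10,
                              short_len = 104L,
                              long_len = 238L,
                              curve_params = list(
                                SHORT_C = list(slope = -3.3219, intercept = 36.3),
                                SHORT_T = list(slope = -3.45, intercept = 37.2),
                                LONG_CFREE = list(slope = -3.3219, intercept = 37.6)),
                              ct_noise_sd = 0.15,
                              indicator_c_fraction = 0.5,
                              indicator_copies = c(1e6, 1e5, 1e4, 1e3),
                              standard_ng = c(10, 2, 0.4, 0.08, 0.016),
                              ipc_ct = 27,
                              n_replicates = 2L,
                              max_cycles = 40,
                              kit_label = "SIM",
                              poisson_sampling = TRUE) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              gdna_input_ng = gdna_input_ng, gdna_well_ng = gdna_well_ng,
              locus_copies_per_ng = locus_copies_per_ng, copy_cv = copy_cv,
              true_conversion_prob = true_conversion_prob,
              breakage_prob_per_nt = breakage_prob_per_nt,
              retention_prob = retention_prob,
              elution_volume = elution_volume,
              short_len = as.integer(short_len), long_len = as.integer(long_len),
              curve_params = curve_params, ct_noise_sd = ct_noise_sd,
              indicator_c_fraction = indicator_c_fraction,
              indicator_copies = indicator_copies, standard_ng = standard_ng,
              ipc_ct = ipc_ct, n_replicates = as.integer(n_replicates),
              max_cycles = max_cycles, kit_label = kit_label,
              poisson_sampling = isTRUE(poisson_sampling))
  probs <- c(true_conversion_prob = cfg$true_conversion_prob,
             breakage_prob_per_nt = cfg$breakage_prob_per_nt,
             retention_prob = cfg$retention_prob,
             indicator_c_fraction = cfg$indicator_c_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (cfg$short_len <= 0 || cfg$long_len <= 0) {
    stop("amplicon lengths must be positive", call. = FALSE)
  }
  if (cfg$ct_noise_sd < 0 || cfg$elution_volume <= 0 || cfg$n_samples < 0) {
    stop("invalid simulation config", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# survival of an L-nt amplicon under independent per-nt breakage
survival_prob <- function(breakage, len) (1 - breakage)^(len - 1)

draw_count <- function(lambda, cfg) {
  if (cfg$poisson_sampling) rpois(length(lambda), lambda) else lambda
}

draw_split <- function(n, p, cfg) {
  if (cfg$poisson_sampling) rbinom(1, n, p) else n * p
}

ct_from_copies <- function(copies, channel, cfg, noise = TRUE) {
  p <- cfg$curve_params[[channel]]
  ct <- p$slope * log10(pmax(copies, 1)) + p$intercept
  if (noise && cfg$ct_noise_sd > 0) {
    ct <- ct + rnorm(length(ct), 0, cfg$ct_noise_sd)
  }
  ct[copies == 0 | ct > cfg$max_cycles] <- NA_real_
  ct[!is.na(ct) & ct <= 0] <- 0.01
  ct
}

#' Closed-form expected metrics for a simulation configuration
#'
#' The ground-truth values the estimation pipeline should recover from a
#' simulated run:
#' \itemize{
#'   \item conversion efficiency `= 100 * true_conversion_prob`;
#'   \item degradation level `= (1-b)^(short_len - long_len)` (the ratio of
#'     the two amplicons' fragmentation survival);
#'   \item recovery `= 100 * retention_prob * (1-b)^(short_len-1) *
#'     gdna_input_ng / (10 * gdna_well_ng)` — the elution-volume correction
#'     cancels the per-ul dilution by construction, and with the default
#'     50 ng input at 5 ng/ul the trailing factor is 1.
#' }
#'
#' @param config A [simulation_config()].
#' @return One-row tibble: `conversion_efficiency`, `degradation_level`,
#'   `recovery`.
#' @export
expected_metrics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$breakage_prob_per_nt
  tibble::tibble(
    conversion_efficiency = 100 * config$true_conversion_prob,
    degradation_level = (1 - b)^(config$short_len - config$long_len),
    recovery = 100 * config$retention_prob *
      survival_prob(b, config$short_len) *
      config$gdna_input_ng / (10 * config$gdna_well_ng)
  )
}

sim_wells <- function(sample_id, role, copies_by_channel, known_amount,
                      replicate, cfg, well_id) {
  chans <- c("SHORT_C", "SHORT_T", "LONG_CFREE", "IPC")
  ct <- vapply(chans, function(ch) {
    if (ch == "IPC") {
      cfg$ipc_ct + if (cfg$ct_noise_sd > 0) rnorm(1, 0, cfg$ct_noise_sd) else 0
    } else {
      cp <- copies_by_channel[[ch]]
      if (is.null(cp)) NA_real_ else ct_from_copies(cp, ch, cfg)
    }
  }, numeric(1))
  tibble::tibble(
    well_id = well_id, sample_id = sample_id, role = role, channel = chans,
    ct = unname(ct), known_amount = known_amount, replicate = replicate
  )
}

#' Simulate a complete plate run with known ground truth
#'
#' Generates a full multiplex qPCR plate — genomic standard dilution series,
#' C/T indicator dilutions, an NTC, and `n_samples` paired gDNA / converted
#' sample well groups in `n_replicates` replicates — from the molecule-level
#' model described in [simulation_config()], together with the per-sample
#' ground truth and the sample sheet that [evaluate_run()] consumes.
#'
#' @param config A [simulation_config()].
#' @return List of class `bisque_sim`: `plate` (a [bisque_plate()]),
#'   `sample_sheet`, `truth` (per-sample tibble of true conversion
#'   efficiency, degradation level and recovery), `config`.
#' @export
simulate_run <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    wells <- list()
    wid <- 0L
    next_id <- function() {
      wid <<- wid + 1L
      sprintf("W%03d", wid)
    }

    for (r in seq_len(cfg$n_replicates)) {
      for (ng in cfg$standard_ng) {
        cp <- draw_count(rep(ng * cfg$locus_copies_per_ng, 2), cfg)
        wells[[length(wells) + 1]] <- sim_wells(
          sprintf("STD_%g", ng), "STANDARD",
          list(SHORT_C = cp[1], SHORT_T = 0, LONG_CFREE = cp[2]),
          ng, r, cfg, next_id())
      }
      for (cpul in cfg$indicator_copies) {
        n_c <- draw_count(cpul * cfg$indicator_c_fraction, cfg)
        n_t <- draw_count(cpul * (1 - cfg$indicator_c_fraction), cfg)
        wells[[length(wells) + 1]] <- sim_wells(
          sprintf("IND_%g", cpul), "CT_INDICATOR",
          list(SHORT_C = n_c, SHORT_T = n_t, LONG_CFREE = 0),
          cpul, r, cfg, next_id())
      }
      wells[[length(wells) + 1]] <- sim_wells(
        "NTC", "NTC", list(SHORT_C = 0, SHORT_T = 0, LONG_CFREE = 0),
        NA_real_, r, cfg, next_id())
    }

    surv_s <- survival_prob(cfg$breakage_prob_per_nt, cfg$short_len)
    surv_l <- survival_prob(cfg$breakage_prob_per_nt, cfg$long_len)

    truth <- vector("list", cfg$n_samples)
    sheet <- vector("list", cfg$n_samples)
    for (i in seq_len(cfg$n_samples)) {
      g_id <- sprintf("G%02d", i)
      bs_id <- sprintf("BS%02d", i)
      # per-individual locus copy-number scatter, shared by both loci
      k <- if (cfg$copy_cv > 0) {
        sdlog <- sqrt(log(1 + cfg$copy_cv^2))
        rlnorm(1, -sdlog^2 / 2, sdlog)
      } else 1
      cpn <- cfg$locus_copies_per_ng * k

      g_lambda <- cfg$gdna_well_ng * cpn
      # converted sample: input copies -> fragmentation -> purification ->
      # single amplifiable strand -> per-ul aliquot of the eluate
      n0 <- cfg$gdna_input_ng * cpn
      lam_short <- n0 * surv_s * cfg$retention_prob * 0.5 / cfg$elution_volume
      lam_long <- n0 * surv_l * cfg$retention_prob * 0.5 / cfg$elution_volume

      for (r in seq_len(cfg$n_replicates)) {
        g_cp <- draw_count(rep(g_lambda, 2), cfg)
        wells[[length(wells) + 1]] <- sim_wells(
          g_id, "GDNA",
          list(SHORT_C = g_cp[1], SHORT_T = 0, LONG_CFREE = g_cp[2]),
          NA_real_, r, cfg, next_id())

        n_short <- draw_count(lam_short, cfg)
        n_conv <- draw_split(n_short, cfg$true_conversion_prob, cfg)
        n_long <- draw_count(lam_long, cfg)
        wells[[length(wells) + 1]] <- sim_wells(
          bs_id, "BSDNA",
          list(SHORT_C = n_short - n_conv, SHORT_T = n_conv,
               LONG_CFREE = n_long),
          NA_real_, r, cfg, next_id())
      }

      truth[[i]] <- tibble::tibble(
        sample_id = bs_id, gdna_id = g_id,
        conversion_efficiency = 100 * cfg$true_conversion_prob,
        degradation_level = surv_s / surv_l,
        recovery = 100 * cfg$retention_prob * surv_s *
          cfg$gdna_input_ng / (10 * cfg$gdna_well_ng)
      )
      sheet[[i]] <- tibble::tibble(
        sample_id = bs_id, gdna_id = g_id, kit = cfg$kit_label,
        elution_volume = cfg$elution_volume
      )
    }

    plate <- bisque_plate(dplyr::bind_rows(wells),
                          max_cycles = cfg$max_cycles,
                          metadata = list(run_id = sprintf("sim-%d", cfg$seed),
                                          seed = cfg$seed))
    structure(list(plate = plate,
                   sample_sheet = dplyr::bind_rows(sheet),
                   truth = dplyr::bind_rows(truth),
                   config = cfg),
              class = "bisque_sim")
  })
}

#' @export
print.bisque_sim <- function(x, ...) {
  cat(sprintf("<bisque_sim> seed %d, %d sample pair(s), %d well records\n",
              x$config$seed, x$config$n_samples, nrow(x$plate$wells)))
  invisible(x)
}
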