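#' Published primer and probe set of the multiplex assay
#'
#' The three primer pairs and four TaqMan probes of the assay: a 104 bp
#' short amplicon in a *CCDC29* (*ANKRD20A20P*) intron carrying the C/T
#' discrimination site, a 238 bp long amplicon in *FLJ39739* with a
#' cytosine-free probe, and a 147 bp synthetic internal positive control
#' (IPC).  The two target assays use cytosine-free primers (forward primers
#' contain no C, reverse primers no G) so they amplify converted and
#' unconverted DNA identically; the IPC is a random synthetic sequence and is
#' exempt from that constraint.
#'
#' @return A tibble with one row per oligo: `target`, `gene`, `oligo`
#'   (`forward`, `reverse`, `probe_C`, `probe_T`, `probe`), `sequence`
#'   (lower case, 5'->3'), `dye` (probes only), `amplicon_bp`, `cfree`
#'   (whether the primer is subject to the cytosine-free design rule).
#' @export
#' @examples
#' a <- bisque_assays()
#' subset(a, oligo == "forward")
bisque_assays <- function() {
  tibble::tribble(
    ~target, ~gene,        ~oligo,    ~sequence,                                  ~dye,  ~amplicon_bp, ~cfree,
    "short", "CCDC29",     "forward", "gaaatggttaagagaaagggaaa",                  NA,    104L,         TRUE,
    "short", "CCDC29",     "reverse", "cccattacatttttcatcctca",                   NA,    104L,         TRUE,
    "short", "CCDC29",     "probe_C", "tgggtgaatacttagaatg",                      "FAM", 104L,         FALSE,
    "short", "CCDC29",     "probe_T", "tgggtgaatatttagaatg",                     "VIC", 104L,         FALSE,
    "long",  "FLJ39739",   "forward", "gggaaaatgaggaagtgatga",                    NA,    238L,         TRUE,
    "long",  "FLJ39739",   "reverse", "acacaaaaaacccttcaaaaaa",                   NA,    238L,         TRUE,
    "long",  "FLJ39739",   "probe",   "aatgttgtatgttatttgtgg",                    "NED", 238L,         FALSE,
    "ipc",   "synthetic",  "forward", "aactgctagaaaaccgcgtc",                     NA,    147L,         FALSE,
    "ipc",   "synthetic",  "reverse", "gaggcaggctcttgctatgt",                     NA,    147L,         FALSE,
    "ipc",   "synthetic",  "probe",   "tccaggcagtgcgtctgctgt",                    "CY5", 147L,         FALSE
  )
}
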