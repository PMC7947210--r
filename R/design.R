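# In-silico bisulfite conversion and Cfree assay design -----------------

check_dna <- function(seq) {
  s <- toupper(seq)
  if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", s)) {
    stop("sequence contains non-DNA characters (allowed: A, C, G, T, N)",
         call. = FALSE)
  }
  s
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' Applies the sequence consequence of bisulfite treatment: every cytosine
#' deaminates to uracil (read as T after PCR) unless protected.  Under
#' `"unmethylated"` every C converts; under `"cpg_methylated"` a C is
#' preserved only when the next base on the same strand is G (fully
#' methylated CpGs, the usual design assumption); `"none"` returns the input
#' unchanged.  The bottom strand is converted on the reverse complement and
#' reported in that strand's 5'->3' orientation.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param methylation `"unmethylated"`, `"cpg_methylated"` or `"none"`.
#' @param strand `"top"` or `"bottom"`.
#' @return The converted sequence (uppercase).
#' @export
#' @examples
#' bisulfite_convert("ACAT")                         # "ATAT"
#' bisulfite_convert("ACGT", "cpg_methylated")       # "ACGT"
bisulfite_convert <- function(seq,
                              methylation = c("unmethylated",
                                              "cpg_methylated", "none"),
                              strand = c("top", "bottom")) {
  methylation <- match.arg(methylation)
  strand <- match.arg(strand)
  s <- check_dna(seq)
  if (strand == "bottom") s <- revcomp(s)
  if (methylation == "none") return(s)
  chars <- strsplit(s, "")[[1]]
  is_c <- chars == "C"
  if (methylation == "cpg_methylated") {
    next_g <- c(chars[-1] == "G", FALSE)
    is_c <- is_c & !next_g
  }
  chars[is_c] <- "T"
  paste(chars, collapse = "")
}

#' Nearest-integer melting temperature estimate for short oligos
#'
#' Wallace rule `2(A+T) + 4(G+C)` for oligos up to 14 nt, otherwise the
#' basic `64.9 + 41 * (GC - 16.4/L)` formula.  Used only to rank candidate
#' windows; assay oligos are expected to be refined manually.
#'
#' @param seq DNA string.
#' @return Tm estimate in degrees C.
#' @export
primer_tm <- function(seq) {
  s <- check_dna(seq)
  chars <- strsplit(s, "")[[1]]
  n_gc <- sum(chars %in% c("G", "C"))
  n_at <- sum(chars %in% c("A", "T"))
  if (nchar(s) <= 14) 2 * n_at + 4 * n_gc
  else 64.9 + 41 * (n_gc - 16.4) / nchar(s)
}

window_starts <- function(seq_len, w) {
  if (w > seq_len) integer(0) else 0:(seq_len - w)
}

#' Scan for cytosine-free primer candidates
#'
#' Exhaustively enumerates every window of the allowed lengths whose
#' top-strand footprint contains no cytosine: any C in the footprint would
#' read as T after bisulfite conversion and break exact annealing.  A
#' qualifying forward primer (the footprint itself) therefore contains no
#' C, and a qualifying reverse primer (the footprint's reverse complement)
#' contains no G.  Such primers anneal identically to converted and
#' unconverted templates, which is what allows a single assay to quantify
#' both.
#'
#' @param seq Top-strand template (typically already in-silico converted or
#'   the untreated reference, depending on the design stage).
#' @param length_range Two-element integer vector, min and max window length
#'   (nt).
#' @param orientation `"forward"` or `"reverse"`.
#' @return Tibble of candidates: `start`, `end` (0-based half-open on the
#'   top strand), `length`, `orientation`, `sequence` (primer 5'->3'),
#'   `gc_fraction` (G+C of the primer), `tm` estimate.  May be empty.
#' @export
scan_cfree_primers <- function(seq, length_range = c(18, 25),
                               orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  s <- check_dna(seq)
  n <- nchar(s)
  rows <- list()
  for (w in length_range[1]:length_range[2]) {
    for (st in window_starts(n, w)) {
      win <- substr(s, st + 1, st + w)
      if (grepl("N", win, fixed = TRUE)) next
      # both orientations need a C-free top-strand footprint: any C there
      # would read T after conversion and break annealing.  The forward
      # primer is then itself C-free; the reverse primer (the footprint's
      # reverse complement) is G-free.
      if (grepl("C", win, fixed = TRUE)) next
      primer <- if (orientation == "forward") win else revcomp(win)
      rows[[length(rows) + 1]] <- tibble::tibble(
        start = st, end = st + w, length = w,
        orientation = orientation, sequence = primer,
        gc_fraction = (nchar(gsub("[^GC]", "", primer))) / w,
        tm = primer_tm(primer)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), orientation = character(0),
                          sequence = character(0), gc_fraction = numeric(0),
                          tm = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Scan for single-site C/T discrimination probe candidates
#'
#' Enumerates windows on the top strand containing exactly one cytosine,
#' with that cytosine in non-CpG context (not followed by G), and no other
#' C.  Each such window supports a TaqMan probe pair differing at only that
#' base: the C version detects unconverted template, the T version detects
#' converted template.
#'
#' @param seq Top-strand template.
#' @param length_range Min and max window length (nt).
#' @return Tibble: `start`, `end` (0-based half-open), `length`,
#'   `variant_position` (0-based offset of the discriminating C within the
#'   window), `seq_c` (probe matching unconverted template), `seq_t`
#'   (converted), `tm_c`.
#' @export
scan_discrimination_probes <- function(seq, length_range = c(15, 25)) {
  s <- check_dna(seq)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  rows <- list()
  for (w in length_range[1]:length_range[2]) {
    for (st in window_starts(n, w)) {
      win_chars <- chars[(st + 1):(st + w)]
      if (any(win_chars == "N")) next
      c_pos <- which(win_chars == "C")
      if (length(c_pos) != 1) next
      abs_pos <- st + c_pos          # 1-based position of the C in seq
      if (abs_pos < n && chars[abs_pos + 1] == "G") next  # CpG context
      seq_c <- paste(win_chars, collapse = "")
      win_chars[c_pos] <- "T"
      rows[[length(rows) + 1]] <- tibble::tibble(
        start = st, end = st + w, length = w,
        variant_position = c_pos - 1L,
        seq_c = seq_c,
        seq_t = paste(win_chars, collapse = ""),
        tm_c = primer_tm(seq_c)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), variant_position = integer(0),
                          seq_c = character(0), seq_t = character(0),
                          tm_c = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' In-silico PCR: locate exact primer annealing sites and extract amplicons
#'
#' Finds every exact match of the forward primer on the top strand and of
#' the reverse complement of the reverse primer downstream of it, and
#' returns each product spanning the forward primer's 5' end through the
#' reverse primer's 5' end inclusive (so the product contains both primer
#' footprints, matching how amplicon sizes are reported).  Multiple products
#' are expected for multicopy targets.  Annealing is exact-match only.
#'
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param template Top-strand template.
#' @param max_product Longest product to report (bp), guards against
#'   pairing distant sites.
#' @return Tibble: `start`, `end` (0-based half-open on the template),
#'   `length`, `sequence`.  Empty when there is no product.
#' @export
#' @examples
#' tpl <- paste0("GAAATT", "AAAAAAAAAA", "CCCGGG")
#' in_silico_pcr("GAAATT", "CCCGGG", tpl)  # 22 bp product
in_silico_pcr <- function(forward, reverse, template, max_product = 5000) {
  f <- check_dna(forward)
  r <- check_dna(reverse)
  tpl <- check_dna(template)
  r_site <- revcomp(r)
  f_hits <- gregexpr(f, tpl, fixed = TRUE)[[1]]
  r_hits <- gregexpr(r_site, tpl, fixed = TRUE)[[1]]
  if (f_hits[1] == -1 || r_hits[1] == -1) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), sequence = character(0)))
  }
  rows <- list()
  for (fs in as.integer(f_hits)) {
    for (rs in as.integer(r_hits)) {
      start0 <- fs - 1L                       # 0-based forward 5' end
      end0 <- rs - 1L + nchar(r_site)          # 0-based half-open past reverse 5' end
      len <- end0 - start0
      if (len < nchar(f) + nchar(r) || len > max_product) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        start = start0, end = end0, length = len,
        sequence = substr(tpl, start0 + 1, end0)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), sequence = character(0)))
  }
  dplyr::bind_rows(rows)
}

#' Expand IUPAC degenerate bases to all concrete sequences
#'
#' Cartesian expansion of every degeneracy code (e.g. the `Y` at a C/T
#' indicator's discrimination site expands to the C and T variants).
#'
#' @param seq Sequence over the IUPAC alphabet.
#' @param max_expansion Error if the expansion would exceed this many
#'   sequences.
#' @return Character vector of concrete A/C/G/T sequences.
#' @export
#' @examples
#' expand_degenerate("AYT")  # "ACT" "ATT"
expand_degenerate <- function(seq, max_expansion = 1024) {
  s <- toupper(seq)
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(s, "")[[1]]
  bad <- !chars %in% names(map)
  if (any(bad)) {
    stop("non-IUPAC character(s): ", paste(unique(chars[bad]), collapse = ", "),
         call. = FALSE)
  }
  opts <- strsplit(unname(map[chars]), "")
  total <- prod(lengths(opts))
  if (total > max_expansion) {
    stop("degenerate expansion of ", total, " sequences exceeds cap of ",
         max_expansion, call. = FALSE)
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  sort(unname(do.call(paste0, grid)))
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA: ", path, call. = FALSE)
  setNames(toupper(as.character(x)), names(x))
}
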