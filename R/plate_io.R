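# Plate data model ------------------------------------------------------

#' Column-mapping schema for qPCR plate exports
#'
#' Instrument exports differ in header naming; a schema maps the columns of a
#' delimited export onto the fields of the plate data model instead of
#' hard-coding one vendor's layout.  The default mirrors a generic
#' "Well / Sample Name / Task / Target Name / CT / Quantity" export.
#'
#' @param well,sample,role,channel,ct,amount,replicate Header names in the
#'   file for each field.  `amount` is the known input amount of standard or
#'   indicator wells (ng or copies/ul); `replicate` may be `NULL`, in which
#'   case replicate indices are assigned in file order within each
#'   (sample, channel) group.
#' @return A named list of class `plate_schema`.
#' @export
plate_schema <- function(well = "Well", sample = "Sample Name", role = "Task",
                         channel = "Target Name", ct = "CT",
                         amount = "Quantity", replicate = NULL) {
  structure(list(well = well, sample = sample, role = role, channel = channel,
                 ct = ct, amount = amount, replicate = replicate),
            class = "plate_schema")
}

new_plate <- function(wells, max_cycles = 40, metadata = list()) {
  structure(list(wells = wells, max_cycles = max_cycles, metadata = metadata),
            class = "bisque_plate")
}

#' Construct a plate from a wells table
#'
#' Low-level constructor used by the reader, the simulator and tests.  The
#' wells table must have columns `well_id`, `sample_id`, `role`, `channel`,
#' `ct` (numeric; `NA` means no amplification, i.e. "Undetermined"),
#' `known_amount` and `replicate`.
#'
#' @param wells A data frame of well records.
#' @param max_cycles Cycling protocol length; numeric Ct must lie in
#'   (0, `max_cycles`].
#' @param metadata Free-form run metadata list (e.g. `run_id`,
#'   `elution_volume` per sample).
#' @return A `bisque_plate` object.
#' @export
bisque_plate <- function(wells, max_cycles = 40, metadata = list()) {
  wells <- tibble::as_tibble(wells)
  needed <- c("well_id", "sample_id", "role", "channel", "ct",
              "known_amount", "replicate")
  if (!"known_amount" %in% names(wells)) wells$known_amount <- NA_real_
  if (!"replicate" %in% names(wells)) wells$replicate <- 1L
  missing <- setdiff(needed, names(wells))
  if (length(missing) > 0) {
    stop("wells table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wells$ct <- as.numeric(wells$ct)
  wells$known_amount <- as.numeric(wells$known_amount)
  wells$replicate <- as.integer(wells$replicate)
  plate <- new_plate(wells[needed], max_cycles = max_cycles,
                     metadata = metadata)
  validate_plate(plate)
}

validate_plate <- function(plate) {
  w <- plate$wells
  bad_role <- setdiff(unique(w$role), ROLES)
  if (length(bad_role) > 0) {
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  bad_chan <- setdiff(unique(w$channel), names(CHANNELS))
  if (length(bad_chan) > 0) {
    stop("unknown channel(s): ", paste(bad_chan, collapse = ", "),
         call. = FALSE)
  }
  out <- !is.na(w$ct) & (w$ct <= 0 | w$ct > plate$max_cycles)
  if (any(out)) {
    stop("Ct outside (0, ", plate$max_cycles, "] in well(s): ",
         paste(unique(w$well_id[out]), collapse = ", "), call. = FALSE)
  }
  key <- paste(w$well_id, w$channel, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(w$well_id[duplicated(key)])
    stop("duplicate well_id + channel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  plate
}

#' @export
print.bisque_plate <- function(x, ...) {
  w <- x$wells
  cat("<bisque_plate> ", nrow(w), " well records, ",
      length(unique(w$sample_id)), " samples, max_cycles = ",
      x$max_cycles, "\n", sep = "")
  tab <- table(w$role[!duplicated(paste(w$sample_id, w$role))])
  cat("  samples by role:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Reading and writing ----------------------------------------------------

parse_ct <- function(x) {
  x <- trimws(as.character(x))
  und <- is.na(x) | x == "" | tolower(x) == "undetermined" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !und & is.na(out)
  if (any(bad)) {
    stop("unparseable Ct value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out[und] <- NA_real_
  out
}

#' Read a qPCR plate export
#'
#' Reads a delimited (CSV or TSV, sniffed from the extension unless `delim`
#' is given) plate export with a header row into the plate data model.
#' "Undetermined" (case-insensitive) or empty Ct cells are parsed as no
#' amplification (`NA`); numeric Ct values are validated against
#' `(0, max_cycles]`.
#'
#' @param path Path to the delimited file.
#' @param schema A [plate_schema()] mapping file headers to fields.
#' @param max_cycles Upper bound for valid Ct values (protocol cycles).
#' @param delim Field delimiter; default: `"\t"` for `.tsv`/`.txt`, `","`
#'   otherwise.
#' @param metadata Optional run metadata list stored on the plate.
#' @return A [bisque_plate()] object.
#' @export
read_plate <- function(path, schema = plate_schema(), max_cycles = 40,
                       delim = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  req <- unlist(schema[!vapply(schema, is.null, logical(1))])
  missing <- setdiff(unname(req), names(raw))
  if (length(missing) > 0) {
    stop("plate file is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wells <- tibble::tibble(
    well_id = as.character(raw[[schema$well]]),
    sample_id = as.character(raw[[schema$sample]]),
    role = toupper(as.character(raw[[schema$role]])),
    channel = toupper(as.character(raw[[schema$channel]])),
    ct = parse_ct(raw[[schema$ct]]),
    known_amount = suppressWarnings(as.numeric(raw[[schema$amount]]))
  )
  if (is.null(schema$replicate)) {
    wells <- dplyr::group_by(wells, .data$sample_id, .data$channel)
    wells <- dplyr::mutate(wells, replicate = dplyr::row_number())
    wells <- dplyr::ungroup(wells)
  } else {
    wells$replicate <- as.integer(raw[[schema$replicate]])
  }
  bisque_plate(wells, max_cycles = max_cycles, metadata = metadata)
}

#' Write a plate back to delimited text
#'
#' Inverse of [read_plate()]: writes the well records with the headers given
#' by `schema`, rendering `NA` Ct as `"Undetermined"`.  A written plate
#' re-read with the same schema round-trips record-for-record.
#'
#' @inheritParams read_plate
#' @param plate A `bisque_plate`.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path, schema = plate_schema(), delim = NULL) {
  if (is.null(delim)) {
    delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  }
  w <- plate$wells
  out <- tibble::tibble(
    a = w$well_id, b = w$sample_id, c = w$role, d = w$channel,
    e = ifelse(is.na(w$ct), "Undetermined", format(w$ct, trim = TRUE, digits = 10)),
    f = w$known_amount, g = w$replicate
  )
  names(out) <- c(schema$well, schema$sample, schema$role, schema$channel,
                  schema$ct, schema$amount,
                  if (is.null(schema$replicate)) "Replicate" else schema$replicate)
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# Replicate collapse -----------------------------------------------------

#' Collapse replicate wells to one record per sample and channel
#'
#' Reactions are typically run in duplicate.  This reduces the plate to one
#' record per (sample, channel): the Ct is the arithmetic mean of the numeric
#' replicate Cts; a group whose replicates are all undetermined stays
#' undetermined.  Two quality flags are attached per record:
#' `flag_dropout` when some but not all replicates were undetermined (the
#' numeric mean is kept rather than discarding a low-copy sample), and
#' `flag_discordant` when the numeric replicate spread exceeds
#' `discordance_cycles`.
#'
#' @param plate A `bisque_plate`.
#' @param discordance_cycles Maximum |delta Ct| between numeric replicates
#'   before the record is flagged discordant (default 0.5 cycles).
#' @return A `bisque_plate` with one record per (sample, channel) and the two
#'   logical flag columns; idempotent on already-collapsed plates.
#' @export
collapse_replicates <- function(plate, discordance_cycles = 0.5) {
  w <- plate$wells
  g <- dplyr::group_by(w, .data$sample_id, .data$role, .data$channel)
  s <- dplyr::summarise(
    g,
    well_id = .data$well_id[1],
    known_amount = .data$known_amount[1],
    n_rep = dplyr::n(),
    n_det = sum(!is.na(.data$ct)),
    spread = if (sum(!is.na(.data$ct)) >= 2) diff(range(.data$ct, na.rm = TRUE)) else 0,
    ct = if (all(is.na(.data$ct))) NA_real_ else mean(.data$ct, na.rm = TRUE),
    .groups = "drop"
  )
  wells <- tibble::tibble(
    well_id = s$well_id,
    sample_id = s$sample_id,
    role = s$role,
    channel = s$channel,
    ct = s$ct,
    known_amount = s$known_amount,
    replicate = 1L,
    flag_dropout = s$n_det > 0 & s$n_det < s$n_rep,
    flag_discordant = s$spread > discordance_cycles
  )
  # carry pre-existing flags through a second collapse (idempotence)
  if ("flag_dropout" %in% names(w)) {
    old <- w[!duplicated(paste(w$sample_id, w$channel)), ]
    key <- paste(wells$sample_id, wells$channel)
    okey <- paste(old$sample_id, old$channel)
    wells$flag_dropout <- wells$flag_dropout | old$flag_dropout[match(key, okey)]
    wells$flag_discordant <- wells$flag_discordant | old$flag_discordant[match(key, okey)]
  }
  new_plate(wells, max_cycles = plate$max_cycles, metadata = plate$metadata)
}
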