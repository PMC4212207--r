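# Sweep CSV format ("kvlipid-sweeps v1"): comment-prefixed header lines
# carrying the units declaration, the voltage protocol and scalar condition
# labels, followed by a CSV table with one time column and one current column
# per step voltage. Values are serialized at 17 significant digits so that a
# write/read cycle is bit-exact.
.SWEEP_FORMAT <- "kvlipid-sweeps v1"

#' Write a sweep family to CSV
#'
#' @param family A \code{\link{current_family}} with a protocol.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sweeps <- function(family, path) {
  stopifnot(inherits(family, "current_family"))
  if (is.null(family$protocol)) stop("cannot serialize a family without a protocol")
  p <- family$protocol
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    paste0("# ", .SWEEP_FORMAT),
    "# units: time=ms current=pA voltage=mV",
    paste0("# holding_voltage: ", num(p$holding_voltage)),
    paste0("# step_voltages: ", num(p$step_voltages)),
    paste0("# holding_duration: ", num(p$holding_duration)),
    paste0("# step_duration: ", num(p$step_duration)),
    paste0("# tail_voltage: ", num(p$tail_voltage)),
    paste0("# tail_duration: ", num(p$tail_duration)),
    paste0("# sample_interval: ", num(p$sample_interval)))
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1,
                    family$metadata)
  for (nm in names(scalars))
    lines <- c(lines, sprintf("# meta %s: %s", nm, as.character(scalars[[nm]])))
  header <- paste(c("time", sprintf("V_%g", p$step_voltages)), collapse = ",")
  rows <- vapply(seq_along(family$time), function(j) {
    paste(sprintf("%.17g", c(family$time[j], family$traces[, j])),
          collapse = ",")
  }, character(1))
  writeLines(c(lines, header, rows), path)
  invisible(path)
}

#' Read a sweep family from CSV
#'
#' @param path A file written by \code{\link{write_sweeps}}.
#' @return A \code{\link{current_family}}.
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop("sweep file not found: ", path)
  all_lines <- readLines(path)
  hdr <- all_lines[startsWith(all_lines, "#")]
  body <- all_lines[!startsWith(all_lines, "#")]
  if (!length(hdr) || !grepl("kvlipid-sweeps", hdr[1]))
    stop("unrecognized sweep file version in ", path)
  if (!any(grepl("^# units:", hdr)))
    stop("sweep file is missing the units declaration: ", path)
  units <- sub("^# units:\\s*", "", hdr[grepl("^# units:", hdr)][1])
  if (!grepl("time=ms", units) || !grepl("current=pA", units))
    stop("unsupported units in sweep file: ", units)

  field <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(ln)) stop("sweep header is missing field: ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, ":\\s*"), "", ln[1]),
                        "\\s+")[[1]])
  }
  protocol <- voltage_protocol(
    holding_voltage = field("holding_voltage"),
    step_voltages = field("step_voltages"),
    holding_duration = field("holding_duration"),
    step_duration = field("step_duration"),
    tail_voltage = field("tail_voltage"),
    tail_duration = field("tail_duration"),
    sample_interval = field("sample_interval"))

  meta_lines <- hdr[grepl("^# meta ", hdr)]
  metadata <- list()
  for (ln in meta_lines) {
    kv <- sub("^# meta ", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    num <- suppressWarnings(as.numeric(val))
    metadata[[key]] <- if (!is.na(num) && grepl("^[-0-9.eE+]+$", val)) num else val
  }

  body <- body[nzchar(body)]
  cols <- strsplit(body, ",", fixed = TRUE)
  ncol_expect <- length(protocol$step_voltages) + 1L
  if (any(lengths(cols) != ncol_expect))
    stop("ragged columns in sweep file: expected ", ncol_expect,
         " fields per row")
  dat <- matrix(as.numeric(unlist(cols[-1])), ncol = ncol_expect, byrow = TRUE)
  current_family(protocol, time = dat[, 1], traces = t(dat[, -1, drop = FALSE]),
                 metadata = metadata)
}

#' Import an Axon Text File (ATF) as a sweep family
#'
#' Thin shim for ATF, the text export of Axon acquisition software: the
#' two-line ATF preamble, optional quoted header records, a column-title line
#' and a tab/comma-separated data table (first column time, remaining columns
#' one trace per sweep). Time in seconds is converted to ms when the time
#' column title declares "(s)". ATF carries no protocol, so supply the
#' \code{protocol} used during acquisition to enable tail extraction.
#'
#' @param path ATF file.
#' @param protocol Optional \code{\link{voltage_protocol}}.
#' @return A \code{\link{current_family}}.
#' @export
read_atf <- function(path, protocol = NULL) {
  if (!file.exists(path)) stop("ATF file not found: ", path)
  lines <- readLines(path)
  if (!grepl("^ATF", lines[1])) stop("not an ATF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "[ \t]+")[[1]])
  n_header <- counts[1]
  titles_line <- lines[3 + n_header]
  sep <- if (grepl("\t", titles_line)) "\t" else ","
  titles <- gsub('"', "", strsplit(titles_line, sep)[[1]])
  data_lines <- lines[-(seq_len(3 + n_header))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  dat <- do.call(rbind, lapply(strsplit(data_lines, sep),
                               function(f) as.numeric(f)))
  time <- dat[, 1]
  if (grepl("\\(s\\)", titles[1], ignore.case = TRUE)) time <- time * 1000
  header_records <- gsub('"', "", lines[2 + seq_len(n_header)])
  fam <- current_family(protocol, time = time,
                        traces = t(dat[, -1, drop = FALSE]),
                        metadata = list(source = "ATF",
                                        atf_header = paste(header_records,
                                                           collapse = "; ")))
  fam
}

#' Write the generating truth of a simulated family to a JSON sidecar
#'
#' @param family A simulated \code{\link{current_family}} (with
#'   \code{metadata$truth}).
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(family, path) {
  stopifnot(inherits(family, "current_family"))
  if (is.null(family$metadata$truth))
    stop("family carries no generating truth (not simulated?)")
  jsonlite::write_json(family$metadata$truth, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# ---- scenario configuration -------------------------------------------------

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.config_bilayer <- function(cfg) {
  bilayer_spec(
    inner = leaflet_composition(unlist(cfg$inner), normalize = TRUE),
    outer = leaflet_composition(unlist(cfg$outer), normalize = TRUE),
    electrolyte_molar = cfg$electrolyte_molar %||% 0.15,
    temperature = cfg$temperature %||% 298)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation scenario configuration (YAML or JSON)
#'
#' A scenario bundles everything one simulated experiment needs: sections
#' \code{bilayer} (\code{inner}/\code{outer} mole fractions,
#' \code{electrolyte_molar}, \code{temperature}), \code{gating},
#' \code{population}, \code{effect} (optional), \code{protocol} and
#' \code{noise} (with the mandatory \code{seed}).
#'
#' @param path Config file.
#' @return A named list of constructed kvlipid objects.
#' @export
read_scenario <- function(path) {
  cfg <- .read_config(path)
  if (is.null(cfg$bilayer)) stop("scenario is missing a 'bilayer' section")
  if (is.null(cfg$protocol)) stop("scenario is missing a 'protocol' section")
  g <- cfg$gating %||% list()
  pop <- cfg$population %||% list()
  pr <- cfg$protocol
  nz <- cfg$noise %||% list()
  if (!is.null(nz$current_sd) && nz$current_sd > 0 && is.null(nz$seed))
    stop("a stochastic scenario must declare a seed")
  list(
    bilayer = .config_bilayer(cfg$bilayer),
    gating = do.call(gating_model, g),
    population = do.call(channel_population, pop),
    effect = if (!is.null(cfg$effect)) do.call(lipid_effect, cfg$effect),
    protocol = voltage_protocol(
      holding_voltage = pr$holding_voltage,
      step_voltages = unlist(pr$step_voltages),
      holding_duration = pr$holding_duration %||% 50,
      step_duration = pr$step_duration %||% 100,
      tail_voltage = pr$tail_voltage %||% pr$holding_voltage,
      tail_duration = pr$tail_duration %||% 50,
      sample_interval = pr$sample_interval %||% 0.5),
    noise = noise_spec(current_sd = nz$current_sd %||% 0,
                       seed = nz$seed %||% 1L),
    registry = if (!is.null(cfg$registry)) read_lipid_registry(cfg$registry)
               else default_lipid_registry())
}
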