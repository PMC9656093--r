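# Masslist and plate-file IO: multi-tab XLSX peak lists, 384-spot plate
# layouts, and automatic generation of per-spot analysis inputs.

PLATE_ROWS <- LETTERS[1:16]   # A..P
PLATE_COLS <- 24L

sanitize_tab_name <- function(x) gsub("[/\\\\[:space:]]+", "_", x)

#' Read an instrument masslist workbook
#'
#' A masslist is a multi-tab XLSX exported from the MALDI-TOF instrument:
#' one tab per plate spot ("experiment"), two columns per tab (peak m/z and
#' peak area). A leading header row of text is tolerated and skipped. Empty
#' tabs are kept (with a warning) as zero-peak experiments.
#'
#' @param path path to the XLSX masslist.
#' @return A named list of data.frames (one per tab, tab order preserved)
#'   with columns \code{mz} and \code{area}.
#' @export
read_masslist <- function(path) {
  if (!file.exists(path)) stop("masslist not found: ", path)
  tabs <- readxl::excel_sheets(path)
  out <- vector("list", length(tabs))
  names(out) <- tabs
  for (i in seq_along(tabs)) {
    df <- suppressMessages(as.data.frame(
      readxl::read_excel(path, sheet = i, col_names = FALSE,
                         col_types = "text")))
    if (nrow(df) == 0L || ncol(df) < 2L) {
      warning("masslist tab '", tabs[i], "' is empty")
      out[[i]] <- data.frame(mz = numeric(0), area = numeric(0))
      next
    }
    v1 <- suppressWarnings(as.numeric(df[[1L]]))
    v2 <- suppressWarnings(as.numeric(df[[2L]]))
    # skip leading header rows where both cells are non-numeric text
    start <- 1L
    while (start <= nrow(df) && is.na(v1[start]) && is.na(v2[start]))
      start <- start + 1L
    if (start > nrow(df)) {
      warning("masslist tab '", tabs[i], "' has no numeric peaks")
      out[[i]] <- data.frame(mz = numeric(0), area = numeric(0))
      next
    }
    idx <- start:nrow(df)
    bad <- idx[is.na(v1[idx]) | is.na(v2[idx])]
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cell in masslist tab '%s', row %d",
                   tabs[i], bad[1]))
    if (any(v1[idx] <= 0))
      stop(sprintf("non-positive m/z in masslist tab '%s'", tabs[i]))
    if (any(v2[idx] < 0))
      stop(sprintf("negative peak area in masslist tab '%s'", tabs[i]))
    out[[i]] <- data.frame(mz = v1[idx], area = v2[idx])
  }
  out
}

#' Convert a masslist workbook to per-tab CSV files
#'
#' Writes one CSV per tab, named after the (sanitized) tab name, into a
#' folder named after the masslist with its extension removed (or into
#' \code{out_dir} if given). Numeric fidelity is preserved at full precision.
#'
#' @param masslist_path path to the XLSX masslist.
#' @param out_dir output directory; defaults to
#'   \code{<dir of masslist>/<basename without extension>}.
#' @return Invisibly, the written file paths.
#' @export
convert_to_multicsv <- function(masslist_path, out_dir = NULL) {
  tabs <- read_masslist(masslist_path)
  if (is.null(out_dir))
    out_dir <- file.path(dirname(masslist_path),
                         tools::file_path_sans_ext(basename(masslist_path)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fn <- paste0(sanitize_tab_name(names(tabs)), ".csv")
  if (anyDuplicated(fn))
    stop("tab name collision after sanitization: ", fn[duplicated(fn)][1])
  paths <- file.path(out_dir, fn)
  for (i in seq_along(tabs)) {
    df <- tabs[[i]]
    lines <- c("mz,area",
               if (nrow(df) > 0L)
                 sprintf("%s,%s", format(df$mz, digits = 15, trim = TRUE),
                         format(df$area, digits = 15, trim = TRUE)))
    writeLines(lines, paths[i])
  }
  invisible(paths)
}

parse_spot_code <- function(code, address) {
  code <- trimws(code)
  if (grepl("^[0-9]*\\.?[0-9]+_[0-9]*$", code)) {
    parts <- strsplit(code, "_", fixed = TRUE)[[1L]]
    vol <- as.numeric(parts[1L])
    if (vol <= 0) stop("non-positive calibration volume at ", address)
    rep <- if (length(parts) >= 2L && nzchar(parts[2L]))
      as.integer(parts[2L]) else NA_integer_
    list(type = "calibration", volume = vol, replicate = rep,
         series = NA_integer_, label = NA_character_)
  } else if (grepl("^[0-9]+#", code)) {
    series <- as.integer(sub("#.*$", "", code))
    if (series < 1L) stop("series id must be >= 1 at ", address)
    list(type = "category", volume = NA_real_, replicate = NA_integer_,
         series = series, label = sub("^[0-9]+#", "", code))
  } else if (grepl("^[0-9]+$", code)) {
    series <- as.integer(code)
    if (series < 1L) stop("series id must be >= 1 at ", address)
    list(type = "category", volume = NA_real_, replicate = NA_integer_,
         series = series, label = paste0("series", code))
  } else {
    stop(sprintf("unrecognized spot code '%s' at %s", code, address))
  }
}

#' Parse a MALDI plate layout file
#'
#' The plate file is a single-sheet XLSX imitating a 384-spot MALDI plate.
#' Row 1 carries common run parameters as alternating key/value cells
#' (recognized keys: \code{is_pmol}, the spiked internal-standard amount;
#' \code{tolerance_da}, the matching tolerance; \code{protein_level};
#' unknown keys are carried through). Rows 2-17 map to plate rows A-P and
#' columns 1-24 to plate columns. Non-empty cells hold spot codes:
#' \code{"<volume>_<replicate>"} (underscore convention, replicate optional)
#' for calibration-curve spots, \code{"<series>#<label>"} or a bare series
#' integer for category-comparison spots.
#'
#' @param path path to the plate XLSX.
#' @return A \code{plate_file} object: list with \code{common} (named list)
#'   and \code{spots} (data.frame in row-major A1..P24 order with columns
#'   \code{address,type,volume,replicate,series,label}).
#' @export
parse_plate <- function(path) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  df <- suppressMessages(as.data.frame(
    readxl::read_excel(path, sheet = 1L, col_names = FALSE,
                       col_types = "text")))
  if (nrow(df) < 1L) stop("plate file is empty")
  # row 1: alternating key, value
  row1 <- as.character(unlist(df[1L, ]))
  row1 <- row1[!is.na(row1) & nzchar(trimws(row1))]
  common <- list()
  if (length(row1) >= 2L)
    for (k in seq(1L, length(row1) - 1L, by = 2L)) {
      key <- trimws(row1[k])
      val <- trimws(row1[k + 1L])
      num <- suppressWarnings(as.numeric(val))
      common[[key]] <- if (is.na(num)) val else num
    }
  spots <- list()
  n_occ <- 0L
  for (r in seq_len(min(nrow(df) - 1L, 16L))) {
    for (cc in seq_len(min(ncol(df), PLATE_COLS))) {
      cell <- df[r + 1L, cc]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      addr <- paste0(PLATE_ROWS[r], cc)
      sc <- parse_spot_code(cell, addr)
      n_occ <- n_occ + 1L
      spots[[n_occ]] <- data.frame(address = addr, type = sc$type,
                                   volume = sc$volume,
                                   replicate = sc$replicate,
                                   series = sc$series, label = sc$label,
                                   stringsAsFactors = FALSE)
    }
  }
  spots <- if (n_occ > 0L) do.call(rbind, spots) else
    data.frame(address = character(0), type = character(0),
               volume = numeric(0), replicate = integer(0),
               series = integer(0), label = character(0))
  if (nrow(spots) > 384L) stop("plate has more than 384 occupied spots")
  # default replicate numbers: occurrence order within each volume
  cal <- spots$type == "calibration"
  if (any(cal & is.na(spots$replicate))) {
    for (v in unique(spots$volume[cal])) {
      sel <- which(cal & spots$volume == v & is.na(spots$replicate))
      taken <- spots$replicate[cal & spots$volume == v & !is.na(spots$replicate)]
      free <- setdiff(seq_len(sum(cal & spots$volume == v)), taken)
      spots$replicate[sel] <- free[seq_along(sel)]
    }
  }
  structure(list(common = common, spots = spots), class = "plate_file")
}

#' @export
print.plate_file <- function(x, ...) {
  cat(sprintf("MALDI plate: %d occupied spots (%d calibration, %d category)\n",
              nrow(x$spots), sum(x$spots$type == "calibration"),
              sum(x$spots$type == "category")))
  if (length(x$common) > 0L)
    cat("common:", paste(names(x$common), unlist(x$common), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Generate per-spot analysis input files
#'
#' Joins a masslist with a plate layout (tab i corresponds to the i-th
#' occupied spot in row-major A1..P24 order, unless an explicit
#' \code{tab_map} is supplied) and writes one input CSV per tab: a metadata
#' header block of \code{key,value} lines (spot address, type,
#' volume/replicate or series/label, and the plate's common parameters)
#' followed by an \code{mz,area} peak table. Calibration spots are routed to
#' \code{calibration_line/}, category spots to \code{analysis/}.
#'
#' @param masslist_path path to the masslist XLSX.
#' @param plate a [parse_plate()] result or a plate-file path.
#' @param out_root output root; defaults to
#'   \code{<dir of masslist>/<basename without extension>}.
#' @param tab_map optional data.frame with columns \code{tab}, \code{address}
#'   overriding the positional tab-to-spot correspondence.
#' @return Invisibly, a data.frame describing the written files.
#' @export
generate_inputs <- function(masslist_path, plate, out_root = NULL,
                            tab_map = NULL) {
  if (is.character(plate)) plate <- parse_plate(plate)
  tabs <- read_masslist(masslist_path)
  spots <- plate$spots
  if (is.null(out_root))
    out_root <- file.path(dirname(masslist_path),
                          tools::file_path_sans_ext(basename(masslist_path)))
  if (!is.null(tab_map)) {
    idx <- match(names(tabs), tab_map$tab)
    if (anyNA(idx))
      stop("tabs missing from tab_map: ",
           paste(names(tabs)[is.na(idx)], collapse = ", "))
    sp_idx <- match(tab_map$address[idx], spots$address)
    if (anyNA(sp_idx))
      stop("tab_map addresses not on the plate: ",
           paste(tab_map$address[idx][is.na(sp_idx)], collapse = ", "))
    spots <- spots[sp_idx, , drop = FALSE]
  } else if (length(tabs) != nrow(spots)) {
    stop(sprintf(
      "masslist has %d tabs but the plate has %d occupied spots",
      length(tabs), nrow(spots)))
  }
  dirs <- c(calibration = file.path(out_root, "calibration_line"),
            category = file.path(out_root, "analysis"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  fn <- paste0(sanitize_tab_name(names(tabs)), ".csv")
  if (anyDuplicated(fn))
    stop("tab name collision after sanitization: ", fn[duplicated(fn)][1])
  written <- data.frame(tab = names(tabs), address = spots$address,
                        type = spots$type,
                        path = rep(NA_character_, length(tabs)),
                        stringsAsFactors = FALSE)
  for (i in seq_along(tabs)) {
    sp <- spots[i, ]
    meta <- c(experiment = names(tabs)[i], address = sp$address,
              type = sp$type)
    meta <- c(meta, if (sp$type == "calibration")
      c(volume_ul = format(sp$volume, digits = 15),
        replicate = as.character(sp$replicate))
      else c(series = as.character(sp$series), label = sp$label))
    for (k in names(plate$common))
      meta[[k]] <- format(plate$common[[k]], digits = 15)
    df <- tabs[[i]]
    path <- file.path(dirs[[sp$type]], fn[i])
    lines <- c(sprintf("%s,%s", names(meta), unname(meta)),
               "mz,area",
               if (nrow(df) > 0L)
                 sprintf("%s,%s", format(df$mz, digits = 15, trim = TRUE),
                         format(df$area, digits = 15, trim = TRUE)))
    writeLines(lines, path)
    written$path[i] <- path
  }
  invisible(written)
}

#' Read a per-spot input file
#'
#' @param path path to an input CSV written by [generate_inputs()].
#' @return List with \code{meta} (named character vector) and \code{peaks}
#'   (data.frame \code{mz,area}).
#' @export
read_spot_input <- function(path) {
  lines <- readLines(path)
  split_at <- match("mz,area", lines)
  if (is.na(split_at)) stop("no 'mz,area' section in input file: ", path)
  meta <- character(0)
  if (split_at > 1L) {
    kv <- strsplit(lines[seq_len(split_at - 1L)], ",", fixed = TRUE)
    meta <- vapply(kv, function(p)
      if (length(p) >= 2L) paste(p[-1L], collapse = ",") else "", "")
    names(meta) <- vapply(kv, `[`, "", 1L)
  }
  peaks <- if (split_at < length(lines)) {
    pk <- utils::read.csv(text = lines[split_at:length(lines)])
    names(pk) <- c("mz", "area")
    pk
  } else data.frame(mz = numeric(0), area = numeric(0))
  list(meta = meta, peaks = peaks)
}
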