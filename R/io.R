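# Delimited spectrum tables and header+block hyperspectral cubes.
# Tables: first column wavenumber, remaining columns intensities; comma
# delimiter for .csv, tab/whitespace otherwise; '#' lines are comments.
# Cubes: <name>.json header + <name>.dat block, row-major, wavenumber-fastest.

table_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a spectrum table
#'
#' Reads a delimited text table (wavenumber in the first column, one spectrum
#' per remaining column) into a [spectrum_set()]. Files stored with a
#' descending axis are reordered to ascending, intensities in step.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab/whitespace-separated. Lines starting with `#` are skipped.
#' @param modality `"IR"` or `"RAMAN"`.
#' @return a [spectrum_set()] with ascending axis; column names become
#'   spectrum ids.
#' @export
read_spectrum_table <- function(path, modality = c("IR", "RAMAN")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop_contract("file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) < 2L)
    stop_contract("spectrum table %s has fewer than 2 rows", path)
  sep <- table_delim(path)
  split1 <- strsplit(lines[1], if (sep == ",") "," else "[\t ]+")[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(split1)))
  first_data <- if (has_header) 2L else 1L
  if (length(lines) - first_data + 1L < 2L)
    stop_contract("spectrum table %s has fewer than 2 data rows", path)
  rows <- strsplit(lines[first_data:length(lines)], if (sep == ",") "," else "[\t ]+")
  ncols <- length(rows[[1]])
  if (ncols < 2L) stop_contract("spectrum table %s needs >= 2 columns", path)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = ncols)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncols)
      stop_contract("line %d of %s has %d fields, expected %d",
                    line_no[first_data + i - 1L], path, length(r), ncols)
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v))
      stop_contract("non-numeric cell on line %d of %s: '%s'",
                    line_no[first_data + i - 1L], path, r[which(is.na(v))[1]])
    vals[i, ] <- v
  }
  wn <- vals[, 1]
  if (anyDuplicated(wn)) {
    d <- wn[duplicated(wn)][1]
    bad <- which(vals[, 1] == d)[2]
    stop_contract("duplicate wavenumber %g on line %d of %s",
                  d, line_no[first_data + bad - 1L], path)
  }
  ord <- order(wn)
  wn <- wn[ord]
  intens <- t(vals[ord, -1, drop = FALSE])
  ids <- if (has_header) split1[-1] else paste0("s", seq_len(nrow(intens)))
  spectrum_set(intens, wavenumber = wn, modality = modality, form = "RAW",
               meta = data.frame(group = "all", id = ids, stringsAsFactors = FALSE))
}

#' Write a spectrum table
#'
#' @param set a [spectrum_set()]
#' @param path output path (`.csv` for comma-separated, anything else
#'   tab-separated). A provenance comment line is written first.
#' @return `path`, invisibly
#' @export
write_spectrum_table <- function(set, path) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  if (n_spectra(set) < 1L) stop_contract("cannot write an empty spectrum set")
  sep <- table_delim(path)
  ids <- set$meta$id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_provenance(paste0("modality=", set$modality)), con)
  writeLines(paste(c("wavenumber", ids), collapse = sep), con)
  body <- cbind(set$wavenumber, t(set$intensity))
  writeLines(apply(body, 1, function(r)
    paste(sprintf("%.17g", r), collapse = sep)), con)
  invisible(path)
}

cube_paths <- function(path) {
  base <- sub("\\.(json|dat)$", "", path)
  list(header = paste0(base, ".json"), data = paste0(base, ".dat"))
}

#' Write a hyperspectral cube
#'
#' Writes `<name>.json` (dimensions, pixel size, axis, dtype, storage) and
#' `<name>.dat` holding the intensity block in row-major, wavenumber-fastest
#' order. `storage = "binary"` writes little-endian floats (`dtype` `"float64"`
#' default, `"float32"` supported); `storage = "text"` writes one value per
#' line, for small human-readable fixtures.
#'
#' @param cube a [hypercube()]
#' @param path base path or either component path
#' @param storage `"binary"` or `"text"`
#' @param dtype `"float64"` or `"float32"` (binary storage only)
#' @return the header path, invisibly
#' @export
write_cube <- function(cube, path, storage = c("binary", "text"),
                       dtype = c("float64", "float32")) {
  stopifnot(inherits(cube, "vib_hypercube"))
  storage <- match.arg(storage)
  dtype <- match.arg(dtype)
  p <- cube_paths(path)
  header <- list(n_rows = cube$n_rows, n_cols = cube$n_cols,
                 pixel_size = cube$pixel_size, modality = cube$modality,
                 axis = cube$wavenumber, storage = storage,
                 dtype = if (storage == "binary") dtype else "text",
                 data_file = basename(p$data),
                 provenance = sub("^# ", "", pkg_provenance()))
  jsonlite::write_json(header, p$header, auto_unbox = TRUE, digits = NA)
  # row-major, wavenumber-fastest: channel varies fastest, then col, then row
  vec <- as.numeric(aperm(cube$data, c(3, 2, 1)))
  if (storage == "binary") {
    con <- file(p$data, "wb")
    on.exit(close(con))
    writeBin(vec, con, size = if (dtype == "float32") 4L else 8L,
             endian = "little")
  } else {
    writeLines(formatC(vec, format = "g", digits = 17), p$data)
  }
  invisible(p$header)
}

#' Read a hyperspectral cube
#'
#' Counterpart of [write_cube()]. The header and block sizes are
#' cross-checked; a mismatch is a format error reporting both sizes.
#'
#' @param path base path or path to either the `.json` header or `.dat` block
#' @return a [hypercube()]
#' @export
read_cube <- function(path) {
  p <- cube_paths(path)
  if (!file.exists(p$header)) stop_contract("cube header not found: %s", p$header)
  h <- jsonlite::read_json(p$header, simplifyVector = TRUE)
  data_path <- file.path(dirname(p$header), h$data_file %||% basename(p$data))
  if (!file.exists(data_path)) stop_contract("cube data block not found: %s", data_path)
  n_expected <- h$n_rows * h$n_cols * length(h$axis)
  if (identical(h$storage, "text") || identical(h$dtype, "text")) {
    vec <- as.numeric(readLines(data_path, warn = FALSE))
  } else {
    size <- if (identical(h$dtype, "float32")) 4L else 8L
    n_avail <- file.info(data_path)$size / size
    con <- file(data_path, "rb")
    on.exit(close(con))
    vec <- readBin(con, "double", n = ceiling(n_avail), size = size,
                   endian = "little")
  }
  if (length(vec) != n_expected)
    stop_contract("cube block %s holds %d values but header implies %d",
                  data_path, length(vec), n_expected)
  arr <- aperm(array(vec, dim = c(length(h$axis), h$n_cols, h$n_rows)), c(3, 2, 1))
  hypercube(arr, h$axis, pixel_size = h$pixel_size,
            modality = h$modality %||% "IR")
}
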