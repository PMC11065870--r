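# Spectrum container, text/mzML readers and atomic CSV writers.

#' Construct a spectrum
#'
#' @param mz strictly increasing m/z axis.
#' @param intensity non-negative intensities, same length as `mz`.
#' @param metadata list of provenance fields (source, seed, config hash).
#' @return `spectrum` object.
#' @export
new_spectrum <- function(mz, intensity, metadata = list()) {
  if (length(mz) != length(intensity)) stop("axes differ in length", call. = FALSE)
  if (anyNA(mz) || anyNA(intensity)) stop("spectrum contains NA/NaN", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE)) stop("m/z axis must be strictly increasing",
                                             call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 metadata = metadata), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, m/z %.2f-%.2f, source=%s\n",
              length(x$mz), min(x$mz), max(x$mz),
              x$metadata$source %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# atomic write contract: write to a temp sibling, then rename
.atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path, call. = FALSE)
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Text dialect: two numeric columns (m/z, intensity), whitespace- or
#' comma-delimited, `#` comment lines. An unsorted axis is sorted with a
#' warning. mzML (first MS1 scan) requires the mzR package.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"text"`, or `"mzML"`.
#' @return a `spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "text", "mzML")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "text"
  }
  if (format == "mzML") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("mzML input requires the mzR package", call. = FALSE)
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1L)
    return(new_spectrum(pk[, 1L], pk[, 2L], metadata = list(source = path)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) stop("malformed spectrum line ", bad[1L], " in ", path,
                        call. = FALSE)
  mz <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(mz) || anyNA(y)) {
    stop("non-numeric value at line ", which(is.na(mz) | is.na(y))[1L],
         " in ", path, call. = FALSE)
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z axis not sorted in ", path, "; sorting")
    o <- order(mz)
    mz <- mz[o]; y <- y[o]
    keep <- c(TRUE, diff(mz) > 0)
    mz <- mz[keep]; y <- y[keep]
  }
  new_spectrum(mz, y, metadata = list(source = path))
}

#' Write a spectrum as two-column text (atomic)
#' @param spec a `spectrum`.
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c("# mz_Th intensity_au",
                 sprintf("# source=%s seed=%s",
                         spec$metadata$source %||% "NA",
                         spec$metadata$seed %||% "NA")), con)
    writeLines(sprintf("%.6f %.8g", spec$mz, spec$intensity), con)
  })
}

#' Read/write residue and adduct tables as CSV
#'
#' Residue tables use columns `name,formula`; adduct tables
#' `name,mass,class`. Adduct masses are written with full double precision
#' so the table round-trips exactly.
#'
#' @param path CSV path.
#' @param table table to write.
#' @name mass_tables
NULL

#' @rdname mass_tables
#' @export
read_residue_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  residue_table(extra = NULL) -> builtin
  extra <- df[!df$name %in% builtin$name, , drop = FALSE]
  residue_table(extra = if (nrow(extra)) extra else NULL)
}

#' @rdname mass_tables
#' @export
write_adduct_table <- function(table, path) {
  .atomic_write(path, function(tmp) {
    out <- table
    out$mass <- vapply(out$mass, function(x) format(x, digits = 17), "")
    write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' @rdname mass_tables
#' @export
read_adduct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 colClasses = c(name = "character", mass = "numeric",
                                class = "character"))
  if (any(df$mass <= 0)) stop("adduct mass shifts must be positive", call. = FALSE)
  df
}

#' Write a mass distribution as CSV (atomic; units in the header)
#' @param md a `mass_distribution`.
#' @param path output path.
#' @export
write_massdist <- function(md, path) {
  pk <- md_peaks(md)
  .atomic_write(path, function(tmp) {
    write.csv(data.frame(mass_Da = pk$mass, abundance = pk$abundance,
                         on_lattice_flag = pk$on_lattice),
              tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Write MP events as one-column CSV (kDa)
#' @param events an `mp_events` vector.
#' @param path output path.
#' @export
write_mp_events <- function(events, path) {
  .atomic_write(path, function(tmp) {
    write.csv(data.frame(mass_kDa = as.numeric(events)), tmp,
              row.names = FALSE, quote = FALSE)
  })
}

#' Read MP events from one-column CSV
#' @param path CSV path with column `mass_kDa`.
#' @return numeric vector of event masses (kDa).
#' @export
read_mp_events <- function(path) {
  df <- read.csv(path, comment.char = "#")
  ev <- as.numeric(df[[1L]])
  if (anyNA(ev)) stop("non-numeric MP event in ", path, call. = FALSE)
  structure(ev, class = "mp_events")
}
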