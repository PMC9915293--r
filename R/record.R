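#' ECG record container
#'
#' An `ecg_record` holds one or more leads of integer-quantized ECG samples
#' (analog-to-digital units, ADU) together with the acquisition metadata the
#' codec needs: sampling frequency, bit resolution and ADU-per-mV gain.
#' Samples stay in ADU throughout the compression path; converting to
#' physical units would destroy losslessness.
#'
#' @param samples integer vector, or a named list of integer vectors (one
#'   per lead, equal lengths).
#' @param fs sampling frequency in Hz.
#' @param bits ADC resolution in bits (8--24). All samples must be
#'   representable at this resolution.
#' @param gain ADU per millivolt; `NA` when unknown (gain is metadata only,
#'   it never touches the codec path).
#' @param signed logical; `TRUE` for two's-complement sample values in
#'   `[-2^(bits-1), 2^(bits-1)-1]`, `FALSE` for offset-binary values in
#'   `[0, 2^bits - 1]`.
#' @return an object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(as.integer(round(500 * sin(seq(0, 4 * pi, length.out = 720)))),
#'                   fs = 360, bits = 11, gain = 200)
#' rec
#' @export
ecg_record <- function(samples, fs, bits, gain = NA_real_, signed = TRUE) {
  if (!is.list(samples)) samples <- list(lead1 = samples)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("lead", seq_along(samples))
  samples <- lapply(samples, function(x) {
    if (!is.numeric(x)) stop("samples must be numeric integers")
    if (any(!is.finite(x)) || any(x != floor(x)))
      stop("samples must be finite integers (ADU)")
    as.integer(x)
  })
  ns <- vapply(samples, length, integer(1))
  if (length(unique(ns)) != 1L) stop("all leads must have the same length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive number")
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 8L || bits > 24L) stop("bits must be in [8, 24]")
  lo <- if (signed) -2^(bits - 1) else 0
  hi <- if (signed) 2^(bits - 1) - 1 else 2^bits - 1
  for (nm in names(samples)) {
    r <- range(samples[[nm]])
    if (r[1] < lo || r[2] > hi)
      stop(sprintf("lead '%s' has samples outside the %d-bit %s range [%d, %d]",
                   nm, bits, if (signed) "signed" else "offset", lo, hi))
  }
  structure(list(leads = samples, fs = as.numeric(fs), bits = bits,
                 gain = as.numeric(gain), signed = isTRUE(signed)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$leads[[1]])
  cat(sprintf("ECG record: %d lead(s), %d samples (%.1f s at %g Hz)\n",
              length(x$leads), n, n / x$fs, x$fs))
  cat(sprintf("  resolution: %d-bit %s, gain: %s ADU/mV\n",
              x$bits, if (x$signed) "signed" else "offset",
              if (is.na(x$gain)) "unknown" else format(x$gain)))
  for (nm in names(x$leads)) {
    s <- x$leads[[nm]]
    cat(sprintf("  %s: range [%d, %d]\n", nm, min(s), max(s)))
  }
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$leads[[1]])

#' Extract one lead from a record
#'
#' @param record an [ecg_record()].
#' @param lead lead name or index; defaults to the first lead.
#' @return integer sample vector.
#' @export
record_lead <- function(record, lead = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$leads[[lead]]
  if (is.null(x)) stop(sprintf("no lead '%s' in record", as.character(lead)))
  x
}

#' Read an ECG record from CSV/text or WFDB files
#'
#' CSV dialect: either one integer per line, or a one-line header
#' `name,fs,bits,gain` followed by one integer per line. Plain streams
#' without a header need `fs` and `bits` supplied. WFDB records are read
#' from the `.hea` header; digital samples only (no physical-unit
#' conversion), signal formats 212 and 16.
#'
#' @param path path to a `.csv`/`.txt` file or a WFDB `.hea` file (or the
#'   record base name without extension).
#' @param format `"auto"`, `"csv"` or `"wfdb"`.
#' @param lead optional lead name or index to keep (default: all leads).
#' @param fs,bits,gain metadata for headerless CSV streams.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"), lead = NULL,
                        fs = NULL, bits = NULL, gain = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "txt")) "csv"
      else if (ext == "hea" || file.exists(paste0(path, ".hea"))) "wfdb"
      else stop(sprintf("cannot identify format of '%s'", path))
  }
  rec <- switch(format,
    csv = read_record_csv(path, fs = fs, bits = bits, gain = gain),
    wfdb = read_wfdb(path))
  if (!is.null(lead)) {
    x <- record_lead(rec, lead)
    nm <- if (is.character(lead)) lead else names(rec$leads)[lead]
    rec$leads <- stats::setNames(list(x), nm)
  }
  rec
}

read_record_csv <- function(path, fs = NULL, bits = NULL, gain = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty CSV record")
  name <- "lead1"
  if (grepl(",", lines[1], fixed = TRUE)) {
    hdr <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
    if (length(hdr) != 4L)
      stop("CSV header must be 'name,fs,bits,gain'")
    name <- hdr[1]
    fs <- as.numeric(hdr[2]); bits <- as.numeric(hdr[3]); gain <- as.numeric(hdr[4])
    lines <- lines[-1]
  }
  if (is.null(fs) || is.null(bits))
    stop("headerless CSV stream needs fs and bits")
  vals <- suppressWarnings(as.numeric(lines))
  if (any(is.na(vals)) || any(vals != floor(vals)))
    stop("CSV record must contain only integer samples")
  ecg_record(stats::setNames(list(as.integer(vals)), name),
             fs = fs, bits = bits, gain = gain)
}

#' Write an ECG record as CSV
#'
#' Writes the dialect [read_record()] accepts: a `name,fs,bits,gain` header
#' line followed by one integer sample per line. Multi-lead records are
#' written one file per lead (`<path>_<lead>.csv`) and a single-lead record
#' to `path` itself.
#'
#' @param record an [ecg_record()].
#' @param path output path.
#' @return invisibly, the path(s) written.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  write1 <- function(nm, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("%s,%g,%d,%g", nm, record$fs, record$bits,
                       record$gain), con)
    writeLines(format(record$leads[[nm]], scientific = FALSE, trim = TRUE), con)
    p
  }
  if (length(record$leads) == 1L) {
    out <- write1(names(record$leads), path)
  } else {
    base <- tools::file_path_sans_ext(path)
    ext <- tools::file_ext(path)
    out <- vapply(names(record$leads), function(nm)
      write1(nm, paste0(base, "_", nm, ".", ext)), character(1))
  }
  invisible(out)
}

# --- minimal WFDB digital reader (header + signal formats 212 and 16) ----

read_wfdb <- function(path) {
  base <- if (tolower(tools::file_ext(path)) == "hea")
    tools::file_path_sans_ext(path) else path
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop(sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rl <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rl) < 3L) stop("WFDB header: record line needs name, nsig, fs")
  nsig <- as.integer(rl[2])
  fs <- as.numeric(sub("/.*$", "", rl[3]))  # drop counter frequency if any
  nsamp <- if (length(rl) >= 4L) as.numeric(rl[4]) else NA_real_
  if (nsig < 1L) stop("WFDB header: no signals")
  if (length(lines) < 1L + nsig) stop("WFDB header: missing signal lines")

  sig <- lapply(lines[2:(1 + nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 2L) stop("WFDB header: malformed signal line")
    fmt <- as.integer(sub("x.*$", "", tok[2]))
    gain <- if (length(tok) >= 3L) tok[3] else "200"
    gain_num <- as.numeric(sub("\\(.*", "", sub("/.*$", "", gain)))
    if (is.na(gain_num) || gain_num == 0) gain_num <- 200
    adcres <- if (length(tok) >= 4L) as.integer(tok[4]) else 12L
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = "_")
      else NA_character_
    list(file = tok[1], fmt = fmt, gain = gain_num, bits = adcres, name = desc)
  })
  nms <- vapply(sig, `[[`, character(1), "name")
  nms[is.na(nms)] <- paste0("sig", which(is.na(nms)))
  for (i in seq_along(sig)) sig[[i]]$name <- nms[i]
  fmts <- unique(vapply(sig, `[[`, integer(1), "fmt"))
  files <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(fmts) != 1L || length(files) != 1L)
    stop("WFDB reader supports a single signal file with one format")
  if (!fmts %in% c(212L, 16L))
    stop(sprintf("WFDB signal format %d not supported (only 212 and 16)", fmts))
  dat <- file.path(dirname(hea), files)
  if (!file.exists(dat)) stop(sprintf("WFDB signal file not found: %s", dat))
  raw <- readBin(dat, "raw", n = file.info(dat)$size)

  flat <- if (fmts == 212L) decode_fmt212(raw) else decode_fmt16(raw)
  ntot <- (length(flat) %/% nsig) * nsig
  m <- matrix(flat[seq_len(ntot)], nrow = nsig)
  if (!is.na(nsamp) && ncol(m) >= nsamp) m <- m[, seq_len(nsamp), drop = FALSE]

  leads <- stats::setNames(lapply(seq_len(nsig), function(i) m[i, ]),
                           make.unique(vapply(sig, `[[`, character(1), "name")))
  bits <- max(vapply(sig, `[[`, integer(1), "bits"))
  gains <- vapply(sig, `[[`, numeric(1), "gain")
  # format-212 MITDB-style records carry offset-binary values around adczero
  signed <- min(vapply(leads, min, integer(1))) < 0
  ecg_record(leads, fs = fs, bits = bits, gain = gains[1], signed = signed)
}

decode_fmt212 <- function(raw) {
  usable <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(usable)])
  b0 <- b[seq(1, usable, by = 3)]
  b1 <- b[seq(2, usable, by = 3)]
  b2 <- b[seq(3, usable, by = 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8)
  s2 <- b2 + bitwShiftL(bitwAnd(b1, 0xF0L), 4)
  sign12 <- function(v) ifelse(v >= 2048L, v - 4096L, v)
  as.integer(rbind(sign12(s1), sign12(s2)))
}

decode_fmt16 <- function(raw) {
  n <- length(raw) %/% 2L
  readBin(raw, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
}
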