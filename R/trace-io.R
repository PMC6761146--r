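#' Condition label for a recording
#'
#' Bundles the chemical condition of a bilayer experiment: total added Ca2+,
#' the agonists Bz-423 and PhAsO (all mM), an optional inhibitor tag and the
#' protein source.
#'
#' @param ca_mm total added Ca2+ (mM).
#' @param bz423_mm Bz-423 concentration (mM).
#' @param phaso_mm PhAsO concentration (mM).
#' @param inhibitor one of "none", "Ba", "MgADP", "Gd", "EGTA", "BKA",
#'   "polyanion".
#' @param source optional tag: "proteoliposome", "direct",
#'   "gel-eluted-monomer", "gel-eluted-dimer", "gel-eluted-oligomer".
#' @return an object of class `condition_label`.
#' @export
condition_label <- function(ca_mm = 0, bz423_mm = 0, phaso_mm = 0,
                            inhibitor = "none", source = NA_character_) {
  inhibitor <- match.arg(inhibitor,
                         c("none", "Ba", "MgADP", "Gd", "EGTA", "BKA",
                           "polyanion"))
  if (any(c(ca_mm, bz423_mm, phaso_mm) < 0)) {
    stop("concentrations must be >= 0")
  }
  structure(list(ca_mm = ca_mm, bz423_mm = bz423_mm, phaso_mm = phaso_mm,
                 inhibitor = inhibitor, source = source),
            class = "condition_label")
}

#' Uniformly sampled current recording
#'
#' The container every analysis stage consumes: an ordered vector of current
#' samples (pA) with the sampling rate, the holding potential on the cis side
#' (trans grounded; positive current = cations flowing cis to trans), the
#' chemical condition, the analog low-pass corner, and an optional note of a
#' known constant instrumental offset.
#'
#' The constructor does not reject invalid inputs; use [validate_trace()] to
#' obtain a list of invariant violations (analysis entry points do this and
#' stop on the first invalid trace).
#'
#' @param samples numeric vector of currents (pA).
#' @param sampling_rate sampling rate (Hz).
#' @param v_cis holding potential on the cis side (mV); NA if unknown.
#' @param condition a [condition_label()].
#' @param filter_cutoff analog low-pass corner (Hz); NA if unknown.
#' @param offset_note known constant offset (pA); NA when absent.
#' @return an object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, v_cis = NA_real_,
                          condition = condition_label(),
                          filter_cutoff = NA_real_,
                          offset_note = NA_real_) {
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 v_cis = as.numeric(v_cis),
                 condition = condition,
                 filter_cutoff = as.numeric(filter_cutoff),
                 offset_note = as.numeric(offset_note)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("current_trace: %d samples @ %g Hz (%.4g s), V_cis = %s mV\n",
              length(x$samples), x$sampling_rate, dur,
              format(x$v_cis)))
  cat(sprintf("  condition: Ca %g mM, Bz-423 %g mM, PhAsO %g mM, inhibitor %s\n",
              x$condition$ca_mm, x$condition$bz423_mm, x$condition$phaso_mm,
              x$condition$inhibitor))
  invisible(x)
}

#' Report invariant violations of a current trace
#'
#' @param trace a [current_trace()].
#' @return character vector of human-readable violations; empty when the
#'   trace satisfies all invariants.
#' @export
validate_trace <- function(trace) {
  v <- character(0)
  if (!inherits(trace, "current_trace")) {
    return("not a current_trace object")
  }
  if (!is.finite(trace$sampling_rate) || trace$sampling_rate <= 0) {
    v <- c(v, sprintf("sampling_rate: must be > 0 (got %s)",
                      format(trace$sampling_rate)))
  }
  if (length(trace$samples) < 1) {
    v <- c(v, "samples: at least 1 sample required")
  }
  bad <- which(!is.finite(trace$samples))
  if (length(bad)) {
    v <- c(v, sprintf("samples: non-finite value at index %d", bad[1]))
  }
  if (is.finite(trace$filter_cutoff) && is.finite(trace$sampling_rate) &&
      trace$sampling_rate > 0 &&
      trace$filter_cutoff > trace$sampling_rate / 2) {
    v <- c(v, "filter_cutoff: must be <= sampling_rate/2")
  }
  if (any(c(trace$condition$ca_mm, trace$condition$bz423_mm,
            trace$condition$phaso_mm) < 0, na.rm = TRUE)) {
    v <- c(v, "condition: concentrations must be >= 0")
  }
  v
}

assert_trace <- function(trace) {
  v <- validate_trace(trace)
  if (length(v)) stop("invalid current_trace: ", paste(v, collapse = "; "))
  invisible(trace)
}

# metadata <-> key=value helpers ------------------------------------------

trace_meta_pairs <- function(trace) {
  cnd <- trace$condition
  p <- c(sample_interval_s = sprintf("%.12g", 1 / trace$sampling_rate),
         v_cis_mv = if (is.finite(trace$v_cis)) sprintf("%.12g", trace$v_cis),
         filter_cutoff_hz = if (is.finite(trace$filter_cutoff))
           sprintf("%.12g", trace$filter_cutoff),
         offset_note_pa = if (is.finite(trace$offset_note))
           sprintf("%.12g", trace$offset_note),
         ca_mm = sprintf("%.12g", cnd$ca_mm),
         bz423_mm = sprintf("%.12g", cnd$bz423_mm),
         phaso_mm = sprintf("%.12g", cnd$phaso_mm),
         inhibitor = cnd$inhibitor,
         source = if (!is.na(cnd$source)) cnd$source)
  p[!vapply(p, is.null, logical(1))]
}

meta_to_trace_fields <- function(kv) {
  num <- function(key) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else NA_real_
  }
  cnd <- condition_label(
    ca_mm = if ("ca_mm" %in% names(kv)) as.numeric(kv[["ca_mm"]]) else 0,
    bz423_mm = if ("bz423_mm" %in% names(kv)) as.numeric(kv[["bz423_mm"]]) else 0,
    phaso_mm = if ("phaso_mm" %in% names(kv)) as.numeric(kv[["phaso_mm"]]) else 0,
    inhibitor = if ("inhibitor" %in% names(kv)) kv[["inhibitor"]] else "none",
    source = if ("source" %in% names(kv)) kv[["source"]] else NA_character_)
  list(v_cis = num("v_cis_mv"), filter_cutoff = num("filter_cutoff_hz"),
       offset_note = num("offset_note_pa"), condition = cnd,
       sample_interval = num("sample_interval_s"))
}

# writers ------------------------------------------------------------------

#' Write a current trace to disk
#'
#' Two plain-text dialects are supported. `atf` is Axon Text Format 1.0
#' (tab-separated, header records carrying the sampling interval and the
#' metadata as `Comment=` entries). `csv` writes a two-column
#' `time_s,current_pA` table plus a `<stem>.meta` sidecar of `key=value`
#' lines (CSV has no standard header block). Currents are written with 4
#' decimal places (a 0.1 fA quantum, far below the pA-scale noise floor);
#' times are sample index times the sampling interval.
#'
#' @param trace a valid [current_trace()].
#' @param path output file path.
#' @param format "atf" or "csv"; default guesses from the file extension.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "atf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.atf$", path, ignore.case = TRUE)) "atf" else "csv"
  }
  assert_trace(trace)
  dt <- 1 / trace$sampling_rate
  n <- length(trace$samples)
  tm <- sprintf("%.10g", (seq_len(n) - 1) * dt)
  cur <- sprintf("%.4f", trace$samples)
  if (format == "atf") {
    meta <- trace_meta_pairs(trace)
    comments <- sprintf("\"Comment=%s=%s\"",
                        names(meta)[-1], unlist(meta[-1], use.names = FALSE))
    header <- c("ATF\t1.0",
                sprintf("%d\t2", 2L + length(comments)),
                "\"AcquisitionMode=Fixed-Length Event-Driven\"",
                sprintf("\"SampleInterval=%s\"", meta[["sample_interval_s"]]),
                comments,
                "\"Time (s)\"\t\"Current (pA)\"")
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(header, paste(tm, cur, sep = "\t")), con, sep = "\n")
  } else {
    con <- file(path, open = "wb")
    writeLines(c("time_s,current_pA", paste(tm, cur, sep = ",")), con,
               sep = "\n")
    close(con)
    meta <- trace_meta_pairs(trace)
    writeLines(paste(names(meta), unlist(meta, use.names = FALSE), sep = "="),
               sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".meta")

# readers ------------------------------------------------------------------

check_time_column <- function(tm, dt = NULL) {
  if (length(tm) >= 2) {
    d <- diff(tm)
    if (any(d <= 0)) stop("format error: non-monotonic time column")
    if (is.null(dt)) dt <- stats::median(d)
    if (max(abs(d - dt)) > 1e-6 * max(dt, 1e-300)) {
      stop("format error: non-uniform time column (relative jitter > 1e-6)")
    }
  }
  dt
}

#' Read a current trace from disk
#'
#' Counterpart of [write_trace()]; accepts the ATF 1.0 and CSV dialects it
#' emits (and tolerates generic two-column files of the same shape). The
#' sampling rate is taken from the declared sampling interval when present,
#' otherwise derived from the time column, which is checked for monotone,
#' uniform spacing.
#'
#' @param path file to read.
#' @param format "atf" or "csv"; default guesses from the extension.
#' @return a [current_trace()].
#' @export
read_trace <- function(path, format = c("auto", "atf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.atf$", path, ignore.case = TRUE)) "atf" else "csv"
  }
  if (format == "atf") read_trace_atf(path) else read_trace_csv(path)
}

read_trace_atf <- function(path) {
  head2 <- readLines(path, n = 2)
  if (length(head2) < 2 || !grepl("^ATF", head2[1])) {
    stop("format error: not an ATF file (missing ATF signature): ", path)
  }
  counts <- suppressWarnings(as.integer(strsplit(head2[2], "\t")[[1]]))
  if (length(counts) < 2 || any(is.na(counts))) {
    stop("format error: malformed ATF record-count line")
  }
  n_rec <- counts[1]
  hdr <- readLines(path, n = 2 + n_rec + 1)
  records <- gsub("^\"|\"$", "", hdr[3:(2 + n_rec)])
  kv <- list()
  for (r in records) {
    if (grepl("^SampleInterval=", r)) {
      kv[["sample_interval_s"]] <- sub("^SampleInterval=", "", r)
    } else if (grepl("^Comment=", r)) {
      body <- sub("^Comment=", "", r)
      eq <- regexpr("=", body, fixed = TRUE)
      if (eq > 0) {
        kv[[substr(body, 1, eq - 1)]] <- substr(body, eq + 1, nchar(body))
      }
    }
  }
  dat <- utils::read.table(path, sep = "\t", skip = 2 + n_rec + 1,
                           colClasses = "numeric",
                           col.names = c("time", "current"))
  finish_read(dat$time, dat$current, kv, path)
}

read_trace_csv <- function(path) {
  dat <- utils::read.csv(path, colClasses = "numeric")
  if (ncol(dat) < 2) stop("format error: CSV needs time and current columns")
  names(dat)[1:2] <- c("time", "current")
  kv <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    lines <- readLines(sp)
    lines <- lines[nzchar(lines)]
    eq <- regexpr("=", lines, fixed = TRUE)
    kv <- as.list(substring(lines, eq + 1))
    names(kv) <- substring(lines, 1, eq - 1)
  }
  finish_read(dat$time, dat$current, kv, path)
}

finish_read <- function(tm, cur, kv, path) {
  bad <- which(!is.finite(cur))
  if (length(bad)) {
    stop(sprintf("data error: non-finite current at data row %d of %s",
                 bad[1], path))
  }
  meta <- meta_to_trace_fields(kv)
  dt <- meta$sample_interval
  if (!is.finite(dt)) dt <- NULL
  dt <- check_time_column(tm, dt)
  if (is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("format error: missing or ambiguous sampling interval in ", path)
  }
  current_trace(cur, sampling_rate = 1 / dt, v_cis = meta$v_cis,
                condition = meta$condition,
                filter_cutoff = meta$filter_cutoff,
                offset_note = meta$offset_note)
}
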