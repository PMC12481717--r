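# Minimal EDF (European Data Format) writer/reader: 16-bit integer samples,
# standard 256-byte fixed header plus 256 bytes per signal. All channels share
# one sampling rate and one physical range. Recordings whose length is not a
# whole number of data records are zero-padded on disk; the true sample count
# is carried in the reserved header field and honoured on read.

EDF_PHYS_RANGE <- c(-800, 800)   # microvolts
EDF_DIG_RANGE <- c(-32768L, 32767L)

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Quantization step of the package's EDF encoding
#'
#' EDF stores 16-bit integers mapped onto a fixed physical range; this returns
#' the physical value of one digital unit (the worst-case round-trip error is
#' half this step).
#'
#' @return microvolts per digital unit.
#' @export
edfQuantizationStep <- function() {
  diff(EDF_PHYS_RANGE) / (EDF_DIG_RANGE[2] - EDF_DIG_RANGE[1])
}

#' Write one recording to an EDF file
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @param recordSeconds duration of one EDF data record (default 0.5 s).
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(recording, path, recordSeconds = 0.5) {
  x <- recording@data
  rate <- recording@rate
  spr <- rate * recordSeconds
  if (spr != round(spr)) stop("recordSeconds * rate must be an integer")
  spr <- as.integer(spr)
  nCh <- nrow(x)
  nSamp <- ncol(x)
  nRec <- ceiling(nSamp / spr)
  meta <- recording@subjectMeta
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(paste(meta$id %||% "X", meta$group %||% "X",
                   sprintf("age=%.3f", meta$age %||% NA_real_)), 80),
    padField("tactileERP synthetic recording", 80),
    padField("01.01.26", 8), padField("00.00.00", 8),
    padField(256 * (nCh + 1), 8),
    padField(sprintf("NSAMP=%d", nSamp), 44),
    padField(nRec, 8),
    padField(format(recordSeconds, digits = 8), 8),
    padField(nCh, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- function(field, width)
    writeChar(paste(vapply(field, padField, "", width = width), collapse = ""),
              con, eos = NULL)
  sig(recording@channelNames, 16)
  sig(rep("synthetic", nCh), 80)
  sig(rep("uV", nCh), 8)
  sig(rep(format(EDF_PHYS_RANGE[1]), nCh), 8)
  sig(rep(format(EDF_PHYS_RANGE[2]), nCh), 8)
  sig(rep(format(EDF_DIG_RANGE[1]), nCh), 8)
  sig(rep(format(EDF_DIG_RANGE[2]), nCh), 8)
  sig(rep("none", nCh), 80)
  sig(rep(spr, nCh), 8)
  sig(rep("", nCh), 32)
  # digitize: linear map physical -> digital, clipped
  scale <- (EDF_DIG_RANGE[2] - EDF_DIG_RANGE[1]) / diff(EDF_PHYS_RANGE)
  xp <- matrix(0L, nCh, nRec * spr)
  q <- round((pmin(pmax(x, EDF_PHYS_RANGE[1]), EDF_PHYS_RANGE[2]) -
                EDF_PHYS_RANGE[1]) * scale) + EDF_DIG_RANGE[1]
  xp[, seq_len(nSamp)] <- as.integer(q)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(xp[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file (optionally with its events TSV) into an EEGRecording
#'
#' @param path EDF file path.
#' @param eventsPath optional events TSV with columns
#'   \code{onset_sample}, \code{onset_s}, \code{level}.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, eventsPath = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8)
  reserved <- trimws(rd(44))
  nRec <- as.integer(trimws(rd(8)))
  recSec <- as.numeric(trimws(rd(8)))
  nCh <- as.integer(trimws(rd(4)))
  rdSig <- function(width)
    vapply(seq_len(nCh), function(i) trimws(rd(width)), "")
  labels <- rdSig(16)
  rdSig(80); rdSig(8)
  pMin <- as.numeric(rdSig(8)); pMax <- as.numeric(rdSig(8))
  dMin <- as.numeric(rdSig(8)); dMax <- as.numeric(rdSig(8))
  rdSig(80)
  spr <- as.integer(rdSig(8))
  rdSig(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  spr <- spr[1]
  rate <- spr / recSec
  total <- nRec * spr
  x <- matrix(0, nCh, total)
  for (r in seq_len(nRec)) {
    block <- readBin(con, "integer", n = nCh * spr, size = 2, signed = TRUE,
                     endian = "little")
    x[, ((r - 1L) * spr + 1L):(r * spr)] <-
      matrix(block, nCh, spr, byrow = TRUE)
  }
  for (i in seq_len(nCh))
    x[i, ] <- pMin[i] + (x[i, ] - dMin[i]) * (pMax[i] - pMin[i]) / (dMax[i] - dMin[i])
  nSamp <- total
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1]]
  if (length(m) == 2) nSamp <- min(total, as.integer(m[2]))
  x <- x[, seq_len(nSamp), drop = FALSE]
  rownames(x) <- labels
  events <- data.frame(onset_sample = integer(), level = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(eventsPath)) {
    ev <- utils::read.delim(eventsPath, stringsAsFactors = FALSE)
    events <- data.frame(onset_sample = as.integer(ev$onset_sample),
                         level = ev$level, stringsAsFactors = FALSE)
  }
  meta <- list(id = NA_character_, group = NA_character_, age = NA_real_)
  pp <- strsplit(patient, " +")[[1]]
  if (length(pp) >= 2) meta$id <- pp[1]
  if (length(pp) >= 2 && pp[2] %in% c("ASD", "TD")) meta$group <- pp[2]
  agem <- regmatches(patient, regexec("age=([0-9.]+)", patient))[[1]]
  if (length(agem) == 2) meta$age <- as.numeric(agem[2])
  new("EEGRecording", data = x, rate = rate, channelNames = labels,
      events = events, subjectMeta = meta)
}

#' Write a simulated cohort to disk (EDF + events TSV + manifest CSV)
#'
#' One EDF file and one events TSV per subject, plus a cohort manifest CSV
#' (\code{subject, group, age, n_events, edf, events}). The written signals
#' round-trip through [readEDF()] to within the 16-bit EDF quantization step.
#'
#' @param cohort output of [simulateCohort()], or a list of
#'   \linkS4class{EEGRecording}s.
#' @param outDir output directory (created if needed).
#' @return the manifest data.frame, invisibly; written to
#'   \code{outDir/manifest.csv}.
#' @export
writeDataset <- function(cohort, outDir) {
  recs <- if (is.list(cohort) && !is.null(cohort$recordings))
    cohort$recordings else cohort
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  rows <- lapply(recs, function(r) {
    id <- r@subjectMeta$id
    edf <- file.path(outDir, paste0(id, ".edf"))
    tsv <- file.path(outDir, paste0(id, "_events.tsv"))
    writeEDF(r, edf)
    ev <- r@events
    utils::write.table(
      data.frame(onset_sample = ev$onset_sample,
                 onset_s = (ev$onset_sample - 1L) / r@rate,
                 level = ev$level),
      tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    data.frame(subject = id, group = r@subjectMeta$group,
               age = r@subjectMeta$age, n_events = nrow(ev),
               edf = edf, events = tsv, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), group = character(), age = numeric(),
               n_events = integer(), edf = character(), events = character(),
               stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
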