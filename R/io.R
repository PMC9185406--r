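#' Write a paired session to a delimited text file
#'
#' Tab-separated columns `ref` and `exp`, preceded by `#`-prefixed header
#' lines carrying the sampling rate, subject id, recorder clip level and the
#' ground-truth R-peak indices (when present).
#'
#' @param session List with `ref` and `exp` [signal_record()]s (as returned
#'   by [synth_session()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", session$ref$fs), con)
  writeLines(sprintf("# subject_id=%s", session$ref$subject_id), con)
  if (!is.null(session$ref$meta$clip_level))
    writeLines(sprintf("# clip_level=%g", session$ref$meta$clip_level), con)
  if (!is.null(session$ref$meta$r_peaks_true))
    writeLines(paste0("# r_peaks_true=",
                      paste(session$ref$meta$r_peaks_true, collapse = ",")), con)
  writeLines("ref\texp", con)
  utils::write.table(
    data.frame(ref = session$ref$samples, exp = session$exp$samples),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a paired session written by [write_session()]
#'
#' @param path Input file path.
#' @return List with `ref` and `exp` [signal_record()]s.
#' @export
read_session <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    h <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(h)) return(NULL)
    sub(paste0("^# ", key, "="), "", h[1])
  }
  fs <- as.numeric(getval("fs"))
  if (!length(fs) || is.na(fs)) stop("missing `fs` header")
  subject_id <- getval("subject_id")
  if (is.null(subject_id)) subject_id <- "S?"
  meta <- list()
  cl <- getval("clip_level")
  if (!is.null(cl)) meta$clip_level <- as.numeric(cl)
  rp <- getval("r_peaks_true")
  if (!is.null(rp))
    meta$r_peaks_true <- as.integer(strsplit(rp, ",")[[1]])
  dat <- utils::read.table(path, sep = "\t", skip = length(hdr) + 1L,
                           col.names = c("ref", "exp"))
  list(ref = signal_record(dat$ref, fs, "REF", subject_id, meta = meta),
       exp = signal_record(dat$exp, fs, "EXP", subject_id, meta = meta))
}
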