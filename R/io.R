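# Delimited-text I/O for traces, result tables and construct sequences.
# All writes are atomic (temp file + rename).

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Write and read magnetic-tweezers traces as delimited text
#'
#' Traces are stored as tab-separated `time`, `force`, `extension`
#' (plus `bp_remaining` when zero-corrected) preceded by a commented header
#' block (`# key: value`) carrying the sampling rate, assay, seed and other
#' metadata. Writing is atomic.
#'
#' @param trace an `mt_trace`.
#' @param path file path.
#' @return `write_trace` returns the path invisibly; `read_trace` returns
#'   an `mt_trace` (without the generator truth, which is not serialised).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mt_trace"))
  md <- attr(trace, "metadata")
  hdr <- c(sprintf("# sampling_rate: %g", sampling_rate(trace)),
           sprintf("# assay: %s", attr(trace, "assay")),
           sprintf("# seed: %s", attr(trace, "seed")))
  for (k in names(md)) {
    v <- md[[k]]
    if (is.atomic(v) && length(v) <= 4)
      hdr <- c(hdr, sprintf("# %s: %s", k, paste(v, collapse = ",")))
  }
  atomic_write(function(tmp) {
    con <- file(tmp, "w")
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(
      as.data.frame(trace), con, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE))
    close(con)
  }, path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 100)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (l in hdr_lines) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) hdr[[trimws(m[2])]] <- trimws(m[3])
  }
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#"),
    error = function(e) stop("malformed trace file ", path, ": ",
                             conditionMessage(e)))
  need <- c("time", "force", "extension")
  if (!all(need %in% names(dat)))
    stop("trace file ", path, " lacks required columns: ",
         paste(setdiff(need, names(dat)), collapse = ", "))
  rate <- as.numeric(hdr$sampling_rate)
  if (!length(rate) || is.na(rate))
    rate <- 1 / stats::median(diff(dat$time))
  md <- hdr[setdiff(names(hdr), c("sampling_rate", "assay", "seed"))]
  out <- mt_trace(dat$time, dat$force, dat$extension, rate,
                  assay = if (is.null(hdr$assay)) "generic" else hdr$assay,
                  seed = if (is.null(hdr$seed)) NA_integer_
                         else suppressWarnings(as.integer(hdr$seed)),
                  metadata = md)
  if ("bp_remaining" %in% names(dat)) out$bp_remaining <- dat$bp_remaining
  out
}

#' Write a result table as tab-separated text (atomic)
#'
#' @param x a data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  atomic_write(function(tmp)
    utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE),
    path)
}

#' Write a hairpin construct stem as FASTA
#'
#' @param construct a [build_hairpin()] object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_construct_fasta <- function(construct, path) {
  stopifnot(inherits(construct, "hairpin_construct"))
  atomic_write(function(tmp)
    seqinr::write.fasta(strsplit(construct$stem_sequence, "")[[1]],
                        names = sprintf("%s_hairpin_stem_%dbp",
                                        construct$type,
                                        construct$stem_length),
                        file.out = tmp),
    path)
}
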