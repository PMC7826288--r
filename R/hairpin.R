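#' Telomeric hairpin constructs for strand-separation assays
#'
#' Builds the stem layout of the telomeric DNA hairpins used in mechanical
#' strand-separation assays. The long construct carries 23 TTAGGG repeats in
#' a 169-bp stem: an 18-bp random fork sequence, ten repeats, a TGG spacer,
#' ten more repeats, a CGTC spacer, three final repeats and a 6-bp filler
#' next to the 4-nt thymine loop. Positions are 1-based and counted from the
#' fork end in the unzipping direction, which places the first base of the
#' two spacers at bp 79 and bp 142. The short construct keeps the same
#' architecture with 13 repeats (ten + TGG + three).
#'
#' The fork random sequence and the loop-side filler are synthetic defaults
#' (the published layout fixes only the block structure and total length);
#' both can be overridden.
#'
#' @param type `"long"` (23 repeats) or `"short"` (13 repeats).
#' @param fork_random 18-bp random dsDNA at the fork end of the stem.
#' @param repeat_unit the telomeric repeat, `"TTAGGG"` on the G-rich strand.
#' @param block_repeats integer vector: repeats per telomeric block. Defaults
#'   to `c(10, 10, 3)` (long) or `c(10, 3)` (short).
#' @param spacers non-telomeric spacers inserted between telomeric blocks;
#'   must have one fewer element than `block_repeats`.
#' @param loop_filler filler between the last repeat and the loop.
#' @param loop hairpin loop nucleotides (not part of the stem).
#' @return an object of class `hairpin_construct` with the G-rich stem
#'   sequence (fork to loop), stem length, spacer coordinates and block
#'   table.
#' @examples
#' hp <- build_hairpin("long")
#' hp$stem_length        # 169
#' hp$spacer_positions   # 79, 142
#' @export
build_hairpin <- function(type = c("long", "short"),
                          fork_random = "GCTAGCATCGATACGGAT",
                          repeat_unit = "TTAGGG",
                          block_repeats = NULL,
                          spacers = NULL,
                          loop_filler = "GATCCA",
                          loop = "TTTT") {
  type <- match.arg(type)
  if (is.null(block_repeats))
    block_repeats <- if (type == "long") c(10L, 10L, 3L) else c(10L, 3L)
  if (is.null(spacers))
    spacers <- if (type == "long") c("TGG", "CGTC") else "TGG"
  if (any(block_repeats <= 0))
    stop("all telomeric blocks must contain at least one repeat")
  if (length(spacers) != length(block_repeats) - 1L)
    stop("need exactly one spacer between consecutive telomeric blocks")
  seqs <- c(fork_random, repeat_unit, spacers, loop_filler, loop)
  if (any(grepl("[^ACGT]", toupper(seqs))))
    stop("layout blocks must contain only A, C, G, T")

  blocks <- data.frame(block = "fork_random",
                       sequence = toupper(fork_random),
                       stringsAsFactors = FALSE)
  for (i in seq_along(block_repeats)) {
    blocks <- rbind(blocks, data.frame(
      block = sprintf("repeats_%d", i),
      sequence = strrep(toupper(repeat_unit), block_repeats[i])))
    if (i < length(block_repeats))
      blocks <- rbind(blocks, data.frame(
        block = sprintf("spacer_%d", i), sequence = toupper(spacers[i])))
  }
  blocks <- rbind(blocks, data.frame(block = "loop_filler",
                                     sequence = toupper(loop_filler)))
  widths <- nchar(blocks$sequence)
  blocks$start <- cumsum(c(1L, widths[-length(widths)]))
  blocks$end <- blocks$start + widths - 1L
  stem <- paste(blocks$sequence, collapse = "")

  sp <- blocks[grepl("^spacer_", blocks$block), , drop = FALSE]
  structure(list(
    type = type,
    stem_sequence = stem,
    stem_length = nchar(stem),
    repeat_unit = toupper(repeat_unit),
    n_repeats = sum(block_repeats),
    blocks = blocks,
    spacer_positions = sp$start,
    spacer_windows = sp[, c("start", "end"), drop = FALSE],
    loop = toupper(loop)
  ), class = "hairpin_construct")
}

#' @export
print.hairpin_construct <- function(x, ...) {
  cat(sprintf("telomeric hairpin (%s): stem %d bp, %d x %s repeats, loop %s\n",
              x$type, x$stem_length, x$n_repeats, x$repeat_unit, x$loop))
  if (length(x$spacer_positions))
    cat("  spacer first bases (from fork end):",
        paste(x$spacer_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Candidate dimer-binding sites on a hairpin stem
#'
#' A TRF1 dimer protects two adjacent TTAGGG motifs (a 12-bp footprint).
#' Returns the 1-based start positions (from the fork end) of every footprint
#' that fits entirely inside a single telomeric block, i.e. that avoids the
#' spacers and block boundaries.
#'
#' @param construct a [build_hairpin()] object.
#' @param footprint footprint length in bp (two repeat units).
#' @return integer vector of footprint start positions.
#' @export
telomeric_sites <- function(construct, footprint = 12L) {
  stopifnot(inherits(construct, "hairpin_construct"))
  unit <- nchar(construct$repeat_unit)
  blocks <- construct$blocks
  rep_blocks <- blocks[grepl("^repeats_", blocks$block), , drop = FALSE]
  out <- integer(0)
  for (i in seq_len(nrow(rep_blocks))) {
    starts <- seq(rep_blocks$start[i], rep_blocks$end[i] - footprint + 1L,
                  by = unit)
    starts <- starts[starts + footprint - 1L <= rep_blocks$end[i]]
    out <- c(out, starts)
  }
  out
}

#' Validate a set of bound dimer footprints on a construct
#'
#' Checks that footprints start at telomeric repeat boundaries, lie entirely
#' within telomeric blocks (spacers are non-binding by construction) and do
#' not overlap each other.
#'
#' @param construct a [build_hairpin()] object.
#' @param sites footprint start positions (bp from the fork end).
#' @param footprint footprint length in bp.
#' @return the sorted sites, invisibly; errors on violation.
#' @export
validate_dimer_sites <- function(construct, sites, footprint = 12L) {
  sites <- sort(as.integer(sites))
  ok <- telomeric_sites(construct, footprint)
  if (!all(sites %in% ok))
    stop("dimer footprint overlaps a spacer or block boundary: ",
         paste(setdiff(sites, ok), collapse = ", "))
  if (length(sites) > 1 && any(diff(sites) < footprint))
    stop("dimer footprints overlap each other")
  invisible(sites)
}
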