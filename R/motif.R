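#' @title PIP-Box motif scanning
#' @description The PIP Box is the eight-residue PCNA-docking motif
#'   Q-x-x-phi-x-x-Omega-Omega (phi hydrophobic, Omega aromatic, x any
#'   residue). Some binding partners carry it in reverse sequence
#'   orientation; a reverse hit is a window whose reversed sequence matches
#'   the forward pattern. Residue classes are configurable because reported
#'   screens differ in how loosely they read "hydrophobic" and "aromatic".
#' @name motif_scan
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.HYDROPHOBIC <- c("L", "I", "M", "V", "F")
.AROMATIC <- c("F", "Y", "W")

#' Compile a PIP-Box position-weight pattern
#'
#' Presets: `"strict"` is the canonical Q-x-x-phi-x-x-Omega-Omega with
#' phi = \{L,I,M,V,F\} and Omega = \{F,Y,W\}; `"relaxed"` drops the
#' position-7 aromatic (Q-x-x-phi-x-x-x-Omega), accommodating reported
#' partners with a non-aromatic residue there. Either class set can be
#' overridden, or a fully custom list of 8 allowed-residue sets supplied.
#'
#' @param preset `"strict"`, `"relaxed"`, or `"custom"`.
#' @param positions For `preset = "custom"`: list of 8 character vectors of
#'   allowed residues.
#' @param hydrophobic,aromatic Residue classes used by the presets.
#' @param name Pattern label (defaults to the preset).
#' @return An object of class `"motif_pattern"`: list with `name` and
#'   `positions` (length-8 list of allowed-residue sets).
#' @export
compile_pattern <- function(preset = c("strict", "relaxed", "custom"),
                            positions = NULL,
                            hydrophobic = .HYDROPHOBIC,
                            aromatic = .AROMATIC,
                            name = NULL) {
  preset <- match.arg(preset)
  any_aa <- .AA20
  if (preset == "custom") {
    if (is.null(positions)) stop("custom pattern needs `positions`", call. = FALSE)
  } else {
    positions <- list("Q", any_aa, any_aa, hydrophobic, any_aa, any_aa,
                      if (preset == "strict") aromatic else any_aa,
                      aromatic)
  }
  if (length(positions) != 8L)
    stop("a PIP-Box pattern has exactly 8 positions", call. = FALSE)
  positions <- lapply(positions, function(p) unique(toupper(p)))
  for (p in positions) {
    if (!length(p)) stop("empty allowed-residue set", call. = FALSE)
    if (!all(p %in% .AA20))
      stop("unknown residues in pattern: ",
           paste(setdiff(p, .AA20), collapse = ","), call. = FALSE)
  }
  structure(list(name = name %||% preset, positions = positions),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  desc <- vapply(x$positions, function(p)
    if (length(p) == length(.AA20)) "x" else paste0("[", paste(p, collapse = ""), "]"),
    character(1))
  cat(sprintf("PIP-Box pattern '%s': %s\n", x$name, paste(desc, collapse = "-")))
  invisible(x)
}

.window_matches <- function(chars, pattern) {
  for (k in 1:8) if (!(chars[k] %in% pattern$positions[[k]])) return(FALSE)
  TRUE
}

#' Scan one protein sequence for PIP-Box motifs
#'
#' Every overlapping 8-residue window is tested; in reverse orientation the
#' reversed window is matched against the forward pattern. Unknown characters
#' never match. Coordinates are 0-based half-open \[start, start+8).
#'
#' @param seq Amino-acid string (one-letter codes).
#' @param pattern A [compile_pattern()] result.
#' @param orientation `"forward"`, `"reverse"`, or `"both"`.
#' @param sequence_id Identifier copied into the hits.
#' @return data.frame with `sequence_id`, `start` (0-based), `end`
#'   (exclusive), `orientation`, `matched` (the substring as it appears in
#'   the sequence) and `pattern_name`; sorted by start then orientation.
#' @export
scan_sequence <- function(seq, pattern,
                          orientation = c("both", "forward", "reverse"),
                          sequence_id = "seq") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(pattern, "motif_pattern"), is.character(seq),
            length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  hits <- list()
  if (n >= 8) {
    for (s in seq_len(n - 7L)) {
      w <- chars[s:(s + 7L)]
      if (orientation %in% c("both", "forward") && .window_matches(w, pattern))
        hits[[length(hits) + 1L]] <- data.frame(
          sequence_id = sequence_id, start = s - 1L, end = s + 7L,
          orientation = "forward", matched = paste(w, collapse = ""),
          pattern_name = pattern$name, stringsAsFactors = FALSE)
      if (orientation %in% c("both", "reverse") && .window_matches(rev(w), pattern))
        hits[[length(hits) + 1L]] <- data.frame(
          sequence_id = sequence_id, start = s - 1L, end = s + 7L,
          orientation = "reverse", matched = paste(w, collapse = ""),
          pattern_name = pattern$name, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence_id = character(0), start = integer(0), end = integer(0),
               orientation = character(0), matched = character(0),
               pattern_name = character(0), stringsAsFactors = FALSE)
  out[order(out$start, out$orientation), , drop = FALSE]
}

#' Scan a FASTA file for PIP-Box motifs
#'
#' @param path FASTA file of protein sequences.
#' @param patterns A single pattern or list of [compile_pattern()] results.
#' @param orientation Passed to [scan_sequence()].
#' @return A hit table (one row per hit, deterministic ordering: file order,
#'   then start, then orientation, then pattern).
#' @export
scan_fasta <- function(path, patterns, orientation = "both") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected '>' header", nonblank[1]),
         call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  res <- list()
  for (i in seq_along(seqs)) {
    id <- sub("\\s.*$", "", names(seqs)[i])
    for (p in patterns) {
      h <- scan_sequence(as.character(seqs[[i]]), p, orientation,
                         sequence_id = id)
      if (nrow(h)) res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res))
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      matched = character(0), pattern_name = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a motif hit table as TSV
#'
#' Human-readable reports use 1-based inclusive coordinates alongside the
#' 0-based half-open API coordinates.
#'
#' @param hits A hit table from [scan_fasta()] or [scan_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  hits$start1 <- hits$start + 1L
  hits$end1 <- hits$end
  utils::write.table(hits[c("sequence_id", "start", "end", "start1", "end1",
                            "orientation", "matched", "pattern_name")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
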