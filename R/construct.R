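#' stallscope: translation at an unassigned stop codon
#'
#' Models a reporter transcript carrying an unassigned (orphan) UAG codon,
#' generates the theoretical search libraries for every translational outcome
#' at the stall, and infers the event(s) behind observed C-terminal peptides.
#'
#' @keywords internal
"_PACKAGE"

## ssrA degradation tag variants (wild-type AA; protease-resistant DD mutant)
SSRA_TAGS <- c(AA = "AANDENYALAA", DD = "AANDENYALDD")

CANONICAL_AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V")

#' Reporter construct with an unassigned codon
#'
#' A reporter coding sequence (DNA, 5'->3', frame 0 at index 0) whose
#' translation stalls at an orphan codon that is decoded by neither a tRNA
#' nor a release factor. Offsets are 0-based nucleotide indices; the
#' "bases skipped" convention used throughout reports a resume position
#' `r` as `s = r - stall_offset`, so suppression at the orphan codon is
#' s = 0, in-frame readthrough past it is s = +3 and a backward slip
#' re-reading the codon before the stall is s = -3.
#'
#' @param coding_sequence DNA string (A/C/G/T only; ambiguity codes rejected).
#' @param stall_offset 0-based index of the first base of the orphan codon;
#'   must be a multiple of 3.
#' @param name construct label.
#' @param orphan_codon the unassigned codon (default "TAG").
#' @param tag_variant ssrA degradation-tag variant appended by tmRNA rescue:
#'   "AA" (wild type) or "DD" (degradation-resistant mutant).
#' @param anchor_peptide residues immediately upstream of the stall in frame
#'   0; validated against the translated sequence when given.
#' @return An object of class `reporter_construct`.
#' @export
reporter_construct <- function(coding_sequence, stall_offset,
                               name = "construct",
                               orphan_codon = "TAG",
                               tag_variant = c("DD", "AA"),
                               anchor_peptide = NULL) {
  tag_variant <- match.arg(tag_variant)
  coding_sequence <- toupper(coding_sequence)
  if (grepl("[^ACGT]", coding_sequence))
    stop("coding_sequence must use the unambiguous DNA alphabet (A/C/G/T)")
  if (nchar(orphan_codon) != 3L)
    stop("orphan_codon must be a 3-nt codon")
  if (stall_offset < 0 || stall_offset %% 3L != 0L)
    stop("stall_offset must be a non-negative multiple of 3 (frame 0)")
  if (stall_offset + 3L > nchar(coding_sequence))
    stop("stall_offset out of range")
  if (substr(coding_sequence, stall_offset + 1L, stall_offset + 3L) != orphan_codon)
    stop("codon at stall_offset is not the orphan codon '", orphan_codon, "'")
  tail_length <- nchar(coding_sequence) - stall_offset - 3L

  x <- structure(list(
    name = name,
    coding_sequence = coding_sequence,
    stall_offset = as.integer(stall_offset),
    orphan_codon = orphan_codon,
    tail_length = as.integer(tail_length),
    tag_variant = tag_variant,
    anchor_peptide = anchor_peptide
  ), class = "reporter_construct")

  if (!is.null(anchor_peptide) && nzchar(anchor_peptide)) {
    pre <- pre_stall_protein(x)
    if (nchar(pre) < nchar(anchor_peptide) ||
        substring(pre, nchar(pre) - nchar(anchor_peptide) + 1L) != anchor_peptide)
      stop("frame-0 translation upstream of the stall does not end with the ",
           "anchor peptide '", anchor_peptide, "'")
  }
  x
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("Reporter construct '", x$name, "': ", nchar(x$coding_sequence),
      " nt, orphan ", x$orphan_codon, " at nt ", x$stall_offset,
      ", ", x$tail_length, " nt downstream tail, ssrA tag variant ",
      x$tag_variant, "\n", sep = "")
  if (!is.null(x$anchor_peptide))
    cat("  anchor peptide: ", x$anchor_peptide, "\n", sep = "")
  invisible(x)
}

#' Load a reporter construct from FASTA plus a config
#'
#' @param fasta_path single-record DNA FASTA.
#' @param config either a YAML file path or a list with elements
#'   `stall_offset`, and optionally `name`, `orphan_codon`, `tag_variant`,
#'   `anchor_peptide`.
#' @return a `reporter_construct`.
#' @export
load_construct <- function(fasta_path, config) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("expected a single-record FASTA, found ", length(seqs), " records")
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$stall_offset))
    stop("config must name stall_offset")
  reporter_construct(
    coding_sequence = as.character(seqs[[1L]]),
    stall_offset = config$stall_offset,
    name = if (!is.null(config$name)) config$name else names(seqs)[1L],
    orphan_codon = if (!is.null(config$orphan_codon)) config$orphan_codon else "TAG",
    tag_variant = if (!is.null(config$tag_variant)) config$tag_variant else "DD",
    anchor_peptide = config$anchor_peptide
  )
}

## decode one codon at a 0-based offset; "*" for a stop, "X" never returned.
## Returns NA beyond the sequence end.
decode_codon <- function(seq, offset) {
  if (offset < 0L || offset + 3L > nchar(seq)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[[substr(seq, offset + 1L, offset + 3L)]])
}

#' Translate from an arbitrary nucleotide offset
#'
#' Decodes successive codons with the standard genetic code starting at
#' `start_offset`. UAA/UGA always terminate. The orphan codon (UAG by
#' default) is never decoded: when `orphan_is_stop` is TRUE it terminates
#' like an ordinary stop; when FALSE it still halts translation -- the
#' ribosome stalls there -- but the terminator is recorded as the orphan,
#' which is how the search libraries treat "the next non-UAG stop codon".
#'
#' @param construct a `reporter_construct`.
#' @param start_offset 0-based nt index (any frame).
#' @param max_residues cap on the number of residues decoded.
#' @param orphan_is_stop treat the orphan codon as an assigned stop.
#' @return list with `start_offset`, `residues`, `terminator` (one of
#'   "stop_codon", "length_cap", "sequence_end"), `stop_offset` (NA unless a
#'   stop/orphan terminated translation) and `stop_is_orphan`.
#' @export
translate_from <- function(construct, start_offset, max_residues = Inf,
                           orphan_is_stop = FALSE) {
  seq <- construct$coding_sequence
  if (start_offset < 0L || start_offset > nchar(seq) - 3L)
    stop("start_offset out of range")
  res <- character(0)
  o <- as.integer(start_offset)
  terminator <- "sequence_end"
  stop_offset <- NA_integer_
  stop_is_orphan <- FALSE
  repeat {
    if (length(res) >= max_residues) { terminator <- "length_cap"; break }
    cd <- if (o + 3L <= nchar(seq)) substr(seq, o + 1L, o + 3L) else ""
    if (nchar(cd) < 3L) { terminator <- "sequence_end"; break }
    if (cd == construct$orphan_codon) {
      terminator <- "stop_codon"; stop_offset <- o; stop_is_orphan <- !orphan_is_stop
      break
    }
    aa <- Biostrings::GENETIC_CODE[[cd]]
    if (aa == "*") { terminator <- "stop_codon"; stop_offset <- o; break }
    res <- c(res, aa)
    o <- o + 3L
  }
  list(start_offset = as.integer(start_offset),
       residues = paste(res, collapse = ""),
       terminator = terminator,
       stop_offset = stop_offset,
       stop_is_orphan = stop_is_orphan)
}

#' Frame-0 protein upstream of the stall
#'
#' @param construct a `reporter_construct`.
#' @return residue string for codons `[0, stall_offset)`.
#' @export
pre_stall_protein <- function(construct) {
  n <- construct$stall_offset %/% 3L
  if (n == 0L) return("")
  tr <- translate_from(construct, 0L, max_residues = n, orphan_is_stop = TRUE)
  if (nchar(tr$residues) != n)
    stop("frame-0 reading upstream of the stall contains a stop codon")
  tr$residues
}

#' Stop-codon landscape of the downstream tail
#'
#' All stop codons (UAA, UGA, and the orphan UAG flagged separately) in each
#' of the three reading-frame classes of the tail, sorted by offset. Offsets
#' are reported both absolutely and in the bases-skipped (s) convention.
#'
#' @param construct a `reporter_construct`.
#' @return data.frame with columns `frame` (0/1/2, `(offset - stall) mod 3`),
#'   `stop_offset` (absolute nt), `s` (relative to the stall), `codon`,
#'   `is_orphan`.
#' @export
stop_landscape <- function(construct) {
  seq <- construct$coding_sequence
  stall <- construct$stall_offset
  offs <- seq_len(nchar(seq)) - 1L
  offs <- offs[offs > stall & offs + 3L <= nchar(seq)]
  if (length(offs) == 0L)
    return(data.frame(frame = integer(0), stop_offset = integer(0),
                      s = integer(0), codon = character(0),
                      is_orphan = logical(0)))
  codons <- substring(seq, offs + 1L, offs + 3L)
  keep <- codons %in% c("TAA", "TGA", "TAG")
  offs <- offs[keep]; codons <- codons[keep]
  data.frame(frame = (offs - stall) %% 3L,
             stop_offset = offs,
             s = offs - stall,
             codon = codons,
             is_orphan = codons == construct$orphan_codon,
             row.names = NULL)
}
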