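#' Trypsin digestion rules
#'
#' Cleavage C-terminal to K/R, suppressed before proline, with a miscleavage
#' allowance and a minimum peptide length, matching the search-engine
#' settings used for the proteomic analysis (>= 5 residues, up to 3
#' miscleavages).
#'
#' @param max_miscleavages maximum uncut internal K/R sites per peptide.
#' @param min_length minimum peptide length in residues.
#' @param cleave_after residues cleaved after (default K, R).
#' @param no_cleave_before residues blocking cleavage when next (default P).
#' @return an object of class `trypsin_spec`.
#' @export
trypsin_spec <- function(max_miscleavages = 3L, min_length = 5L,
                         cleave_after = c("K", "R"),
                         no_cleave_before = "P") {
  stopifnot(max_miscleavages >= 0L, min_length >= 1L)
  structure(list(max_miscleavages = as.integer(max_miscleavages),
                 min_length = as.integer(min_length),
                 cleave_after = cleave_after,
                 no_cleave_before = no_cleave_before),
            class = "trypsin_spec")
}

#' Search-library configuration
#'
#' @param max_tail_residues cap on decoded tail length per entry (default 38
#'   residues downstream of the resume point).
#' @param resume_window integer nt interval of resume offsets `s` considered,
#'   relative to the stall (default -9..+45; must cover the observed -6..+19).
#' @param max_tag_truncation maximum number of decoded tail residues before
#'   an appended ssrA tag.
#' @param combinatorial_anchor anchor for the separate combinatorial library.
#' @param combinatorial_positions number of free positions `X` in the
#'   combinatorial anchor+X^k library.
#' @return a list of class `library_config`.
#' @export
library_config <- function(max_tail_residues = 38L,
                           resume_window = c(-9L, 45L),
                           max_tag_truncation = 12L,
                           combinatorial_anchor = "LEHHHHHH",
                           combinatorial_positions = 3L) {
  stopifnot(max_tail_residues >= 1L, length(resume_window) == 2L,
            resume_window[1L] <= resume_window[2L],
            max_tag_truncation >= 0L, combinatorial_positions >= 1L)
  if (resume_window[1L] > -6L || resume_window[2L] < 19L)
    warning("resume_window does not cover the observed -6..+19 nt range")
  structure(list(max_tail_residues = as.integer(max_tail_residues),
                 resume_window = as.integer(resume_window),
                 max_tag_truncation = as.integer(max_tag_truncation),
                 combinatorial_anchor = combinatorial_anchor,
                 combinatorial_positions = as.integer(combinatorial_positions)),
            class = "library_config")
}

library_entry <- function(sequence, product, category, construct_name,
                          suppressed_residue = NA_character_,
                          resume_offset = NA_integer_,
                          truncation = NA_integer_,
                          tag_variant = NA_character_) {
  data.frame(sequence = sequence, product = product, category = category,
             suppressed_residue = suppressed_residue,
             resume_offset = resume_offset, truncation = truncation,
             tag_variant = tag_variant, construct_name = construct_name,
             stringsAsFactors = FALSE)
}

#' Suppression library: one entry per canonical residue at the orphan codon
#'
#' Each entry is the full frame-0 product with one canonical amino acid
#' decoded at the orphan codon and translation continuing in frame to the
#' next stop codon or the tail cap, so tryptic digestion yields correctly
#' anchored peptides such as LEHHHHHH-Q-GAR.
#'
#' @param construct a `reporter_construct`.
#' @param cfg a `library_config`.
#' @return data.frame of 20 library entries.
#' @export
suppression_variants <- function(construct, cfg = library_config()) {
  pre <- pre_stall_protein(construct)
  cont <- translate_from(construct, construct$stall_offset + 3L,
                         max_residues = cfg$max_tail_residues,
                         orphan_is_stop = FALSE)$residues
  do.call(rbind, lapply(CANONICAL_AA, function(aa) {
    seqs <- paste0(pre, aa, cont)
    library_entry(seqs, seqs, "suppression", construct$name,
                  suppressed_residue = aa)
  }))
}

#' C-tail library: one entry per resume offset
#'
#' For every nucleotide resume offset `s` in the window, the tail decoded
#' from `stall_offset + s` to the next non-orphan stop codon (any in-tail
#' UAG stalls translation again and also ends the entry) or to the residue
#' cap. `sequence` is the free C-tail fragment as listed in the search
#' library; `product` places the same tail in its translated context
#' (upstream protein + anchor + tail) so that digestion also yields the
#' anchored junction peptides observed by mass spectrometry.
#'
#' @inheritParams suppression_variants
#' @return data.frame of library entries (empty decodes dropped).
#' @export
tail_library <- function(construct, cfg = library_config()) {
  stall <- construct$stall_offset
  pre <- pre_stall_protein(construct)
  window <- seq(cfg$resume_window[1L], cfg$resume_window[2L])
  window <- window[stall + window >= 0L &
                     stall + window + 3L <= nchar(construct$coding_sequence)]
  if (length(window) == 0L) stop("resume window is empty after clipping")
  rows <- lapply(window, function(s) {
    tail_seq <- translate_from(construct, stall + s,
                               max_residues = cfg$max_tail_residues,
                               orphan_is_stop = FALSE)$residues
    if (nchar(tail_seq) < 1L) return(NULL)
    library_entry(tail_seq, paste0(pre, tail_seq), "tail", construct$name,
                  resume_offset = s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no tail entries: every resume offset decodes nothing")
  out
}

#' ssrA-tagged library: anchor + decoded tail residues + degradation tag
#'
#' tmRNA rescue appends the full ssrA tag to whatever the ribosome has
#' synthesised when rescued. Entries cover tagging directly at the stall
#' (t = 0, one entry) and after decoding t = 1..max_tag_truncation tail
#' residues at each resume offset.
#'
#' @inheritParams suppression_variants
#' @return data.frame of library entries, deduplicated by sequence.
#' @export
tagged_variants <- function(construct, cfg = library_config()) {
  stall <- construct$stall_offset
  pre <- pre_stall_protein(construct)
  tag <- SSRA_TAGS[[construct$tag_variant]]
  rows <- list(library_entry(paste0(pre, tag), paste0(pre, tag), "tagged",
                             construct$name, resume_offset = 0L,
                             truncation = 0L,
                             tag_variant = construct$tag_variant))
  if (cfg$max_tag_truncation >= 1L) {
    window <- seq(cfg$resume_window[1L], cfg$resume_window[2L])
    window <- window[stall + window >= 0L &
                       stall + window + 3L <= nchar(construct$coding_sequence)]
    for (s in window) {
      tail_seq <- translate_from(construct, stall + s,
                                 max_residues = cfg$max_tag_truncation,
                                 orphan_is_stop = FALSE)$residues
      if (nchar(tail_seq) < 1L) next
      for (t in seq_len(nchar(tail_seq))) {
        seqs <- paste0(pre, substr(tail_seq, 1L, t), tag)
        rows[[length(rows) + 1L]] <-
          library_entry(seqs, seqs, "tagged", construct$name,
                        resume_offset = s, truncation = t,
                        tag_variant = construct$tag_variant)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$sequence), , drop = FALSE]
}

#' Combinatorial anchor+X^k library
#'
#' All anchor + X1..Xk sequences over the 20 canonical residues, kept as a
#' separate library from the mechanistic one, used to detect peptides that
#' no single reading of the transcript can produce.
#'
#' @param cfg a `library_config`.
#' @return data.frame of `20^k` unique entries.
#' @export
combinatorial_library <- function(cfg = library_config()) {
  k <- cfg$combinatorial_positions
  grids <- rev(expand.grid(rep(list(CANONICAL_AA), k),
                           stringsAsFactors = FALSE))
  xs <- do.call(paste0, grids)
  seqs <- sort(paste0(cfg$combinatorial_anchor, xs))
  library_entry(seqs, seqs, "combinatorial", cfg$combinatorial_anchor)
}

## cleavage positions: cut after index i (1-based) when residue i is K/R and
## residue i+1 is not P
cleavage_sites <- function(residues, spec) {
  n <- length(residues)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  i[residues[i] %in% spec$cleave_after &
      !(residues[i + 1L] %in% spec$no_cleave_before)]
}

digest_one <- function(protein, spec) {
  residues <- strsplit(protein, "")[[1L]]
  cuts <- c(0L, cleavage_sites(residues, spec), length(residues))
  cuts <- unique(cuts)
  nfrag <- length(cuts) - 1L
  if (nfrag < 1L) return(character(0))
  peps <- character(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + spec$max_miscleavages)
    for (j in i:jmax) {
      len <- cuts[j + 1L] - cuts[i]
      if (len >= spec$min_length)
        peps <- c(peps, substr(protein, cuts[i] + 1L, cuts[j + 1L]))
    }
  }
  peps
}

#' Tryptic digest of library entries
#'
#' Cleaves after K/R except before P, emitting every peptide that spans at
#' most `max_miscleavages` internal cleavage sites and has at least
#' `min_length` residues; deduplicates by sequence, merging parent entries.
#' C-tail entries are digested both as the free fragment and in their
#' anchored product context.
#'
#' @param entries a library data.frame (from the `*_variants` / `*_library`
#'   builders, possibly rbind-ed) or a character vector of proteins.
#' @param spec a `trypsin_spec`.
#' @return data.frame with columns `peptide`, `n_parents`, `parents`
#'   (collapsed `category:row` references).
#' @export
digest <- function(entries, spec = trypsin_spec()) {
  if (is.character(entries))
    entries <- library_entry(entries, entries, "protein",
                             construct_name = "input")
  prot <- unique(data.frame(
    protein = c(entries$sequence, entries$product),
    parent = rep(paste0(entries$category, ":", seq_len(nrow(entries))), 2L),
    stringsAsFactors = FALSE))
  hits <- lapply(seq_len(nrow(prot)), function(i) {
    peps <- digest_one(prot$protein[i], spec)
    if (length(peps) == 0L) return(NULL)
    data.frame(peptide = unique(peps), parent = prot$parent[i],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(peptide = character(0), n_parents = integer(0),
                      parents = character(0)))
  agg <- stats::aggregate(parent ~ peptide, data = hits,
                          FUN = function(p) paste(sort(unique(p)),
                                                  collapse = ";"))
  agg$n_parents <- lengths(strsplit(agg$parents <- agg$parent, ";"))
  agg$parent <- NULL
  agg <- agg[order(agg$peptide), c("peptide", "n_parents", "parents")]
  rownames(agg) <- NULL
  agg
}

#' Write a search library to FASTA
#'
#' Headers encode category and provenance; records are ordered
#' deterministically by (category, resume offset, sequence) so identical
#' inputs give byte-identical files.
#'
#' @param entries library data.frame.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_library <- function(entries, path) {
  if (nrow(entries) == 0L) stop("refusing to write an empty library")
  ord <- order(entries$category,
               ifelse(is.na(entries$resume_offset), -999L,
                      entries$resume_offset),
               entries$sequence)
  entries <- entries[ord, , drop = FALSE]
  hdr <- sprintf("%s|%s|s=%s|t=%s|aa=%s|tag=%s",
                 entries$category, entries$construct_name,
                 ifelse(is.na(entries$resume_offset), ".",
                        entries$resume_offset),
                 ifelse(is.na(entries$truncation), ".", entries$truncation),
                 ifelse(is.na(entries$suppressed_residue), ".",
                        entries$suppressed_residue),
                 ifelse(is.na(entries$tag_variant), ".", entries$tag_variant))
  aa <- Biostrings::AAStringSet(entries$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Build the two search libraries of the study
#'
#' The mechanistic library (the unmodified release product, suppression,
#' C-tail and ssrA-tagged entries) and the separate combinatorial
#' anchor+XXX library. The release product (translation released at the
#' stall without modification, as by ArfA/ArfB) is included so the bare
#' anchor C-terminus is itself searchable.
#'
#' @inheritParams suppression_variants
#' @return list with data.frames `main` and `combinatorial`.
#' @export
build_search_libraries <- function(construct, cfg = library_config()) {
  pre <- pre_stall_protein(construct)
  list(main = rbind(library_entry(pre, pre, "release", construct$name),
                    suppression_variants(construct, cfg),
                    tail_library(construct, cfg),
                    tagged_variants(construct, cfg)),
       combinatorial = combinatorial_library(cfg))
}
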