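#' Event-inference configuration
#'
#' @param resume_window integer nt interval (relative to the stall) in which
#'   a frameshifted ribosome may resume decoding.
#' @param event_budget junction budget. `NULL` (default) returns every
#'   explanation with at most one junction more than the minimal count, so
#'   near-minimal alternatives (a -6 slip versus two -3 slips) are surfaced;
#'   a number fixes the cap outright.
#' @param junction_cap hard search bound used to decide a peptide is
#'   unexplainable when `event_budget` is NULL.
#' @param min_tag_match minimum number of C-terminal ssrA-tag residues
#'   required to call a tag match.
#' @param allow_unanchored also map peptides that do not start with a suffix
#'   of the frame-0 pre-stall product; such peptides must lie entirely in
#'   the tail region (mRNA start at or after stall - 9 nt).
#' @return a list of class `inference_config`.
#' @export
inference_config <- function(resume_window = c(-9L, 45L),
                             event_budget = NULL,
                             junction_cap = 3L,
                             min_tag_match = 3L,
                             allow_unanchored = TRUE) {
  stopifnot(length(resume_window) == 2L, resume_window[1L] <= resume_window[2L],
            is.null(event_budget) || event_budget >= 0L,
            junction_cap >= 0L, min_tag_match >= 1L)
  structure(list(resume_window = as.integer(resume_window),
                 event_budget = if (is.null(event_budget)) NULL
                                else as.integer(event_budget),
                 junction_cap = as.integer(junction_cap),
                 min_tag_match = as.integer(min_tag_match),
                 allow_unanchored = isTRUE(allow_unanchored)),
            class = "inference_config")
}

## decode a codon into a residue, "stop", "orphan" or NA (out of sequence)
decode_at <- function(construct, offset) {
  seq <- construct$coding_sequence
  if (offset < 0L || offset + 3L > nchar(seq)) return(NA_character_)
  cd <- substr(seq, offset + 1L, offset + 3L)
  if (cd == construct$orphan_codon) return("orphan")
  aa <- unname(Biostrings::GENETIC_CODE[[cd]])
  if (aa == "*") "stop" else aa
}

## can translation legitimately end here (no tag)? Either the next codon
## terminates/stalls (true protein C-terminus), the sequence ends, or the
## peptide ends at a tryptic site (internal peptide of a longer product).
valid_terminus <- function(construct, last_residue, pos) {
  nxt <- decode_at(construct, pos)
  is.na(nxt) || nxt %in% c("stop", "orphan") ||
    (last_residue %in% c("K", "R") && nxt != "P")
}

#' Explain an observed peptide as translational events on the construct
#'
#' Exhaustively searches for ways the peptide can be produced from the
#' transcript: an anchor (the longest suffix of the frame-0 pre-stall
#' product that prefixes the peptide), at most one suppressed residue
#' decoded exactly at the orphan codon, mRNA segments decoded with the
#' standard code separated by frameshift junctions (resume offsets bounded
#' by the resume window), and an optional C-terminal ssrA-tag suffix.
#' A junction-free reading must also terminate plausibly: at a stop codon,
#' at the orphan (stall then rescue/release), at the sequence end, or at a
#' tryptic K/R boundary not followed by proline.
#'
#' Explanations are returned sorted by (number of junctions, number of
#' suppression events, absolute net shift), so the most parsimonious
#' mechanistic reading comes first; with the default budget every
#' explanation with at most minimal+1 junctions is reported.
#'
#' @param peptide residue string (canonical amino acids).
#' @param construct a `reporter_construct`.
#' @param cfg an `inference_config`.
#' @return list of explanations, each a list with `anchored`, `anchor_len`,
#'   `suppressed_residue`, `segments` (data.frame: `pep_start`, `length`,
#'   `mrna_start`, `s`), `junctions` (data.frame: `delta_nt`, `resume_s`),
#'   `tag_variant`, `tag_len`, `n_junctions`, `n_events`, `net_shift`,
#'   `extent` (3'-most decoded nt, s convention). Empty list when nothing
#'   within budget explains the peptide.
#' @export
explain <- function(peptide, construct, cfg = inference_config()) {
  res <- strsplit(peptide, "")[[1L]]
  n <- length(res)
  if (n == 0L) stop("peptide is empty")
  if (!all(res %in% CANONICAL_AA))
    stop("non-canonical residue in peptide: ",
         paste(setdiff(res, CANONICAL_AA), collapse = ","))
  stall <- construct$stall_offset
  seqlen <- nchar(construct$coding_sequence)
  cap <- if (!is.null(cfg$event_budget)) cfg$event_budget else cfg$junction_cap

  window_abs <- stall + seq(cfg$resume_window[1L], cfg$resume_window[2L])
  window_abs <- window_abs[window_abs >= 0L & window_abs + 3L <= seqlen]

  acc <- new.env(parent = emptyenv())
  acc$sol <- list()

  ## one tag-stripped sub-problem per admissible tag-suffix length
  tag <- SSRA_TAGS[[construct$tag_variant]]
  tag_lens <- 0L
  for (m in seq(cfg$min_tag_match, min(nchar(tag), n))) {
    if (substring(peptide, n - m + 1L) ==
        substring(tag, nchar(tag) - m + 1L))
      tag_lens <- c(tag_lens, m)
  }

  emit <- function(state, tag_len) {
    segs <- state$segs
    if (!is.null(state$cur)) segs <- c(segs, list(state$cur))
    acc$sol[[length(acc$sol) + 1L]] <- list(
      anchor_len = state$anchor_len,
      supp = state$supp,
      supp_seg = state$supp_seg,
      segments = segs,
      junctions = state$junc,
      tag_len = tag_len)
  }

  ## state: idx (next residue 1-based within the tag-stripped peptide),
  ## pos (offset of the next codon), cur = c(start, len) open segment
  dfs <- function(state, nn, rr, tag_len) {
    if (state$idx > nn) {
      ok <- tag_len > 0L ||
        valid_terminus(construct,
                       if (nn >= 1L) rr[nn] else "", state$pos)
      if (ok) emit(state, tag_len)
      return(invisible())
    }
    a <- decode_at(construct, state$pos)
    want <- rr[state$idx]
    ## continue in frame
    if (!is.na(a) && a == want) {
      st <- state
      st$idx <- state$idx + 1L
      st$pos <- state$pos + 3L
      st$cur <- if (is.null(state$cur)) c(state$pos, 1L)
                else c(state$cur[1L], state$cur[2L] + 1L)
      dfs(st, nn, rr, tag_len)
    }
    ## near-cognate suppression, exactly at the stall
    if (identical(a, "orphan") && state$pos == stall && is.na(state$supp)) {
      st <- state
      st$idx <- state$idx + 1L
      st$pos <- state$pos + 3L
      st$supp <- want
      ## the suppressed residue is not segment-decoded: close any open
      ## segment; frame-0 decoding resumes after the orphan codon
      st$segs <- if (is.null(state$cur)) state$segs
                 else c(state$segs, list(state$cur))
      st$cur <- NULL
      st$supp_seg <- length(st$segs)
      dfs(st, nn, rr, tag_len)
    }
    ## frameshift junction to any in-window resume offset
    if (state$n_junc < cap) {
      for (o in window_abs) {
        if (o == state$pos) next
        if (!identical(decode_at(construct, o), want)) next
        st <- state
        st$idx <- state$idx + 1L
        st$n_junc <- state$n_junc + 1L
        st$junc <- c(state$junc,
                     list(c(delta = o - state$pos, resume_s = o - stall)))
        st$segs <- if (is.null(state$cur)) state$segs
                   else c(state$segs, list(state$cur))
        st$cur <- c(o, 1L)
        st$pos <- o + 3L
        dfs(st, nn, rr, tag_len)
      }
    }
  }

  pre <- pre_stall_protein(construct)
  for (tag_len in tag_lens) {
    nn <- n - tag_len
    if (nn < 1L) next    # a bare tag carries no translated evidence
    rr <- res[seq_len(nn)]
    sub <- substr(peptide, 1L, nn)
    ## anchored: longest suffix of the pre-stall product prefixing the peptide
    lmax <- 0L
    for (l in seq(min(nn, nchar(pre)), 1L)) {
      if (substring(pre, nchar(pre) - l + 1L) == substr(sub, 1L, l)) {
        lmax <- l
        break
      }
    }
    if (lmax >= 1L) {
      st <- list(idx = lmax + 1L, pos = stall, anchor_len = lmax,
                 supp = NA_character_, supp_seg = NA_integer_,
                 segs = list(), cur = NULL, junc = list(), n_junc = 0L)
      dfs(st, nn, rr, tag_len)
    }
    ## unanchored: tryptic fragment mapped entirely within the tail region
    if (cfg$allow_unanchored && lmax == 0L) {
      starts <- seq(max(0L, stall - 9L), seqlen - 3L)
      for (o in starts) {
        if (!identical(decode_at(construct, o), rr[1L])) next
        st <- list(idx = 2L, pos = o + 3L, anchor_len = 0L,
                   supp = NA_character_, supp_seg = NA_integer_,
                   segs = list(), cur = c(o, 1L), junc = list(),
                   n_junc = 0L)
        dfs(st, nn, rr, tag_len)
      }
    }
  }

  if (length(acc$sol) == 0L) return(list())
  out <- lapply(acc$sol, function(s) {
    nj <- length(s$junctions)
    segs <- if (length(s$segments))
      data.frame(pep_start = NA_integer_,
                 length = vapply(s$segments, `[`, integer(1L), 2L),
                 mrna_start = vapply(s$segments, `[`, integer(1L), 1L))
    else data.frame(pep_start = integer(0), length = integer(0),
                    mrna_start = integer(0))
    if (nrow(segs)) {
      idx <- s$anchor_len
      starts <- integer(nrow(segs))
      for (i in seq_len(nrow(segs))) {
        if (!is.na(s$supp) && isTRUE(s$supp_seg == i - 1L)) idx <- idx + 1L
        starts[i] <- idx + 1L
        idx <- idx + segs$length[i]
      }
      segs$pep_start <- starts
      segs$s <- segs$mrna_start - stall
    } else segs$s <- integer(0)
    junc <- if (nj) data.frame(
      delta_nt = vapply(s$junctions, `[[`, numeric(1L), "delta"),
      resume_s = vapply(s$junctions, `[[`, numeric(1L), "resume_s"))
    else data.frame(delta_nt = numeric(0), resume_s = numeric(0))
    net <- if (s$anchor_len >= 1L && nj == 1L) junc$resume_s[1L]
           else if (s$anchor_len >= 1L && nj == 0L && !is.na(s$supp)) 0
           else NA_real_
    extent <- 0
    if (!is.na(s$supp)) extent <- 3
    if (nrow(segs)) extent <- max(extent, segs$s + 3 * segs$length)
    if (s$anchor_len == 0L && nrow(segs) == 0L) extent <- NA_real_
    list(anchored = s$anchor_len >= 1L,
         anchor_len = s$anchor_len,
         suppressed_residue = s$supp,
         segments = segs,
         junctions = junc,
         tag_variant = if (s$tag_len > 0L) construct$tag_variant
                       else NA_character_,
         tag_len = s$tag_len,
         n_junctions = nj,
         n_events = nj,
         net_shift = net,
         extent = extent)
  })
  minimal <- min(vapply(out, `[[`, integer(1L), "n_junctions"))
  keep_cap <- if (is.null(cfg$event_budget)) minimal + 1L else cfg$event_budget
  out <- Filter(function(e) e$n_junctions <= keep_cap, out)
  key <- vapply(out, function(e)
    paste(e$anchor_len, e$suppressed_residue, e$tag_len,
          paste(e$segments$mrna_start, e$segments$length, collapse = ","),
          sep = "|"), character(1L))
  ord <- order(vapply(out, `[[`, integer(1L), "n_junctions"),
               !is.na(vapply(out, `[[`, character(1L), "suppressed_residue")),
               abs(vapply(out, function(e)
                 ifelse(is.na(e$net_shift), Inf, e$net_shift), numeric(1L))),
               key)
  out[ord]
}

#' Classify a peptide by its minimal-event explanations
#'
#' @param peptide the observed residue string.
#' @param explanations output of [explain()] for the same peptide/construct.
#' @return one of "termination_or_release" (the unmodified anchor product),
#'   "suppression" (junction-free, tag-free explanation with a residue
#'   decoded at the orphan codon), "tagged" (any explanation carries an
#'   ssrA-tag match), "frameshift" (minimal explanation uses one junction,
#'   or the peptide is a junction-free unanchored tail fragment -- the
#'   frameshift then lies upstream of its tryptic boundary),
#'   "fidelity_loss_candidate" (no explanation below two junctions), or
#'   "unexplained".
#' @export
classify <- function(peptide, explanations) {
  if (length(explanations) == 0L) return("unexplained")
  nj <- vapply(explanations, `[[`, integer(1L), "n_junctions")
  supp <- !is.na(vapply(explanations, `[[`, character(1L),
                        "suppressed_residue"))
  tagged <- vapply(explanations, `[[`, integer(1L), "tag_len") > 0L
  anchored <- vapply(explanations, `[[`, logical(1L), "anchored")
  plain_anchor <- vapply(explanations, function(e)
    e$anchored && nrow(e$segments) == 0L && is.na(e$suppressed_residue) &&
      e$tag_len == 0L, logical(1L))
  if (any(plain_anchor)) return("termination_or_release")
  if (any(nj == 0L & supp & !tagged)) return("suppression")
  if (any(tagged)) return("tagged")
  if (min(nj) == 1L) return("frameshift")
  if (min(nj) == 0L && all(!anchored[nj == 0L])) return("frameshift")
  "fidelity_loss_candidate"
}

#' Summarize an identification table against the construct
#'
#' Filters identifications by score, explains and classifies each unique
#' peptide, and aggregates counts per category and per net frameshift
#' offset, together with the maximum downstream decoded extent (the 3'-most
#' decoded nucleotide past the stall over all explanations).
#'
#' @param identifications data.frame with columns `sequence`, `score` (and
#'   optionally `sample`).
#' @param construct a `reporter_construct`.
#' @param cfg an `inference_config`.
#' @param score_threshold minimum identification score retained (default 15,
#'   the study's manual-validation threshold).
#' @return list of class `stall_summary`: `peptides` (per-peptide table),
#'   `by_category`, `by_offset`, `max_downstream_extent`, `n_filtered`.
#' @export
summarize_identifications <- function(identifications, construct,
                                      cfg = inference_config(),
                                      score_threshold = 15) {
  stopifnot(all(c("sequence", "score") %in% names(identifications)))
  if (nrow(identifications) == 0L) stop("empty identification table")
  keep <- identifications$score >= score_threshold
  ids <- identifications[keep, , drop = FALSE]
  uniq <- unique(ids$sequence)
  rows <- lapply(uniq, function(p) {
    ex <- explain(p, construct, cfg)
    cat_ <- classify(p, ex)
    nj <- if (length(ex)) min(vapply(ex, `[[`, integer(1L), "n_junctions"))
          else NA_integer_
    net <- if (length(ex)) ex[[1L]]$net_shift else NA_real_
    tagged <- length(ex) > 0L &&
      any(vapply(ex, `[[`, integer(1L), "tag_len") > 0L)
    ext <- if (length(ex)) {
      e <- vapply(ex, `[[`, numeric(1L), "extent")
      if (all(is.na(e))) NA_real_ else max(e, na.rm = TRUE)
    } else NA_real_
    data.frame(peptide = p, category = cat_, n_events = nj,
               net_shift = net, tagged = tagged, extent = ext,
               best_score = max(ids$score[ids$sequence == p]),
               stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, rows)
  by_category <- table(peptides$category)
  shifts <- peptides$net_shift[peptides$category == "frameshift" &
                                 !is.na(peptides$net_shift)]
  by_offset <- table(shifts)
  ext <- peptides$extent
  structure(list(peptides = peptides,
                 by_category = by_category,
                 by_offset = by_offset,
                 max_downstream_extent = if (all(is.na(ext))) NA_real_
                                         else max(ext, na.rm = TRUE),
                 n_filtered = sum(!keep)),
            class = "stall_summary")
}

#' @export
print.stall_summary <- function(x, ...) {
  cat("Peptide summary:", nrow(x$peptides), "unique peptides (",
      x$n_filtered, "identifications below threshold )\n")
  print(x$by_category)
  cat("maximum downstream decoded extent: +", x$max_downstream_extent,
      " nt past the stall\n", sep = "")
  invisible(x)
}

#' Dump per-peptide explanations as JSON
#'
#' @param peptides character vector of peptides.
#' @param construct a `reporter_construct`.
#' @param path output path.
#' @param cfg an `inference_config`.
#' @return invisibly, the path.
#' @export
explanations_to_json <- function(peptides, construct, path,
                                 cfg = inference_config()) {
  out <- lapply(peptides, function(p) {
    ex <- explain(p, construct, cfg)
    list(peptide = p,
         category = classify(p, ex),
         explanations = lapply(ex, function(e) {
           e$segments <- as.list(e$segments)
           e$junctions <- as.list(e$junctions)
           e
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
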