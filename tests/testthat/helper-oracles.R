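# Independent brute-force oracles for the digestion and event-inference
# engines, plus small shared fixtures. Both oracles enumerate candidate
# solutions forward (generate-and-test) rather than searching backward from
# the peptide, so agreement with the package implementations is meaningful.

# every substring of `protein` that is a legal tryptic peptide under `spec`
digest_oracle <- function(protein, spec) {
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  is_site <- function(i) i >= 1L && i < n && res[i] %in% spec$cleave_after &&
    !(res[i + 1L] %in% spec$no_cleave_before)
  peps <- character(0)
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L < spec$min_length) next
    if (!(i == 1L || is_site(i - 1L))) next
    if (!(j == n || is_site(j))) next
    internal <- if (j > i) sum(vapply(i:(j - 1L), is_site, logical(1L))) else 0L
    if (internal > spec$max_miscleavages) next
    peps <- c(peps, paste(res[i:j], collapse = ""))
  }
  sort(unique(peps))
}

# canonical signature of an explanation list, for set comparison
explain_sig <- function(ex) {
  sort(vapply(ex, function(e) paste(
    e$anchor_len,
    ifelse(is.na(e$suppressed_residue), ".", e$suppressed_residue),
    e$tag_len,
    paste(e$segments$mrna_start, e$segments$length, sep = ":",
          collapse = ","),
    sep = "|"), character(1L)))
}

# forward enumeration over (tag suffix x anchor/start x junction boundary
# sets x resume offsets x suppression position); cfg$event_budget must be a
# number so both sides enumerate the same stratum.
explain_oracle <- function(peptide, construct, cfg) {
  stopifnot(!is.null(cfg$event_budget))
  res <- strsplit(peptide, "")[[1L]]
  n <- length(res)
  stall <- construct$stall_offset
  seqlen <- nchar(construct$coding_sequence)
  budget <- cfg$event_budget
  window <- stall + seq(cfg$resume_window[1L], cfg$resume_window[2L])
  window <- window[window >= 0L & window + 3L <= seqlen]
  tag <- stallscope:::SSRA_TAGS[[construct$tag_variant]]
  pre <- pre_stall_protein(construct)
  dec <- function(o) stallscope:::decode_at(construct, o)
  offs_for <- function(aa)
    window[vapply(window, function(o) identical(dec(o), aa), logical(1L))]

  env <- new.env(); env$sols <- character(0)

  walk <- function(rr, pos0, anchor_len, B, resumes, t, tag_len) {
    pos <- pos0; segs <- list(); cur <- NULL; ji <- 0L
    supp <- NA_character_
    for (i in seq_along(rr)) {
      if ((i - 1L) %in% B) {
        ji <- ji + 1L
        o <- resumes[ji]
        if (o == pos) return(invisible())
        if (!is.null(cur)) { segs <- c(segs, list(cur)); cur <- NULL }
        pos <- o
      }
      if (i == t) {
        if (pos != stall || !identical(dec(pos), "orphan"))
          return(invisible())
        supp <- rr[i]
        if (!is.null(cur)) { segs <- c(segs, list(cur)); cur <- NULL }
        pos <- pos + 3L
      } else {
        if (!identical(dec(pos), rr[i])) return(invisible())
        cur <- if (is.null(cur)) c(pos, 1L) else c(cur[1L], cur[2L] + 1L)
        pos <- pos + 3L
      }
    }
    if (!is.null(cur)) segs <- c(segs, list(cur))
    ok <- tag_len > 0L ||
      stallscope:::valid_terminus(construct, rr[length(rr)], pos)
    if (!ok) return(invisible())
    env$sols <- c(env$sols, paste(
      anchor_len, ifelse(is.na(supp), ".", supp), tag_len,
      paste(vapply(segs, `[`, numeric(1L), 1L),
            vapply(segs, `[`, numeric(1L), 2L), sep = ":", collapse = ","),
      sep = "|"))
  }

  enumerate <- function(rr, pos0, anchor_len, b_min, tag_len, allow_supp) {
    m <- length(rr)
    if (m == 0L) {
      # pure anchor (tag or valid stall terminus); rr empty only if anchored
      last <- substring(pre, nchar(pre), nchar(pre))
      if (tag_len > 0L ||
          stallscope:::valid_terminus(construct, last, stall))
        env$sols <- c(env$sols,
                      paste(anchor_len, ".", tag_len, "", sep = "|"))
      return(invisible())
    }
    for (j in 0:budget) {
      Bs <- if (j == 0L) list(integer(0))
            else if (m - b_min < j) list()
            else utils::combn(seq(b_min, m - 1L), j, simplify = FALSE)
      for (B in Bs) {
        ts <- 0L
        if (allow_supp) ts <- c(ts, setdiff(seq_len(m), B + 1L))
        for (t in ts) {
          decoded <- setdiff(seq_len(m), t)
          cand <- lapply(B, function(b) {
            bi <- b + 1L
            if (bi == t) integer(0) else offs_for(rr[bi])
          })
          if (any(lengths(cand) == 0L) && length(cand)) next
          grids <- if (length(cand)) expand.grid(cand) else NULL
          nrep <- if (is.null(grids)) 1L else nrow(grids)
          for (g in seq_len(nrep)) {
            resumes <- if (is.null(grids)) integer(0)
                       else as.integer(grids[g, ])
            walk(rr, pos0, anchor_len, B, resumes, t, tag_len)
          }
        }
      }
    }
  }

  ntag <- nchar(tag)
  tag_lens <- 0L
  for (m in seq(cfg$min_tag_match, min(ntag, n)))
    if (substring(peptide, n - m + 1L) == substring(tag, ntag - m + 1L))
      tag_lens <- c(tag_lens, m)

  for (tag_len in tag_lens) {
    nn <- n - tag_len
    if (nn < 1L) next
    rr <- res[seq_len(nn)]
    lmax <- 0L
    for (l in seq(min(nn, nchar(pre)), 1L)) {
      if (substring(pre, nchar(pre) - l + 1L) ==
          paste(rr[1:l], collapse = "")) { lmax <- l; break }
    }
    if (lmax >= 1L) {
      enumerate(rr[seq_len(nn - lmax) + lmax], stall, lmax,
                b_min = 0L, tag_len = tag_len, allow_supp = TRUE)
    } else if (cfg$allow_unanchored) {
      starts <- seq(max(0L, stall - 9L), seqlen - 3L)
      starts <- starts[vapply(starts, function(o)
        identical(dec(o), rr[1L]), logical(1L))]
      for (o in starts) {
        # first residue is the placement itself; junctions/supp only later
        env2 <- enumerate_unanchored(rr, o, tag_len, env, budget, stall,
                                     dec, offs_for, construct, walk)
      }
    }
  }
  sort(unique(env$sols))
}

# unanchored: fix the placement offset of residue 1, enumerate the rest
enumerate_unanchored <- function(rr, o, tag_len, env, budget, stall, dec,
                                 offs_for, construct, walk) {
  m <- length(rr)
  for (j in 0:budget) {
    Bs <- if (j == 0L) list(integer(0))
          else if (m - 1L < j) list()
          else utils::combn(seq(1L, m - 1L), j, simplify = FALSE)
    for (B in Bs) {
      ts <- c(0L, setdiff(seq(2L, length.out = max(0L, m - 1L)), B + 1L))
      for (t in ts) {
        cand <- lapply(B, function(b) {
          bi <- b + 1L
          if (bi == t) integer(0) else offs_for(rr[bi])
        })
        if (any(lengths(cand) == 0L) && length(cand)) next
        grids <- if (length(cand)) expand.grid(cand) else NULL
        nrep <- if (is.null(grids)) 1L else nrow(grids)
        for (g in seq_len(nrep)) {
          resumes <- if (is.null(grids)) integer(0)
                     else as.integer(grids[g, ])
          walk(rr, o, 0L, B, resumes, t, tag_len)
        }
      }
    }
  }
}

# rebuild the peptide from an explanation's parts (soundness check)
resynthesize <- function(peptide, e, construct) {
  n <- nchar(peptide)
  out <- rep(NA_character_, n)
  if (e$anchor_len > 0L) {
    pre <- pre_stall_protein(construct)
    out[seq_len(e$anchor_len)] <-
      strsplit(substring(pre, nchar(pre) - e$anchor_len + 1L), "")[[1L]]
  }
  if (nrow(e$segments)) for (i in seq_len(nrow(e$segments))) {
    for (k in seq_len(e$segments$length[i]) - 1L) {
      o <- e$segments$mrna_start[i] + 3L * k
      cd <- substr(construct$coding_sequence, o + 1L, o + 3L)
      out[e$segments$pep_start[i] + k] <- Biostrings::GENETIC_CODE[[cd]]
    }
  }
  if (e$tag_len > 0L) {
    tag <- stallscope:::SSRA_TAGS[[construct$tag_variant]]
    out[seq(n - e$tag_len + 1L, n)] <-
      strsplit(substring(tag, nchar(tag) - e$tag_len + 1L), "")[[1L]]
  }
  open <- which(is.na(out))
  if (!is.na(e$suppressed_residue)) {
    if (length(open) != 1L) return(NA_character_)
    out[open] <- e$suppressed_residue
  } else if (length(open)) return(NA_character_)
  paste(out, collapse = "")
}

# 39-nt toy construct (anchor M K . L E H H, small three-frame tail) used
# for oracle-equivalence tests
tiny_construct <- function() {
  reporter_construct("ATGAAACTGGAACACCACTAGGGTGCTCGTTAAGTTTGA",
                     stall_offset = 18L, name = "tiny",
                     tag_variant = "DD", anchor_peptide = "LEHH")
}

random_peptides <- function(n, len_range = c(5L, 12L), seed = 42L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- sample(seq(len_range[1L], len_range[2L]), 1L)
      paste(sample(stallscope:::CANONICAL_AA, k, replace = TRUE),
            collapse = "")
    }, character(1L))
  })
}
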