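#' Transcription-factor operator sequences
#'
#' Consensus operators for the three stimulus-responsive transcription
#' factors: CRP (glucose, via cAMP), FNR (oxygen) and FruR
#' (fructose-1,6-bisphosphate / glycolytic flux).
#'
#' @return Named character vector of operator sequences.
#' @export
default_operators <- function() {
  c(CRP = "AAATGTGATCTAGATCACATTT",
    FNR = "TTGATTTACATCAA",
    FruR = "GCTGAAACGTTTCAAG")
}

#' Load the bundled sigma70 promoter cores
#'
#' Core sequences span -35 to +1 (36 bp: -35 hexamer, 17 bp spacer, -10
#' hexamer, 6 bp discriminator, +1 base). The bundled file provides
#' synthetic stand-ins for the four named constitutive promoters; the
#' originals are registry/literature sequences that contain >5 bp internal
#' repeats and would not survive the library's own synthesis screens, so
#' repeat-free synthetic cores with the same architecture are shipped
#' instead (see the file's comment header).
#'
#' @param path TSV with columns `name` and `core` (defaults to the bundled
#'   `promoter_cores_synthetic.tsv`).
#' @return Named character vector of core sequences.
#' @export
load_promoter_cores <- function(path = system.file(
    "extdata", "promoter_cores_synthetic.tsv", package = "dynlogic")) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(toupper(df$core), df$name)
}

# geometry of a core: hexamer starts relative to the core's first base
CORE_M35_OFF <- 0L
CORE_M10_OFF <- 23L   # 6 (hexamer) + 17 (spacer)
CORE_PLUS1_OFF <- 35L

#' Construct a promoter backbone
#'
#' A backbone is a `design_length`-bp promoter design: an upstream spacer,
#' the sigma70 core (-35 to +1) and a 50-bp downstream spacer. Coordinates
#' are 0-based, half-open, local to the design.
#'
#' @param name backbone name.
#' @param core 36-bp core sequence (-35 hexamer, 17 bp spacer, -10
#'   hexamer, discriminator, +1).
#' @param upstream,downstream spacer sequences; their lengths plus the
#'   core must equal `design_length`.
#' @param design_length total design length (bp).
#' @return An object of class `promoter_backbone` with fields `sequence`,
#'   `minus35_start`, `minus10_start`, `plus1`.
#' @export
promoter_backbone <- function(name, core, upstream, downstream,
                              design_length = 150) {
  seq <- paste0(upstream, core, downstream)
  if (nchar(seq) != design_length)
    stop(sprintf("backbone '%s': assembled length %d != design length %d",
                 name, nchar(seq), design_length))
  u <- nchar(upstream)
  structure(list(name = name, sequence = toupper(seq),
                 core = toupper(core),
                 minus35_start = u + CORE_M35_OFF,
                 minus10_start = u + CORE_M10_OFF,
                 plus1 = u + CORE_PLUS1_OFF,
                 design_length = design_length),
            class = "promoter_backbone")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate backbones from cores and random spacers
#'
#' Combines each core with `n_spacers` independently drawn random spacer
#' pairs (uniform over ACGT, seeded). Each assembled backbone is itself
#' passed through [apply_filters()] (with its own core whitelisted) and
#' the spacers are redrawn until the backbone passes, up to 100 attempts.
#'
#' @param cores named character vector of core sequences
#'   (default [load_promoter_cores()]).
#' @param n_spacers random spacer sets per core.
#' @param seed RNG seed.
#' @param design_length total design length (bp).
#' @return List of [promoter_backbone()] objects (length
#'   `length(cores) * n_spacers`), named `<core>_s<i>`.
#' @export
generate_backbones <- function(cores = load_promoter_cores(),
                               n_spacers = 3, seed = 7L,
                               design_length = 150) {
  down_len <- 50L
  out <- list()
  withr_seed(seed, {
    for (cn in names(cores)) {
      core <- cores[[cn]]
      up_len <- design_length - down_len - nchar(core)
      if (up_len <= 0)
        stop("design_length too short for core '", cn, "'")
      for (i in seq_len(n_spacers)) {
        ok <- FALSE
        for (try in seq_len(100)) {
          bb <- promoter_backbone(sprintf("%s_s%d", cn, i), core,
                                  random_dna(up_len), random_dna(down_len),
                                  design_length)
          fails <- apply_filters(bb$sequence,
                                 whitelist = c(bb$minus35_start,
                                               bb$minus10_start))
          if (!length(fails)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("spacer generation failed filters 100x for core '", cn, "'")
        out[[bb$name]] <- bb
      }
    }
  })
  out
}

#' Screen a design sequence against synthesis-QC filters
#'
#' A sequence fails if (a) any exact direct repeat of length >= 6 occurs
#' twice (`"repeat"`), (b) a BsaI recognition site (GGTCTC or its reverse
#' complement GAGACC) occurs on either strand (`"bsai"`), or (c) a
#' spurious sigma70 promoter-like pair occurs -- a <=1-mismatch match to
#' TTGACA followed 15-19 bp later by a <=1-mismatch match to TATAAT --
#' anywhere other than the intended core (`"sigma70"`).
#'
#' @param seq DNA sequence (ACGT only).
#' @param whitelist optional integer pair `c(minus35_start, minus10_start)`
#'   (0-based) identifying the intended core's hexamers, which are exempt
#'   from the sigma70 screen.
#' @param filters subset of `c("repeat", "bsai", "sigma70")` to apply.
#' @return Character vector of failure reasons; empty (`character(0)`)
#'   when the sequence passes.
#' @export
apply_filters <- function(seq, whitelist = NULL,
                          filters = c("repeat", "bsai", "sigma70")) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters")
  reasons <- character(0)
  if ("repeat" %in% filters && has_direct_repeat(seq, 6L))
    reasons <- c(reasons, "repeat")
  if ("bsai" %in% filters &&
      (grepl("GGTCTC", seq, fixed = TRUE) ||
       grepl("GAGACC", seq, fixed = TRUE)))
    reasons <- c(reasons, "bsai")
  if ("sigma70" %in% filters &&
      has_spurious_sigma70(seq, whitelist))
    reasons <- c(reasons, "sigma70")
  reasons
}

# any k-mer occurring twice (exact direct repeat of length >= k)
has_direct_repeat <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < 2L * k) return(FALSE)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  anyDuplicated(kmers) > 0L
}

# 0-based start positions of <=1-mismatch matches of a hexamer
hexamer_hits <- function(seq, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                max.mismatch = 1, with.indels = FALSE)
  Biostrings::start(m) - 1L
}

has_spurious_sigma70 <- function(seq, whitelist = NULL) {
  h35 <- hexamer_hits(seq, "TTGACA")
  if (!length(h35)) return(FALSE)
  h10 <- hexamer_hits(seq, "TATAAT")
  if (!length(h10)) return(FALSE)
  for (i in h35) {
    for (j in h10) {
      gap <- j - (i + 6L)
      if (gap >= 15L && gap <= 19L) {
        if (!is.null(whitelist) &&
            i == whitelist[1L] && j == whitelist[2L]) next
        return(TRUE)
      }
    }
  }
  FALSE
}

new_library_member <- function(sequence, backbone, operators, positions,
                               mode, filter_status = NULL) {
  structure(list(sequence = sequence, backbone = backbone,
                 operators = operators, positions = as.integer(positions),
                 mode = mode, filter_status = filter_status),
            class = "library_member")
}

# splice an operator into a backbone sequence at a 0-based position
splice_operator <- function(seq, op_seq, pos, mode) {
  L <- nchar(seq)
  k <- nchar(op_seq)
  if (mode == "replace") {
    if (pos < 0 || pos + k > L) return(NULL)
    paste0(substr(seq, 1, pos), op_seq, substr(seq, pos + k + 1, L))
  } else {
    if (pos < 0 || pos > L) return(NULL)
    paste0(substr(seq, 1, pos), op_seq, substr(seq, pos + 1, L))
  }
}

#' Scan an operator across a backbone
#'
#' Produces one candidate per feasible insertion position at
#' single-nucleotide resolution. `replace` mode (default) overwrites the
#' backbone bases and preserves total length; `insert` mode lengthens the
#' design. Candidates are not yet filtered; see [build_library()].
#'
#' @param backbone a [promoter_backbone()].
#' @param op_name operator name.
#' @param op_seq operator sequence.
#' @param mode `"replace"` or `"insert"`.
#' @param range optional integer vector of 0-based positions to scan
#'   (default: every feasible position).
#' @return List of `library_member` candidates.
#' @export
scan_insert <- function(backbone, op_name, op_seq,
                        mode = c("replace", "insert"), range = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(backbone, "promoter_backbone"))
  L <- nchar(backbone$sequence)
  k <- nchar(op_seq)
  if (k >= L) stop("operator longer than backbone")
  if (is.null(range)) {
    range <- if (mode == "replace") 0:(L - k) else 0:L
  }
  out <- vector("list", length(range))
  for (idx in seq_along(range)) {
    pos <- range[idx]
    s <- splice_operator(backbone$sequence, op_seq, pos, mode)
    if (is.null(s)) next
    out[[idx]] <- new_library_member(s, backbone$name, op_name, pos, mode)
  }
  out[!vapply(out, is.null, logical(1))]
}

# anchor position of a named dual-insertion site on a backbone
site_anchor <- function(backbone, site, pair_len) {
  switch(site,
    plus1 = backbone$plus1,
    minus10_minus35_spacer = backbone$minus35_start + 6L,
    upstream_minus35 = backbone$minus35_start - pair_len,
    stop("unknown dual-insertion site: ", site))
}

#' Insert two operators with variable spacing
#'
#' Places operator A at the site anchor and operator B downstream of it,
#' separated by a gap of `6 + offset` bp of retained backbone sequence
#' (nominal 6-bp inter-operator gap; offsets -6..+6 vary it over 0..12
#' bp, so offset 0 reproduces the nominal geometry). Sites follow the
#' design's named insertion points: the +1 site, the 17-bp spacer between
#' the -35 and -10 hexamers, or immediately upstream of the -35 hexamer.
#' Geometrically infeasible (site, offset) pairs are skipped and recorded
#' in the `skipped` attribute.
#'
#' @param backbone a [promoter_backbone()].
#' @param op_a_name,op_a_seq,op_b_name,op_b_seq the operator pair.
#' @param sites subset of
#'   `c("plus1", "minus10_minus35_spacer", "upstream_minus35")`.
#' @param offsets integer offsets from the nominal spacing, within -6..+6.
#' @return List of `library_member` candidates (metadata records both
#'   positions), with attribute `skipped` listing infeasible geometries.
#' @export
dual_insert <- function(backbone, op_a_name, op_a_seq, op_b_name, op_b_seq,
                        sites = c("plus1", "minus10_minus35_spacer",
                                  "upstream_minus35"),
                        offsets = -6:6) {
  stopifnot(inherits(backbone, "promoter_backbone"))
  if (any(abs(offsets) > 6)) stop("offsets must lie within -6..+6")
  ka <- nchar(op_a_seq)
  kb <- nchar(op_b_seq)
  out <- list()
  skipped <- character(0)
  for (site in sites) {
    for (off in offsets) {
      gap <- 6L + off
      pair_len <- ka + gap + kb
      anchor <- site_anchor(backbone, site, pair_len)
      pos_b <- anchor + ka + gap
      s <- splice_operator(backbone$sequence, op_a_seq, anchor, "replace")
      if (!is.null(s)) s <- splice_operator(s, op_b_seq, pos_b, "replace")
      if (is.null(s)) {
        skipped <- c(skipped, sprintf("%s offset %+d: out of design",
                                      site, off))
        next
      }
      out[[length(out) + 1L]] <- new_library_member(
        s, backbone$name, c(op_a_name, op_b_name), c(anchor, pos_b),
        "replace")
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Finalize a library member into a synthesis oligo
#'
#' Flanks the design with the two 20-bp amplification tails and re-checks
#' the tail junctions for BsaI conflicts; a junction that creates a BsaI
#' site is rejected with an error.
#'
#' @param member a passing `library_member`.
#' @param tails character vector of two 20-bp tails (left, right; both on
#'   the oligo's sense strand). Defaults to the amplification-primer
#'   annealing ends.
#' @return The oligo sequence (design length + 40 bp).
#' @export
finalize_oligo <- function(member,
                           tails = c("AACTCAACTCCTGTGGCGTG",
                                     "CCACTCACGTATACGTGCGA")) {
  stopifnot(inherits(member, "library_member"))
  if (!is.null(member$filter_status) && length(member$filter_status))
    stop("member did not pass filters: ",
         paste(member$filter_status, collapse = ", "))
  if (any(nchar(tails) != 20L)) stop("tails must be 20 bp")
  oligo <- paste0(tails[1L], member$sequence, tails[2L])
  # junction windows spanning tail/design boundaries
  left_j <- substr(oligo, 21L - 5L, 21L + 5L)
  right_j <- substr(oligo, nchar(oligo) - 25L, nchar(oligo) - 15L)
  for (win in c(left_j, right_j)) {
    if (grepl("GGTCTC", win, fixed = TRUE) ||
        grepl("GAGACC", win, fixed = TRUE))
      stop("tail junction creates a BsaI site; oligo rejected")
  }
  oligo
}

#' Library design specification
#'
#' Bundles everything [build_library()] needs: the cores, operators,
#' design geometry, dual-insertion sites and offsets, enabled filters,
#' amplification tails and the RNG seed for spacer generation.
#'
#' @param cores named character vector of core sequences.
#' @param operators named character vector of operator sequences.
#' @param design_length design length (bp).
#' @param n_spacers random spacer sets per core.
#' @param single_insertion scan single operators at every position.
#' @param dual_sites dual-insertion site names.
#' @param dual_offsets spacing offsets, within -6..+6.
#' @param filters filters to enforce.
#' @param tails amplification tails (two 20-bp sequences).
#' @param rng_seed seed for spacer generation.
#' @return An object of class `library_design_spec`.
#' @export
library_design_spec <- function(cores = load_promoter_cores(),
                                operators = default_operators(),
                                design_length = 150,
                                n_spacers = 3,
                                single_insertion = TRUE,
                                dual_sites = c("plus1",
                                               "minus10_minus35_spacer",
                                               "upstream_minus35"),
                                dual_offsets = -6:6,
                                filters = c("repeat", "bsai", "sigma70"),
                                tails = c("AACTCAACTCCTGTGGCGTG",
                                          "CCACTCACGTATACGTGCGA"),
                                rng_seed = 7L) {
  if (any(abs(dual_offsets) > 6)) stop("dual offsets must be within -6..+6")
  if (design_length <= max(nchar(operators)))
    stop("design_length must exceed the longest operator")
  structure(list(cores = cores, operators = operators,
                 design_length = design_length, n_spacers = n_spacers,
                 single_insertion = single_insertion,
                 dual_sites = dual_sites, dual_offsets = dual_offsets,
                 filters = filters, tails = tails, rng_seed = rng_seed),
            class = "library_design_spec")
}

#' Read a library design spec from YAML
#'
#' @param path YAML file; keys mirror the arguments of
#'   [library_design_spec()] (missing keys take the defaults).
#' @return A [library_design_spec()].
#' @export
read_design_spec <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("design_length", "n_spacers", "single_insertion",
               "dual_sites", "dual_offsets", "filters", "tails",
               "rng_seed"))
    if (!is.null(x[[nm]])) args[[nm]] <- x[[nm]]
  if (!is.null(x$operators)) args$operators <- unlist(x$operators)
  if (!is.null(x$cores)) args$cores <- unlist(x$cores)
  do.call(library_design_spec, args)
}

#' Build the combinatorial promoter library
#'
#' Generates the backbones (cores x seeded random spacers), scans every
#' single-operator insertion at single-nucleotide resolution, adds all
#' dual insertions of distinct operator pairs over the named sites and
#' spacing offsets, screens every candidate with [apply_filters()] (the
#' intended core whitelisted), and returns the deduplicated passing
#' members plus a summary. Identical spec and seed give a byte-identical
#' library.
#'
#' @param spec a [library_design_spec()].
#' @param verbose print progress.
#' @return List with `members` (passing, deduplicated `library_member`s),
#'   `backbones`, and `summary` (candidate/pass counts per backbone,
#'   operator and failure reason).
#' @export
build_library <- function(spec = library_design_spec(), verbose = FALSE) {
  stopifnot(inherits(spec, "library_design_spec"))
  backbones <- generate_backbones(spec$cores, spec$n_spacers,
                                  seed = spec$rng_seed,
                                  design_length = spec$design_length)
  ops <- spec$operators
  candidates <- list()
  for (bb in backbones) {
    if (spec$single_insertion) {
      for (on in names(ops))
        candidates <- c(candidates, scan_insert(bb, on, ops[[on]]))
    }
    if (length(spec$dual_sites) && length(ops) > 1L) {
      for (a in names(ops)) for (b in names(ops)) {
        if (a == b) next  # same-operator pairs always fail the repeat screen
        candidates <- c(candidates,
                        dual_insert(bb, a, ops[[a]], b, ops[[b]],
                                    sites = spec$dual_sites,
                                    offsets = spec$dual_offsets))
      }
    }
    if (verbose) message("backbone ", bb$name, ": ",
                         length(candidates), " cumulative candidates")
  }

  wl <- lapply(backbones, function(b) c(b$minus35_start, b$minus10_start))
  fail_counts <- integer(0)
  passing <- vector("list", length(candidates))
  np <- 0L
  for (m in candidates) {
    reasons <- apply_filters(m$sequence, whitelist = wl[[m$backbone]],
                             filters = spec$filters)
    if (length(reasons)) {
      for (r in reasons)
        fail_counts[r] <- (if (is.na(fail_counts[r])) 0L
                           else fail_counts[r]) + 1L
    } else {
      m$filter_status <- character(0)
      np <- np + 1L
      passing[[np]] <- m
    }
  }
  passing <- passing[seq_len(np)]

  seqs <- vapply(passing, function(m) m$sequence, character(1))
  keep <- !duplicated(seqs)
  members <- passing[keep]
  if (!length(members))
    stop("empty library; failure breakdown: ",
         paste(sprintf("%s=%d", names(fail_counts), fail_counts),
               collapse = ", "))

  by_backbone <- table(vapply(members, function(m) m$backbone,
                              character(1)))
  by_operator <- table(unlist(lapply(members, function(m) m$operators)))
  list(members = members, backbones = backbones,
       summary = list(n_candidates = length(candidates),
                      n_pass = np,
                      n_unique = length(members),
                      failures = as.list(fail_counts),
                      by_backbone = as.list(by_backbone),
                      by_operator = as.list(by_operator)))
}

member_id <- function(m) {
  paste(c("lib", m$backbone, m$operators, m$positions), collapse = "_")
}

#' Write library FASTA and metadata TSV
#'
#' FASTA is wrapped at 80 columns with headers
#' `>lib_<backbone>_<operator>_<pos>[_<op2>_<pos2>]`; the TSV records
#' member id, backbone, operator(s), position(s) and filter status.
#'
#' @param lib result of [build_library()].
#' @param fasta_path,tsv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the member ids written.
#' @export
write_library_fasta <- function(lib, fasta_path, tsv_path = NULL) {
  ids <- vapply(lib$members, member_id, character(1))
  if (!is.null(fasta_path)) {
    con <- file(fasta_path, "w")
    on.exit(close(con))
    for (i in seq_along(lib$members)) {
      writeLines(paste0(">", ids[i]), con)
      s <- lib$members[[i]]$sequence
      starts <- seq(1, nchar(s), by = 80)
      writeLines(substring(s, starts, pmin(starts + 79, nchar(s))), con)
    }
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(
      id = ids,
      backbone = vapply(lib$members, function(m) m$backbone, character(1)),
      operators = vapply(lib$members,
                         function(m) paste(m$operators, collapse = ","),
                         character(1)),
      positions = vapply(lib$members,
                         function(m) paste(m$positions, collapse = ","),
                         character(1)),
      filter_status = "pass")
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(ids)
}
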