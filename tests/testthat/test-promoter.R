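# a small backbone set for fast unit tests; the full default build is
# exercised in the acceptance suite
small_spec <- function() {
  cores <- load_promoter_cores()[1:2]
  library_design_spec(cores = cores, n_spacers = 1, rng_seed = 11L)
}

test_that("backbone generation is seeded, filtered, and sized 4 x 3", {
  bbs <- generate_backbones(seed = 7L)
  expect_length(bbs, 12)
  expect_true(all(vapply(bbs, function(b) nchar(b$sequence), integer(1))
                  == 150))
  # every backbone passes its own screens
  for (b in bbs) {
    expect_length(apply_filters(b$sequence,
                                whitelist = c(b$minus35_start,
                                              b$minus10_start)), 0)
    expect_equal(substr(b$sequence, b$minus35_start + 1,
                        b$minus35_start + nchar(b$core)), b$core)
  }
  # determinism: same seed, byte-identical sequences
  bbs2 <- generate_backbones(seed = 7L)
  expect_identical(lapply(bbs, `[[`, "sequence"),
                   lapply(bbs2, `[[`, "sequence"))
  expect_length(generate_backbones(n_spacers = 1, seed = 3L), 4)
})

test_that("single-operator scans cover every position exactly once", {
  bb <- generate_backbones(n_spacers = 1, seed = 5L)[[1]]
  ops <- default_operators()
  cand <- scan_insert(bb, "FNR", ops[["FNR"]])  # 14 bp operator
  expect_length(cand, 150 - 14 + 1)
  expect_true(startsWith(cand[[1]]$sequence, ops[["FNR"]]))
  for (m in cand) {
    expect_equal(nchar(m$sequence), 150)
    expect_equal(substr(m$sequence, m$positions + 1,
                        m$positions + 14), ops[["FNR"]])
  }
})

test_that("dual insertion produces 13 spacing variants per site", {
  bb <- generate_backbones(n_spacers = 1, seed = 5L)[[1]]
  ops <- default_operators()
  cand <- dual_insert(bb, "CRP", ops[["CRP"]], "FNR", ops[["FNR"]],
                      sites = "plus1")
  expect_length(cand, 13)
  for (m in cand) {
    expect_equal(substr(m$sequence, m$positions[1] + 1,
                        m$positions[1] + 22), ops[["CRP"]])
    expect_equal(substr(m$sequence, m$positions[2] + 1,
                        m$positions[2] + 14), ops[["FNR"]])
  }
  # offset 0 corresponds to the nominal 6 bp gap
  gaps <- vapply(cand, function(m)
    m$positions[2] - (m$positions[1] + 22L), integer(1))
  expect_equal(sort(gaps), 0:12)
  expect_error(dual_insert(bb, "CRP", ops[["CRP"]], "FNR", ops[["FNR"]],
                           offsets = -8:8), "-6")
})

test_that("filters flag BsaI sites, direct repeats, spurious promoters", {
  base <- "ACGTGCATCGATCCGGTTAACCTGA"
  expect_equal(apply_filters(paste0(base, "GGTCTC", "TTACG")), "bsai")
  expect_equal(apply_filters(paste0(base, "GAGACC", "TTACG")), "bsai")
  # ACGTAA twice -> repeat
  expect_true("repeat" %in% apply_filters(
    paste0("ACGTAACCGGTTGCAT", "ACGTAA", "GGCCTT")))
  # TTGACA ... 17 bp ... TATAAT is a spurious promoter unless whitelisted
  sigma <- paste0("GCGGCC", "TTGACA", "CATCGGCTCAACTGTTG", "TATAAT",
                  "CCGGAA")
  expect_true("sigma70" %in% apply_filters(sigma))
  expect_false("sigma70" %in% apply_filters(sigma, whitelist = c(6L, 29L)))
  # one-mismatch hexamers are still caught
  sigma_mm <- sub("TTGACA", "TTTACA", sigma)
  expect_true("sigma70" %in% apply_filters(sigma_mm))
  expect_error(apply_filters("ACGTN"), "non-ACGT")
  expect_length(apply_filters("ACGTGCATCGATCCGGTTAACCTGA"), 0)
})

test_that("oligo finalization adds tails and rejects BsaI junctions", {
  m <- structure(list(sequence = strrep("ACGTGCATCG", 15),
                      backbone = "b", operators = "CRP", positions = 0L,
                      mode = "replace", filter_status = character(0)),
                 class = "library_member")
  oligo <- finalize_oligo(m)
  expect_equal(nchar(oligo), 190)
  expect_true(startsWith(oligo, "AACTCAACTCCTGTGGCGTG"))
  expect_true(endsWith(oligo, "CCACTCACGTATACGTGCGA"))
  # left tail ends in ...G; a design starting GTCTC creates GGTCTC
  m_bad <- m
  m_bad$sequence <- paste0("GTCTC", substr(m$sequence, 6, 150))
  expect_error(finalize_oligo(m_bad), "BsaI")
  # members that failed filters are refused
  m_fail <- m
  m_fail$filter_status <- "bsai"
  expect_error(finalize_oligo(m_fail), "did not pass")
})

test_that("library build honors filters, dedup, and determinism", {
  lib <- build_library(small_spec())
  seqs <- vapply(lib$members, function(m) m$sequence, character(1))
  expect_gt(length(seqs), 100)
  expect_false(any(duplicated(seqs)))
  expect_true(all(nchar(seqs) == 150))
  expect_false(any(grepl("GGTCTC", seqs, fixed = TRUE)))
  expect_false(any(grepl("GAGACC", seqs, fixed = TRUE)))
  # operator presence at recorded offsets, exhaustively
  ops <- default_operators()
  for (m in lib$members) {
    for (i in seq_along(m$operators)) {
      op <- ops[[m$operators[i]]]
      expect_equal(substr(m$sequence, m$positions[i] + 1,
                          m$positions[i] + nchar(op)), op)
    }
  }
  # no direct repeats >= 6 bp: spot-check against an independent oracle
  has_rep <- function(s) {
    kmers <- substring(s, 1:(nchar(s) - 5), 6:nchar(s))
    anyDuplicated(kmers) > 0
  }
  expect_false(any(vapply(seqs, has_rep, logical(1))))
  # determinism under the design seed
  lib2 <- build_library(small_spec())
  seqs2 <- vapply(lib2$members, function(m) m$sequence, character(1))
  expect_identical(seqs, seqs2)
})

test_that("library FASTA and metadata round out the build", {
  lib <- build_library(small_spec())
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ids <- write_library_fasta(lib, fa, tsv)
  lines <- readLines(fa)
  expect_equal(sum(startsWith(lines, ">")), length(lib$members))
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 80))
  meta <- read.delim(tsv)
  expect_equal(nrow(meta), length(lib$members))
  expect_true(all(meta$filter_status == "pass"))
  expect_equal(meta$id[1], ids[1])
})

test_that("design specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_spacers = 2, rng_seed = 42,
                        dual_offsets = -2:2), path)
  spec <- read_design_spec(path)
  expect_equal(spec$n_spacers, 2)
  expect_equal(spec$rng_seed, 42)
  expect_equal(spec$dual_offsets, -2:2)
  expect_equal(spec$design_length, 150)
})
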