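test_that("fully adherent constraints appear in every positive", {
  spec <- motif_spec("strict", "S",
                     tibble::tibble(offset = -3L, residues = "R", q = 1))
  bm <- generate_benchmark(spec, 50, 2, seed = 1)
  pos <- benchmark_positives(bm)
  expect_true(all(substr(pos, 11 - 3, 11 - 3) == "R"))
  expect_true(all(substr(pos, 11, 11) == "S"))
  expect_true(all(substr(benchmark_negatives(bm), 11, 11) == "S"))
})

test_that("generation is deterministic and respects requested sizes", {
  spec <- motif_preset("14-3-3")
  b1 <- generate_benchmark(spec, 100, 10, seed = 42)
  b2 <- generate_benchmark(spec, 100, 10, seed = 42)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_lte(sum(b1$label == "positive"), 100)
  n_neg <- sum(b1$label == "negative")
  expect_gt(n_neg, 900)
  expect_lte(n_neg, 1000)
  expect_false(any(duplicated(b1$peptide)))
  b3 <- generate_benchmark(spec, 100, 10, seed = 43)
  expect_false(identical(b1$peptide, b3$peptide))
})

test_that("constraint adherence stays inside its binomial 99% interval", {
  spec <- motif_preset("14-3-3")
  n <- 400
  bm <- generate_benchmark(spec, n, 1, seed = 7)
  pos <- benchmark_positives(bm)
  for (i in seq_len(nrow(spec$constraints))) {
    off <- spec$constraints$offset[i]
    set <- strsplit(spec$constraints$residues[i], "")[[1]]
    q <- spec$constraints$q[i]
    hits <- sum(substr(pos, 11 + off, 11 + off) %in% set)
    # background draws can also land in the residue set
    p_bg <- length(set) / 20
    p_eff <- q + (1 - q) * p_bg
    lo <- qbinom(0.005, length(pos), p_eff)
    hi <- qbinom(0.995, length(pos), p_eff)
    expect_gte(hits, lo)
    expect_lte(hits, hi)
  }
})

test_that("negatives reproduce the background composition", {
  bm <- generate_benchmark(motif_preset("null-st"), 150, 4, seed = 8)
  neg <- benchmark_negatives(bm)
  chars <- unlist(strsplit(sub("S", "", neg, fixed = TRUE), ""))
  tab <- table(factor(chars, levels = phosphobind:::PBP_STANDARD))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("null generators leave classes indistinguishable per position", {
  bm <- generate_benchmark(motif_preset("null-st"), 200, 1, seed = 9)
  pos <- benchmark_positives(bm)
  neg <- benchmark_negatives(bm)
  # pooled per-offset composition test at a handful of offsets
  for (off in c(-5, -1, 3)) {
    a <- table(factor(substr(pos, 11 + off, 11 + off),
                      levels = phosphobind:::PBP_STANDARD))
    b <- table(factor(substr(neg, 11 + off, 11 + off),
                      levels = phosphobind:::PBP_STANDARD))
    keep <- (a + b) > 0
    p <- suppressWarnings(
      stats::chisq.test(rbind(a[keep], b[keep]))$p.value)
    expect_gt(p, 1e-4)
  }
})

test_that("impossible specifications are rejected", {
  expect_error(
    motif_spec("bad", "S",
               tibble::tibble(offset = -1L, residues = "", q = 0.5)),
    "nonempty")
  expect_error(
    motif_spec("bad", "S",
               tibble::tibble(offset = 0L, residues = "R", q = 0.5)),
    "nonzero")
  expect_error(motif_spec("bad", "B"), "S, T or Y")
  expect_error(generate_benchmark(motif_preset("null-st"), 0, 1), "n_pos")
})

test_that("child motifs extend their parent's constraint set", {
  parent <- motif_preset("14-3-3")
  child <- motif_extend(parent,
                        tibble::tibble(offset = -6L, residues = "K",
                                       q = 0.8))
  expect_identical(child$center_class, parent$center_class)
  expect_true(all(
    paste(parent$constraints$offset, parent$constraints$residues) %in%
      paste(child$constraints$offset, child$constraints$residues)))
  expect_identical(nrow(child$constraints),
                   nrow(parent$constraints) + 1L)
})

test_that("proteome generation records planted truth and is byte-stable", {
  out0 <- generate_proteome(n_proteins = 5, length_range = c(60L, 90L),
                            seed = 12)
  expect_identical(nrow(out0$truth), 0L)

  spec <- motif_spec("strict", "S",
                     tibble::tibble(offset = -3L, residues = "R", q = 1))
  out <- generate_proteome(n_proteins = 10, length_range = c(120L, 160L),
                           planted = list(list(spec = spec, count = 8)),
                           seed = 13)
  expect_identical(nrow(out$truth), 8L)
  for (i in seq_len(8)) {
    seq_i <- out$proteins[[out$truth$protein_id[i]]]
    p <- out$truth$position[i]
    expect_identical(substr(seq_i, p, p), "S")
    expect_identical(substr(seq_i, p - 3, p - 3), "R")
  }
  out2 <- generate_proteome(n_proteins = 10, length_range = c(120L, 160L),
                            planted = list(list(spec = spec, count = 8)),
                            seed = 13)
  expect_identical(out$proteins, out2$proteins)
  # identical FASTA bytes
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(out$proteins, f1)
  write_fasta(out2$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(
    generate_proteome(n_proteins = 2, length_range = c(30L, 35L),
                      planted = list(list(spec = spec, count = 500)),
                      seed = 14),
    "room|collision")
})
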