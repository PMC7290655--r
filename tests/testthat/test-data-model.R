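test_that("window extraction pads termini and keeps the stated geometry", {
  expect_identical(extract_pbp("MSK", 2, m = 2, n = 2)$peptide, "*MSK*")
  expect_identical(extract_pbp("STY", 1, m = 2, n = 2)$peptide, "**STY")
  # full-length window of the default geometry is a 21-mer
  expect_identical(nchar(extract_pbp("MSK", 2, m = 10, n = 10)$peptide), 21L)
  # interior window needs no padding and recovers the source substring
  seq <- "MARTLSPQKWY"
  w <- extract_pbp(seq, 6, m = 3, n = 3)
  expect_identical(w$peptide, substr(seq, 3, 9))
  expect_identical(w$residue, "S")
})

test_that("window extraction validates inputs and maps unusual residues", {
  expect_error(extract_pbp("MSK", 0, 2, 2), "outside")
  expect_error(extract_pbp("MSK", 4, 2, 2), "outside")
  expect_error(extract_pbp("MSK", 1, 2, 2, center_classes = c("S", "T")),
               "not one of")
  # selenocysteine and ambiguity codes collapse onto the padding symbol
  expect_identical(extract_pbp("AUSXB", 3, m = 2, n = 2)$peptide, "A*S**")
})

test_that("stripping padding always recovers a substring of the source", {
  seq <- "MKTAYSSLRSPTWYELS"
  for (pos in seq_len(nchar(seq))) {
    for (mn in list(c(2L, 2L), c(5L, 3L), c(10L, 10L))) {
      pep <- extract_pbp(seq, pos, mn[1], mn[2])$peptide
      expect_identical(nchar(pep), mn[1] + 1L + mn[2])
      core <- gsub("\\*", "", pep)
      expect_true(grepl(core, seq, fixed = TRUE))
    }
  }
})

# 5 S, 3 T, 2 Y; the annotated pS sits at position 4
counting_protein <- c(P1 = "MSKSPSLSGSARTLTCTWAYDYG")

test_that("benchmark construction counts positives and negatives correctly", {
  sites <- tibble::tibble(protein_id = "P1", position = 4L, residue = "S")
  bm <- build_benchmark(counting_protein, sites, m = 3, n = 3,
                        center_classes = c("S", "T"))
  expect_s3_class(bm, "pbs_benchmark")
  expect_identical(sum(bm$label == "positive"), 1L)
  expect_identical(sum(bm$label == "negative"), 7L)  # 5 S + 3 T - 1
  expect_true(all(bm$residue %in% c("S", "T")))
})

test_that("benchmarks are de-duplicated and classes are disjoint", {
  # two annotated sites with identical windows collapse to one positive
  prot <- c(A = "GGGRRSPPLGGGRRSPPLGGG")
  sites <- tibble::tibble(protein_id = c("A", "A"),
                          position = c(6L, 15L), residue = "S")
  bm <- build_benchmark(prot, sites, m = 3, n = 3, center_classes = "S")
  expect_identical(sum(bm$label == "positive"), 1L)
  expect_false(any(duplicated(bm$peptide)))

  # three-protein fixture with overlapping duplicate negatives: the count
  # must equal a brute-force enumeration of distinct negative strings
  prots <- c(X = "AASKLSKLAA", Y = "CCSKLSKLCC", Z = "AASKLSKLAA")
  sites <- tibble::tibble(protein_id = "X", position = 3L, residue = "S")
  bm <- build_benchmark(prots, sites, m = 2, n = 2, center_classes = "S",
                        negative_proteins = prots)
  # oracle: enumerate every S window by hand
  oracle <- character(0)
  for (nm in names(prots)) {
    s <- prots[[nm]]
    padded <- paste0("**", s, "**")
    for (p in which(strsplit(s, "")[[1]] == "S")) {
      if (nm == "X" && p == 3) next
      oracle <- c(oracle, substr(padded, p, p + 4))
    }
  }
  pos_pep <- bm$peptide[bm$label == "positive"]
  oracle <- setdiff(unique(oracle), pos_pep)
  expect_setequal(bm$peptide[bm$label == "negative"], oracle)
  expect_length(intersect(pos_pep, bm$peptide[bm$label == "negative"]), 0)
})

test_that("benchmark construction is idempotent on its own site output", {
  prots <- c(X = "AASKLSKLAA", Y = "CCSTLSKLCC")
  sites <- tibble::tibble(protein_id = c("X", "Y"),
                          position = c(3L, 6L), residue = "S")
  bm1 <- build_benchmark(prots, sites, m = 2, n = 2,
                         center_classes = c("S", "T"))
  sites2 <- dplyr::filter(bm1, label == "positive")[
    , c("protein_id", "position", "residue")]
  bm2 <- build_benchmark(prots, sites2, m = 2, n = 2,
                         center_classes = c("S", "T"))
  expect_identical(as.data.frame(bm1), as.data.frame(bm2))
})

test_that("site validation errors name the offending protein and position", {
  prots <- c(X = "AASKLSKLAA")
  expect_error(
    build_benchmark(prots, tibble::tibble(protein_id = "X", position = 4L,
                                          residue = "S"), m = 2, n = 2),
    "X:4")
  expect_error(
    build_benchmark(prots, tibble::tibble(protein_id = "Q", position = 3L,
                                          residue = "S"), m = 2, n = 2),
    "Q:3")
  expect_error(
    build_benchmark(prots, tibble::tibble(protein_id = character(),
                                          position = integer(),
                                          residue = character())),
    "no positive sites")
})

test_that("hierarchy nodes inherit central classes and validate structure", {
  grp <- hierarchy_node("pS/pT", "group")
  expect_identical(grp$center_classes, c("S", "T"))
  expect_identical(hierarchy_node("pY", "group")$center_classes, "Y")
  fam <- hierarchy_node("14-3-3", "family", parent = grp)
  expect_identical(fam$center_classes, c("S", "T"))
  cl <- hierarchy_node("YWHAZ", "cluster", parent = fam)
  expect_identical(cl$parent$parent$name, "pS/pT")
  expect_error(hierarchy_node("YWHAZ", "cluster", parent = grp), "family")
  expect_error(hierarchy_node("14-3-3", "family"), "parent")
})

test_that("benchmark TSV round trip preserves content and geometry", {
  bm <- generate_benchmark(toy_motif_k5(), 10, 3, m = 2, n = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(bm, path)
  back <- read_benchmark(path)
  expect_identical(as.data.frame(back), as.data.frame(bm))
  expect_identical(attr(back, "m"), attr(bm, "m"))
  expect_identical(attr(back, "center_classes"), attr(bm, "center_classes"))
})
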