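# Exhaustive enumeration of all aligned residue pairings, binned by
# unordered pair: the independent oracle for the 231-vector encoder.
pvt_oracle <- function(q, pos, w, m62 = blosum62_21()) {
  qc <- strsplit(q, "")[[1]]
  alpha <- pbp_alphabet()
  labels <- pvt_pairs()
  num <- stats::setNames(numeric(231), labels)
  den <- stats::setNames(numeric(231), labels)
  for (j in seq_along(qc)) {
    for (p in pos) {
      a <- qc[j]
      b <- substr(p, j, j)
      ia <- match(a, alpha)
      ib <- match(b, alpha)
      lab <- paste0(alpha[min(ia, ib)], alpha[max(ia, ib)])
      num[lab] <- num[lab] + m62[a, b] * w[j]
      den[lab] <- den[lab] + 1
    }
  }
  ifelse(den > 0, num / pmax(den, 1), 0)
}

test_that("the pair index has 231 sorted unordered labels", {
  pp <- pvt_pairs()
  expect_length(pp, 231)
  expect_false(any(duplicated(pp)))
  expect_identical(pp[1:3], c("AA", "AC", "AD"))
  expect_identical(pp[231], "**")
  expect_identical(pp[21], "A*")
})

test_that("every encoding has exactly 231 components", {
  pos <- random_peptides(3, 5, seed = 1, center = "S")
  v <- encode_pvt(random_peptides(1, 5, seed = 2, center = "S"), pos,
                  rep(1, 5))
  expect_length(v, 231)
  expect_identical(names(v), pvt_pairs())
})

test_that("a query identical to the single positive yields only self pairs", {
  q <- "RKSAP"
  w <- c(2, 1, 0.5, 1, 3)
  m62 <- blosum62_21()
  v <- encode_pvt(q, q, w)
  qc <- strsplit(q, "")[[1]]
  for (a in unique(qc)) {
    lab <- paste0(a, a)
    pos_a <- which(qc == a)
    expect_equal(v[[lab]], m62[a, a] * mean(w[pos_a]))
  }
  realized <- paste0(unique(qc), unique(qc))
  expect_true(all(v[setdiff(names(v), realized)] == 0))
})

test_that("the encoder matches the brute-force pair enumeration", {
  withr::with_seed(42, w <- round(runif(5, -1, 3), 2))
  pos <- c("ARNDS", "GHSKS")
  for (q in c("WKCMS", "ARNDS", "AAAAA")) {
    expect_equal(unname(encode_pvt(q, pos, w)),
                 unname(pvt_oracle(q, pos, w)))
  }
  # longer window, more positives
  pos2 <- random_peptides(6, 9, seed = 8, center = "S")
  withr::with_seed(9, w2 <- rnorm(9))
  q2 <- random_peptides(1, 9, seed = 10, center = "S")
  expect_equal(unname(encode_pvt(q2, pos2, w2)),
               unname(pvt_oracle(q2, pos2, w2)))
})

test_that("constant weights collapse to scaled substitution scores", {
  m62 <- blosum62_21()
  pos <- random_peptides(4, 7, seed = 3, center = "T")
  q <- random_peptides(1, 7, seed = 4, center = "T")
  v <- encode_pvt(q, pos, rep(2.5, 7))
  qc <- strsplit(q, "")[[1]]
  alpha <- pbp_alphabet()
  realized <- unique(unlist(lapply(seq_len(7), function(j) {
    vapply(pos, function(p) {
      ia <- match(qc[j], alpha)
      ib <- match(substr(p, j, j), alpha)
      paste0(alpha[min(ia, ib)], alpha[max(ia, ib)])
    }, character(1))
  })))
  for (lab in realized) {
    a <- substr(lab, 1, 1)
    b <- substr(lab, 2, 2)
    expect_equal(v[[lab]], 2.5 * m62[a, b])
  }
})

test_that("pair scores are weighted means bounded by the weight range", {
  withr::with_seed(5, w <- runif(9, 0.2, 4))
  pos <- random_peptides(5, 9, seed = 6, center = "S")
  q <- random_peptides(1, 9, seed = 7, center = "S")
  v <- encode_pvt(q, pos, w)
  m62 <- blosum62_21()
  for (lab in names(v)[v != 0]) {
    a <- substr(lab, 1, 1)
    b <- substr(lab, 2, 2)
    if (m62[a, b] == 0) next
    wmean <- v[[lab]] / m62[a, b]
    expect_gte(wmean, min(w) - 1e-12)
    expect_lte(wmean, max(w) + 1e-12)
  }
})

test_that("encoding ignores the order of the positive set", {
  pos <- random_peptides(5, 5, seed = 12, center = "S")
  withr::with_seed(13, w <- rnorm(5))
  q <- "ARKSP"
  expect_equal(encode_pvt(q, pos, w), encode_pvt(q, rev(pos), w))
  expect_equal(encode_pvt(q, pos, w), encode_pvt(q, sample(pos), w))
})

test_that("batch encoding equals per-item encoding", {
  pos <- random_peptides(4, 5, seed = 14, center = "S")
  qs <- random_peptides(6, 5, seed = 15, center = "S")
  withr::with_seed(16, w <- rnorm(5))
  batch <- pvt_encode(qs, pos, w)
  expect_identical(dim(batch), c(6L, 231L))
  for (i in seq_along(qs)) {
    expect_equal(unname(batch[i, ]), unname(encode_pvt(qs[i], pos, w)))
  }
})

test_that("the encoder validates its inputs", {
  expect_error(pvt_encode("AAAA", character(0), rep(1, 4)), "empty")
  expect_error(pvt_encode("AAAA", "AAAAA", rep(1, 4)), "same length")
  expect_error(pvt_encode("AAAA", "AAAA", rep(1, 3)), "length")
})
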