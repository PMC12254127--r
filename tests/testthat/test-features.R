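seq_from_proto <- function(proto) {
  paste0(proto, "TGG", strrep("G", 36))
}

test_that("exactly 175 uniquely named features, stable across calls", {
  nms <- feature_names()
  expect_length(nms, 175L)
  expect_equal(anyDuplicated(nms), 0L)

  fv <- extract_features(seq_from_proto(random_protospacer()))
  expect_length(fv, 175L)
  expect_identical(names(fv), nms)
  expect_identical(names(extract_features(seq_from_proto(random_protospacer()))),
                   nms)
})

test_that("a poly-G protospacer has the forced composition values", {
  fv <- extract_features(seq_from_proto(strrep("G", 20)))
  expect_equal(unname(fv["GC_content"]), 1)
  expect_equal(unname(fv[c("count_A", "count_C", "count_G", "count_T")]),
               c(0, 0, 20, 0))
  expect_equal(unname(fv["count_GG"]), 19)
  expect_equal(unname(fv["count_GGG"]), 18)
  expect_equal(unname(fv["count_AT"]), 0)
})

test_that("k-mer count groups satisfy the window-sum identities", {
  set.seed(8)
  mono <- paste0("count_", c("A", "C", "G", "T"))
  di <- grep("^count_[ACGT]{2}$", feature_names(), value = TRUE)
  tri <- grep("^count_[ACGT]{3}$", feature_names(), value = TRUE)
  for (i in 1:10) {
    proto <- random_protospacer()
    fv <- extract_features(seq_from_proto(proto))
    expect_equal(sum(fv[mono]), 20)
    expect_equal(sum(fv[di]), 19)
    expect_equal(sum(fv[tri]), 18)
    expect_equal(unname(fv["GC_content"]),
                 unname((fv["count_C"] + fv["count_G"]) / 20))

    # brute-force recount of a random trimer
    kmer <- sample(tri, 1)
    pat <- sub("count_", "", kmer)
    hits <- sum(vapply(1:18, function(j) substr(proto, j, j + 2) == pat,
                       logical(1)))
    expect_equal(unname(fv[kmer]), hits)
  }
})

test_that("positional indicator group has exactly one active flag per position", {
  set.seed(9)
  for (i in 1:5) {
    proto <- random_protospacer()
    pam_n <- sample(c("A", "C", "G", "T"), 1)
    s <- paste0(proto, pam_n, "GG", strrep("G", 36))
    fv <- extract_features(s)
    for (pos in 1:21) {
      block <- fv[paste0("Pos_", pos, "_", c("A", "C", "G", "T"))]
      expect_equal(sum(block), 1)
      ch <- substr(s, pos, pos)
      expect_equal(unname(fv[paste0("Pos_", pos, "_", ch)]), 1)
    }
  }
})

test_that("'N' in the protospacer errors by default, zero-fills when asked", {
  s <- paste0(strrep("A", 10), "N", strrep("A", 9), "TGG", strrep("G", 36))
  expect_error(extract_features(s), "N")
  expect_warning(fv <- extract_features(s, on_n = "zero"), "zero-filled")
  expect_length(fv, 175L)
  expect_equal(unname(fv["count_A"]), 0)
  expect_equal(unname(fv["Pos_11_A"]), 0) # the N position has no active flag
  expect_equal(sum(fv[paste0("Pos_11_", c("A", "C", "G", "T"))]), 0)
})

test_that("nearest-neighbour Tm matches an independent table-lookup oracle", {
  # independent re-summation with explicitly enumerated SantaLucia stacks
  oracle_tm <- function(seq, ct = 5e-8, na = 0.05) {
    H <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
    S <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    dh <- 0; ds <- 0
    for (i in 1:(n - 1)) {
      st <- paste0(ch[i], ch[i + 1])
      dh <- dh + H[[st]]; ds <- ds + S[[st]]
    }
    for (e in c(ch[1], ch[n])) {
      if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    selfc <- identical(paste(rev(unname(comp[ch])), collapse = ""), seq)
    if (selfc) ds <- ds - 1.4
    ds <- ds + 0.368 * (n - 1) * log(na)
    dh * 1000 / (ds + 1.987 * log(ct / ifelse(selfc, 1, 4))) - 273.15
  }
  set.seed(10)
  for (i in 1:10) {
    s <- random_protospacer()
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-12)
  }
  # self-complementary duplex takes the symmetry branch
  expect_equal(melting_temperature("GAATTC"), oracle_tm("GAATTC"),
               tolerance = 1e-12)
})

test_that("Tm responds to GC content and respects duplex symmetry", {
  expect_gt(melting_temperature("GCGCGCGCGC"), melting_temperature("ATATATATAT"))
  # GC enrichment at fixed length is monotone
  tms <- vapply(0:10, function(k) {
    melting_temperature(paste0(strrep("G", k), strrep("A", 10 - k)))
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
  # a duplex and its reverse complement share stacks, hence Tm
  set.seed(11)
  for (i in 1:5) {
    s <- random_protospacer()
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    expect_equal(melting_temperature(s), melting_temperature(rc),
                 tolerance = 1e-9)
  }
  expect_error(melting_temperature("A"), "at least 2")
  expect_error(melting_temperature("ACGN"), "A,C,G,T")
})

test_that("feature matrices stack per-record descriptors", {
  recs <- fixture_records(n_guides = 3)$records
  mat <- extract_feature_matrix(recs)
  expect_equal(dim(mat), c(6L, 175L))
  expect_identical(colnames(mat), feature_names())
  expect_equal(mat[2, ], extract_features(recs$sequence[2]))
})
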