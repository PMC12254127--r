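test_that("median split puts strictly-above-median records in the high group", {
  recs <- data.frame(sequence = rep(strrep("A", 59), 4),
                     activity = c(0.1, 0.2, 0.3, 0.4), variant = "v")
  gr <- median_split(recs)
  expect_equal(gr$threshold, 0.25)
  expect_setequal(gr$high$activity, c(0.3, 0.4))
  expect_setequal(gr$low$activity, c(0.1, 0.2))

  # odd n with distinct values: the median element itself goes low
  recs5 <- data.frame(sequence = rep(strrep("A", 59), 5),
                      activity = 1:5 / 10, variant = "v")
  gr5 <- median_split(recs5)
  expect_equal(nrow(gr5$high), 2L)
  expect_true(all(gr5$high$activity > gr5$threshold))
  expect_true(all(gr5$low$activity <= gr5$threshold))

  expect_error(median_split(recs[1, ]), "at least 2")
  const <- recs; const$activity <- 0.5
  expect_error(median_split(const), "empty")
})

test_that("group sizes are balanced up to tie mass at the median", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    act <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    recs <- data.frame(sequence = rep(strrep("A", 59), n), activity = act,
                       variant = "v")
    gr <- tryCatch(median_split(recs), error = function(e) NULL)
    if (is.null(gr)) next
    ties <- sum(act == gr$threshold)
    # ties at the median all fall to the low group, so the imbalance is
    # bounded by twice the tie mass (plus one for odd n)
    expect_lte(abs(nrow(gr$high) - nrow(gr$low)), 2L * ties + 1L)
    expect_equal(nrow(gr$high) + nrow(gr$low), n)
  }
})

test_that("identical foreground and background give near-zero, non-significant scores", {
  set.seed(13)
  seqs <- paste0(random_protospacer(40), "TGG", strrep("G", 36))
  recs <- data.frame(sequence = rep(seqs, 2),
                     activity = rep(c(1, 0), each = 40), variant = "v")
  gr <- median_split(recs)
  enr <- enrichment(gr)
  # every foreground frequency equals its background frequency
  expect_true(all(abs(enr$scores) < 1))
  expect_true(all(abs(enr$scores) < enr$significance_threshold))
})

test_that("an extreme planted nucleotide scores strongly positive and significant", {
  set.seed(14)
  fg <- paste0("G", random_protospacer(60, len = 19), "TGG", strrep("G", 36))
  bg <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               random_protospacer(60, len = 19), "TGG", strrep("G", 36))
  recs <- data.frame(sequence = c(fg, bg),
                     activity = rep(c(1, 0), each = 60), variant = "v")
  enr <- enrichment(median_split(recs))
  expect_gt(enr$scores["1", "G"], enr$significance_threshold)
  top <- top_enriched(enr, 1)
  expect_equal(top$position, 1L)
  expect_equal(top$nucleotide, "G")
})

test_that("swapping foreground and background flips enrichment to depletion", {
  set.seed(15)
  fg <- paste0("G", random_protospacer(50, len = 19), "TGG", strrep("G", 36))
  bg <- paste0(rep(c("A", "T"), 25), random_protospacer(50, len = 19), "TGG",
               strrep("G", 36))
  recs_fwd <- data.frame(sequence = c(fg, bg),
                         activity = rep(c(1, 0), each = 50), variant = "v")
  recs_rev <- data.frame(sequence = c(fg, bg),
                         activity = rep(c(0, 1), each = 50), variant = "v")
  e_fwd <- suppressMessages(enrichment(median_split(recs_fwd)))
  e_rev <- suppressMessages(enrichment(median_split(recs_rev)))
  expect_gt(e_fwd$scores["1", "G"], 0)
  expect_lt(e_rev$scores["1", "G"], 0)
})

test_that("scores grow with foreground count at fixed background", {
  make_enr <- function(k) {
    # k of 40 foreground guides carry G at position 1; background uniform
    first <- c(rep("G", k), sample(c("A", "C", "T"), 40 - k, replace = TRUE))
    fg <- paste0(first, random_protospacer(40, len = 19), "TGG", strrep("G", 36))
    set.seed(99) # same background every time
    bg <- paste0(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 random_protospacer(40, len = 19), "TGG", strrep("G", 36))
    recs <- data.frame(sequence = c(fg, bg),
                       activity = rep(c(1, 0), each = 40), variant = "v")
    suppressMessages(enrichment(median_split(recs)))$scores["1", "G"]
  }
  set.seed(16)
  scores <- vapply(c(15, 25, 35), make_enr, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("planted simulation motifs surface as the top enrichment cells", {
  sim <- generate_dataset(sim_config(n_guides = 400, variants = "WT-SpCas9",
                                     noise_sd = 0, seed = 17))
  enr <- enrichment(median_split(sim$records), positions = 1:20)
  motif <- sim$truth$motif
  top <- top_enriched(enr, length(motif$pos))
  expect_setequal(paste(top$position, top$nucleotide),
                  paste(motif$pos, motif$nt))
  expect_true(all(top$score > 0))
})

test_that("enrichment matrices export to CSV", {
  set.seed(18)
  seqs <- paste0(random_protospacer(30), "TGG", strrep("G", 36))
  recs <- data.frame(sequence = seqs, activity = runif(30), variant = "v")
  enr <- suppressMessages(enrichment(median_split(recs)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_enrichment_csv(enr, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(dim(back), c(23L, 5L))
  expect_equal(back$position, 1:23)
})
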