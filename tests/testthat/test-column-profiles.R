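# Naive term-by-term entropy oracle used throughout: independent of the
# package's implementation path.
naive_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  s <- 0
  for (pi in p) s <- s - pi * log(pi)
  s
}

test_that("shannon_entropy matches hand-derived and closed-form values", {
  expect_equal(shannon_entropy(c(Y = 27)), 0)
  expect_equal(shannon_entropy(c(A = 5, C = 5, D = 5, E = 5)), log(4))
  # 20 Tyr / 7 Phe in 27 sequences, value frozen from the naive summation
  expect_equal(shannon_entropy(c(Y = 20, F = 7)), 0.572280698802, tolerance = 1e-10)
  expect_equal(conservation_score(shannon_entropy(c(Y = 20, F = 7)), 20),
               0.808968009640, tolerance = 1e-10)
  expect_error(shannon_entropy(c(Y = 0)), "all-gap")
})

test_that("entropy agrees with the naive oracle on random columns", {
  set.seed(42)
  for (rep in 1:200) {
    counts <- table(factor(sample(AA_ALPHABET, 27, replace = TRUE),
                           levels = AA_ALPHABET))
    counts <- counts[counts > 0]
    counts <- stats::setNames(as.integer(counts), names(counts))
    S <- shannon_entropy(counts)
    expect_equal(S, naive_entropy(counts), tolerance = 1e-12)
    C <- conservation_score(S, 20)
    expect_gte(C, 0); expect_lte(C, 1)
  }
})

test_that("entropy is invariant to sequence order and residue relabeling", {
  aln <- gen_alignment(alignment_spec(10, lapply(1:30, function(i) {
    column_spec(stats::setNames(c(4, 3, 2, 1), sample(AA_ALPHABET, 4)))
  }), seed = 7))$alignment
  prof <- profile_alignment(aln)
  shuffled <- aln[sample(nrow(aln)), ]
  class(shuffled) <- class(aln)
  expect_equal(profile_alignment(shuffled)$entropy, prof$entropy)
  # relabeling: swap two residue letters alignment-wide
  swapped <- aligned_seqs(aln$seq_id, chartr("AW", "WA", aln$sequence))
  expect_equal(profile_alignment(swapped)$entropy, prof$entropy)
})

test_that("doubling every sequence leaves S, C and mean hydropathy unchanged", {
  aln <- gen_alignment(alignment_spec(9, lapply(1:12, function(i) {
    column_spec(stats::setNames(c(5, 3, 1), sample(AA_ALPHABET, 3)))
  }), seed = 3))$alignment
  doubled <- aligned_seqs(c(aln$seq_id, paste0(aln$seq_id, "_dup")),
                          rep(aln$sequence, 2))
  p1 <- profile_alignment(aln)
  p2 <- profile_alignment(doubled)
  expect_equal(p2$entropy, p1$entropy)
  expect_equal(p2$conservation, p1$conservation)
  expect_equal(p2$hydropathy_mean, p1$hydropathy_mean)
  expect_equal(p2$hydropathy_sum, 2 * p1$hydropathy_sum)
})

test_that("conservation score is strictly decreasing in entropy for fixed m", {
  S <- seq(0, log(20), length.out = 50)
  C <- conservation_score(S, 20)
  expect_true(all(diff(C) < 0))
  expect_equal(conservation_score(0, 20), 1)
  expect_equal(conservation_score(log(20), 20), 0)
  expect_error(conservation_score(log(20) + 0.1, 20), "out of range")
})

test_that("conservation bins partition [0,1] with the stated boundaries", {
  expect_equal(bin_conservation(0.45), "high")
  expect_equal(bin_conservation(0.40), "moderate")
  expect_equal(bin_conservation(0.35), "moderate")
  expect_equal(bin_conservation(0.34), "low")
  grid <- seq(0, 1, by = 0.01)
  bins <- bin_conservation(grid)
  expect_true(all(bins %in% c("high", "moderate", "low")))
  expect_equal(length(bins), length(grid))
})

test_that("the gap rule zeroes exactly the columns with more than one gap", {
  rec <- tibble::tibble(conservation = c(0.9, 0.9, 0.9),
                        bin = c("high", "high", "high"),
                        gap_count = c(0L, 1L, 2L))
  out <- apply_gap_rule(rec)
  expect_equal(out$conservation, c(0.9, 0.9, 0))
  expect_equal(out$bin, c("high", "high", "gap_zeroed"))
})

test_that("column hydropathy matches hand evaluation", {
  scale <- hydrophobicity_scale()
  allG <- column_counts(aligned_seqs(letters[1:4], rep("G", 4)), 1)
  expect_equal(column_hydropathy(allG, scale)$hydropathy_sum, 0)
  allI <- column_counts(aligned_seqs(letters[1:5], rep("I", 5)), 1)
  expect_equal(column_hydropathy(allI, scale)$hydropathy_mean, scale[["I"]])
  # mixed column {W:2, T:3}: mean = (2*3.4 + 3*0.4) / 5 = 1.6
  mix <- column_counts(aligned_seqs(letters[1:5],
                                    c("W", "W", "T", "T", "T")), 1)
  h <- column_hydropathy(mix, scale)
  expect_equal(h$hydropathy_sum, 2 * 3.4 + 3 * 0.4)
  expect_equal(h$hydropathy_mean, 1.6)
})

test_that("hydropathy mean stays within the scale's range", {
  set.seed(11)
  scale <- hydrophobicity_scale()
  for (rep in 1:50) {
    counts <- table(factor(sample(AA_ALPHABET, 20, replace = TRUE),
                           levels = AA_ALPHABET))
    counts <- stats::setNames(as.integer(counts), names(counts))
    prof <- structure(list(counts = counts[counts > 0], n_obs = 20),
                      class = "column_profile")
    h <- column_hydropathy(prof, scale)
    expect_gte(h$hydropathy_mean, min(scale))
    expect_lte(h$hydropathy_mean, max(scale))
  }
})

test_that("position classification follows the neutral-then-hydropathy order", {
  cfg <- profile_config()
  # 80% glycine column: neutral regardless of hydropathy
  expect_equal(classify_position("high", 0.1, 0.8, cfg), "neutral")
  # all-isoleucine: hydrophobic; all-aspartate: hydrophilic
  expect_equal(classify_position("high", nozaki_tanford[["I"]], 0, cfg),
               "hydrophobic")
  expect_equal(classify_position("high", nozaki_tanford[["D"]], 0, cfg),
               "hydrophilic")
  # low/gap-zeroed columns are never classified
  expect_true(is.na(classify_position("low", 3, 0, cfg)))
  expect_true(is.na(classify_position("gap_zeroed", 3, 0, cfg)))
})

test_that("shipped Nozaki-Tanford values match the AAindex reference", {
  skip_if_not_installed("seqinr")
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  ref <- e$aaindex[["NOZY710101"]]$I
  ref1 <- stats::setNames(as.numeric(ref),
                          vapply(names(ref), function(x) {
                            suppressWarnings(bio3d::aa321(toupper(x)))
                          }, ""))
  expect_equal(nozaki_tanford[names(ref1)], ref1[names(ref1)],
               tolerance = 1e-12)
})

test_that("profile_alignment handles uniform and fully gapped inputs", {
  ident <- aligned_seqs(paste0("s", 1:5), rep("YRDEG", 5))
  prof <- profile_alignment(ident)
  expect_true(all(prof$conservation == 1))
  expect_true(all(prof$bin == "high"))

  gappy <- aligned_seqs(paste0("s", 1:5),
                        c("A-C-E", "A-C-E", "A---E", "--C--", "-----"))
  pg <- profile_alignment(gappy)
  expect_true(all(pg$conservation == 0))
  expect_true(all(pg$bin == "gap_zeroed"))
})

test_that("the conservation histogram counts every column once", {
  aln <- synthetic_cid_alignment(seed = 5)$alignment
  prof <- profile_alignment(aln)
  hist <- conservation_histogram(prof)
  expect_equal(sum(hist$n_columns), nrow(prof))
})
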