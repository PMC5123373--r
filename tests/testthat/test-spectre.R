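test_that("coverage normalization maps counts to [0, 1] by the maximum", {
  expect_equal(normalize_coverage(c(0, 2, 4))$values, c(0, 0.5, 1))
  expect_equal(normalize_coverage(c(5, 5, 5))$values, c(1, 1, 1))
  zero <- normalize_coverage(c(0, 0, 0))
  expect_false(zero$scorable)
  expect_equal(zero$values, c(0, 0, 0))
  expect_error(normalize_coverage(numeric(0)), "length")
})

test_that("coherence identities: self-coherence 1, degenerate constant 0", {
  spec <- window_spec()
  periodic <- rep(c(1, 0, 0), 10)
  expect_equal(as.numeric(coherence_at_frequency(periodic, periodic, spec)), 1)
  # identical signals cohere at every bin carrying power
  set.seed(1)
  x <- runif(30)
  for (bin in 1:5) {
    expect_equal(as.numeric(coherence_at_frequency(x, x, spec, bin = bin)), 1,
                 tolerance = 1e-12)
  }
  # constant signal has no power at the codon bin
  deg <- coherence_at_frequency(rep(1, 30), ideal_signal(30), spec)
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  # periodic coverage vs the ideal reference: full coherence in any frame
  expect_equal(as.numeric(coherence_at_frequency(periodic, ideal_signal(30, 1),
                                                 spec)), 1)
})

test_that("noisy-signal coherence matches the direct-DFT oracle", {
  spec <- window_spec()
  set.seed(7)
  for (rep in 1:20) {
    x <- rep(c(1, 0, 0), 10) + rnorm(30, sd = 0.2)
    y <- ideal_signal(30)
    got <- as.numeric(coherence_at_frequency(x, y, spec))
    expect_gt(got, 0)
    expect_lt(got, 1)
    expect_equal(got, oracle_welch_coherence(x, y), tolerance = 1e-9)
  }
})

test_that("windowed score enumerates windows per the step rule", {
  # exact periodic coverage, length 36: windows start at 0, 3, 6
  sc <- spectre_score(normalize_coverage(rep(c(1, 0, 0), 12)))
  expect_equal(sc$n_windows, 3L)
  expect_equal(sc$window_scores$window_start, c(0L, 3L, 6L))
  expect_equal(sc$window_scores$coherence, rep(1, 3))
  expect_equal(sc$score, 1)
  # M = floor((|C| - N)/L) + 1 against explicit enumeration
  set.seed(3)
  for (i in 1:50) {
    len <- sample(30:400, 1)
    L <- sample(1:9, 1)
    spec <- window_spec(step = L)
    v <- runif(len)
    sc <- spectre_score(normalize_coverage(v), spec)
    expect_equal(sc$n_windows, floor((len - 30) / L) + 1)
    expect_equal(sc$window_scores$window_start,
                 seq(0L, len - 30L, by = L))
  }
})

test_that("too-short and empty regions are unscorable with a reason", {
  sc <- spectre_score(normalize_coverage(runif(29)))
  expect_false(sc$scorable)
  expect_identical(sc$reason, "too short")
  expect_true(is.na(sc$score))
  sc <- spectre_score(normalize_coverage(rep(0, 100)))
  expect_identical(sc$reason, "no coverage")
})

test_that("scores are scale-invariant, bounded, and frame-consistent", {
  set.seed(11)
  v <- rpois(120, 3)
  v[v < 0] <- 0
  base <- spectre_score(normalize_coverage(v))
  for (k in c(0.5, 2, 17)) {
    expect_equal(spectre_score(normalize_coverage(v * k))$score, base$score)
  }
  expect_true(all(base$window_scores$coherence >= 0 &
                  base$window_scores$coherence <= 1))
  # pure periodic coverage: matching frame never scores below shifted frames
  periodic <- rep(c(1, 0, 0), 40)
  s0 <- spectre_score(normalize_coverage(periodic), frame_offset = 0)$score
  for (f in 1:2) {
    expect_gte(s0, spectre_score(normalize_coverage(periodic),
                                 frame_offset = f)$score)
  }
})

test_that("pipeline score equals the independent reimplementation", {
  set.seed(21)
  for (i in 1:25) {
    len <- sample(30:300, 1)
    v <- runif(len)
    expect_equal(spectre_score(normalize_coverage(v))$score,
                 oracle_windowed_score(v), tolerance = 1e-9)
  }
})

test_that("within-codon shuffling does not increase the expected score", {
  set.seed(5)
  shuffle_codons <- function(v) {
    for (c0 in seq(1, length(v) - 2, by = 3)) {
      v[c0:(c0 + 2)] <- v[c0 + sample(0:2)]
    }
    v
  }
  n_rep <- 40
  orig <- shuf <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    counts <- rep(c(1, 0, 0), 40) * rpois(120, 5)
    orig[r] <- spectre_score(normalize_coverage(counts))$score
    shuf[r] <- spectre_score(normalize_coverage(shuffle_codons(counts)))$score
  }
  expect_gte(mean(orig), mean(shuf))
})

test_that("window tracks lift to genomic intervals and conserve width", {
  # each window's genomic pieces must cover exactly that window's
  # transcript coordinates; random coverage gives every window a distinct
  # value to match rows against
  check_lift <- function(model, region) {
    coords <- region_coords(model, region)
    set.seed(13)
    sc <- spectre_score(normalize_coverage(runif(length(coords))))
    trk <- window_track(sc, model, region)
    expect_true(all(diff(trk$start) >= 0))
    for (i in seq_len(sc$n_windows)) {
      rows <- trk[abs(trk$value - sc$window_scores$coherence[i]) < 1e-14, ]
      m <- sc$window_scores$window_start[i]
      covered <- unlist(mapply(function(s, e) seq(s, e - 1), rows$start,
                               rows$end, SIMPLIFY = FALSE))
      expect_setequal(covered, coords[(m + 1):(m + 30)])
      expect_equal(sum(rows$end - rows$start), 30)
    }
  }
  # single exon: windows lift to single intervals of width 30
  single <- toy_model("+")
  trk1 <- window_track(spectre_score(normalize_coverage(runif(60))),
                       single, "CDS")
  expect_true(all(trk1$end - trk1$start == 30))
  # junction-straddling windows split but conserve total width, on both
  # strands; minus strand descends in genomic space as transcript
  # coordinates ascend
  spliced <- transcript_model("txs", "g", "chr1", "+",
                              exons = rbind(c(100L, 120L), c(300L, 360L)),
                              cds = rbind(c(100L, 120L), c(300L, 340L)))
  check_lift(spliced, "CDS")
  minus <- transcript_model("txm", "g", "chr1", "-",
                            exons = rbind(c(100L, 160L), c(300L, 360L)))
  expect_equal(region_coords(minus, "full")[1], 359L)
  check_lift(minus, "full")
})
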