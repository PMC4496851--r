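test_that("nle is the negative common log, with E = mN/2^BS supplementing zeros", {
  expect_equal(nle_weight(make_hit(evalue = 1e-5)), 5.0)
  expect_equal(nle_weight(make_hit(evalue = 1.0)), 0.0)
  # zero E-value, invert policy: 700*log10(2) - log10(300 * 1e6)
  hit <- make_hit(evalue = 0, bitscore = 700, qlen = 300, qend = 100)
  stats <- list(total_residues = 1e6, num_sequences = 3000)
  expect_equal(nle_weight(hit, stats),
               700 * log10(2) - log10(3e8))
  expect_equal(nle_weight(hit, stats), 202.2445, tolerance = 1e-4)
  # fixed cap policy
  expect_equal(nle_weight(hit, stats,
                          metric_config(zero_evalue_policy = "fixed_cap")),
               181)
  expect_error(nle_weight(make_hit(evalue = 0)), "stats")
  expect_error(nle_weight(make_hit(evalue = 2)), "cutoff")
})

test_that("nle under invert_eq1 agrees with -log10(E) on tables built from the identity", {
  set.seed(7)
  bits <- runif(50, 30, 550)
  qlen <- sample(50:500, 50, replace = TRUE)
  N <- 1e5
  ev <- 10^(log10(qlen) + log10(N) - bits * log10(2))
  hits <- make_hit()[rep(1, 50), ]
  hits$evalue <- pmin(ev, 1)
  hits$bitscore <- bits
  hits$qlen <- qlen
  keep <- hits$evalue > 1e-180 & hits$evalue <= 1
  direct <- nle_weight(hits[keep, ])
  via_identity <- hits$bitscore[keep] * log10(2) - log10(hits$qlen[keep] * N)
  expect_equal(direct, via_identity, tolerance = 1e-9)
})

test_that("bit score weight is a passthrough of column 12", {
  expect_equal(bit_score_weight(make_hit(bitscore = 200)), 200)
  expect_equal(bit_score_weight(make_hit(bitscore = 0.5)), 0.5)
})

test_that("bsr divides by the smaller self bit score, falling back to 2*length", {
  hit <- make_hit(bitscore = 200)
  expect_equal(bsr_weight(hit, c(q1 = 400, s1 = 500)), 0.5)
  # a self-scored hit against its own SBS gives 1
  self <- make_hit("q1", "q1", bitscore = 412)
  expect_equal(bsr_weight(self, c(q1 = 412)), 1.0)
  # fallback: no SBS entries, min length 100 -> proxy 200
  hit2 <- make_hit(bitscore = 100, qlen = 100, slen = 150)
  expect_equal(bsr_weight(hit2, setNames(numeric(0), character(0))), 0.5)
  hit3 <- hit2
  hit3$qlen <- NA
  expect_error(bsr_weight(hit3, setNames(numeric(0), character(0))),
               "neither")
})

test_that("anchored length adds the shorter overhang on each side", {
  # end-to-end alignment: no overhangs
  expect_equal(anchored_length(make_hit()), 100)
  # fragment inside a full-length sequence: overhangs one-sided only
  inside <- make_hit(length = 100, qstart = 101, qend = 200, sstart = 1,
                     send = 100, qlen = 200, slen = 100)
  expect_equal(anchored_length(inside), 100)
  # opposing-end overlap: both overhangs point away, neither is shared
  opposing <- make_hit(length = 60, qstart = 61, qend = 120, sstart = 1,
                       send = 60, qlen = 120, slen = 120)
  expect_equal(anchored_length(opposing), 60)
  expect_equal(bal_weight(transform(opposing, bitscore = 120)), 2.0)
  # short domain hit between two long sequences: overhangs dominate
  domain <- make_hit(length = 50, qstart = 151, qend = 200, sstart = 151,
                     send = 200, qlen = 350, slen = 350, bitscore = 100)
  expect_equal(anchored_length(domain), 350)
  expect_equal(bal_weight(domain), 100 / 350)
})

test_that("compute_edge_weights bundles the four metrics consistently", {
  fx <- three_scenario_fixture()
  hit <- make_hit(evalue = 1e-50, bitscore = 200)
  ew <- compute_edge_weights(hit, setNames(numeric(0), character(0)),
                             fx$stats)
  expect_equal(ew$bs, 200)
  expect_equal(ew$nle, 50)
  expect_equal(ew$bsr, 200 / 200)  # SBS proxy 2*100
  expect_equal(ew$bal, 2.0)
  expect_equal(ew$id1, "q1")
  expect_equal(ew$id2, "s1")
  # an unfiltered hit violates the contract
  expect_error(compute_edge_weights(make_hit(evalue = 1e-3),
                                    fx$self_scores, fx$stats),
               "cutoff")
  # orientation does not change the weights when scores tie
  flip <- make_hit("s1", "q1", evalue = 1e-50, bitscore = 200)
  ew2 <- compute_edge_weights(flip, setNames(numeric(0), character(0)),
                              fx$stats)
  expect_equal(ew2[, c("id1", "id2", "bs", "nle", "bsr", "bal")],
               ew[, c("id1", "id2", "bs", "nle", "bsr", "bal")])
})

test_that("each metric increases strictly with bit score", {
  base <- make_hit(bitscore = 100, evalue = 1e-20)
  higher <- make_hit(bitscore = 150, evalue = 1e-30)
  ss <- c(q1 = 400, s1 = 400)
  stats <- list(total_residues = 1e5, num_sequences = 10)
  for (f in list(bit_score_weight,
                 function(h) nle_weight(h, stats),
                 function(h) bsr_weight(h, ss),
                 bal_weight)) {
    expect_gt(f(higher), f(base))
  }
})

test_that("bal never exceeds bs, and bsr is bounded by bs", {
  set.seed(11)
  for (i in 1:25) {
    L <- sample(60:400, 2)
    alen <- sample(30:min(L), 1)
    qs <- sample(seq_len(L[1] - alen + 1), 1)
    ss <- sample(seq_len(L[2] - alen + 1), 1)
    hit <- make_hit(length = alen, qstart = qs, qend = qs + alen - 1,
                    sstart = ss, send = ss + alen - 1,
                    bitscore = runif(1, 25, 2 * alen),
                    evalue = 10^runif(1, -60, -6), qlen = L[1], slen = L[2])
    expect_lte(bal_weight(hit), bit_score_weight(hit))
    expect_lte(bsr_weight(hit, setNames(numeric(0), character(0))),
               bit_score_weight(hit))
  }
})

test_that("bsr and bal compress the scale of the three canonical scenarios", {
  fx <- three_scenario_fixture()
  ew <- compute_edge_weights(fx$hits, fx$self_scores, fx$stats)
  cvs <- vapply(metric_names(), function(m) coefficient_of_variation(ew[[m]]),
                numeric(1))
  expect_lt(cvs[["bsr"]], cvs[["bs"]])
  expect_lt(cvs[["bsr"]], cvs[["nle"]])
  expect_lt(cvs[["bal"]], cvs[["bs"]])
  expect_lt(cvs[["bal"]], cvs[["nle"]])
})
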