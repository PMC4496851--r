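test_that("scheme codes expand alphabetically with repeat-then-truncate", {
  expect_equal(expand_scheme("1323", c("org1", "org2", "org3", "org4")),
               c(org1 = 1L, org2 = 3L, org3 = 2L, org4 = 3L))
  # shorter code repeats: "12" over 5 organisms acts as "12121"
  expect_equal(unname(expand_scheme("12", paste0("org", 1:5))),
               c(1L, 2L, 1L, 2L, 1L))
  # longer code truncates
  expect_equal(unname(expand_scheme("321", c("a", "b"))), c(3L, 2L))
  # organisms are sorted before mapping
  expect_equal(expand_scheme("12", c("zeta", "alpha")),
               c(alpha = 1L, zeta = 2L))
  expect_error(expand_scheme("102", c("a", "b", "c")), "digit 0")
  expect_error(fragmentation_scheme("0"), "digit 0")
  expect_error(fragmentation_scheme(""), "digit string")
})

test_that("the half-split scheme maps onto the eleven ECK organisms as published", {
  eck <- eck_composition()
  pieces <- expand_scheme("11122222112", eck$organism)
  expect_equal(unname(pieces[c("Anopheles gambiae", "Arabidopsis thaliana",
                               "Caenorhabditis elegans",
                               "Saccharomyces cerevisiae",
                               "Schizosaccharomyces pombe")]),
               rep(1L, 5))
  expect_equal(unname(pieces[c("Chlamydomonas reinhardtii",
                               "Ciona intestinalis",
                               "Drosophila melanogaster",
                               "Encephalitozoon cuniculi", "Homo sapiens",
                               "Toxoplasma gondii")]),
               rep(2L, 6))
})

test_that("label assignment follows organisms, and shuffling preserves group multisets", {
  db <- toy_db(lengths = rep(100, 8),
               organisms = rep(c("orgA", "orgB"), 4),
               groups = rep(c("g1", "g2"), each = 4))
  ordered <- assign_labels(db, fragmentation_scheme("12"))
  expect_equal(unname(ordered[db$organism == "orgA"]), rep(1L, 4))
  expect_equal(unname(ordered[db$organism == "orgB"]), rep(2L, 4))
  # all-ones scheme labels everything 1
  expect_equal(unname(assign_labels(db, fragmentation_scheme("1"))), rep(1L, 8))
  sch <- fragmentation_scheme("12", label_mode = "shuffled", seed = 4)
  shuffled <- assign_labels(db, sch)
  for (g in c("g1", "g2")) {
    expect_equal(sort(shuffled[db$group == g]), sort(ordered[db$group == g]),
                 ignore_attr = TRUE)
  }
  expect_identical(assign_labels(db, sch), assign_labels(db, sch))
})

test_that("even splitting gives near-equal pieces with remainder leftmost", {
  db <- toy_db(lengths = c(100, 100, 99), organisms = c("a", "a", "a"),
               groups = c("g1", "g1", "g1"))
  labels <- setNames(c(2L, 3L, 1L), db$id)
  fr <- fragment_sequences(db, labels, "even")
  lens <- split(fr$fragments$end - fr$fragments$start + 1L,
                fr$fragments$parent_id)
  expect_equal(unname(lens[[db$id[1]]]), c(50L, 50L))
  expect_equal(unname(lens[[db$id[2]]]), c(34L, 33L, 33L))
  # label 1: unchanged record with original id and full coordinates
  intact <- fr$fragments[fr$fragments$parent_id == db$id[3], ]
  expect_equal(intact$fragment_id, db$id[3])
  expect_equal(c(intact$start, intact$end), c(1L, 99L))
  # precondition: pieces must fit
  expect_error(fragment_sequences(db, setNames(c(2L, 3L, 200L), db$id), "even"),
               db$id[3])
})

test_that("fragments tile their parent exactly, in both modes", {
  set.seed(19)
  db <- toy_db(lengths = sample(40:300, 12),
               organisms = rep(c("orgA", "orgB", "orgC"), 4),
               groups = rep(c("g1", "g2", "g3", "g4"), each = 3))
  db$seq <- vapply(db$length, function(L)
    paste(sample(LETTERS[1:20], L, replace = TRUE), collapse = ""),
    character(1))
  for (mode in c("even", "random")) {
    labels <- setNames(sample(1:3, nrow(db), replace = TRUE), db$id)
    fr <- fragment_sequences(db, labels, mode, seed = 7)
    f <- fr$fragments
    for (pid in db$id) {
      mine <- f[f$parent_id == pid, ]
      mine <- mine[order(mine$piece_index), ]
      expect_equal(mine$piece_count, rep(nrow(mine), nrow(mine)))
      expect_equal(mine$start[1], 1L)
      expect_equal(mine$end[nrow(mine)], db$length[db$id == pid])
      if (nrow(mine) > 1) {
        expect_equal(mine$start[-1], head(mine$end, -1) + 1L)
      }
      # sum of fragment lengths equals the parent length
      expect_equal(sum(mine$end - mine$start + 1L),
                   db$length[db$id == pid])
      # concatenating fragment sequences reconstructs the parent
      expect_equal(paste(fr$db$seq[match(mine$fragment_id, fr$db$id)],
                         collapse = ""),
                   db$seq[db$id == pid])
    }
    if (mode == "random") {
      expect_true(all(fr$db$length >= 10))
    }
  }
})

test_that("random breakpoints respect the minimum fragment length and the seed", {
  db <- toy_db(lengths = 61, organisms = "a", groups = "g")
  labels <- setNames(2L, db$id)
  fr1 <- fragment_sequences(db, labels, "random", seed = 3,
                            min_fragment_length = 30)
  expect_true(all(fr1$db$length >= 30))
  fr2 <- fragment_sequences(db, labels, "random", seed = 3,
                            min_fragment_length = 30)
  expect_identical(fr1$fragments, fr2$fragments)
  expect_error(fragment_sequences(db, setNames(3L, db$id), "random",
                                  min_fragment_length = 30),
               "pieces")
})

test_that("fragment maps round-trip through the sidecar TSV", {
  db <- toy_db()
  fr <- fragment_sequences(db, setNames(c(2L, 1L, 3L), db$id), "even")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_map(fr$fragments, path)
  expect_equal(read_fragment_map(path), fr$fragments)
})

test_that("projecting onto intact parents reproduces the input table", {
  b <- generate_benchmark(synthetic_config(num_groups = 6, seed = 2))
  fr <- fragment_database(b$db, fragmentation_scheme("1"))
  proj <- project_hits(b$best, b$self_scores, fr$fragments, b$stats,
                       recompute_evalue = FALSE)
  pairs <- proj[proj$qseqid != proj$sseqid, ]
  pairs <- pairs[order(pairs$qseqid, pairs$sseqid), ]
  want <- b$best[order(b$best$qseqid, b$best$sseqid), ]
  expect_equal(pairs, want, ignore_attr = TRUE)
  # self hits reproduce the parent SBS (fraction 1)
  selfs <- extract_self_scores(proj)
  expect_equal(selfs[names(b$self_scores)], b$self_scores)
})

test_that("an aligned midpoint split yields two half-score hits and no bridges", {
  db <- toy_db(lengths = c(100, 100), organisms = c("a", "b"),
               groups = c("g1", "g1"))
  hit <- make_hit(db$id[1], db$id[2], length = 100, bitscore = 300,
                  evalue = 1e-60)
  selfs <- setNames(c(200, 200), db$id)
  fr <- fragment_sequences(db, setNames(c(2L, 2L), db$id), "even")
  stats <- database_stats(db)
  proj <- project_hits(hit, selfs, fr$fragments, stats)
  cross <- proj[proj$qseqid != proj$sseqid, ]
  expect_equal(nrow(cross), 2L)
  expect_equal(cross$length, c(50, 50))
  expect_equal(cross$bitscore, c(150, 150))
  # both hits pair fragments of the same rank; none cross the midpoint
  expect_equal(substr(cross$qseqid, nchar(cross$qseqid) - 4, 100),
               substr(cross$sseqid, nchar(cross$sseqid) - 4, 100))
  expect_equal(cross$qstart, c(1, 1))
  expect_equal(cross$qend, c(50, 50))
})

test_that("offset breakpoints create an opposing-end bridge hit", {
  db <- toy_db(lengths = c(100, 100), organisms = c("a", "b"),
               groups = c("g1", "g1"))
  hit <- make_hit(db$id[1], db$id[2], length = 100, bitscore = 300,
                  evalue = 1e-60)
  selfs <- setNames(c(200, 200), db$id)
  # manual breakpoints: parent 1 split at 50, parent 2 split at 80
  fragments <- data.frame(
    fragment_id = c("p1_f1of2", "p1_f2of2", "p2_f1of2", "p2_f2of2"),
    parent_id = rep(db$id, each = 2),
    piece_index = c(1L, 2L, 1L, 2L), piece_count = 2L,
    start = c(1L, 51L, 1L, 81L), end = c(50L, 100L, 80L, 100L),
    organism = rep(db$organism, each = 2), group = "g1",
    stringsAsFactors = FALSE
  )
  proj <- project_hits(hit, selfs, fragments, database_stats(db))
  cross <- proj[proj$qseqid != proj$sseqid, ]
  bridge <- cross[cross$qseqid == "p1_f2of2" & cross$sseqid == "p2_f1of2", ]
  expect_equal(nrow(bridge), 1L)
  expect_equal(bridge$length, 30)           # columns 51..80
  expect_equal(bridge$bitscore, 300 * 30 / 100)
  expect_equal(c(bridge$qstart, bridge$qend), c(1, 30))   # start of p1_f2
  expect_equal(c(bridge$sstart, bridge$send), c(51, 80))  # end of p2_f1
  # all projected coordinates stay inside fragment bounds
  expect_true(all(cross$qend <= cross$qlen & cross$send <= cross$slen))
  expect_true(all(cross$qstart >= 1 & cross$sstart >= 1))
  expect_true(all(cross$bitscore <= 300))
})
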