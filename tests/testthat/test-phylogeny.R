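# Presence matrix, Fitch/Sankoff scoring, exact search, bootstrap.

pm <- function(...) {
  m <- rbind(...)
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  m
}

test_that("presence matrix honours detection, absence calls and UNKNOWN", {
  sheet <- tiny_sheet(n_t = 2)
  ids <- c("chr1:1:A>T", "chr1:2:A>T", "chr1:3:A>T")
  obs <- rbind(
    do.call(rbind, lapply(ids, function(v) rbind(
      obs_row(v, "T1", "WES", 150, 45), obs_row(v, "T2", "WES", 150, 45),
      obs_row(v, "BLOOD", "WES", 150, 0)))),
    obs_row("chr1:1:A>T", "M1", "TES1", 4000, 130),  # detected
    obs_row("chr1:2:A>T", "M1", "TES1", 4000, 0),    # tested ABSENT
    obs_row("chr1:3:A>T", "M1", "WES", 150, 0))      # untestable
  ar <- data.frame(variant_id = ids[2:3], target_sample_id = "M1",
                   decision = c("ABSENT", "UNDETERMINED"),
                   stringsAsFactors = FALSE)
  m <- build_presence_matrix(obs, sheet, ar)
  expect_equal(m["T1", ], c(`chr1:1:A>T` = 1L, `chr1:2:A>T` = 1L,
                            `chr1:3:A>T` = 1L))
  expect_equal(unname(m["BLOOD", ]), c(0L, 0L, 0L))
  expect_equal(unname(m["M1", ]), c(1L, 0L, NA))
  bad_sheet <- rbind(sheet,
                     data.frame(sample_id = "T9", patient_id = "P1",
                                region_class = "T", timepoint = "primary",
                                purity = 0.5, assays = "WES"))
  expect_error(build_presence_matrix(obs, bad_sheet, ar), "zero covered")
})

test_that("fitch score counts private mutations and trunk gains", {
  # star-like data: every sample has one private SNV
  m <- pm(BLOOD = c(0, 0, 0), A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))
  star <- ape::read.tree(text = "(BLOOD,A,B,C);")
  expect_equal(fitch_score(star, m), 3L)
  # an all-present column costs one trunk gain on any tree rooted at blood
  m2 <- pm(BLOOD = 0, A = 1, B = 1, C = 1)
  for (t in all_rooted_trees(rownames(m2), "BLOOD"))
    expect_equal(fitch_score(t, m2), 1L)
  expect_error(fitch_score(star, pm(BLOOD = 0, X = 1, Y = 0, Z = 1)),
               "disagree")
})

test_that("fitch score agrees with an independent implementation", {
  set.seed(31)
  for (i in 1:8) {
    m <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12,
                dimnames = list(c("BLOOD", "A", "B", "C", "D"), NULL))
    m["BLOOD", ] <- 0L
    m[sample(length(m), 4)] <- NA
    m["BLOOD", is.na(m["BLOOD", ])] <- 0L
    chm <- matrix(as.character(m), nrow = 5, dimnames = dimnames(m))
    chm[is.na(chm)] <- "?"
    pd <- phangorn::phyDat(chm, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    tr <- ape::rtree(5, tip.label = rownames(m))
    colnames(m) <- paste0("v", 1:12)
    expect_equal(fitch_score(tr, m), as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("nested private mutation sets give a caterpillar of full score", {
  # S1 subset S2 subset S3 on top of a shared trunk
  m <- pm(BLOOD = c(0, 0, 0, 0), S3 = c(1, 0, 0, 1), S2 = c(1, 1, 0, 1),
          S1 = c(1, 1, 1, 1))
  tr <- parsimony_tree(m, "BLOOD")
  expect_equal(attr(tr, "parsimony_score"), 4L)
  expect_equal(sort(ape::node.depth.edgelength(tr)[1:4]), c(0, 2, 3, 4))
  # identical samples collapse to a star with all mutations on the trunk
  m2 <- pm(BLOOD = c(0, 0), A = c(1, 1), B = c(1, 1), C = c(1, 1))
  st <- parsimony_tree(m2, "BLOOD")
  expect_equal(st$Nnode, 2L)
  expect_equal(attr(st, "parsimony_score"), 2L)
  bm <- branch_mutations(st)
  expect_equal(sum(bm$n_gains), 2L)
})

test_that("exact search attains the exhaustive minimum and breaks ties canonically", {
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(rbinom(5 * 15, 1, 0.5), 5, 15,
                dimnames = list(c("BLOOD", "A", "B", "C", "D"),
                                paste0("v", 1:15)))
    m["BLOOD", ] <- 0L
    tr <- parsimony_tree(m, "BLOOD")
    expect_equal(attr(tr, "parsimony_score"), exhaustive_min_score(m, "BLOOD"))
    expect_equal(sum(tr$edge.length), attr(tr, "parsimony_score"))
  }
  expect_error(parsimony_tree(matrix(0L, 15, 3,
    dimnames = list(c(paste0("S", 1:14), "BLOOD"), NULL)), "BLOOD"),
    "12")
})

test_that("UNKNOWN margin cells never add parsimony cost", {
  m <- pm(BLOOD = c(0, 0, 0), T1 = c(1, 1, 0), T2 = c(1, 1, 1),
          M1 = c(1, NA, NA))
  tr <- parsimony_tree(m, "BLOOD")
  expect_equal(attr(tr, "parsimony_score"), 3L)
})

test_that("bootstrap is seeded, confident on clean data, split on conflict", {
  # fully compatible matrix, >= 20 characters per informative branch
  m <- pm(BLOOD = rep(0, 60),
          T1 = rep(c(1, 1, 0), each = 20),
          T2 = rep(c(1, 1, 1), each = 20),
          T3 = rep(c(1, 0, 0), each = 20))
  bt <- bootstrap_support(m, "BLOOD", n_replicates = 200, seed = 9)
  supp <- as.integer(bt$node.label[nzchar(bt$node.label)])
  expect_true(all(supp >= 99))
  bt2 <- bootstrap_support(m, "BLOOD", n_replicates = 200, seed = 9)
  expect_identical(bt$node.label, bt2$node.label)
  # two characters supporting conflicting splits -> support near 50
  mc <- pm(BLOOD = c(0, 0), A = c(1, 0), B = c(1, 1), C = c(0, 1),
           D = c(0, 0))
  btc <- bootstrap_support(mc, "BLOOD", n_replicates = 1000, seed = 5)
  sc <- as.integer(btc$node.label[nzchar(btc$node.label)])
  expect_true(all(abs(sc - 50) <= 5))
  expect_error(bootstrap_support(mc, "BLOOD", 0), "replicates")
})

test_that("attachment depth measures root-to-parent mutation distance", {
  tr <- ape::read.tree(text = "(BLOOD:0,((T1:3,T2:2):10,M1:1):5);")
  expect_equal(leaf_attachment_depth(tr, "M1"), 5)
  expect_equal(leaf_attachment_depth(tr, "T1"), 15)
  expect_equal(leaf_attachment_depth(tr, "BLOOD"), 0)
  expect_error(leaf_attachment_depth(tr, "X"), "no leaf")
})
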