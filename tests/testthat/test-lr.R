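test_that("interaction score is the product of cluster means with a strict detection gate", {
  means_on <- matrix(c(5, 6, 0.05, 2), 2, 2,
                     dimnames = list(c("L", "R"), c("s", "r")))
  means_off <- matrix(c(3, 1, 4, 2), 2, 2,
                      dimnames = list(c("L", "R"), c("s", "r")))
  profiles <- list(ON = toy_profile(means_on), OFF = toy_profile(means_off))
  pairs <- data.frame(ligand = "L", receptor = "R")
  rec <- score_pairs(profiles, pairs)

  pick <- function(cond, s, r)
    rec[rec$condition == cond & rec$sender == s & rec$receiver == r, ]
  expect_equal(pick("ON", "s", "s")$score, 5 * 6)
  expect_true(pick("ON", "s", "s")$detected)
  # ligand mean 0.05 in sender "r": below the 0.1 CPM gate
  expect_false(pick("ON", "r", "s")$detected)
  expect_equal(pick("ON", "r", "s")$score, 0)
  expect_equal(rec$viz_score, 10 * rec$score)
  # all ordered pairs including self-pairs, both conditions
  expect_equal(nrow(rec), 2 * 2 * 2)
})

test_that("scores equal the naive double-loop oracle on random fixtures", {
  set.seed(23)
  for (rep in 1:3) {
    n_cl <- sample(3:6, 1); n_pairs <- sample(5:20, 1)
    genes <- sprintf("g%02d", 1:30)
    mk <- function() {
      m <- matrix(rexp(30 * n_cl, rate = 1 / 50), 30, n_cl,
                  dimnames = list(genes, sprintf("k%d", 1:n_cl)))
      m[sample(length(m), 30)] <- 0  # plant undetectable entries
      m
    }
    profiles <- list(ON = toy_profile(mk()), OFF = toy_profile(mk()))
    pairs <- data.frame(ligand = sample(genes, n_pairs, replace = TRUE),
                        receptor = sample(genes, n_pairs, replace = TRUE))
    got <- score_pairs(profiles, pairs)
    ref <- lr_oracle(profiles, pairs)
    key <- function(d) paste(d$pair, d$sender, d$receiver, d$condition)
    expect_equal(got$score[match(key(ref), key(got))], ref$score)
  }
})

test_that("prioritization keeps a triple above 20 in at least one condition, strictly", {
  rec <- data.frame(
    pair = rep(c("p1", "p2", "p3"), each = 2),
    sender = "a", receiver = "b",
    condition = rep(c("ON", "OFF"), 3),
    score = c(15, 25,   20, 20,   0, 0))
  kept <- prioritize_pairs(rec, min_score = 20)
  expect_setequal(unique(kept$pair), "p1")
  expect_equal(nrow(kept), 2)  # both conditions of the kept triple
  expect_equal(nrow(prioritize_pairs(rec[rec$score == 0, ])), 0)
})

test_that("condition deltas and ratios are arithmetic on matched triples", {
  rec <- data.frame(
    pair = rep(c("p1", "p2"), each = 2), ligand = "L", receptor = "R",
    sender = "a", receiver = "b",
    condition = rep(c("OFF", "ON"), 2),
    score = c(40, 10, 7, 7))
  d <- condition_delta(rec, conditions = c("OFF", "ON"))
  expect_equal(d$delta[d$pair == "p1"], 30)
  expect_equal(d$ratio[d$pair == "p1"], 41 / 11)
  expect_equal(d$delta[d$pair == "p2"], 0)
  expect_equal(d$ratio[d$pair == "p2"], 1)

  # a triple present in one condition is reported missing, not dropped
  rec2 <- rbind(rec, data.frame(pair = "p3", ligand = "L", receptor = "R",
                                sender = "a", receiver = "b",
                                condition = "OFF", score = 99))
  d2 <- condition_delta(rec2)
  expect_true(is.na(d2$delta[d2$pair == "p3"]))
})

test_that("score is monotone in sender ligand expression and scale consistent", {
  base <- matrix(c(2, 3), 2, 1, dimnames = list(c("L", "R"), "k"))
  pairs <- data.frame(ligand = "L", receptor = "R")
  s <- vapply(c(2, 5, 9), function(v) {
    m <- base; m["L", "k"] <- v
    p <- list(ON = toy_profile(m), OFF = toy_profile(m))
    score_pairs(p, pairs)$score[1]
  }, 0)
  expect_true(all(diff(s) >= 0))

  # CPM cancels library size: rescaling raw counts leaves scores unchanged
  m <- matrix(rpois(40 * 30, 4), 40, 30,
              dimnames = list(c("L", "R", sprintf("g%02d", 1:38)),
                              sprintf("c%02d", 1:30)))
  cl <- rep(c("s", "r", "z"), 10)
  p1 <- cluster_means(cpm_normalize(toy_counts(m, cluster = cl)))
  p2 <- cluster_means(cpm_normalize(toy_counts(m * 7L, cluster = cl)))
  s1 <- score_pairs(list(ON = p1, OFF = p1), pairs)
  s2 <- score_pairs(list(ON = p2, OFF = p2), pairs)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("viz scaling never reorders scores and inputs are validated", {
  set.seed(3)
  m <- matrix(rexp(20 * 4, 1 / 30), 20, 4,
              dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c", "d")))
  profiles <- list(ON = toy_profile(m), OFF = toy_profile(m * 1.3))
  pairs <- data.frame(ligand = sample(rownames(m), 6),
                      receptor = sample(rownames(m), 6))
  rec <- score_pairs(profiles, pairs)
  expect_identical(order(rec$score), order(rec$viz_score))

  expect_error(score_pairs(profiles, pairs[0, ]), "non-empty")
  expect_warning(
    score_pairs(profiles, data.frame(ligand = c("g01", "nope"),
                                     receptor = c("g02", "g03"))),
    "skipped")
})

test_that("the planted ligand-receptor signal tops the condition delta", {
  sim <- simulate_counts(tiny_config(n_cells = 700, seed = 41,
                                     lr_fc = c(ON = 1, OFF = 10)))
  # the 60-gene fixture needs a detection floor matched to its universe
  cpm <- cpm_normalize(qc_filter(sim$matrix, min_genes = 10))
  profiles <- lapply(c(ON = "ON", OFF = "OFF"), function(cond) {
    idx <- cpm$cell_meta$condition == cond
    sub <- structure(list(cpm = cpm$cpm[, idx],
                          cell_meta = cpm$cell_meta[idx, ]),
                     class = "cpm_matrix")
    cluster_means(sub)
  })
  pairs <- simulate_lr_pairs(sim$truth, n_decoys = 25, seed = 2)
  d <- condition_delta(score_pairs(profiles, pairs))
  expect_equal(d$pair[1], "Lg-Rc")
  expect_equal(d$sender[1], "C")
  expect_equal(d$receiver[1], "A")
})
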