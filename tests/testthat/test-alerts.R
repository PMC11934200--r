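fake_expl <- function(mol_id, prob, bits = integer(0), weights = numeric(0)) {
  structure(list(
    mol_id = mol_id, model_probability = prob,
    weights = data.frame(bit = as.integer(bits), weight = weights),
    fit_quality = 0.9, constant_model = FALSE,
    config = explainer_config()
  ), class = "local_explanation")
}

test_that("only confident, correctly predicted actives are selected", {
  ex <- list(a = fake_expl("a", 0.79), b = fake_expl("b", 0.95),
             c = fake_expl("c", 0.95), d = fake_expl("d", 0.85),
             e = fake_expl("e", 0.30))
  y <- c(a = 1, b = 0, c = 1, d = 1, e = 1)
  kept <- select_confident_actives(ex, y, threshold = 0.8)
  expect_setequal(names(kept), c("c", "d"))
  # exactly at the threshold is kept
  kept2 <- select_confident_actives(list(z = fake_expl("z", 0.8)),
                                    c(z = 1), threshold = 0.8)
  expect_length(kept2, 1)
})

test_that("attribution emits one row per environment of each active bit", {
  fp <- fingerprint("CCO")
  active <- fp$bits[1]
  inactive <- setdiff(0:1023, fp$bits)[1]
  e <- fake_expl("m1", 0.9, bits = c(active, inactive), weights = c(0.4, 0.8))
  att <- attribute_fragments(e, fp)
  expect_true(all(att$bit == active))
  expect_equal(nrow(att), nrow(fp$environments[[as.character(active)]]))
  expect_true(all(att$weight == 0.4))
  expect_true(all(!is.na(att$fragment_smiles)))
  # no weighted bits at all -> empty attribution set
  expect_equal(nrow(attribute_fragments(fake_expl("m2", 0.9), fp)), 0)
})

test_that("a colliding bit yields several attributions sharing one weight", {
  # folding to 16 bits forces distinct environments onto the same bit
  fp <- fingerprint("CCOP(=S)(OC)OC", n_bits = 16L)
  counts <- vapply(fp$environments, nrow, integer(1))
  collided <- as.integer(names(counts)[counts >= 2][1])
  expect_false(is.na(collided))
  e <- fake_expl("m1", 0.95, bits = collided, weights = 0.6)
  att <- attribute_fragments(e, fp)
  expect_gte(nrow(att), 2)
  expect_true(all(att$weight == 0.6))
})

test_that("the verdict compares positive and negative weight sums", {
  fp <- fingerprint("CCO")
  b <- fp$bits
  mk_att <- function(w) {
    e <- fake_expl("m", 0.9, bits = b[seq_along(w)], weights = w)
    attribute_fragments(e, fp)
  }
  v1 <- molecule_verdict(mk_att(c(0.3, -0.1)))
  expect_identical(v1$verdict, "disruptor")
  v2 <- molecule_verdict(mk_att(c(-0.3, -0.1)))
  expect_identical(v2$verdict, "non-disruptor")
  expect_equal(v2$positive_sum, 0)
  v3 <- molecule_verdict(mk_att(numeric(0)))
  expect_identical(v3$verdict, "non-disruptor")
  # conservation: positive - negative equals the signed sum
  att <- mk_att(c(0.5, -0.2, 0.1))
  v <- molecule_verdict(att)
  expect_equal(v$positive_sum - v$negative_sum, sum(att$weight))
})

test_that("alert aggregation groups, floors, and ranks fragments", {
  att <- data.frame(
    mol_id = c("a", "b", "a", "c", "c"),
    bit = c(1L, 2L, 3L, 4L, 5L),
    fragment_smiles = c("F1", "F1", "F2", "F2", "F3"),
    weight = c(0.3, 0.5, 0.4, 0.2, 0.05),
    stringsAsFactors = FALSE
  )
  tab <- aggregate_alerts(att, weight_floor = 0.1)
  expect_identical(tab$fragment_smiles, c("F1", "F2"))
  expect_equal(tab$occurrences, c(2, 2))
  expect_equal(tab$total_weight, c(0.8, 0.6))
  # the 0.05 attribution was floored out entirely
  expect_false("F3" %in% tab$fragment_smiles)
  # exactly at the floor is excluded ("greater than" rule)
  at_floor <- att; at_floor$weight <- rep(0.1, 5)
  expect_equal(nrow(aggregate_alerts(at_floor, weight_floor = 0.1)), 0)
  expect_equal(nrow(aggregate_alerts(att[0, ], weight_floor = 0.1)), 0)
})

test_that("one molecule's repeated motif counts once per fragment", {
  att <- data.frame(
    mol_id = c("a", "a", "a"),
    bit = c(1L, 1L, 2L),
    fragment_smiles = c("F1", "F1", "F1"),
    weight = c(0.4, 0.4, 0.3),
    stringsAsFactors = FALSE
  )
  tab <- aggregate_alerts(att, weight_floor = 0.1)
  expect_equal(tab$occurrences, 1)
  # same bit deduplicated, different bit adds its weight
  expect_equal(tab$total_weight, 0.7)
})

test_that("raising the floor never grows any surviving entry", {
  set.seed(12)
  att <- data.frame(
    mol_id = sample(letters[1:6], 40, replace = TRUE),
    bit = sample(1:20, 40, replace = TRUE),
    fragment_smiles = sample(paste0("F", 1:8), 40, replace = TRUE),
    weight = runif(40, -0.2, 0.8),
    stringsAsFactors = FALSE
  )
  lo <- aggregate_alerts(att, weight_floor = 0.1)
  hi <- aggregate_alerts(att, weight_floor = 0.3)
  for (f in hi$fragment_smiles) {
    expect_lte(hi$occurrences[hi$fragment_smiles == f],
               lo$occurrences[lo$fragment_smiles == f])
    expect_lte(hi$total_weight[hi$fragment_smiles == f],
               lo$total_weight[lo$fragment_smiles == f])
  }
})

test_that("highlights carry fragment atom sets and their union", {
  fp <- fingerprint("CC(=O)Nc1ccccc1")
  e <- fake_expl("m", 0.9, bits = fp$bits[1:2], weights = c(0.5, 0.4))
  att <- attribute_fragments(e, fp)
  hl <- render_highlights(att)
  expect_equal(length(hl$fragments), nrow(att))
  expect_identical(hl$fragments[[1]]$atoms, att$atom_indices[[1]])
  expect_setequal(hl$atoms, sort(unique(unlist(att$atom_indices))))
  empty <- render_highlights(att[0, ])
  expect_length(empty$fragments, 0)
  expect_length(empty$atoms, 0)
})
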