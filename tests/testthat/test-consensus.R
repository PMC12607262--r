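test_that("frequency multiset counts occurrences and memberships", {
  sets <- xyz_ensemble()
  cm <- build_frequency_multiset(sets)
  e <- cm$entries
  counts <- setNames(e$count, e$key)
  xk <- sets$B$key
  expect_equal(unname(counts[xk]), 3L)
  expect_setequal(e$count, c(3L, 1L, 1L))
  expect_equal(sort(e$membership), sort(c(1, 1/3, 1/3)))
  expect_true(all(e$flag == "none"))

  two <- build_frequency_multiset(sets[c("A", "A")])
  expect_true(all(two$entries$membership == 1))

  expect_error(build_frequency_multiset(sets["A"]),
               class = "rnaconsensus_ensemble_too_small")
})

test_that("threshold consensus keeps keys with count >= n", {
  cm <- build_frequency_multiset(xyz_ensemble())
  expect_equal(threshold_consensus(cm, 2), xyz_ensemble()$B$key)
  expect_length(threshold_consensus(cm, 1), 3L)
  expect_equal(threshold_consensus(cm, 3), xyz_ensemble()$B$key)
  expect_error(threshold_consensus(cm, 0),
               class = "rnaconsensus_parameter_error")
  expect_error(threshold_consensus(cm, 4),
               class = "rnaconsensus_parameter_error")
})

test_that("threshold consensus is antitone in n and order-invariant", {
  for (seed in 1:5) {
    ens <- synth_ensemble(5, 12, core_size = 10, noise_rate = 3,
                          seed = seed)
    cm <- build_frequency_multiset(ens$sets)
    for (n in 1:4) {
      expect_true(all(threshold_consensus(cm, n + 1) %in%
                        threshold_consensus(cm, n)))
    }
    perm <- build_frequency_multiset(rev(ens$sets))
    expect_equal(perm$entries[order(perm$entries$key), ],
                 cm$entries[order(cm$entries$key), ])
  }
})

test_that("dot-bracket constraints parse, with pseudoknots and x", {
  c1 <- parse_constraints("((.x.))", 7)
  expect_equal(c1$pairs, data.frame(i = c(1L, 2L), j = c(7L, 6L)))
  expect_equal(c1$states[4], "forced_unpaired")
  expect_equal(c1$states[c(3, 5)], c("free", "free"))

  c2 <- parse_constraints("([)]", 4)
  expect_equal(c2$pairs, data.frame(i = c(1L, 2L), j = c(3L, 4L)))

  expect_error(parse_constraints("((.", 3), "position",
               class = "rnaconsensus_constraint_error")
  expect_error(parse_constraints("())", 3),
               class = "rnaconsensus_constraint_error")
  expect_error(parse_constraints("(.)", 5),
               class = "rnaconsensus_constraint_error")
  expect_error(parse_constraints("(?)", 3),
               class = "rnaconsensus_constraint_error")
})

ten_nt_cm <- function(sets = xyz_ensemble()) {
  residues <- data.frame(chain = "A", number = 1:10, icode = "",
                         base = strsplit("GGCAUAUGCC", "")[[1]],
                         stringsAsFactors = FALSE)
  build_frequency_multiset(sets, residues = residues)
}

test_that("constraints flag required and forbidden consensus entries", {
  cm <- ten_nt_cm()
  # (1,10) observed in all models; (3,8) observed never; x at 4 hits the
  # stacking-adjacent pair? stacking is never flagged.
  db <- "(.(x...).)"
  cm2 <- apply_constraints(cm, parse_constraints(db, 10))
  e <- cm2$entries
  req <- e[e$flag == "required", ]
  expect_equal(nrow(req), 2L)
  expect_true(all(req$membership == 1))
  new_pair <- req[req$count == 0L, ]
  expect_equal(nrow(new_pair), 1L)
  expect_equal(c(new_pair$num_i, new_pair$num_j), c(3L, 8L))
  # the x position pairs nothing in this ensemble; stacking at 3-4 untouched
  expect_false(any(e$flag == "x_forbidden" & e$kind == "stacking"))

  # x at a paired position forbids the pair
  cm3 <- apply_constraints(cm, parse_constraints(".x........", 10))
  e3 <- cm3$entries
  forb <- e3[e3$flag == "x_forbidden", ]
  expect_equal(nrow(forb), 1L)
  expect_equal(forb$num_i, 2L)  # the y pair (2,9)

  # empty constraint leaves the multiset unchanged
  cm4 <- apply_constraints(cm, parse_constraints("..........", 10))
  expect_equal(cm4$entries, cm$entries)
})

test_that("consensus dot-bracket renders, resolves conflicts, assigns families", {
  cm <- ten_nt_cm(list(
    interaction_set(rbind(interaction("canonical_pair", "A", 1, "A", 10),
                          interaction("canonical_pair", "A", 2, "A", 9))[1:8],
                    "m1"),
    interaction_set(rbind(interaction("canonical_pair", "A", 1, "A", 10),
                          interaction("canonical_pair", "A", 2, "A", 9))[1:8],
                    "m2")))
  dbn <- consensus_to_dotbracket(cm)
  expect_equal(dbn[2], "((......))")
  expect_equal(nchar(dbn[1]), 10L)

  # greedy keeps the higher-membership pair on a shared endpoint
  cm$entries <- rbind(cm$entries, within(cm$entries[1, ], {
    num_j <- 5L; membership <- 0.4; count <- 1L
    key <- interaction("canonical_pair", "A", 1, "A", 5)$key
  }))
  dbn2 <- consensus_to_dotbracket(cm, cutoff = 0.3)
  expect_equal(dbn2[2], "((......))")

  # crossing pairs get distinct bracket families
  cm2 <- ten_nt_cm(list(
    interaction_set(rbind(interaction("canonical_pair", "A", 1, "A", 5),
                          interaction("canonical_pair", "A", 3, "A", 8))[1:8],
                    "m1"),
    interaction_set(rbind(interaction("canonical_pair", "A", 1, "A", 5),
                          interaction("canonical_pair", "A", 3, "A", 8))[1:8],
                    "m2")))
  expect_equal(consensus_to_dotbracket(cm2)[2], "(.[.)..]..")
})

test_that("unanimous ensembles round-trip consensus through the parser", {
  s <- interaction_set(rbind(interaction("canonical_pair", "A", 1, "A", 10),
                             interaction("canonical_pair", "A", 3, "A", 7))[1:8],
                       "m1")
  cm <- ten_nt_cm(list(s, interaction_set(as.data.frame(s)[1:8], "m2")))
  expect_setequal(threshold_consensus(cm, 2), s$key)
  dbn <- consensus_to_dotbracket(cm, confidence_level = 2)
  back <- parse_constraints(dbn[2], 10)
  expect_equal(back$pairs, data.frame(i = c(1L, 3L), j = c(10L, 7L)))
})
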