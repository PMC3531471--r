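test_that("probability table satisfies base cases, closed form and recurrence", {
  tab <- build_probability_table(2, 6, 10)
  expect_equal(unname(tab$P["0", ]), rep(1, 11))          # P[0][j] = 1
  expect_equal(tab$P["3", "2"], 0)                        # i > j
  expect_equal(tab$P["1", "2"], 0.75)                     # 1 - (1/2)^2
  tab4 <- build_probability_table(4, 6, 10)
  expect_equal(tab4$P["1", "1"], 0.25)                    # 1/q
  for (q in c(2, 3, 4, 24)) {
    t <- build_probability_table(q, 6, 10)
    expect_equal(unname(t$P["1", ]), 1 - (1 - 1 / q)^(0:10),
                 tolerance = 1e-12)
    # recurrence holds entrywise
    for (i in 2:6) for (j in 1:10) {
      expect_equal(t$P[i + 1, j + 1],
                   (1 / q) * t$P[i, j] + (1 - 1 / q) * t$P[i + 1, j])
    }
  }
  expect_error(build_probability_table(0, 3, 3), "q")
})

test_that("probability table is monotone in both indices and bounded", {
  for (q in c(2, 4)) {
    tab <- build_probability_table(q, 8, 12)
    expect_true(all(tab$P >= 0 & tab$P <= 1))
    expect_true(all(apply(tab$P, 1, diff) >= 0))   # nondecreasing in j
    expect_true(all(apply(tab$P, 2, diff) <= 0))   # nonincreasing in i
  }
})

test_that("table entries match Monte-Carlo embedding frequencies", {
  trials <- 20000
  set.seed(21)
  for (q in c(2, 4)) {
    tab <- build_probability_table(q, 6, 10)
    for (i in 1:6) {
      freq <- mc_embed_freq(q, i, 10, trials)
      for (j in 1:10) {
        p <- tab$P[i + 1, j + 1]
        se <- sqrt(max(p * (1 - p), 1 / trials) / trials)
        expect_lt(abs(freq[j] - p), 4 * se + 1e-12)
      }
    }
  }
})

test_that("heuristic value is the product of remaining-part probabilities", {
  inst <- scs_instance(c("ab", "ba"))
  tab <- build_probability_table(2, 2, 2)
  done <- advance(advance(advance(new_candidate(inst), "a", inst), "b", inst),
                  "a", inst)
  expect_equal(heuristic_value(done, inst, tab), 1)       # complete candidate

  # one string, r = j: only the all-match path survives, so h = (1/q)^r
  one <- scs_instance("aaa", alphabet = letters[1:4])
  t4 <- build_probability_table(4, 3, 3)
  expect_equal(heuristic_value(new_candidate(one), one, t4), (1 / 4)^3)

  # componentwise smaller remaining lengths never score worse
  inst2 <- scs_instance(c("abab", "bb"))
  t2 <- build_probability_table(2, 4, 4)
  a <- advance(new_candidate(inst2), "a", inst2)
  expect_gte(heuristic_value(a, inst2, t2),
             heuristic_value(new_candidate(inst2), inst2, t2))
  # log form agrees with the plain product
  expect_equal(exp(heuristic_value(a, inst2, t2, log = TRUE)),
               heuristic_value(a, inst2, t2))
  expect_error(heuristic_value(a, inst2, build_probability_table(2, 1, 1)),
               "bounds")
})

test_that("embedding one more symbol below the horizon never decreases the heuristic", {
  # the guarantee holds while the reference length j = max r is unchanged
  # (advancing the unique longest remainder shrinks j and may trade off)
  set.seed(22)
  for (rep in 1:40) {
    inst <- generate_random_instance(sample(2:4, 1),
                                     lengths = sample(2:6, 3, replace = TRUE),
                                     seed = rep)
    tab <- build_probability_table(length(inst$alphabet), max(inst$lengths))
    cand <- new_candidate(inst)
    while (!is_complete(cand, inst)) {
      h <- heuristic_value(cand, inst, tab, log = TRUE)
      jb <- max(inst$lengths - cand$lambdas)
      fronts <- unique(unlist(Map(function(ch, l, n) if (l < n) ch[l + 1],
                                  inst$chars, cand$lambdas, inst$lengths)))
      cand <- advance(cand, sample(fronts, 1), inst)
      if (max(inst$lengths - cand$lambdas) == jb)
        expect_gte(heuristic_value(cand, inst, tab, log = TRUE), h)
    }
    expect_equal(heuristic_value(cand, inst, tab), 1)
  }
})

test_that("dominance is componentwise, reflexive and level-checked", {
  inst <- scs_instance(c("aba", "bab"))
  mk <- function(seq, lam) structure(list(seq = seq, lambdas = lam),
                                     class = "scs_candidate")
  expect_true(dominates(mk("abx", c(3L, 2L)), mk("aby", c(2L, 2L))))
  expect_false(dominates(mk("abx", c(3L, 1L)), mk("aby", c(2L, 2L))))
  a <- mk("ab", c(2L, 1L)); b <- mk("ba", c(2L, 1L))
  expect_true(dominates(a, b))
  expect_true(dominates(b, a))        # identical vectors dominate both ways
  expect_true(dominates(a, a))        # reflexive
  expect_error(dominates(mk("a", 1L), mk("ab", 2L)), "same level")
})
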