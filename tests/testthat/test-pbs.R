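test_that("contributes detects symbols at string fronts", {
  inst <- scs_instance(c("ab", "ba"), alphabet = c("a", "b", "c"))
  c0 <- new_candidate(inst)
  expect_true(contributes(c0, "a", inst))
  expect_true(contributes(c0, "b", inst))
  expect_false(contributes(c0, "c", inst))
  done <- advance(advance(advance(c0, "a", inst), "b", inst), "a", inst)
  expect_false(contributes(done, "a", inst))
  expect_false(contributes(done, "b", inst))
})

test_that("extend_beam generates only contributing children, bounded in number", {
  inst <- scs_instance(c("ab", "ba"), alphabet = c("a", "b", "c"))
  ext <- extend_beam(list(new_candidate(inst)), inst)
  expect_identical(length(ext$children), 2L)  # 'c' child excluded
  expect_identical(vapply(ext$children, `[[`, "", "seq"), c("a", "b"))
  expect_null(ext$complete)
  expect_lte(length(ext$children), 1 * length(inst$alphabet))
  # a complete child is reported instead of enqueued
  almost <- advance(advance(new_candidate(inst), "a", inst), "b", inst)
  ext2 <- extend_beam(list(almost), inst)
  expect_identical(ext2$complete$seq, "aba")
})

test_that("linear ranking selects rank r with probability prop. to N - r + 1", {
  expect_identical(linear_rank_index(1), 1L)
  set.seed(31)
  draws2 <- replicate(20000, linear_rank_index(2))
  expect_lt(abs(mean(draws2 == 1) - 2 / 3), 4 * sqrt(2 / 9 / 20000))
  draws3 <- replicate(30000, linear_rank_index(3))
  p <- tabulate(draws3, 3) / 30000
  for (r in 1:3) {
    pr <- (3 - r + 1) / 6
    expect_lt(abs(p[r] - pr), 4 * sqrt(pr * (1 - pr) / 30000))
  }
  expect_error(linear_rank_sample(list()), "empty")
  expect_identical(linear_rank_sample(list("only"))[[1]], "only")
})

test_that("select_beam is greedy at mu = 0 and top-kw at kb = kw", {
  inst <- scs_instance(c("aab", "abb", "bba"))
  tab <- build_probability_table(2, 3)
  ext <- extend_beam(list(new_candidate(inst)), inst)
  h <- vapply(ext$children, heuristic_value, numeric(1), inst = inst, tab = tab,
              log = TRUE)
  # kb = kw: exactly the top-kw by heuristic
  top <- select_beam(ext$children, pbs_config(kw = 1, kb = 1, mu = 0), inst, tab)
  expect_identical(top[[1]]$seq, ext$children[[which.max(h)]]$seq)
  # mu = 0, kb = 0: purely greedy selection, same leading choice
  greedy <- select_beam(ext$children, pbs_config(kw = 2, kb = 0, mu = 0), inst, tab)
  expect_identical(greedy[[1]]$seq, ext$children[[which.max(h)]]$seq)
  expect_lte(length(greedy), 2L)
  # every selected member is a dominator or undominated by all dominators
  sel <- select_beam(ext$children, pbs_config(kw = 3, kb = 1, mu = 0), inst, tab)
  doms <- sel[1]
  for (cand in sel[-1])
    expect_false(any(vapply(doms, dominates, logical(1), b = cand)))
})

test_that("pbs_solve returns valid supersequences within length bounds", {
  inst1 <- scs_instance("ab")
  expect_identical(pbs_solve(inst1, pbs_config(kw = 3)), "ab")
  inst <- scs_instance(c("ab", "ba"))
  z <- pbs_solve(inst, pbs_config(kw = 2, kb = 0, mu = 0))
  expect_identical(nchar(z), 3L)  # exact optimum on this instance
  set.seed(32)
  for (rep in 1:20) {
    r <- generate_random_instance(sample(2:4, 1),
                                  lengths = sample(2:8, 3, replace = TRUE),
                                  seed = rep)
    z <- pbs_solve(r, pbs_config(kw = 5, kb = 2, mu = 0.3), seed = rep)
    expect_true(is_supersequence_of_all(z, r))
    expect_gte(nchar(z), max(r$lengths))
    expect_lte(nchar(z), sum(r$lengths))
  }
})

test_that("pbs_solve is reproducible under a seed and seed-free when deterministic", {
  r <- generate_random_instance(4, lengths = c(10, 10, 20), seed = 7)
  a <- pbs_solve(r, pbs_config(kw = 10, kb = 2, mu = 0.5), seed = 99)
  b <- pbs_solve(r, pbs_config(kw = 10, kb = 2, mu = 0.5), seed = 99)
  expect_identical(a, b)
  det <- pbs_config(kw = 10, kb = 10, mu = 0)
  expect_identical(pbs_solve(r, det, seed = 1), pbs_solve(r, det, seed = 2))
  det2 <- pbs_config(kw = 10, kb = 3, mu = 0)
  expect_identical(pbs_solve(r, det2, seed = 1), pbs_solve(r, det2, seed = 2))
})

test_that("the R reference engine and the C++ engine agree in deterministic mode", {
  set.seed(33)
  for (rep in 1:8) {
    r <- generate_random_instance(sample(2:4, 1),
                                  lengths = sample(2:7, 3, replace = TRUE),
                                  seed = 100 + rep)
    for (kb in c(0L, 2L, 5L)) {
      cfg <- pbs_config(kw = 5, kb = kb, mu = 0)
      expect_identical(pbs_solve(r, cfg, engine = "r"),
                       pbs_solve(r, cfg, engine = "cpp"))
    }
  }
})

test_that("wider beams do not hurt on random instances", {
  # scaled-down form of the beam-width trend: paired over seeds, q = 8
  lens <- c(10, 10, 10, 20, 20)
  n1 <- n100 <- numeric(20)
  for (i in 1:20) {
    r <- generate_random_instance(8, lengths = lens, seed = 200 + i)
    n1[i] <- nchar(pbs_solve(r, pbs_config(kw = 1, kb = 1), seed = i))
    n100[i] <- nchar(pbs_solve(r, pbs_config(kw = 100, kb = 11), seed = i))
  }
  expect_lte(mean(n100), mean(n1))
})
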