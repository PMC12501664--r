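## Exhaustive-oracle checks of the greedy selection machinery on small
## libraries where every candidate subset can be enumerated directly.

test_that("cached objective equals direct recomputation", {
  lib <- toy_library(); sch <- toy_scheme(); cache <- toy_cache()
  for (idx in list(c(1, 4, 6, 8), c(2, 3, 5, 7, 9), 1:10)) {
    o_cache <- encoding_objective(idx, lib, sch, cache)
    o_direct <- encoding_objective(idx, lib, sch, NULL)
    expect_lt(max(abs(o_cache / o_direct - 1), na.rm = TRUE), 1e-6)
  }
})

test_that("a single open interval has zero contamination, hence zero objective", {
  lib <- toy_library()
  o <- encoding_objective(3, lib, interval_scheme(0))
  expect_equal(unname(o["contamination"]), 0)
  expect_equal(unname(o["objective"]), 0)
})

test_that("doubling spectral power rescales the noise term by 1/4 and leaves
          contamination unchanged", {
  lib <- toy_library(); sch <- toy_scheme()
  lib2 <- lib
  lib2$power <- lib$power * 2
  lib2$b_si <- lib$b_si * 2
  lib2$spectra <- lapply(lib$spectra, function(s) {
    s$power <- s$power * 2; s$bvalue <- s$bvalue * 2; s })
  idx <- c(1, 4, 6, 8)
  o1 <- encoding_objective(idx, lib, sch)
  o2 <- encoding_objective(idx, lib2, sch)
  expect_equal(unname(o2["noise"] / o1["noise"]), 0.25, tolerance = 1e-10)
  expect_equal(unname(o2["contamination"] / o1["contamination"]), 1,
               tolerance = 1e-10)
})

test_that("every greedy pruning step matches exhaustive one-removal search", {
  lib <- oracle_library(); sch <- toy_scheme()
  cache <- gram_cache(lib, sch)
  pr <- greedy_prune(lib, sch, cache)
  sets <- pr$sets
  for (i in seq_len(length(sets) - 1)) {
    cur <- sets[[i]]
    objs <- vapply(seq_along(cur), function(k)
      encoding_objective(cur[-k], lib, sch, cache)["objective"], numeric(1))
    removed <- setdiff(cur, sets[[i + 1]])
    expect_equal(objs[match(removed, cur)], min(objs), tolerance = 1e-9)
    ## recorded objective agrees with the oracle's minimum
    expect_equal(unname(pr$trace$objective[i + 1]), unname(min(objs)),
                 tolerance = 1e-9)
  }
  ## nestedness across M within one prune run
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("a library of N members is returned unchanged by pruning", {
  lib <- sub_library(toy_library(), c(1, 4, 6))
  sch <- toy_scheme()
  pr <- greedy_prune(lib, sch)
  expect_length(pr$sets, 1)
  expect_equal(pr$sets[[1]], 1:3)
})

test_that("pruning removes an exact duplicate when the rest are essential", {
  ## three members each dominating one interval plus a duplicated spectrum:
  ## dropping any distinct member is rank-deficient (objective +Inf), so the
  ## oracle (and greedy) drops a copy of the duplicate first
  lib4 <- sub_library(toy_library(), c(1, 5, 8, 1))
  sch <- toy_scheme()
  cache <- gram_cache(lib4, sch)
  objs <- vapply(1:4, function(k)
    encoding_objective((1:4)[-k], lib4, sch, cache)["objective"], numeric(1))
  expect_true(which.min(objs) %in% c(1, 4))      # a duplicate goes first
  expect_true(all(!is.finite(objs[2:3])))
  pr <- greedy_prune(lib4, sch, cache)
  removed <- setdiff(1:4, pr$sets[[2]])
  expect_true(removed %in% c(1, 4))
})

test_that("the initial grow pair matches exhaustive pair enumeration", {
  lib <- oracle_library(); sch <- toy_scheme()
  cache <- gram_cache(lib, sch)
  gr <- greedy_grow(lib, sch, cache, m_max = 4)
  pairs <- t(utils::combn(library_size(lib), 2))
  objs <- apply(pairs, 1, function(p)
    encoding_objective(p, lib, sch, cache)["objective"])
  expect_equal(sort(gr$sets[[1]]), sort(pairs[which.min(objs), ]))
  ## each growth step matches exhaustive one-addition search
  sets <- gr$sets
  for (i in seq_len(length(sets) - 1)) {
    cur <- sets[[i]]
    rest <- setdiff(seq_len(library_size(lib)), cur)
    objs <- vapply(rest, function(cnd)
      encoding_objective(c(cur, cnd), lib, sch, cache)["objective"],
      numeric(1))
    added <- setdiff(sets[[i + 1]], cur)
    expect_equal(objs[match(added, rest)], min(objs), tolerance = 1e-9)
  }
})

test_that("growing to the full library reproduces the full-library objective", {
  lib <- oracle_library(); sch <- toy_scheme()
  cache <- gram_cache(lib, sch)
  gr <- greedy_grow(lib, sch, cache, m_max = library_size(lib))
  full <- encoding_objective(seq_len(library_size(lib)), lib, sch, cache)
  last <- gr$trace[nrow(gr$trace), ]
  expect_equal(last$objective, unname(full["objective"]), tolerance = 1e-9)
})

test_that("select_best takes the per-M minimum of both variants", {
  lib <- oracle_library(); sch <- toy_scheme()
  cache <- gram_cache(lib, sch)
  pr <- greedy_prune(lib, sch, cache)
  gr <- greedy_grow(lib, sch, cache, m_max = library_size(lib))
  best <- select_best(pr, gr)
  for (i in seq_len(nrow(best$trace))) {
    M <- best$trace$M[i]
    op <- pr$trace$objective[pr$trace$M == M]
    og <- gr$trace$objective[gr$trace$M == M]
    expect_lte(best$trace$objective[i], min(op, og) + 1e-15)
  }
  ## identical inputs return either branch unchanged
  same <- select_best(pr, pr)
  expect_equal(sort(same$trace$objective), sort(pr$trace$objective))
})

test_that("selection is deterministic across repeated runs", {
  lib <- oracle_library(); sch <- toy_scheme()
  pr1 <- greedy_prune(lib, sch)
  pr2 <- greedy_prune(lib, sch)
  expect_identical(pr1$sets, pr2$sets)
  gr1 <- greedy_grow(lib, sch, m_max = 5)
  gr2 <- greedy_grow(lib, sch, m_max = 5)
  expect_identical(gr1$sets, gr2$sets)
})

test_that("rank-deficient candidate sets score +Inf", {
  lib <- toy_library(); sch <- toy_scheme()
  ## two copies of one member cannot encode three intervals
  lib3 <- sub_library(lib, c(4, 4, 4))
  o <- encoding_objective(1:3, lib3, sch)
  expect_true(!is.finite(o["objective"]))
})
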