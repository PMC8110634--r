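test_that("loop enumeration and classification on a constructed case", {
  # A <-> B (both +), plus B -> C -> A with C -> A negative:
  # one direct reinforcing 2-loop, one balancing indirect 3-loop
  d <- make_cld(rbind(c("A", "B"), c("B", "A"), c("B", "C"), c("C", "A")),
                polarity = c(1L, 1L, 1L, -1L))
  loops <- enumerate_loops(d, max_length = 3)
  expect_length(loops, 2)
  expect_equal(loops[[1]]$members, c("A", "B"))
  expect_equal(loops[[1]]$loop_class, "reinforcing")
  expect_equal(loops[[1]]$length_class, "direct")
  expect_equal(loops[[2]]$members, c("A", "B", "C"))
  expect_equal(loops[[2]]$polarity_product, -1L)
  expect_equal(loops[[2]]$loop_class, "balancing")
  expect_equal(loops[[2]]$length_class, "indirect")
  # closing edge last: A->B, B->C, C->A
  expect_equal(loops[[2]]$polarities, c(1L, 1L, -1L))

  dag <- make_cld(rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
  expect_length(enumerate_loops(dag, 4), 0)
  expect_error(enumerate_loops(d, 1), "max_length")
})

test_that("enumeration equals subset brute force on random digraphs", {
  set.seed(606)
  for (i in 1:60) {
    d <- random_cld(sample(3:6, 1), p = 0.35)
    ml <- sample(2:5, 1)
    expect_equal(loop_keys(enumerate_loops(d, ml)), cycles_bf(d, ml))
  }
})

test_that("both traversal directions of a vertex set are distinct loops", {
  tri <- make_cld(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                        c("A", "C"), c("C", "B"), c("B", "A")))
  loops <- enumerate_loops(tri, 3)
  three <- Filter(function(l) length(l$members) == 3, loops)
  expect_length(three, 2)
  expect_equal(sort(vapply(three, function(l) paste(l$members,
                                                    collapse = ">"),
                           character(1))),
               c("A>B>C", "A>C>B"))
})

test_that("polarity product is invariant under rotation of the start", {
  set.seed(707)
  for (i in 1:20) {
    d <- random_cld(5, p = 0.4)
    for (l in enumerate_loops(d, 4)) {
      k <- length(l$members)
      pol <- stats::setNames(d$connections$polarity,
                             paste(d$connections$source,
                                   d$connections$target, sep = ">"))
      for (r in seq_len(k)) {
        rot <- c(l$members[r:k], l$members[seq_len(r - 1)])
        nxt <- c(rot[-1], rot[1])
        expect_equal(prod(pol[paste(rot, nxt, sep = ">")]),
                     l$polarity_product)
      }
    }
  }
})

test_that("flipping one edge's polarity flips exactly its loops' classes", {
  set.seed(808)
  d <- generate_random_cld(n_variables = 8, n_connections = 25,
                           reciprocal_fraction = 0.3, seed = 4,
                           n_exogenous = 1)
  loops0 <- enumerate_loops(d, 4)
  expect_gt(length(loops0), 0)
  e <- sample(nrow(d$connections), 1)
  flip <- d
  flip$connections$polarity[e] <- -flip$connections$polarity[e]
  loops1 <- enumerate_loops(flip, 4)
  expect_equal(loop_keys(loops0), loop_keys(loops1))
  edge <- paste(d$connections$source[e], d$connections$target[e], sep = ">")
  for (i in seq_along(loops0)) {
    k <- length(loops0[[i]]$members)
    edges_i <- paste(loops0[[i]]$members,
                     c(loops0[[i]]$members[-1], loops0[[i]]$members[1]),
                     sep = ">")
    if (edge %in% edges_i) {
      expect_false(loops0[[i]]$loop_class == loops1[[i]]$loop_class)
    } else {
      expect_equal(loops0[[i]]$loop_class, loops1[[i]]$loop_class)
    }
  }
})

test_that("direct-loop count equals the reciprocal-pair tally", {
  set.seed(909)
  for (i in 1:20) {
    d <- random_cld(sample(4:7, 1), p = 0.4)
    key <- paste(d$connections$source, d$connections$target, sep = ">")
    rev <- paste(d$connections$target, d$connections$source, sep = ">")
    n_pairs <- sum(key %in% rev) / 2
    loops <- enumerate_loops(d, 2)
    expect_length(loops, n_pairs)
  }
})

test_that("scale classification distinguishes within, cross and unlabeled", {
  vars <- data.frame(name = c("A", "B", "C"),
                     category = c("brain", "brain", "physical"),
                     scale = c("cellular", "cellular", NA))
  d <- cld(vars, data.frame(source = c("A", "B", "B", "C"),
                            target = c("B", "A", "C", "B"),
                            polarity = "+"))
  expect_equal(classify_loop_scale(c("A", "B"), d, "category"),
               "within_scale")
  expect_equal(classify_loop_scale(c("A", "B"), d, "scale"), "within_scale")
  expect_equal(classify_loop_scale(c("B", "C"), d, "category"),
               "cross_scale")
  expect_equal(classify_loop_scale(c("B", "C"), d, "scale"), "unlabeled")
  expect_error(classify_loop_scale(c("A", "Z"), d), "not declared")

  # auto label field falls back to category when scales are missing
  loops <- enumerate_loops(d, 2)
  expect_equal(attr(loops, "scale_label_field"), "category")
})

test_that("loops_containing filters enumeration by membership", {
  d <- planted_cycle_cld(n_direct = 2, n_indirect = 1, n_balancing = 0)
  hit <- loops_containing(d, "direct01_a", 3)
  expect_length(hit, 1)
  expect_equal(hit[[1]]$members, c("direct01_a", "direct01_b"))
  none <- loops_containing(chain_cld(c("X", "Y", "Z")), "Y", 3)
  expect_length(none, 0)
  expect_error(loops_containing(d, "nope", 3), "unknown variable")
})

test_that("loop_table assigns RD/RI identifiers deterministically", {
  expect_equal(nrow(loop_table(list())), 0)
  expect_named(loop_table(list()),
               c("loop", "first_variable", "second_variable",
                 "third_variable", "loop_class", "scale_class"))

  one <- enumerate_loops(make_cld(rbind(c("A", "B"), c("B", "A"))), 2)
  tab <- loop_table(one)
  expect_equal(tab$loop, "RD1")
  expect_true(is.na(tab$third_variable))

  d <- planted_cycle_cld(n_direct = 2, n_indirect = 2, n_balancing = 1)
  tab <- loop_table(enumerate_loops(d, 3))
  expect_equal(sum(startsWith(tab$loop, "RD")), 2)
  expect_equal(sum(startsWith(tab$loop, "RI")), 3)
  expect_equal(tab$loop[startsWith(tab$loop, "RD")], c("RD1", "RD2"))
})
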