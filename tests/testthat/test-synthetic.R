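test_that("generator is deterministic and satisfies its constraints", {
  a <- generate_random_cld(n_variables = 38, n_connections = 150, seed = 1)
  b <- generate_random_cld(n_variables = 38, n_connections = 150, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$variables), 38)
  expect_equal(nrow(a$connections), 150)
  expect_length(exogenous_variables(a), 3)
  expect_equal(nrow(validate_cld(a)$errors), 0)
  c_ <- generate_random_cld(n_variables = 38, n_connections = 150, seed = 2)
  expect_false(identical(a$connections, c_$connections))
})

test_that("generated diagrams respect exogeneity, density and signs", {
  set.seed(31)
  for (i in 1:10) {
    nv <- sample(8:20, 1)
    ne <- sample(1:3, 1)
    m <- sample((nv - ne):(3 * nv), 1)
    d <- generate_random_cld(n_variables = nv, n_connections = m,
                             n_exogenous = ne, seed = sample.int(1e6, 1))
    expect_equal(nrow(d$connections), m)
    expect_length(exogenous_variables(d), ne)
    expect_false(any(d$connections$source == d$connections$target))
    expect_equal(nrow(validate_cld(d)$errors), 0)
  }
  # sign control
  pos <- generate_random_cld(12, 40, negative_fraction = 0, seed = 9,
                             n_exogenous = 2)
  expect_true(all(pos$connections$polarity == 1))
  loops <- enumerate_loops(pos, 4)
  expect_true(all(vapply(loops, `[[`, character(1), "loop_class") ==
                    "reinforcing"))
})

test_that("generator rejects infeasible requests", {
  expect_error(generate_random_cld(5, 100, n_exogenous = 2, seed = 1),
               "infeasible")
  expect_error(generate_random_cld(5, 2, n_exogenous = 1, seed = 1),
               "infeasible")
  expect_error(generate_random_cld(5, 10, n_exogenous = 5, seed = 1),
               "n_exogenous")
})

test_that("reciprocal-pair fraction is controllable", {
  lo <- generate_random_cld(20, 60, reciprocal_fraction = 0, seed = 2,
                            n_exogenous = 2)
  hi <- generate_random_cld(20, 60, reciprocal_fraction = 0.6, seed = 2,
                            n_exogenous = 2)
  frac <- function(d) {
    key <- paste(d$connections$source, d$connections$target)
    rev <- paste(d$connections$target, d$connections$source)
    mean(key %in% rev)
  }
  expect_gt(frac(hi), frac(lo) + 0.2)
})

test_that("planted cycle census is recovered exactly", {
  d <- planted_cycle_cld(n_direct = 14, n_indirect = 16, n_balancing = 0)
  tab <- loop_table(enumerate_loops(d, 3))
  expect_equal(sum(startsWith(tab$loop, "RD")), 14)
  expect_equal(sum(startsWith(tab$loop, "RI")), 16)
  expect_true(all(tab$loop_class == "reinforcing"))
  expect_equal(nrow(validate_cld(d)$errors), 0)

  one_bal <- planted_cycle_cld(0, 0, 1)
  loops <- enumerate_loops(one_bal, 3)
  expect_length(loops, 1)
  expect_equal(loops[[1]]$loop_class, "balancing")
  expect_equal(sum(loops[[1]]$polarities == -1L), 1)

  single <- planted_cycle_cld(1, 0, 0)
  tab <- loop_table(enumerate_loops(single, 3))
  expect_equal(tab$loop, "RD1")

  # planted census equals enumeration across random census requests
  set.seed(77)
  for (i in 1:10) {
    nd <- sample(0:4, 1); ni <- sample(0:4, 1); nb <- sample(0:3, 1)
    if (nd + ni + nb == 0) nb <- 1
    d <- planted_cycle_cld(nd, ni, nb, seed = i)
    loops <- enumerate_loops(d, 3)
    cls <- vapply(loops, `[[`, character(1), "loop_class")
    len <- vapply(loops, function(l) length(l$members), integer(1))
    expect_equal(sum(len == 2), nd)
    expect_equal(sum(len == 3 & cls == "reinforcing"), ni)
    expect_equal(sum(cls == "balancing"), nb)
  }
})

test_that("loop-table fixture implies the row cycles", {
  rows <- data.frame(
    loop = c("RD1", "RI1"),
    first_variable = c("Amyloid beta burden", "Oxidative stress"),
    second_variable = c("Neuroinflammation", "Neuronal dysfunction"),
    third_variable = c("", "Circadian misalignment"))
  d <- fixture_from_loop_table(rows)
  key <- paste(d$connections$source, d$connections$target, sep = ">")
  expect_setequal(key, c(
    "Amyloid beta burden>Neuroinflammation",
    "Neuroinflammation>Amyloid beta burden",
    "Oxidative stress>Neuronal dysfunction",
    "Neuronal dysfunction>Circadian misalignment",
    "Circadian misalignment>Oxidative stress"))
  expect_true(all(d$connections$polarity == 1))
  # single RI row: one 3-cycle, no 2-cycles
  d3 <- fixture_from_loop_table(rows[2, ])
  loops <- enumerate_loops(d3, 3)
  expect_length(loops, 1)
  expect_equal(length(loops[[1]]$members), 3)

  expect_error(fixture_from_loop_table(
    data.frame(first_variable = "A", second_variable = "",
               third_variable = "")), "fewer than 2")
})

test_that("every printed loop is recovered on the packaged fixture", {
  fix <- fixture_from_loop_table(ad_loop_rows())
  expect_equal(nrow(validate_cld(fix)$errors), 0)
  loops <- enumerate_loops(fix, 3)
  keys <- loop_keys(loops)
  rows <- ad_loop_rows()
  for (i in seq_len(nrow(rows))) {
    mem <- unlist(rows[i, c("first_variable", "second_variable",
                            "third_variable")], use.names = FALSE)
    mem <- mem[!is.na(mem) & mem != ""]
    expect_true(canon(mem) %in% keys,
                label = paste("loop", rows$loop[i], "recovered"))
  }
  # all-positive canonical polarity: every loop reinforcing
  expect_true(all(vapply(loops, `[[`, character(1), "loop_class") ==
                    "reinforcing"))
})
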