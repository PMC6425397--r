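test_that("count inputs are scaled by the per-junction conductance", {
  c1 <- make_conn(matrix(c(0, 1, 1, 0), 2), matrix(0, 2, 2))
  expect_equal(unname(c1$gap), matrix(c(0, 100, 100, 0), 2))
  c2 <- connectome(matrix(c(0, 250, 250, 0), 2), matrix(0, 2, 2),
                   data.frame(name = c("A", "B"), group = "inter",
                              inhibitory = FALSE),
                   input = "conductance")
  expect_equal(unname(c2$gap), matrix(c(0, 250, 250, 0), 2))
})

test_that("invalid bundles are rejected", {
  roster <- data.frame(name = c("A", "B"), group = "inter",
                       inhibitory = FALSE)
  expect_error(connectome(matrix(c(0, 1, 0, 0), 2), matrix(0, 2, 2), roster),
               "symmetric")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2), matrix(0, 2, 2),
                          roster), "negative")
  expect_error(connectome(matrix(0, 2, 2), matrix(0, 3, 3), roster),
               "square")
  expect_error(connectome(matrix(0, 2, 2), matrix(0, 2, 2),
                          data.frame(name = c("A", "A"), group = "inter",
                                     inhibitory = FALSE)),
               "duplicate")
  expect_error(connectome(matrix(0, 3, 3), matrix(0, 3, 3), roster),
               "roster")
})

test_that("reversal potentials follow the inhibitory flag", {
  c1 <- make_conn(matrix(0, 2, 2), matrix(0, 2, 2),
                  inhibitory = c(TRUE, FALSE))
  expect_equal(c1$roster$reversal_potential, c(-48, 0))
})

test_that("synaptic degree counts nonzero in plus out connections", {
  syn <- matrix(0, 4, 4)
  syn[2, 1] <- 1; syn[3, 1] <- 2; syn[1, 4] <- 1  # out 2, in 1 for neuron 1
  c1 <- make_conn(matrix(0, 4, 4), syn)
  expect_equal(synaptic_degree(c1, 1), 3)
  expect_equal(synaptic_degree(c1, "T02"), 1)
  # brute force on a fully connected layer: every neuron has 2 (n - 1)
  cf <- make_conn(matrix(0, 4, 4), full_syn(4))
  for (i in 1:4) expect_equal(synaptic_degree(cf, i), 6)
  c0 <- make_conn(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(synaptic_degree(c0, 2), 0)
  expect_error(synaptic_degree(c0, 9), "range")
})

test_that("edge width is the max of the two directed synapse counts", {
  syn <- matrix(0, 3, 3)
  syn[2, 1] <- 3   # A -> B has 3 synapses
  syn[1, 2] <- 1   # B -> A has 1
  c1 <- make_conn(matrix(0, 3, 3), syn)
  expect_equal(edge_width(c1, 1, 2), 3)
  expect_equal(edge_width(c1, 2, 1), 3)
  expect_equal(edge_width(c1, 1, 3), 0)
  expect_error(edge_width(c1, 2, 2), "distinct")
})

test_that("ablation zeroes rows and columns; reinsertion is exact inverse", {
  set.seed(11)
  c0 <- prop_net(seed = 3, n = 6)
  c1 <- ablate(c0, c("N002", "N005"))
  for (i in c(2, 5)) {
    expect_true(all(c1$gap[i, ] == 0) && all(c1$gap[, i] == 0))
    expect_true(all(c1$syn[i, ] == 0) && all(c1$syn[, i] == 0))
  }
  expect_equal(c1$active, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # partial reinsertion restores only the requested neuron
  c2 <- reinsert(c1, "N002")
  expect_true(all(c2$syn[5, ] == 0) && all(c2$syn[, 5] == 0))
  ref <- c0
  ref <- ablate(ref, "N005")
  expect_equal(c2$gap, ref$gap)
  expect_equal(c2$syn, ref$syn)
  # full reinsertion is the identity
  c3 <- reinsert(c2, "N005")
  expect_identical(c3$gap, c0$gap)
  expect_identical(c3$syn, c0$syn)
  expect_true(all(c3$active))
  # ablate everything -> all-zero matrices; re-ablating is a no-op
  call <- ablate(c0, 1:6)
  expect_true(all(call$gap == 0) && all(call$syn == 0))
  expect_equal(ablate(call, 1), call)
  # reinserting a never-ablated neuron is the identity
  expect_equal(reinsert(c0, 3), c0)
  # gap symmetry preserved by every operation
  for (cc in list(c1, c2, c3, call)) {
    expect_equal(cc$gap, t(cc$gap))
  }
})

test_that("bundle write/load round-trips (csv within precision, npy exact)", {
  c0 <- prop_net(seed = 9, n = 7)
  for (fmt in c("csv", "npy")) {
    dir <- withr::local_tempdir()
    write_connectome(c0, dir, format = fmt)
    c1 <- load_connectome(dir)
    expect_equal(unname(c1$gap), unname(c0$gap),
                 tolerance = if (fmt == "csv") 1e-12 else 0)
    expect_equal(unname(c1$syn), unname(c0$syn),
                 tolerance = if (fmt == "csv") 1e-12 else 0)
    expect_equal(c1$roster$name, c0$roster$name)
    expect_equal(c1$roster$inhibitory, c0$roster$inhibitory)
    expect_true(all(c1$active))
  }
})

test_that("the transpose_syn flag flips the stored orientation", {
  syn <- matrix(0, 2, 2)
  syn[1, 2] <- 4  # in TO-FROM convention: synapse to 1 from 2
  roster <- data.frame(name = c("A", "B"), group = "inter",
                       inhibitory = FALSE)
  a <- connectome(matrix(0, 2, 2), syn, roster)
  b <- connectome(matrix(0, 2, 2), t(syn), roster, transpose_syn = TRUE)
  expect_equal(a$syn, b$syn)
})

test_that("npy arrays round-trip through the binary format", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(35), 5, 7)
  f <- file.path(dir, "m.npy")
  write_npy(m, f)
  expect_identical(read_npy(f), m)
  v <- c(1.5, -2.25, 0, 1e-300)
  write_npy(v, file.path(dir, "v.npy"))
  expect_identical(read_npy(file.path(dir, "v.npy")), v)
})
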