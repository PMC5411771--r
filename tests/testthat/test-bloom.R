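test_that("inserted keys are always found; repeated inserts set no new bits", {
  f <- bloom_filter(2^14, h = 3, seed = 1)
  set.seed(1)
  keys <- random_keys(500)
  expect_false(any(bf_contains(f, keys))) # empty filter
  bf_insert(f, keys)
  expect_true(all(bf_contains(f, keys)))
  pc <- bf_popcount(f)
  bf_insert(f, keys)
  expect_identical(bf_popcount(f), pc)
  # numeric keys are accepted too
  f2 <- bloom_filter(1024, h = 2)
  bf_insert(f2, c(0, 17, 2^40))
  expect_true(all(bf_contains(f2, c(0, 17, 2^40))))
})

test_that("bit occupancy matches the closed form", {
  set.seed(2)
  f <- bloom_filter(1e6, h = 1)
  keys <- unique(random_keys(1e5))
  bf_insert(f, keys)
  expected <- 1e6 * (1 - (1 - 1 / 1e6)^length(keys))
  expect_lt(abs(bf_popcount(f) / expected - 1), 0.01)
})

test_that("analytic FPR has the right limits and approximation accuracy", {
  expect_equal(fpr_analytic(1000, 4, 0), 0)
  expect_equal(fpr_analytic(1, 1, 1), 1)
  # exact and exponential forms agree closely in the operating regime
  expect_lt(abs(fpr_analytic(8e6, 1, 1e6) - fpr_analytic(8e6, 1, 1e6, approx = TRUE)),
            1e-4)
  expect_error(fpr_analytic(0, 1, 10), "m")
})

test_that("fresh keys hit at the analytic false-positive rate", {
  set.seed(3)
  for (case in list(c(h = 1, p = 0.05), c(h = 4, p = 0.10))) {
    h <- case[["h"]]; p <- case[["p"]]
    m <- 2^20
    # invert the approximate form for the insert count
    n <- round(-m / h * log(1 - p^(1 / h)))
    f <- bloom_filter(m, h = h)
    bf_insert(f, random_keys(n))
    probes <- random_keys(1e5)
    emp <- mean(bf_contains(f, probes))
    ana <- fpr_analytic(m, h, bf_inserts(f))
    expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / 1e5))
  }
})

test_that("size_for_fpr returns the smallest admissible byte-rounded size", {
  for (h in 1:5) {
    m <- size_for_fpr(1e6, 0.05, h = h)
    expect_equal(m %% 8, 0)
    expect_lte(fpr_analytic(m, h, 1e6), 0.05)
    expect_gt(fpr_analytic(m - 8, h, 1e6), 0.05)
  }
  expect_gte(size_for_fpr(1e6, 0.01), size_for_fpr(1e6, 0.05))
  expect_gte(size_for_fpr(1e6, 0.05), size_for_fpr(1e6, 0.20))
  expect_equal(size_for_fpr(0, 0.05), 8)
  expect_error(size_for_fpr(1e6, 1.5), "target_fpr")
})

test_that("cascade: repeated insertions climb one level per call", {
  cf <- cascading_bloom_filter(2^16, c = 3, h = 4)
  key <- "00000000deadbeef"
  cbf_insert(cf, key)
  expect_true(cbf_contains(cf, key, level = 1))
  expect_false(cbf_contains(cf, key, level = 2))
  expect_false(cbf_solid_contains(cf, key))
  cbf_insert(cf, rep(key, 2))
  expect_true(cbf_contains(cf, key, level = 2))
  expect_true(cbf_solid_contains(cf, key))
})

test_that("cascade equals exact count thresholding at negligible FPR", {
  set.seed(4)
  keys <- random_keys(2000)
  mult <- sample(1:5, length(keys), replace = TRUE)
  cf <- cascading_bloom_filter(2^22, c = 3, h = 4)
  cbf_insert(cf, rep(keys, mult))
  expect_identical(cbf_solid_contains(cf, keys), mult >= 3)
  # never-inserted keys are (essentially) never solid at this size
  expect_false(any(cbf_solid_contains(cf, random_keys(2000))))
  # per-level distinct insert counts match the multiplicity distribution
  expect_equal(cbf_info(cf)$level_inserts,
               c(sum(mult >= 1), sum(mult >= 2), sum(mult >= 3)))
})

test_that("memory accounting: c cascade levels plus equal tracking filter", {
  expect_equal(total_memory(1e6, 1), 2e6)
  expect_equal(total_memory(1e6, 3), 4e6)
  cf <- cascading_bloom_filter(1e4, c = 3)
  tr <- bloom_filter(1e4)
  expect_equal(cbf_bits(cf) + bf_bits(tr), total_memory(cbf_info(cf)$m, 3))
})

test_that("dropping early cascade levels keeps the solid set queryable", {
  cf <- cascading_bloom_filter(2^12, c = 2)
  cbf_insert(cf, rep("00000000000000ff", 2))
  cbf_drop_early(cf)
  expect_true(cbf_solid_contains(cf, "00000000000000ff"))
  expect_error(cbf_contains(cf, "00000000000000ff", level = 1), "dropped")
})

test_that("chance-connection probability decays as fpr^(k-1-o)", {
  expect_equal(chance_connection_probability(0.3, k = 31, o = 30), 1)
  expect_equal(chance_connection_probability(0, k = 31, o = 10), 0)
  expect_equal(chance_connection_probability(0.05, k = 31, o = 25), 0.05^5)
  expect_error(chance_connection_probability(0.05, k = 31, o = 31), "o")
})

test_that("a serialized filter round-trips", {
  f <- bloom_filter(4096, h = 3, seed = 9)
  set.seed(6)
  keys <- random_keys(100)
  bf_insert(f, keys)
  path <- tempfile(fileext = ".bloom")
  save_bloom(f, path, k = 21)
  g <- load_bloom(path)
  expect_true(all(bf_contains(g, keys)))
  expect_identical(bf_popcount(g), bf_popcount(f))
  expect_identical(bf_inserts(g), bf_inserts(f))
  expect_equal(attr(g, "k"), 21)
  unlink(path)
})
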