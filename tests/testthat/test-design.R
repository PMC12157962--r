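test_that("sample-size rules reproduce canonical and corner cases exactly", {
  cases <- list(
    list(c = 4, t = 2, a = 7, B = 20, orme = 143L, block = 400L, rec = 400L),
    list(c = 2, t = 2, a = 250, B = 1, orme = 2L, block = 20L, rec = 20L),
    list(c = 3, t = 2, a = 10, B = 5, orme = 75L, block = 100L, rec = 100L)
  )
  for (cs in cases) {
    out <- sample_size_requirements(c = cs$c, t = cs$t, a = cs$a, B = cs$B)
    expect_identical(out$orme_n, cs$orme)
    expect_identical(out$block_rule_n, cs$block)
    expect_identical(out$recommended_n, cs$rec)
  }
  expect_error(sample_size_requirements(c = 0, t = 2, a = 7, B = 20), "positive")
  expect_error(sample_size_requirements(c = 4, t = 1, a = 7, B = 20), "2 alternatives")
})

test_that("Orme requirement is monotone in its dimensions", {
  base <- sample_size_requirements(c = 3, t = 2, a = 6, B = 5)$orme_n
  for (cc in 3:6) {
    expect_gte(sample_size_requirements(c = cc, t = 2, a = 6, B = 5)$orme_n, base)
    base <- sample_size_requirements(c = cc, t = 2, a = 6, B = 5)$orme_n
  }
  prev <- Inf
  for (aa in c(2, 4, 8, 16)) {
    cur <- sample_size_requirements(c = 4, t = 2, a = aa, B = 5)$orme_n
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_lte(sample_size_requirements(c = 4, t = 3, a = 7, B = 5)$orme_n,
             sample_size_requirements(c = 4, t = 2, a = 7, B = 5)$orme_n)
})

test_that("dummy encoding follows the reference-category convention", {
  sp <- npi_attribute_space()
  nm <- predictor_names(sp)
  expect_length(nm, 12)                      # 11 attribute predictors + ASC
  expect_identical(nm[1], "asc_left")
  expect_identical(nm[12], "fee")

  x <- encode_profile(c(masks = "public", dining = "any_group",
                        vocalization = "allowed", events = "allowed",
                        quarantine = "none", booster = "not_compulsory",
                        fee = "30"), sp, position = "left")
  expect_equal(x[["masks.public"]], 1)
  expect_equal(x[["fee"]], 30)
  expect_equal(x[["asc_left"]], 1)
  expect_equal(sum(x) - x[["fee"]], 2)       # only the mask dummy and the ASC

  ref <- encode_profile(c(masks = "none", dining = "any_group",
                          vocalization = "allowed", events = "allowed",
                          quarantine = "none", booster = "not_compulsory",
                          fee = "0"), sp, position = "right")
  expect_true(all(ref == 0))

  expect_error(encode_profile(c(masks = "sometimes", dining = "any_group",
                                vocalization = "allowed", events = "allowed",
                                quarantine = "none", booster = "not_compulsory",
                                fee = "0"), sp), "unknown level")
})

test_that("encoding is injective and decodable over the full factorial", {
  sp <- npi_attribute_space()
  grid <- expand.grid(lapply(sp$attributes, function(a) a$levels),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 1152)
  enc <- t(apply(grid, 1, function(lv) encode_profile(lv, sp, "right")))
  expect_equal(nrow(unique(enc)), 1152)      # injective
  for (i in sample.int(1152, 60)) {          # decode round trip (sampled)
    dec <- decode_profile(enc[i, ], sp)
    expect_identical(unname(dec$levels), unname(unlist(grid[i, ])))
  }
})

test_that("generated designs satisfy structural invariants deterministically", {
  d <- canonical_design()
  df <- as.data.frame(d)
  expect_equal(length(unique(df$block)), 20)
  expect_equal(nrow(df), 20 * 7 * 2)
  # every block has exactly 7 tasks of 2 distinct alternatives
  for (b in unique(df$block)) {
    blk <- df[df$block == b, ]
    expect_equal(length(unique(blk$task)), 7)
    for (tk in unique(blk$task)) {
      alts <- blk[blk$task == tk, !(names(blk) %in% c("block", "task", "alt", "left_asc"))]
      expect_false(any(duplicated(alts)))
    }
  }
  expect_equal(df$left_asc, as.numeric(df$alt == 1))

  sp <- small_space()
  dm <- design_dims(3, 4, 2, sp)
  d1 <- generate_design(sp, dm, seed = 5, n_iter = 150)
  d2 <- generate_design(sp, dm, seed = 5, n_iter = 150)
  d3 <- generate_design(sp, dm, seed = 6, n_iter = 150)
  expect_identical(d1$levels, d2$levels)
  expect_false(identical(d1$levels, d3$levels))
})

test_that("infeasible dimensions are rejected", {
  sp <- tiny_space()                         # only 4 distinct profiles
  expect_error(generate_design(sp, design_dims(1, 1, 5, sp), seed = 1),
               "infeasible")
})

test_that("a single binary attribute with one task yields the unique pair", {
  sp <- attribute_space(categorical = list(z = c("a", "b")),
                        cost_name = "fee", cost_levels = c(0, 1))
  # force a 1-task design over a space with 4 profiles: both alternatives
  # must be distinct profiles
  d <- generate_design(sp, design_dims(1, 1, 2, sp), seed = 3, n_iter = 50)
  expect_false(identical(d$levels[1, ], d$levels[2, ]))
})

test_that("the optimised design is at least as balanced as 1,000 random ones", {
  balance_dev <- function(df, sp) {
    dev <- 0
    n <- nrow(df)
    for (a in sp$attributes) {
      cnt <- table(factor(as.character(df[[a$name]]), levels = a$levels))
      dev <- dev + sum(abs(cnt - n / length(a$levels))) / n
    }
    dev / length(sp$attributes)
  }
  sp <- npi_attribute_space()
  opt_dev <- balance_dev(as.data.frame(canonical_design()), sp)
  dm <- design_dims(20, 7, 2, sp)
  random_devs <- vapply(1:1000, function(i) {
    balance_dev(as.data.frame(generate_design(sp, dm, seed = 1000 + i,
                                              n_iter = 0)), sp)
  }, 0)
  expect_lte(opt_dev, min(random_devs))
})

test_that("the overlap weight pulls per-task overlap towards its target", {
  sp <- small_space()
  dm <- design_dims(4, 5, 2, sp)
  mean_overlap <- function(w) {
    devs <- vapply(1:3, function(s) {
      d <- generate_design(sp, dm, seed = 30 + s, n_iter = 400,
                           weights = c(balance = 1, d_error = 1, overlap = w))
      mean(dcemix:::overlap_fractions(d$levels, rep(seq_len(dm$B * dm$a),
                                                    each = dm$t)))
    }, 0)
    mean(devs)
  }
  target <- 1 / 3
  expect_lte(abs(mean_overlap(25) - target), abs(mean_overlap(0) - target) + 0.02)
})

test_that("design CSV export carries profiles and the encoded matrix", {
  d <- generate_design(small_space(), design_dims(2, 3, 2, small_space()),
                       seed = 9, n_iter = 100)
  tmp <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  write_design(d, tmp, tmp2)
  prof <- read.csv(tmp)
  enc <- read.csv(tmp2, check.names = FALSE)
  expect_equal(nrow(prof), 12)
  expect_true(all(c("block", "task", "alt", "a1", "a2", "fee", "left_asc")
                  %in% names(prof)))
  expect_equal(as.matrix(enc[, predictor_names(small_space())]),
               encoded_design_matrix(d), ignore_attr = TRUE)
})
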