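test_that("bundled instrument specs carry the documented structure", {
  specs <- bundled_instruments()
  expect_equal(nrow(specs[["DRS-R-98"]]$items), 13L)
  expect_true(all(specs[["DRS-R-98"]]$items$n_categories == 4L))
  expect_equal(nrow(specs[["MDAS"]]$items), 10L)
  expect_equal(specs[["CAM-S-LF"]]$max_score, 19L)
  expect_equal(specs[["CAM-S-SF"]]$max_score, 7L)
  expect_equal(specs[["DRS-R-98"]]$max_score, 39L)
  expect_equal(specs[["MDAS"]]$max_score, 30L)
  # sleep disturbance dichotomizes at moderate-or-worse everywhere
  for (s in specs[c("DRS-R-98", "MDAS", "CAM-S-LF")]) {
    sleep <- s$items[s$items$domain == "sleep_wake", ]
    expect_equal(sleep$cut, 2L)
    expect_true(all(s$items$cut[s$items$domain != "sleep_wake"] == 1L))
  }
})

test_that("spec loading validates structure and recomputes max_score", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: mini",
               "items:",
               "  - {id: x, domain: dx, categories: 2}"), f)
  s <- load_instrument_spec(f)
  expect_equal(s$max_score, 1L)  # single binary item
  writeLines(c("name: bad",
               "items:",
               "  - {id: x, domain: dx, categories: 1}"), f)
  expect_error(load_instrument_spec(f), "at least 2 categories")
  writeLines(c("name: bad2",
               "items:",
               "  - {id: x, categories: 3}"), f)
  expect_error(load_instrument_spec(f), "missing field 'domain'")
  expect_error(load_instrument_spec("/nonexistent.yaml"), "not found")
  expect_error(
    instrument_spec("c", data.frame(id = "x", domain = "d",
                                    n_categories = 3L, cut = 3L)),
    "cut out of range")
})

test_that("recode_missing maps administrative codes and rejects bad ratings", {
  spec <- toy_spec()
  raw <- data.frame(person_id = 1:3, day = 1L,
                    a = c("2", "refused", "0"),
                    b = c("1", "uncertain", ""),
                    c = c("0", "1", "dont_know"),
                    stringsAsFactors = FALSE)
  tab <- recode_missing(raw, spec)
  expect_identical(tab$a, c(2L, NA_integer_, 0L))
  expect_identical(tab$b, c(1L, NA_integer_, NA_integer_))
  expect_identical(tab$c, c(0L, 1L, NA_integer_))
  raw$a[2] <- "5"  # out of range on a 4-category item
  expect_error(recode_missing(raw, spec), "out of range 0..3")
  raw$a[2] <- "maybe"
  expect_error(recode_missing(raw, spec), "unrecognized code")
})

test_that("sum scores honor the missing-item rule and proration flag", {
  spec <- bundled_instruments("CAM-S-LF")[[1]]
  top <- as.list(setNames(spec$items$n_categories - 1L, spec$items$id))
  full <- cbind(data.frame(person_id = 1L, day = 1L), as.data.frame(top))
  zero <- full
  zero[spec$items$id] <- 0L
  part <- full
  part[[spec$items$id[3]]] <- NA_integer_
  tab <- response_table(rbind(full, within(zero, day <- 2L),
                              within(part, day <- 3L)), spec)
  sc <- sum_score(tab, spec)
  expect_equal(sc$score, c(19, 0, NA))
  pr <- sum_score(tab, spec, prorate = TRUE)
  expect_equal(pr$prorated, c(FALSE, FALSE, TRUE))
  expect_equal(pr$score[3], 19)  # 17 observed over 9 items, scaled to 10
  expect_true(all(pr$score <= spec$max_score))
})

test_that("dichotomization applies cuts, is monotone and idempotent", {
  spec <- bundled_instruments("DRS-R-98")[[1]]
  set.seed(3)
  st <- simulate_responses(flat_theta(150),
                           default_true_params(bundled_instruments("DRS-R-98"))[[1]],
                           spec, missing_rate = 0.05)
  d1 <- dichotomize(st, spec)
  # sleep cut 2: mild (1) -> 0; other items: mild -> 1
  sleep <- "sleep_wake_disturbance"
  expect_true(all(d1[[sleep]][st[[sleep]] == 1] == 0, na.rm = TRUE))
  expect_true(all(d1[[sleep]][st[[sleep]] >= 2] == 1, na.rm = TRUE))
  expect_true(all(d1$orientation[st$orientation == 1] == 1, na.rm = TRUE))
  expect_true(all(is.na(d1[[sleep]]) == is.na(st[[sleep]])))
  # coarsening never raises a sum score
  s_poly <- sum_score(st, spec)$score
  s_bin <- sum_score(d1, dichotomize_spec(spec))$score
  keep <- !is.na(s_poly)
  expect_true(all(s_bin[keep] <= s_poly[keep]))
  # idempotent
  d2 <- dichotomize(d1, dichotomize_spec(spec))
  expect_identical(as.data.frame(d2), as.data.frame(d1))
})

test_that("anchor maps follow the configured domain lists", {
  specs <- bundled_instruments(c("DRS-R-98", "MDAS", "CAM-S-LF"))
  maps <- build_anchor_maps(specs, anchor_domains = bundled_anchor_domains())
  expect_equal(nrow(maps[["MDAS"]]), 6L)
  expect_equal(nrow(maps[["CAM-S-LF"]]), 7L)
  expect_true("delusions" %in% maps[["MDAS"]]$domain)
  expect_false("attention" %in% maps[["MDAS"]]$domain)
  expect_false("memory" %in% maps[["CAM-S-LF"]]$domain)
  expect_length(attr(maps, "shared_domains"), 7L)
  # every pair shares the fine domain label
  for (m in maps) {
    ref <- specs[["DRS-R-98"]]$items
    for (r in seq_len(nrow(m))) {
      expect_equal(ref$domain[ref$id == m$reference_item[r]], m$domain[r])
    }
  }
  # anchor items with a coarse shared label all lie in the three-way set
  # (delusions is a pairwise MDAS anchor without a three-way label)
  coarse <- function(nm) unique(specs[[nm]]$items$shared[
    specs[[nm]]$items$domain %in% maps[[nm]]$domain])
  labs <- unlist(lapply(c("MDAS", "CAM-S-LF"), coarse))
  expect_true(all(labs[!is.na(labs)] %in% attr(maps, "shared_domains")))
  expect_true(anyNA(labs))
  # unknown anchor domain is a configuration error
  expect_error(
    build_anchor_maps(specs, anchor_domains = list(MDAS = c("nope", "orientation"))),
    "not present in both")
  # disjoint toy specs give an empty map
  t1 <- instrument_spec("t1", data.frame(id = "x", domain = "dx",
                                         n_categories = 2L, cut = 1L))
  t2 <- instrument_spec("t2", data.frame(id = "y", domain = "dy",
                                         n_categories = 2L, cut = 1L))
  m0 <- build_anchor_maps(list(t1 = t1, t2 = t2), reference = "t1")
  expect_equal(nrow(m0[["t2"]]), 0L)
})
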