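test_that("recoding maps synonyms, passes unknowns through and keeps best ranks", {
  peer_map <- c("older peer" = "peer", "younger peer" = "peer",
                "friend" = "peer", "peer" = "peer")
  expect_equal(recode_categories("older peer", peer_map, quiet = TRUE), "peer")
  expect_equal(recode_categories("mother", character(0), quiet = TRUE), "mother")
  expect_message(recode_categories("mother", peer_map), "unmapped")

  lists <- data.frame(participant_id = "p1", society = "BaYaka",
                      domain = "intra", rank = 1:3,
                      category = c("friend", "peer", "mother"))
  out <- recode_freelists(lists, peer_map, quiet = TRUE)
  expect_equal(out$category, c("peer", "mother"))
  expect_equal(out$rank, 1:2)  # peer keeps the earliest rank

  # re-ranking is per list when several lists collapse differently
  multi <- rbind(lists,
                 data.frame(participant_id = "p2", society = "BaYaka",
                            domain = "intra", rank = 1:4,
                            category = c("mother", "friend", "older peer",
                                         "aunt")))
  out2 <- recode_freelists(multi, peer_map, quiet = TRUE)
  p2 <- out2[out2$participant_id == "p2", ]
  expect_equal(p2$category, c("mother", "peer", "aunt"))
  expect_equal(p2$rank, 1:3)
  expect_silent(smiths_salience(out2))
})

test_that("Smith's salience follows the inverse-percentile-rank definition", {
  one <- data.frame(participant_id = "p1", rank = 1:2, category = c("A", "B"))
  tab <- smiths_salience(one)
  expect_equal(tab$smiths_s[tab$category == "A"], 1.0)
  expect_equal(tab$smiths_s[tab$category == "B"], 0.5)
  expect_equal(tab$frequency, c(1L, 1L))

  # always listed first in every list -> S = 1
  many <- do.call(rbind, lapply(1:7, function(i) {
    data.frame(participant_id = paste0("p", i), rank = 1:2,
               category = c("mother", paste0("other", i)))
  }))
  tabm <- smiths_salience(many)
  expect_equal(tabm$smiths_s[tabm$category == "mother"], 1.0)

  expect_error(smiths_salience(one[0, ]), "no free lists")
  dup <- rbind(one, one[1, ])
  expect_error(smiths_salience(dup), "distinct")
})

test_that("salience and frequency match the double-loop oracle on random fixtures", {
  for (s in 1:200) {
    lists <- make_random_lists(seed = 3000 + s,
                               n_lists = sample(3:15, 1),
                               n_cats = sample(3:8, 1))
    tab <- smiths_salience(lists)
    oracle <- oracle_salience(lists)
    expect_equal(stats::setNames(tab$smiths_s, tab$category),
                 oracle[tab$category], tolerance = 1e-12)
    # frequency columns agree between the two tables
    ft <- frequency_table(lists)
    expect_equal(stats::setNames(tab$frequency, tab$category)[ft$category],
                 stats::setNames(ft$frequency, ft$category))
    # rank-sum identity: sum_c S_c = (1/N) sum_p (L_p + 1)/2
    lens <- tapply(lists$rank, lists$participant_id, length)
    expect_equal(sum(tab$smiths_s),
                 sum((lens + 1) / 2) / length(lens), tolerance = 1e-12)
    # salience bounded in [0, 1], zero iff absent
    expect_true(all(tab$smiths_s > 0 & tab$smiths_s <= 1))
  }
})

test_that("salience is invariant to the order lists are supplied in", {
  lists <- make_random_lists(seed = 41, n_lists = 10)
  shuffled <- lists[rev(seq_len(nrow(lists))), ]
  expect_equal(smiths_salience(shuffled), smiths_salience(lists))
})

test_that("salience tables can be computed per society and domain", {
  a <- make_random_lists(seed = 1)
  b <- make_random_lists(seed = 2)
  b$domain <- "inter"
  combined <- rbind(a, b)
  tab <- salience_by_group(combined)
  expect_setequal(unique(tab$domain), c("intra", "inter"))
  sub <- tab[tab$domain == "intra", c("category", "frequency", "smiths_s")]
  rownames(sub) <- NULL
  expected <- as.data.frame(smiths_salience(a))
  attr(expected, "n_lists") <- NULL
  expect_equal(sub, expected)
})

test_that("mechanism tables reproduce printed-style percentages", {
  # counts with denominators 35 and 31 respondents
  mk <- function(soc, domain, counts) {
    mechs <- rep(names(counts), counts)
    data.frame(participant_id = sprintf("%s%02d", soc, seq_along(mechs)),
               society = soc, domain = domain, mechanism = mechs,
               stringsAsFactors = FALSE)
  }
  reports <- rbind(
    mk("Bandongo", "intra", c("Instruction" = 22, "Observation/Imitation" = 8,
                              "Self" = 5)),
    mk("Bandongo", "inter", c("Instruction" = 15, "Observation/Imitation" = 12,
                              "Self" = 8)),
    mk("BaYaka", "intra", c("Instruction" = 4, "Observation/Imitation" = 24,
                            "Play" = 1, "Self" = 2)),
    mk("BaYaka", "inter", c("Instruction" = 3, "Observation/Imitation" = 22,
                            "Self" = 1, "No Answer" = 5)))
  tab <- mechanism_table(reports)
  pct <- function(soc, domain, mech) {
    tab$percent[tab$society == soc & tab$domain == domain & tab$mechanism == mech]
  }
  expect_equal(pct("Bandongo", "intra", "Instruction"), 62.86)
  expect_equal(pct("Bandongo", "inter", "Instruction"), 42.86)
  expect_equal(pct("BaYaka", "intra", "Observation/Imitation"), 77.42)
  expect_equal(pct("BaYaka", "inter", "Observation/Imitation"), 70.97)
  expect_equal(pct("Bandongo", "intra", "Self"), 14.29)
  expect_equal(pct("BaYaka", "inter", "No Answer"), 16.13)
  # zero counts display as 0.00
  expect_equal(pct("Bandongo", "intra", "Play"), 0)
  # per society x domain the displayed percentages sum to 100 within rounding
  for (soc in c("Bandongo", "BaYaka")) {
    for (dom in c("intra", "inter")) {
      s <- sum(tab$percent[tab$society == soc & tab$domain == dom])
      expect_lt(abs(s - 100), 0.02 + 1e-9)
    }
  }
  expect_error(mechanism_table(rbind(reports, reports[1, ])), "more than one")
  bad <- reports; bad$mechanism[1] <- "Osmosis"
  expect_error(mechanism_table(bad), "unknown mechanism")
})

test_that("free-list and mechanism CSV files read back validated", {
  lists <- make_random_lists(seed = 55)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(lists, path, row.names = FALSE)
  back <- read_freelists(path)
  rownames(back) <- NULL; rownames(lists) <- NULL
  expect_equal(back, lists)
  expect_error(read_freelists(file.path(tempdir(), "nope.csv")), "not found")
})
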