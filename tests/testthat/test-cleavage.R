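test_that("default rule sets match the configured specificities", {
  rules <- load_enzyme_rules()
  get <- function(nm) rules[rules$name == nm, ]
  expect_setequal(get("trypsin")$p1[[1]], c("K", "R"))
  expect_setequal(get("pepsin_ph1.3")$p1[[1]], c("F", "L"))
  expect_setequal(get("chymotrypsin")$p1[[1]], c("F", "Y", "W", "L", "M", "N", "H"))
  expect_equal(get("oligopeptidase_f")$min_length, 4L)
  expect_setequal(
    get("proteinase_p1")$pairs[[1]],
    c("PG", "GL", "IL", "VF", "PL", "PK", "PW", "PF", "QH", "QL")
  )
  expect_equal(nrow(gi_enzymes()), 3)
  expect_equal(nrow(microbial_enzymes()), 2)
})

test_that("rule construction rejects invalid configurations", {
  expect_error(enzyme_rule("x", p1 = "B"), "Unknown residue")
  expect_error(enzyme_rule("x", p1 = "K", min_length = 1), "min_length")
  expect_error(enzyme_rule("x", pairs = "KRA"), "two-letter")
  f <- withr::local_tempfile(lines = c("bad:", '  p1: ["K", "1"]'))
  expect_error(load_enzyme_rules(f), "Unknown residue")
})

test_that("cleavage sites follow the P1/P1' predicate with 0-based bonds", {
  trypsin <- enzyme_rule("trypsin", p1 = c("K", "R"))
  expect_identical(find_cleavage_sites("AWKLFDDGV", trypsin), 2L)
  expect_identical(find_cleavage_sites("GG", trypsin), integer(0))
  chymo <- gi_enzymes() |> dplyr::filter(name == "chymotrypsin")
  # terminal residue has no following bond, so M at the end contributes none
  expect_identical(find_cleavage_sites("TESYFVFSVGM", chymo), c(3L, 4L, 6L))
  # P1' exclusion blocks a site
  noP <- enzyme_rule("noP", p1 = "K", exclusions = "P")
  expect_identical(find_cleavage_sites("AKPAKA", noP), 4L)
  # pair-level specificity
  pairy <- enzyme_rule("p1pair", pairs = "GL")
  expect_identical(find_cleavage_sites("AGLA", pairy), 1L)
  expect_identical(find_cleavage_sites("AGAL", pairy), integer(0))
  # substrates under the length floor are untouched
  floor4 <- enzyme_rule("floor", p1 = "K", min_length = 4)
  expect_identical(find_cleavage_sites("AKA", floor4), integer(0))
})

test_that("simultaneous digestion releases the expected fragments", {
  gi <- gi_enzymes()
  d <- digest_sequence("TESYFVFSVGM", gi)
  expect_true("VF" %in% d$fragment)
  expect_equal(d$start[d$fragment == "VF"], 6)
  expect_equal(d$end[d$fragment == "VF"], 7)
  expect_equal(digest_sequence("AWKLFDDGV", gi)$fragment[1], "AW")
  # no matching site: the whole sequence is the single fragment
  inert <- enzyme_rule("inert", p1 = "W")
  expect_equal(digest_sequence("GAGAGA", inert)$fragment, "GAGAGA")
  expect_error(digest_sequence("GG", gi[0, ]), "at least one")
})

test_that("digestion satisfies concatenation identity and matches a brute-force oracle", {
  gi <- gi_enzymes()
  peps <- random_peptides(1000, length_range = c(2, 60), seed = 7)
  for (s in peps$sequence) {
    d <- digest_sequence(s, gi)
    expect_identical(paste(d$fragment, collapse = ""), s)
    expect_identical(d$fragment, oracle_digest(s, gi))
  }
})

test_that("digestion is a fixed point after one pass", {
  gi <- gi_enzymes()
  peps <- random_peptides(100, length_range = c(5, 40), seed = 11)
  for (s in peps$sequence) {
    frags <- digest_sequence(s, gi)$fragment
    redigested <- unlist(lapply(frags, function(f) digest_sequence(f, gi)$fragment))
    expect_identical(redigested, frags)
  }
})

test_that("enlarging a P1 set never removes cut sites", {
  base_rule <- enzyme_rule("base", p1 = c("K", "R"))
  peps <- random_peptides(200, length_range = c(2, 40), seed = 13)
  for (extra in c("G", "L", "D")) {
    bigger <- enzyme_rule("bigger", p1 = c("K", "R", extra))
    for (s in peps$sequence[1:50]) {
      expect_true(all(
        find_cleavage_sites(s, base_rule) %in% find_cleavage_sites(s, bigger)
      ))
    }
  }
})

test_that("unique_fragments filters by length and partitions cleanly", {
  ref <- reference_peptides()
  both <- unique_fragments(ref, lengths = 2:3)
  di <- unique_fragments(ref, lengths = 2)
  tri <- unique_fragments(ref, lengths = 3)
  expect_setequal(both$fragment, c(di$fragment, tri$fragment))
  expect_equal(nrow(both), nrow(di) + nrow(tri))
  # the published parent attribution for ER
  er <- both$parents[both$fragment == "ER"][[1]]
  expect_true(all(c("AP01280", "AP01282", "AP01284") %in% er))
  # a single dipeptide maps to itself
  one <- unique_fragments(tibble::tibble(apd_id = "x", sequence = "GG"))
  expect_equal(one$fragment, "GG")
  expect_equal(one$parents[[1]], "x")
  # duplicates within one parent are deduplicated in the map
  rep2 <- unique_fragments(tibble::tibble(apd_id = "x", sequence = "AKAK"))
  expect_equal(rep2$parents[rep2$fragment == "AK"][[1]], "x")
})

test_that("digestion container supports tidy/glance accessors", {
  d <- digest_sequence("AWKLFDDGV", gi_enzymes(), parent_id = "AP01805")
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("fragment", "start", "end"))
  g <- glance(d)
  expect_equal(g$parent_id, "AP01805")
  expect_equal(g$parent_length, 9)
  expect_equal(g$n_fragments, nrow(td))
  expect_equal(g$n_cuts, g$n_fragments - 1)
})
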