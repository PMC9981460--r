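# Fragment specificity, top-3 ranking and the averaging cascade.

sch <- label_scheme("K")

test_that("fragment specificity counts covered target sites", {
  y5 <- fragment_specificity("KYSLAPVAKE", "y5", sch)
  expect_true(y5$diagnostic)
  expect_identical(y5$sites_covered, 9L)
  b9 <- fragment_specificity("KYSLAPVAKE", "b9", sch)
  expect_false(b9$diagnostic)
  expect_identical(b9$n_sites_covered, 2L)
  y3 <- fragment_specificity("KYSLAPVAKE", "y3", label_scheme("W"))
  expect_false(y3$diagnostic)
  expect_identical(y3$n_sites_covered, 0L)
  expect_error(fragment_specificity("KYSLAPVAKE", "y12", sch), "invalid")
})

test_that("fragments are ranked by mean abundance rank across samples", {
  recs <- rbind(
    data.frame(sample = "s1", fragment = c("y4", "y5", "y6", "y7"),
               area = c(100, 50, 50, 10)),
    data.frame(sample = "s2", fragment = c("y4", "y5", "y6", "y7"),
               area = c(90, 60, 60, 20)))
  r <- rank_fragments(recs)
  expect_equal(r$ranking$mean_rank[match(c("y4", "y5", "y6", "y7"),
                                         r$ranking$fragment)],
               c(1.0, 2.5, 2.5, 4.0))
  expect_identical(r$top, c("y4", "y5", "y6"))
  # ties at the cutoff resolved lexicographically
  tie <- data.frame(sample = "s1", fragment = c("y4", "y7", "y5", "y6"),
                    area = c(100, 10, 10, 10))
  expect_identical(rank_fragments(tie)$top, c("y4", "y5", "y6"))
  single <- data.frame(sample = "s1", fragment = "y5", area = 5)
  expect_identical(rank_fragments(single)$top, "y5")
})

test_that("state fractions normalise per fragment then average", {
  # one diagnostic fragment, areas (producer HH, mixed, consumer LL)
  recs <- make_transition_records(
    "KYSLAPVAKE", "y5", c("HH", "HL", "LH", "LL"),
    areas = c(30, 7.5, 7.5, 55))
  prof <- state_fractions(recs, sch)
  expect_equal(profile_fractions(prof), c(`0` = 0.30, `1` = 0.15,
                                          `2` = 0.55))
  expect_identical(prof$profile$state_class,
                   c("producer", "mixed", "consumer"))
  # two fragments with fractions (.2,.2,.6) and (.4,.2,.4): unweighted mean
  recs2 <- rbind(
    make_transition_records("KYSLAPVAKE", "y5",
                            c("HH", "HL", "LH", "LL"),
                            areas = c(20, 10, 10, 60)),
    make_transition_records("KYSLAPVAKE", "y3",
                            c("HH", "HL", "LH", "LL"),
                            areas = c(40, 10, 10, 40)))
  expect_equal(profile_fractions(state_fractions(recs2, sch)),
               c(`0` = 0.3, `1` = 0.2, `2` = 0.5))
  # site-resolved mixed components sum to the reported mixed fraction
  sr <- state_fractions(recs2, sch)$site_resolved
  expect_equal(sum(sr$fraction[sr$state %in% c("HL", "LH")]), 0.2)
})

test_that("profiles are invariant to record order", {
  cfg <- sim_config(seed = 5, sigma = 0.1, n_cells = 500)
  rep <- write_transition_report(cfg)$report
  p1 <- state_fractions(rep, sch)
  set.seed(1)
  p2 <- state_fractions(rep[sample(nrow(rep)), ], sch)
  expect_equal(p1$profile, p2$profile)
})

test_that("missing state rows are zero-filled with a warning", {
  recs <- make_transition_records("KYSLAPVAKE", "y5",
                                  c("HH", "LL"), areas = c(25, 75))
  expect_warning(prof <- state_fractions(recs, sch), "area 0")
  expect_equal(profile_fractions(prof),
               c(`0` = 0.25, `1` = 0, `2` = 0.75))
})

test_that("non-diagnostic-only peptides are flagged unquantifiable", {
  recs <- rbind(
    make_transition_records("KYSLAPVAKE", "y5",
                            c("HH", "HL", "LH", "LL"),
                            areas = c(30, 7.5, 7.5, 55)),
    make_transition_records("AKKAAAAAAE", "y2",   # covers no site
                            c("HH", "HL", "LH", "LL"),
                            areas = c(1, 1, 1, 1)))
  prof <- state_fractions(recs, sch)
  expect_identical(prof$unquantifiable, "AKKAAAAAAE")
})

test_that("precursor-level fractions merge the mixed components", {
  recs <- data.frame(sample = "s1", condition = "c1", replicate = 1L,
                     peptide = "KYSLAPVAKE", k = c(0L, 1L, 2L),
                     area = c(1, 2, 1))
  prof <- precursor_level_fractions(recs)
  expect_equal(profile_fractions(prof),
               c(`0` = 0.25, `1` = 0.5, `2` = 0.25))
  single <- data.frame(sample = "s1", condition = "c1", replicate = 1L,
                       peptide = "KYSLAPVAKE", k = 2L, area = 10)
  expect_equal(unname(profile_fractions(
    precursor_level_fractions(single, n_sites = 2L))), c(0, 0, 1))
})

test_that("fragment- and precursor-level profiles agree without noise", {
  cfg <- sim_config(model = "homogeneous", p = 0.35, sigma = 0,
                    seed = 9, n_cells = 2000)
  rep <- write_transition_report(cfg)$report
  frag_prof <- state_fractions(rep, sch)
  # MS1 view: sum the state areas of one fragment per peptide over k
  ms1 <- rep[rep$fragment == "y5", ]
  ms1$k <- vapply(strsplit(ms1$state, ""), function(x)
    sum(x == "L"), integer(1))
  ms1 <- aggregate(area ~ sample + condition + replicate + peptide + k,
                   ms1, sum)
  prec_prof <- precursor_level_fractions(ms1, n_sites = 2L)
  expect_equal(profile_fractions(frag_prof),
               profile_fractions(prec_prof), tolerance = 1e-9)
})

test_that("transition report CSV round trips through the reader", {
  cfg <- sim_config(seed = 13, n_cells = 200)
  path <- tempfile(fileext = ".csv")
  write_transition_report(cfg, path = path)
  recs <- read_transition_report(path)
  expect_named(recs, c("sample", "condition", "replicate", "peptide",
                       "state", "fragment", "area"))
  # a report missing a required column is rejected by name
  broken <- tempfile(fileext = ".csv")
  utils::write.csv(recs[, setdiff(names(recs), "area")], broken,
                   row.names = FALSE)
  expect_error(read_transition_report(broken), "area")
  # column maps rename foreign headers onto the canonical ones
  renamed <- tempfile(fileext = ".csv")
  recs2 <- recs
  names(recs2)[names(recs2) == "area"] <- "Total Area"
  utils::write.csv(recs2, renamed, row.names = FALSE)
  expect_equal(read_transition_report(renamed,
                                      col_map = c(area = "Total Area")),
               recs)
})
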