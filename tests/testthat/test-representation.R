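test_that("protection criteria select units inclusively", {
  u <- make_units(paste0("u", 1:4), pa_coverage = c(0, 0.05, 0.10, 0.4))
  expect_setequal(select_protected_units(u, "coverage", 0.10),
                  c("u3", "u4"))
  expect_setequal(select_protected_units(u, "presence"),
                  c("u2", "u3", "u4"))
  expect_setequal(select_protected_units(u, "coverage", 0),
                  paste0("u", 1:4))
  expect_error(select_protected_units(u, "coverage"), "threshold")
})

test_that("representation index reproduces printed worked examples", {
  cs <- paste0("u", 1:552)
  expect_equal(representation_index(cs, cs[1:261])$i_e_rounded, 47.3)
  expect_equal(representation_index(cs, cs[1:57])$i_e_rounded, 10.3)
  cs2 <- paste0("v", 1:276)
  expect_equal(representation_index(cs2, cs2[1:144])$i_e_rounded, 52.2)
  expect_equal(representation_index(cs2, cs2[1:31])$i_e_rounded, 11.2)

  r <- representation_index(cs, cs) # fully protected
  expect_equal(r$i_e, 100)
  expect_equal(r$a + r$b, 552L)
  expect_error(representation_index(character(0), "u1"), "empty")
})

test_that("representation is non-increasing in the coverage threshold", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    u <- make_units(paste0("u", 1:n),
                    pa_coverage = ifelse(runif(n) < 0.4, 0, runif(n)))
    cs <- sample(u$unit_id, sample(3:n, 1))
    tab <- assess_representation(cs, u, c(0, 0.05, 0.1, 0.2, 0.3, 0.4))
    cov_rows <- tab[tab$criterion == "coverage", ]
    expect_true(all(diff(cov_rows$i_e) <= 1e-12))
    expect_true(all(tab$i_e[tab$criterion == "presence"] >=
                      cov_rows$i_e[cov_rows$threshold > 0] - 1e-12))
    expect_true(all(tab$a + tab$b == length(cs)))
  }
})

test_that("gap identification matches brute-force set evaluation", {
  # fully protected: no gaps at all
  inc <- make_inc(list(u1 = "a", u2 = "b"))
  g0 <- identify_gaps(c("u1", "u2"), c("u1", "u2"), inc)
  expect_length(g0$gap_units, 0)
  expect_length(g0$uncovered_species, 0)

  # single-occurrence species in a gap unit: uncovered both ways
  inc1 <- make_inc(list(u1 = "a", u2 = "b"))
  for (d in c("rangewide", "cs_only")) {
    g <- identify_gaps(c("u1", "u2"), "u2", inc1, definition = d)
    expect_equal(g$gap_units, "u1")
    expect_equal(g$uncovered_species, "a")
  }

  # species in a gap CS unit but also in a protected non-CS unit:
  # uncovered under cs_only, covered under rangewide
  inc2 <- make_inc(list(u1 = c("a", "b"), u2 = "c", u3 = "a",
                        u4 = "d", u5 = "e"))
  cs <- c("u1", "u2")
  s_p <- c("u2", "u3")
  g_rw <- identify_gaps(cs, s_p, inc2, universe = c("a", "b", "c"),
                        definition = "rangewide")
  g_cs <- identify_gaps(cs, s_p, inc2, universe = c("a", "b", "c"),
                        definition = "cs_only")
  expect_false("a" %in% g_rw$uncovered_species)
  expect_true("a" %in% g_cs$uncovered_species)
  expect_true("b" %in% g_rw$uncovered_species)

  # randomised brute force for each definition
  set.seed(23)
  for (i in 1:15) {
    inc <- rand_instance(8, 14)
    csm <- sample(inc$units, 4)
    sp <- sample(inc$units, 3)
    uni <- species_of(inc, csm)
    gaps <- setdiff(csm, sp)
    occ <- inc$units_by_species[uni]
    exp_rw <- sort(names(occ)[vapply(occ, function(x) !any(x %in% sp),
                                     logical(1))])
    exp_cs <- sort(names(occ)[vapply(occ, function(x) {
      inx <- intersect(x, csm)
      length(inx) > 0 && all(inx %in% gaps)
    }, logical(1))])
    expect_equal(identify_gaps(csm, sp, inc, uni,
                               definition = "rangewide")$uncovered_species,
                 exp_rw)
    expect_equal(identify_gaps(csm, sp, inc, uni,
                               definition = "cs_only")$uncovered_species,
                 exp_cs)
  }
})

test_that("gap reports flag threatened and endemic subsets", {
  inc <- make_inc(list(u1 = c("a", "b"), u2 = "c"))
  sp <- suppressMessages(validate_species_table(data.frame(
    species_id = c("a", "b", "c"), threatened = c(TRUE, FALSE, FALSE),
    endemic = c(TRUE, TRUE, FALSE))))
  g <- identify_gaps(c("u1", "u2"), "u2", inc, species_table = sp)
  expect_setequal(g$uncovered_species, c("a", "b"))
  expect_equal(g$threatened_uncovered, "a")
  expect_setequal(g$endemic_uncovered, c("a", "b"))
})

test_that("congruence over the union matches printed percentages", {
  cs <- paste0("c", 1:552)
  pa <- c(cs[1:489], paste0("p", 1:(1670 - 489)))
  units <- make_units(union(cs, pa))
  cg <- congruence_summary(cs, pa, units)
  expect_equal(cg$n_union, 1670 + 552 - 489)
  expect_equal(cg$n_common, 489L)
  expect_equal(cg$pct_common_int, 28)

  cs2 <- paste0("d", 1:276)
  pa2 <- c(cs2[1:248], paste0("q", 1:(1670 - 248)))
  cg2 <- congruence_summary(cs2, pa2, make_units(union(cs2, pa2)))
  expect_equal(cg2$pct_common_int, 15)

  un <- make_units(c("a", "b", "c", "d"))
  expect_equal(congruence_summary(c("a", "b"), c("c", "d"), un)$pct_common, 0)
  expect_equal(congruence_summary(c("a", "b"), c("a", "b"), un)$pct_common,
               100)
  # area share weights by unit area
  un2 <- make_units(c("a", "b"), area = c(300, 100))
  cg3 <- congruence_summary(c("a", "b"), "a", un2)
  expect_equal(cg3$area_pct_common, 75)
})

test_that("coverage classes partition the set and conserve area", {
  u0 <- make_units(paste0("u", 1:3), pa_coverage = 0)
  cl0 <- coverage_class_areas(paste0("u", 1:3), u0)
  expect_equal(cl0$area_pct[cl0$class == "0"], 100)

  u1 <- make_units(c("a", "b"), area = 50, pa_coverage = c(0.07, 0.25))
  cl1 <- coverage_class_areas(c("a", "b"), u1)
  expect_equal(cl1$n_units[cl1$class == "[0.05,0.1)"], 1L)
  expect_equal(cl1$n_units[cl1$class == "[0.2,0.3)"], 1L)
  expect_equal(cl1$area_pct[cl1$class == "[0.05,0.1)"], 50)

  # brute-force tally on random data
  set.seed(12)
  u <- make_units(paste0("u", 1:30), area = runif(30, 10, 100),
                  pa_coverage = ifelse(runif(30) < 0.3, 0, runif(30)))
  cl <- coverage_class_areas(u$unit_id, u)
  expect_equal(sum(cl$n_units), 30L)
  expect_equal(sum(cl$area_pct), 100, tolerance = 1e-9)
  edges <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 1.000001)
  for (j in seq_len(nrow(cl))) {
    manual <- if (cl$class[j] == "0") {
      u$pa_coverage == 0
    } else {
      u$pa_coverage >= cl$lower[j] & u$pa_coverage < edges[j] &
        u$pa_coverage > 0
    }
    expect_equal(cl$n_units[j], sum(manual))
    expect_equal(cl$area[j], sum(u$area[manual]))
  }
  expect_error(coverage_class_areas(u$unit_id, u, c(0, 0.5, 0.3)),
               "increasing")
})

test_that("regional capture proportions match a naive per-region count", {
  set.seed(8)
  strata <- c("N", "C", "S")
  units <- validate_unit_table(data.frame(
    unit_id = paste0("u", 1:12), stratum = rep(strata, each = 4),
    region = rep(strata, each = 4), area = 1, pa_coverage = 0))
  sets <- lapply(1:12, function(i) sample(paste0("s", 1:15), 3))
  names(sets) <- units$unit_id
  inc <- suppressWarnings(make_inc(sets))
  # assign each species the region of one of its occurrence units, as a
  # consistent biogeographic attribution
  region_of_unit <- stats::setNames(units$region, units$unit_id)
  sp <- suppressMessages(validate_species_table(data.frame(
    species_id = inc$species,
    taxon_group = sample(c("g1", "g2"), length(inc$species), TRUE),
    region = vapply(inc$units_by_species[inc$species],
                    function(u) unname(region_of_unit[u[1]]), character(1)))))

  # CS containing all units captures every species everywhere
  re_all <- regional_effectiveness(units$unit_id, inc, sp, units,
                                   universe = inc$species)
  expect_true(all(re_all$pct[re_all$n_species > 0] == 100))

  csm <- sample(units$unit_id, 5)
  re <- regional_effectiveness(csm, inc, sp, units, universe = inc$species)
  for (j in seq_len(nrow(re))) {
    spp <- sp$species_id[sp$region == re$region[j] &
                           sp$taxon_group == re$taxon_group[j]]
    cs_units_in <- intersect(csm,
                             units$unit_id[units$region == re$region[j]])
    captured <- sum(vapply(spp, function(s)
      any(inc$units_by_species[[s]] %in% cs_units_in), logical(1)))
    expect_equal(re$n_captured[j], captured)
  }
  expect_true(is.finite(attr(re, "mean")))

  sp_bad <- sp
  sp_bad$region[1] <- NA
  expect_error(regional_effectiveness(csm, inc, sp_bad, units,
                                      universe = inc$species), "region")
})

test_that("the time series recomputes the single-year path per year", {
  cs <- paste0("u", 1:6)
  const <- expand.grid(unit_id = cs, year = 2000:2002)
  const$pa_coverage <- rep(c(0, 0, 0.2, 0.3, 0.4, 0.5), times = 3)
  ts0 <- representation_time_series(cs, const, "presence")
  expect_true(all(ts0$i_e == ts0$i_e[1]))

  set.seed(3)
  u <- make_units(cs, pa_coverage = runif(6, 0, 0.6))
  tl <- simulate_pa_timeline(u, 1995:2000, "monotone", seed = 4)
  ts1 <- representation_time_series(cs, tl, "coverage", threshold = 0.1)
  expect_true(all(diff(ts1$i_e) >= 0)) # nondecreasing coverage paths
  # self-consistency with the single-year path
  for (y in c(1995L, 1998L)) {
    suby <- tl[tl$year == y, ]
    uy <- make_units(suby$unit_id, pa_coverage = suby$pa_coverage)
    ry <- representation_index(cs,
                               select_protected_units(uy, "coverage", 0.1))
    expect_equal(ts1$i_e[ts1$year == y], ry$i_e)
  }
  expect_error(representation_time_series(cs, tl, years = 1800), "1800")
})
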