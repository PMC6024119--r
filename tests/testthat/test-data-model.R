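test_that("incidence construction is binary, deduplicated and validated", {
  inc <- incidence_matrix(data.frame(
    species_id = c("sp1", "sp2", "sp1"), unit_id = c("u1", "u1", "u2")))
  expect_equal(length(inc$species), 2L)
  expect_equal(length(inc$units), 2L)
  expect_equal(unname(unit_richness(inc)["u1"]), 2L)

  expect_warning(
    inc2 <- incidence_matrix(data.frame(
      species_id = c("sp1", "sp2", "sp1", "sp1"),
      unit_id = c("u1", "u1", "u2", "u1"))),
    "1 duplicate")
  expect_equal(inc2$species_by_unit, inc$species_by_unit)

  expect_error(incidence_matrix(data.frame(x = 1)), "required column")
  expect_error(incidence_matrix(data.frame(species_id = character(0),
                                           unit_id = character(0))),
               "empty")
})

test_that("presence records round-trip through delimited text exactly", {
  set.seed(42)
  inc <- rand_instance(20, 50)
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_presence_records(inc, path, sep = sep)
    back <- read_presence_records(path) # separator auto-detected
    # oracle: set equality of the record sets
    key <- function(x) sort(with(as.data.frame(x),
                                 paste(species_id, unit_id)))
    expect_identical(key(back), key(inc))
  }
})

test_that("per-unit richness equals the count of distinct records", {
  set.seed(7)
  inc <- rand_instance(12, 30)
  df <- as.data.frame(inc)
  for (u in inc$units) {
    expect_equal(unname(unit_richness(inc)[u]),
                 length(unique(df$species_id[df$unit_id == u])))
  }
})

test_that("unit table validation derives pa_present and enforces bounds", {
  u <- validate_unit_table(data.frame(
    unit_id = c("u1", "u2"), stratum = "strA", area = 1000,
    pa_coverage = c(0.25, 0)))
  expect_equal(u$pa_present, c(TRUE, FALSE))

  # explicit override marks point-only PAs present despite zero coverage
  u2 <- validate_unit_table(data.frame(
    unit_id = "u3", stratum = "strA", area = 10, pa_coverage = 0,
    pa_present = 1))
  expect_true(u2$pa_present)

  expect_error(validate_unit_table(data.frame(
    unit_id = "u1", stratum = "a", area = 1000, pa_coverage = 1.3)),
    "pa_coverage.*u1")
  expect_error(validate_unit_table(data.frame(
    unit_id = "u1", stratum = "a", area = -5, pa_coverage = 0.1)),
    "area")
  expect_error(validate_unit_table(data.frame(
    unit_id = c("u1", "u1"), stratum = "a", area = 1, pa_coverage = 0)),
    "duplicate")
})

test_that("species table fills absent flags and rejects duplicates", {
  expect_message(
    sp <- validate_species_table(data.frame(species_id = c("a", "b"))),
    "endemic")
  expect_false(any(sp$endemic))
  expect_false(any(sp$threatened))

  sp2 <- validate_species_table(data.frame(
    species_id = "sp1", taxon_group = "mammal", threatened = 1,
    nationally_protected = 0, endemic = "false", region = "regionN"))
  expect_true(sp2$threatened)
  expect_false(sp2$endemic)

  expect_error(validate_species_table(data.frame(
    species_id = c("a", "a"))), "duplicate")
  expect_error(validate_species_table(
    data.frame(species_id = "a", taxon_group = "dragon"),
    groups = c("mammal", "bird")), "dragon")
})

test_that("dataset cross-validation flags checklist species without records", {
  inc <- make_inc(list(u1 = c("a", "b")))
  sp <- suppressMessages(validate_species_table(
    data.frame(species_id = c("a", "b", "c"))))
  un <- make_units("u1")
  rep <- validate_dataset(inc, sp, un)
  expect_equal(rep$species_without_occurrences, "c")
  expect_length(rep$species_missing_from_table, 0)
})

test_that("PA area allocation splits evenly and conserves totals", {
  pa <- data.frame(pa_id = "p1", total_area = 300)
  links <- data.frame(pa_id = "p1", unit_id = c("u1", "u2", "u3"))
  alloc <- allocate_pa_area(pa, links)
  expect_equal(alloc$allocated_area, rep(100, 3))

  links$area <- c(200, 100, NA)
  expect_error(allocate_pa_area(pa, links), "partial")
  alloc2 <- allocate_pa_area(
    data.frame(pa_id = "p1", total_area = 300),
    data.frame(pa_id = "p1", unit_id = c("u1", "u2"), area = c(200, 100)))
  expect_equal(alloc2$allocated_area, c(200, 100))

  expect_error(allocate_pa_area(
    data.frame(pa_id = c("p1", "p2"), total_area = c(10, 10)),
    data.frame(pa_id = "p1", unit_id = "u1")), "p2")

  # conservation on a random multi-PA configuration
  set.seed(11)
  pa3 <- data.frame(pa_id = paste0("p", 1:5),
                    total_area = round(runif(5, 10, 500)))
  links3 <- do.call(rbind, lapply(1:5, function(i) data.frame(
    pa_id = paste0("p", i),
    unit_id = sample(paste0("u", 1:4), sample(1:3, 1)))))
  alloc3 <- allocate_pa_area(pa3, links3)
  expect_equal(as.numeric(tapply(alloc3$allocated_area, alloc3$pa_id, sum)[
    pa3$pa_id]), pa3$total_area)
})

test_that("overlapping PA contributions add and coverage is capped", {
  units <- make_units(c("u1", "u2"), area = c(150, 1000))
  alloc <- rbind(
    data.frame(pa_id = "p1", unit_id = "u1", allocated_area = 100),
    data.frame(pa_id = "p2", unit_id = "u1", allocated_area = 100),
    data.frame(pa_id = "p2", unit_id = "u2", allocated_area = 250))
  expect_warning(out <- compute_pa_coverage(units, alloc), "capped")
  # oracle: min(unit area, summed contributions) / unit area
  expect_equal(out$pa_coverage, c(min(150, 200) / 150, 250 / 1000))
  expect_true(all(out$pa_present))
})

test_that("wide per-year coverage columns convert to long format", {
  u <- validate_unit_table(data.frame(
    unit_id = c("u1", "u2"), stratum = "a", area = 1,
    pa_coverage = c(0.2, 0), cov_2000 = c(0.1, 0), cov_2010 = c(0.2, 0)))
  long <- coverage_by_year(u)
  expect_equal(nrow(long), 4L)
  expect_equal(long$pa_coverage[long$year == 2010 & long$unit_id == "u1"],
               0.2)
  expect_error(coverage_by_year(make_units("u1")), "cov_")
})
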