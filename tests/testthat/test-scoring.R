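sch <- fastview_schema()

test_that("category rating follows the consistently-positive/negative rule", {
  pwo <- "Pavement width and obstructions"
  resp <- function(w, f, p) {
    c("Pavement width (metres)" = w, "Street furniture placement" = f,
      "Presence of cars parked on the pavement" = p)
  }
  # wide pavement, aligned furniture, no pavement parking: top score
  expect_equal(score_category(resp(">3", "Aligned to side", "No cars on pavement"),
                              pwo, sch), 2L)
  # consistently negative: poor
  expect_equal(score_category(resp("no pavement", "Poorly placed", "Cars on pavement"),
                              pwo, sch), 0L)
  # neither consistently good nor poor: fair
  expect_equal(score_category(resp(">3", "Poorly placed", "No cars on pavement"),
                              pwo, sch), 1L)
  # a lone intermediate response among N/As is neither all-positive nor all-negative
  expect_equal(score_category(resp("2–3", "N/A", "N/A"), pwo, sch), 1L)
  # intermediate blocks "all negative" too
  expect_equal(score_category(resp("1–2", "Poorly placed", "Cars on pavement"),
                              pwo, sch), 1L)
  # all-N/A category carries no information
  expect_true(is.na(score_category(
    c("Pavement trip hazards" = "N/A", "Pavement surface consistency" = "N/A",
      "Reinstatements in pavement surface" = "N/A"),
    "Pavement surface quality", sch)))
  expect_error(score_category(resp(">3", "Aligned to side", "hovering"), pwo, sch),
               "legal codes")
  expect_error(score_category(resp(">3", "Aligned to side", "No cars on pavement")[-2],
                              pwo, sch), "no response")
})

test_that("scoring a record scores every category; extremes hit 2 and 0", {
  top <- score_audits(fixture_record(sch), sch)
  expect_equal(nrow(top), 9)
  expect_true(all(top$rating == 2L))
  bottom <- score_audits(fixture_record(sch, "last_ordinal"), sch)
  expect_true(all(bottom$rating == 0L))
})

test_that("vectorised scoring matches category-by-category application", {
  truth <- sim_config(n_links = 25, seed = 42) |> simulate_truth()
  recs <- simulate_audit_records(truth, sch, flip_prob = 0.3, seed = 99)
  expect_equal(nrow(validate_record(recs, sch)), 0)
  scored <- score_audits(recs, sch)

  for (i in sample(nrow(recs), 5)) {
    for (cat in unique(sch$category)) {
      facs <- unique(sch$factor[sch$category == cat])
      resp <- vapply(facs, function(f) recs[[paste(cat, f, sep = "::")]][i],
                     character(1))
      names(resp) <- facs
      expected <- score_category(resp, cat, sch)
      got <- scored$rating[scored$link_id == recs$link_id[i] &
                             scored$category == cat]
      expect_equal(got, expected)
    }
  }
})

test_that("scoring depends on polarity only, not on level wording", {
  make <- function(codes) {
    path <- tempfile(fileext = ".json")
    jsonlite::write_json(list(version = "t", categories = list(list(
      name = "C", factors = list(list(
        name = "F", allows_na = FALSE,
        levels = lapply(codes, function(x) list(code = x))
      ), list(
        name = "G", allows_na = FALSE,
        levels = lapply(codes, function(x) list(code = x))
      ))
    ))), path, auto_unbox = TRUE)
    load_schema(path)
  }
  s1 <- make(c("alpha", "beta", "gamma"))
  s2 <- make(c("shiny", "dull", "grim"))
  combos <- expand.grid(f = 1:3, g = 1:3)
  for (i in seq_len(nrow(combos))) {
    r1 <- score_category(c(F = c("alpha", "beta", "gamma")[combos$f[i]],
                           G = c("alpha", "beta", "gamma")[combos$g[i]]), "C", s1)
    r2 <- score_category(c(F = c("shiny", "dull", "grim")[combos$f[i]],
                           G = c("shiny", "dull", "grim")[combos$g[i]]), "C", s2)
    expect_equal(r1, r2)
  }
})

test_that("side combination is a commutative, idempotent worst-side rule", {
  expect_equal(combine_sides(2L, 2L), 2L)
  expect_equal(combine_sides(2L, 0L), 0L)
  expect_equal(combine_sides(1L, NA), 1L) # pavement on one side only
  expect_true(is.na(combine_sides(NA, NA)))
  grid <- expand.grid(a = c(0:2, NA), b = c(0:2, NA))
  expect_equal(combine_sides(grid$a, grid$b), combine_sides(grid$b, grid$a))
  expect_equal(combine_sides(grid$a, grid$a), as.integer(grid$a))
  expect_equal(combine_sides(2L, 0L, rule = "max"), 2L)
})

test_that("combining link sides collapses the side column", {
  scored <- tibble::tibble(
    link_id = c("L1", "L1", "L2"), side = c("A", "B", "A"),
    rater_id = "R1", occasion = 1L, mode = "streetview",
    category = "Lighting", rating = c(2L, 0L, 1L)
  )
  out <- combine_link_sides(scored)
  expect_false("side" %in% names(out))
  expect_equal(out$rating[out$link_id == "L1"], 0L)
  expect_equal(out$rating[out$link_id == "L2"], 1L)
})

test_that("rating matrices take the shapes of the three reliability designs", {
  study <- simulate_study(sim_config(seed = 11))
  m_inter <- build_rating_matrix(study$inter, "Lighting", "inter_rater")
  expect_equal(dim(m_inter), c(54, 4)) # item + 3 raters
  expect_equal(sort(setdiff(names(m_inter), "item")), c("R1", "R2", "R3"))

  m_intra <- build_rating_matrix(study$intra, "Lighting", "intra_rater")
  expect_equal(dim(m_intra), c(60, 3)) # 3 raters x 20 links, 2 occasions
  expect_equal(setdiff(names(m_intra), "item"), c("occasion_1", "occasion_2"))

  m_crit <- build_rating_matrix(study$criterion, "Lighting", "criterion")
  expect_equal(dim(m_crit), c(30, 3))
  expect_setequal(setdiff(names(m_crit), "item"), c("streetview", "onsite"))

  # one link, two modes is a legal 1 x 2 design
  one <- study$criterion |>
    dplyr::filter(link_id == link_id[1], category == "Lighting")
  expect_equal(dim(build_rating_matrix(one, "Lighting", "criterion")), c(1, 3))

  dup <- dplyr::bind_rows(study$inter, study$inter[1, ])
  expect_error(build_rating_matrix(dup, study$inter$category[1], "inter_rater"),
               "duplicate")
})

test_that("rating-matrix cells are confined to 0/1/2/missing", {
  expect_error(as_rating_matrix(cbind(a = c(1, 3), b = c(1, 1))), "cells")
  expect_error(as_rating_matrix(cbind(a = c(1, 2))), "at least 2")
})
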