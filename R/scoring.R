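#' Reduce factor responses to a good/fair/poor category rating
#'
#' The data-reduction rule of the audit instrument: within a category, ignore
#' N/A responses; if every remaining response is the factor's most positive
#' level the category is rated good (2); if every remaining response is the
#' most negative level it is rated poor (0); anything in between — any
#' intermediate response, or a mix of positives and negatives — is fair (1).
#' A category in which every factor was answered N/A carries no information
#' and rates as missing (`NA`).
#'
#' For example, a street with wide pavements (>3 m), street furniture aligned
#' to the side, and no cars parked on the pavement takes the top score (2) in
#' the pavement width and obstructions category.
#'
#' @param responses named character vector of level codes; names are the
#'   factor names of `category`. All factors of the category must be present.
#' @param category category name.
#' @param schema an `instrument_schema`.
#' @return integer rating 0, 1 or 2, or `NA_integer_` when all responses are
#'   N/A.
#' @examples
#' sch <- fastview_schema()
#' score_category(
#'   c("Pavement width (metres)" = ">3",
#'     "Street furniture placement" = "Aligned to side",
#'     "Presence of cars parked on the pavement" = "No cars on pavement"),
#'   "Pavement width and obstructions", sch
#' )
#' @export
score_category <- function(responses, category, schema) {
  sub <- schema[schema$category == category, ]
  if (nrow(sub) == 0) stop_fv("unknown category: '", category, "'")
  facs <- unique(sub$factor)
  missing <- setdiff(facs, names(responses))
  if (length(missing) > 0) {
    stop_fv("category '", category, "': no response for factor(s) ",
            paste0("'", missing, "'", collapse = ", "))
  }
  pol <- vapply(facs, function(f) level_polarity(schema, f, responses[[f]]),
                character(1))
  rate_polarities(pol)
}

# The rule itself, on polarity tags. Shared by the scalar and vector paths.
rate_polarities <- function(pol) {
  if (anyNA(pol)) stop_fv("unknown level code in responses")
  pol <- pol[pol != "not_applicable"]
  if (length(pol) == 0) return(NA_integer_)
  if (all(pol == "positive")) return(2L)
  if (all(pol == "negative")) return(0L)
  1L
}

#' Score audit records across all categories
#'
#' Applies [score_category()] to every category of the schema for every
#' record, after validating the records. The result is long (tidy): one row
#' per record x category, ready for [combine_link_sides()] and
#' [build_rating_matrix()].
#'
#' @param records audit records, one row per (link, side, rater, occasion,
#'   mode) with `"<category>::<factor>"` response columns (see
#'   [validate_record()]).
#' @param schema an `instrument_schema`.
#' @param validate if `TRUE` (default), run [validate_record()] first and fail
#'   with the list of violations.
#' @return a tibble with the identifier columns of `records` plus `category`
#'   and `rating` (0/1/2 or `NA`).
#' @export
score_audits <- function(records, schema, validate = TRUE) {
  records <- tibble::as_tibble(records)
  if (validate) {
    v <- validate_record(records, schema)
    if (nrow(v) > 0) {
      stop_fv("records do not validate (", nrow(v), " violation(s)); first: ",
              v$field[1], " - ", v$detail[1])
    }
  }
  sf <- schema_factors(schema)
  id_cols <- intersect(c("link_id", "side", "rater_id", "occasion", "mode", "date"),
                       names(records))
  # polarity lookup keyed by "<category>::<factor>" + normalized code
  key <- paste(field_name(schema$category, schema$factor), normalize_code(schema$code))
  pol_map <- stats::setNames(schema$polarity, key)

  per_cat <- lapply(unique(sf$category), function(cat) {
    cols <- field_name(cat, sf$factor[sf$category == cat])
    pol <- vapply(cols, function(cl) {
      pol_map[paste(cl, normalize_code(as.character(records[[cl]])))]
    }, character(nrow(records)))
    pol <- matrix(pol, nrow = nrow(records))
    rating <- apply(pol, 1, rate_polarities)
    dplyr::bind_cols(records[id_cols],
                     tibble::tibble(category = cat, rating = as.integer(rating)))
  })
  purrr::list_rbind(per_cat) |>
    dplyr::arrange(dplyr::across(dplyr::any_of(c("link_id", "side", "rater_id",
                                                 "occasion", "mode"))))
}

#' Combine the ratings of the two road sides
#'
#' Each link is audited on both sides of the road where possible; agreement
#' statistics work on one rating per link, so side ratings are collapsed
#' first. The default rule is the minimum (worst side): walkability of a link
#' is constrained by its least walkable usable side. Where one side was not
#' audited (e.g. a road with a pavement on one side only) the audited side's
#' rating carries through.
#'
#' @param a,b integer rating vectors (0/1/2 or `NA`), recycled to a common
#'   length.
#' @param rule `"min"` (default, worst side) or `"max"` (best side).
#' @return integer vector of combined ratings; `NA` only where both inputs
#'   are `NA`.
#' @examples
#' combine_sides(c(2L, 2L, 1L), c(2L, 0L, NA))
#' @export
combine_sides <- function(a, b, rule = c("min", "max")) {
  rule <- match.arg(rule)
  f <- if (rule == "min") pmin else pmax
  out <- f(a, b, na.rm = TRUE)
  out[is.na(a) & is.na(b)] <- NA_integer_
  as.integer(out)
}

#' @rdname combine_sides
#' @param scored a long scored tibble from [score_audits()] with a `side`
#'   column.
#' @return `combine_link_sides()` returns the scored tibble with `side`
#'   collapsed away: one row per (link, rater, occasion, mode, category).
#' @export
combine_link_sides <- function(scored, rule = c("min", "max")) {
  rule <- match.arg(rule)
  if (!"side" %in% names(scored)) return(tibble::as_tibble(scored))
  keys <- intersect(c("link_id", "rater_id", "occasion", "mode", "category"),
                    names(scored))
  scored |>
    dplyr::summarise(
      rating = if (all(is.na(.data$rating))) NA_integer_ else {
        agg <- if (rule == "min") min else max
        as.integer(agg(.data$rating, na.rm = TRUE))
      },
      .by = dplyr::all_of(keys)
    )
}

#' Assemble a rating matrix for a reliability design
#'
#' A rating matrix is the items-by-columns table an agreement statistic
#' consumes: one row per audit unit, one column per rater, occasion or mode,
#' each cell a 0/1/2 category rating (or `NA`). The three reliability designs
#' map onto it as:
#'
#' * `inter_rater` — items are links, columns are raters (one occasion, one
#'   mode).
#' * `intra_rater` — items are (rater, link) pairs pooled across raters,
#'   columns are occasions 1 and 2.
#' * `criterion` — items are (rater, link) pairs, columns are the two audit
#'   modes (`streetview`, `onsite`), pairing each rater's own desk and
#'   on-site audits.
#'
#' Side ratings, if still present, are collapsed with [combine_link_sides()]
#' first.
#'
#' @param scored a long scored tibble ([score_audits()] output, or the
#'   simulator's).
#' @param category category name to extract.
#' @param design one of `"inter_rater"`, `"intra_rater"`, `"criterion"`.
#' @param occasion occasion used for the inter-rater design (default 1).
#' @param mode mode used for the inter- and intra-rater designs (default
#'   `"streetview"`).
#' @param side_rule passed to [combine_link_sides()].
#' @return a `rating_matrix`: a tibble whose first column is `item` and whose
#'   remaining columns are the design's rating columns, with attributes
#'   `category` and `design`.
#' @export
build_rating_matrix <- function(scored, category, design = c("inter_rater",
                                "intra_rater", "criterion"),
                                occasion = 1L, mode = "streetview",
                                side_rule = "min") {
  design <- match.arg(design)
  scored <- combine_link_sides(scored, rule = side_rule)
  sub <- scored[scored$category == category, ]
  if (nrow(sub) == 0) stop_fv("no scored audits for category '", category, "'")

  sub <- switch(design,
    inter_rater = {
      s <- sub[sub$occasion == occasion & sub$mode == mode, ]
      if (length(unique(s$rater_id)) < 2) {
        stop_fv("inter_rater design needs >= 2 raters")
      }
      dplyr::transmute(s, item = as.character(.data$link_id),
                       column = as.character(.data$rater_id), rating = .data$rating)
    },
    intra_rater = {
      s <- sub[sub$mode == mode & sub$occasion %in% c(1L, 2L), ]
      if (length(unique(s$occasion)) < 2) {
        stop_fv("intra_rater design needs occasions 1 and 2")
      }
      dplyr::transmute(s, item = paste(.data$rater_id, .data$link_id, sep = ":"),
                       column = paste0("occasion_", .data$occasion), rating = .data$rating)
    },
    criterion = {
      s <- sub[sub$occasion == occasion, ]
      if (length(unique(s$mode)) < 2) {
        stop_fv("criterion design needs both 'streetview' and 'onsite' audits")
      }
      dplyr::transmute(s, item = paste(.data$rater_id, .data$link_id, sep = ":"),
                       column = .data$mode, rating = .data$rating)
    }
  )
  dup <- sub |> dplyr::count(.data$item, .data$column) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_fv("duplicate audits for the same design cell, e.g. item '",
            dup$item[1], "', column '", dup$column[1], "'")
  }
  wide <- tidyr::pivot_wider(sub, id_cols = "item", names_from = "column",
                             values_from = "rating")
  wide <- wide[order(wide$item), ]
  new_rating_matrix(wide, category = category, design = design)
}

new_rating_matrix <- function(wide, category = NA_character_, design = NA_character_) {
  if (ncol(wide) < 3) stop_fv("a rating matrix needs at least 2 rating columns")
  cells <- unlist(wide[-1])
  if (!all(is.na(cells) | cells %in% 0:2)) {
    stop_fv("rating-matrix cells must be 0, 1, 2 or missing")
  }
  out <- tibble::as_tibble(wide)
  attr(out, "category") <- category
  attr(out, "design") <- design
  class(out) <- c("rating_matrix", class(tibble::tibble()))
  out
}

#' Construct a rating matrix from a plain table
#'
#' Convenience constructor for matrices that did not come through
#' [build_rating_matrix()] (simulated columns, published examples, tests).
#'
#' @param x a matrix or data frame of ratings in `{0, 1, 2, NA}`; if it has no
#'   `item` column one is generated.
#' @param category,design optional labels carried as attributes.
#' @return a `rating_matrix`.
#' @export
as_rating_matrix <- function(x, category = NA_character_, design = NA_character_) {
  x <- as.data.frame(x)
  if (!"item" %in% names(x)) {
    x <- cbind(item = sprintf("item_%03d", seq_len(nrow(x))), x)
  } else {
    x <- x[c("item", setdiff(names(x), "item"))]
  }
  new_rating_matrix(tibble::as_tibble(x), category = category, design = design)
}

# numeric cell matrix (items x columns), item ids as rownames
rating_cells <- function(x) {
  m <- as.matrix(as.data.frame(x)[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- x$item
  m
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat("<rating_matrix> ", attr(x, "design") %||% "?", " / ",
      attr(x, "category") %||% "?", ": ", nrow(x), " items x ",
      ncol(x) - 1, " columns\n", sep = "")
  NextMethod()
}
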