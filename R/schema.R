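#' The FASTVIEW street-audit instrument schema
#'
#' An instrument schema describes a street-audit rubric: an ordered set of
#' walkability categories (e.g. pavement surface quality, lighting), each
#' holding one to three observable factors (e.g. pavement width), each factor
#' offering a fixed ordered list of response levels printed from the most
#' positive option through to the most negative. The schema drives record
#' validation, polarity lookup and the good/fair/poor data-reduction rule.
#'
#' The schema is represented as a tibble with one row per level, in instrument
#' order, with columns `category`, `factor`, `code` (the verbatim level text),
#' `polarity` (one of `"positive"`, `"intermediate"`, `"negative"`,
#' `"not_applicable"`) and `allows_na` (whether the factor offers an N/A
#' level). The instrument version tag is stored in the `"version"` attribute.
#'
#' Polarity follows the positional rule implied by the level ordering: within
#' each factor the first listed non-N/A level is positive, the last is
#' negative, and anything between is intermediate. A two-level factor
#' (e.g. "Landmarks; no landmarks") therefore has one positive and one
#' negative level and no intermediate.
#'
#' @param path path to a schema JSON file. The bundled FASTVIEW definition is
#'   used by [fastview_schema()].
#' @return an `instrument_schema` tibble (see Details).
#' @examples
#' sch <- fastview_schema()
#' dplyr::count(sch, category)
#' @seealso [validate_record()], [level_polarity()], [score_audits()]
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop_fv("schema file not found: ", path)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_fv("schema file does not parse as JSON: ", conditionMessage(e))
  )
  if (is.null(raw$categories) || length(raw$categories) == 0) {
    stop_fv("schema file has no categories")
  }
  rows <- purrr::imap(raw$categories, function(cat, i) {
    if (is.null(cat$name) || !nzchar(cat$name)) {
      stop_fv("category #", i, " has no name")
    }
    if (is.null(cat$factors) || length(cat$factors) == 0) {
      stop_fv("category '", cat$name, "' has no factors")
    }
    fac_names <- purrr::map_chr(cat$factors, function(f) f$name %||% "")
    if (anyDuplicated(fac_names)) {
      stop_fv("category '", cat$name, "': duplicate factor name '",
              fac_names[duplicated(fac_names)][1], "'")
    }
    purrr::imap(cat$factors, function(fac, j) {
      if (is.null(fac$name) || !nzchar(fac$name)) {
        stop_fv("category '", cat$name, "': factor #", j, " has no name")
      }
      if (is.null(fac$levels) || length(fac$levels) < 2) {
        stop_fv("category '", cat$name, "', factor '", fac$name,
                "': needs at least 2 levels")
      }
      tibble::tibble(
        category = cat$name,
        factor = fac$name,
        code = purrr::map_chr(fac$levels, function(l) {
          if (is.null(l$code)) {
            stop_fv("category '", cat$name, "', factor '", fac$name,
                    "': level without a code")
          }
          trimws(l$code)
        }),
        polarity = purrr::map_chr(fac$levels, function(l) l$polarity %||% NA_character_),
        allows_na = isTRUE(fac$allows_na)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  # Polarity may be omitted in hand-written files; derive it positionally.
  rows <- rows |>
    dplyr::group_by(.data$category, .data$factor) |>
    dplyr::mutate(polarity = dplyr::coalesce(.data$polarity, positional_polarity(.data$code))) |>
    dplyr::ungroup()
  new_instrument_schema(rows, version = raw$version %||% "unversioned")
}

# Assign polarity by position: N/A codes tagged not_applicable, then first
# remaining level positive, last negative, middles intermediate.
positional_polarity <- function(codes) {
  is_na_level <- normalize_code(codes) %in% c("n/a", "na", "n/a*")
  pol <- rep("intermediate", length(codes))
  pol[is_na_level] <- "not_applicable"
  idx <- which(!is_na_level)
  pol[idx[1]] <- "positive"
  pol[idx[length(idx)]] <- "negative"
  pol
}

new_instrument_schema <- function(rows, version) {
  sch <- tibble::as_tibble(rows)
  attr(sch, "version") <- version
  class(sch) <- c("instrument_schema", class(tibble::tibble()))
  check_schema(sch)
  sch
}

# Structural invariants; called on every load and construction.
check_schema <- function(sch) {
  cats <- unique(sch$category)
  for (cat in cats) {
    sub <- sch[sch$category == cat, ]
    facs <- unique(sub$factor)
    n_fac <- length(facs)
    if (n_fac < 1 || n_fac > 3) {
      stop_fv("category '", cat, "': must have 1-3 factors, has ", n_fac)
    }
    for (fac in facs) {
      lv <- sub[sub$factor == fac, ]
      who <- paste0("category '", cat, "', factor '", fac, "'")
      if (nrow(lv) < 2) stop_fv(who, ": needs at least 2 levels")
      if (anyDuplicated(normalize_code(lv$code))) {
        stop_fv(who, ": duplicate level codes")
      }
      n_na <- sum(lv$polarity == "not_applicable")
      if (lv$allows_na[1] && n_na != 1) {
        stop_fv(who, ": allows_na factors need exactly one N/A level")
      }
      if (!lv$allows_na[1] && n_na != 0) {
        stop_fv(who, ": has an N/A level but allows_na is FALSE")
      }
      ordinal <- lv$polarity[lv$polarity != "not_applicable"]
      if (ordinal[1] != "positive" ||
          ordinal[length(ordinal)] != "negative" ||
          sum(ordinal == "positive") != 1 || sum(ordinal == "negative") != 1 ||
          !all(ordinal[-c(1, length(ordinal))] == "intermediate")) {
        stop_fv(who, ": polarity must run positive (first listed) through ",
                "intermediate to negative (last listed)")
      }
    }
    if (any(duplicated(facs))) stop_fv("category '", cat, "': duplicate factor names")
  }
  if (anyDuplicated(cats)) stop_fv("duplicate category names")
  invisible(sch)
}

#' @rdname load_schema
#' @export
fastview_schema <- function() {
  load_schema(system.file("extdata", "fastview.json", package = "fastview"))
}

#' Write an instrument schema to JSON
#'
#' Inverse of [load_schema()]: the written file parses back to a schema equal
#' to the original, field for field.
#'
#' @param schema an `instrument_schema`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  cats <- lapply(unique(schema$category), function(cat) {
    sub <- schema[schema$category == cat, ]
    list(
      name = cat,
      factors = lapply(unique(sub$factor), function(fac) {
        lv <- sub[sub$factor == fac, ]
        list(
          name = fac,
          allows_na = lv$allows_na[1],
          levels = purrr::map2(lv$code, lv$polarity, function(code, pol) {
            list(code = code, polarity = pol)
          })
        )
      })
    )
  })
  jsonlite::write_json(
    list(version = attr(schema, "version"), categories = cats),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Look up the polarity of a level code
#'
#' @param schema an `instrument_schema`.
#' @param factor factor name (unqualified, e.g. `"Pavement width (metres)"`).
#' @param code level code; matched case-insensitively, with whitespace trimmed
#'   and the ASCII hyphen accepted as an alias for the en-dash in range codes.
#' @return one of `"positive"`, `"intermediate"`, `"negative"`,
#'   `"not_applicable"`.
#' @examples
#' level_polarity(fastview_schema(), "Pavement width (metres)", ">3")
#' @export
level_polarity <- function(schema, factor, code) {
  sub <- schema[schema$factor == factor, ]
  if (nrow(sub) == 0) stop_fv("unknown factor: '", factor, "'")
  hit <- normalize_code(sub$code) == normalize_code(code)
  if (!any(hit)) {
    stop_fv("unknown level '", code, "' for factor '", factor,
            "'; legal codes: ", paste(sub$code, collapse = "; "))
  }
  sub$polarity[which(hit)[1]]
}

# Distinct (category, factor, allows_na) table in instrument order.
schema_factors <- function(schema) {
  dplyr::distinct(tibble::as_tibble(schema)[c("category", "factor", "allows_na")])
}

#' Validate audit records against an instrument schema
#'
#' Checks each record (row) for the two data contracts an audit record must
#' satisfy: every factor of every category answered (N/A counts as an answer
#' where the factor allows it), and every response drawn from that factor's
#' level set. Violations are returned as data, never raised, so a batch of
#' field records can be triaged in one pass.
#'
#' @param records a data frame with one row per audit record: identifier
#'   columns (`link_id`, `side`, `rater_id`, `occasion`, `mode`, optionally
#'   `date`) and one response column per factor named
#'   `"<category>::<factor>"`.
#' @param schema an `instrument_schema`.
#' @return a tibble of violations with columns `row`, `link_id`, `field`,
#'   `issue` (`"missing_response"`, `"unknown_code"`, `"missing_column"`,
#'   `"bad_identifier"`) and `detail`. Zero rows means the records are valid.
#' @examples
#' sch <- fastview_schema()
#' rec <- blank_record(sch)
#' nrow(validate_record(rec, sch)) # one violation per unanswered factor
#' @export
validate_record <- function(records, schema) {
  records <- tibble::as_tibble(records)
  fields <- field_name(schema_factors(schema)$category, schema_factors(schema)$factor)
  legal <- split(normalize_code(schema$code), field_name(schema$category, schema$factor))
  legal_print <- split(schema$code, field_name(schema$category, schema$factor))

  out <- list()
  emit <- function(row, field, issue, detail) {
    link <- if ("link_id" %in% names(records)) as.character(records$link_id[row]) else NA_character_
    out[[length(out) + 1]] <<- tibble::tibble(
      row = row, link_id = link, field = field, issue = issue, detail = detail
    )
  }

  absent <- setdiff(fields, names(records))
  for (f in absent) emit(NA_integer_, f, "missing_column", "factor column absent from records")

  if ("side" %in% names(records)) {
    bad <- which(!records$side %in% c("A", "B"))
    for (i in bad) emit(i, "side", "bad_identifier", paste0("side must be 'A' or 'B', got '", records$side[i], "'"))
  }
  if ("mode" %in% names(records)) {
    bad <- which(!records$mode %in% c("streetview", "onsite"))
    for (i in bad) emit(i, "mode", "bad_identifier", paste0("mode must be 'streetview' or 'onsite', got '", records$mode[i], "'"))
  }
  if ("occasion" %in% names(records)) {
    occ <- suppressWarnings(as.integer(records$occasion))
    bad <- which(is.na(occ) | occ < 1)
    for (i in bad) emit(i, "occasion", "bad_identifier", "occasion must be an integer >= 1")
  }

  for (f in intersect(fields, names(records))) {
    vals <- as.character(records[[f]])
    miss <- which(is.na(vals) | !nzchar(trimws(vals)))
    for (i in miss) emit(i, f, "missing_response", "no response recorded")
    known <- setdiff(seq_along(vals), miss)
    bad <- known[!normalize_code(vals[known]) %in% legal[[f]]]
    for (i in bad) {
      emit(i, f, "unknown_code",
           paste0("'", vals[i], "' is not a level; legal codes: ",
                  paste(legal_print[[f]], collapse = "; ")))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(row = integer(), link_id = character(), field = character(),
                   issue = character(), detail = character())
  } else {
    purrr::list_rbind(out)
  }
}

#' @rdname validate_record
#' @export
validate_records <- validate_record

#' Template audit record for an instrument
#'
#' Returns a one-row tibble with the identifier columns and one (empty)
#' response column per factor, useful as a data-entry template and in tests.
#'
#' @inheritParams validate_record
#' @param link_id,side,rater_id,occasion,mode identifier values for the row.
#' @return a one-row tibble.
#' @export
blank_record <- function(schema, link_id = "L001", side = "A",
                         rater_id = "R1", occasion = 1L, mode = "streetview") {
  sf <- schema_factors(schema)
  rec <- tibble::tibble(
    link_id = link_id, side = side, rater_id = rater_id,
    occasion = as.integer(occasion), mode = mode
  )
  for (f in field_name(sf$category, sf$factor)) rec[[f]] <- NA_character_
  rec
}

#' Read and write audit-record CSV files
#'
#' Audit records travel as UTF-8 CSV with a mandatory header: one row per
#' (link, side, rater, occasion, mode) and factor columns named
#' `"<category>::<factor>"`.
#'
#' @param path file path.
#' @param records a records tibble (see [validate_record()]).
#' @return `read_audit_records()` returns a tibble; `write_audit_records()`
#'   returns `path` invisibly.
#' @export
read_audit_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    occasion = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
}

#' @rdname read_audit_records
#' @export
write_audit_records <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @export
print.instrument_schema <- function(x, ...) {
  cat("<instrument_schema> version ", attr(x, "version"), ": ",
      length(unique(x$category)), " categories, ",
      nrow(dplyr::distinct(tibble::as_tibble(x)[c("category", "factor")])),
      " factors, ", nrow(x), " levels\n", sep = "")
  NextMethod()
}
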