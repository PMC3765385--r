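#' Percent observed agreement
#'
#' The proportion of items on which all compared columns give the same
#' category rating, as a percentage. Items with any missing cell are dropped
#' listwise. With more than two columns the default is the mean of all
#' pairwise two-column agreements (`method = "pairwise"`); `method = "all"`
#' instead counts only items on which every column agrees.
#'
#' @param x a `rating_matrix` (or matrix/data frame coercible via
#'   [as_rating_matrix()]).
#' @param method multi-column aggregation, `"pairwise"` (default) or
#'   `"all"`.
#' @return percentage in \eqn{[0, 100]}.
#' @examples
#' m <- as_rating_matrix(cbind(a = c(2, 1, 0), b = c(2, 1, 1)))
#' percent_agreement(m) # 2 of 3 items agree
#' @export
percent_agreement <- function(x, method = c("pairwise", "all")) {
  method <- match.arg(method)
  m <- complete_cells(x)
  if (ncol(m) == 2 || method == "all") {
    same <- apply(m, 1, function(r) all(r == r[1]))
    return(100 * mean(same))
  }
  pairs <- utils::combn(ncol(m), 2)
  mean(apply(pairs, 2, function(p) 100 * mean(m[, p[1]] == m[, p[2]])))
}

complete_cells <- function(x, log_excluded = FALSE) {
  m <- if (inherits(x, "rating_matrix")) rating_cells(x) else {
    rating_cells(as_rating_matrix(x))
  }
  keep <- stats::complete.cases(m)
  if (log_excluded && any(!keep)) {
    message(sum(!keep), " item(s) with missing cells excluded")
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop_fv("no complete items: every row has a missing cell")
  m
}

#' Cohen's kappa for two columns of categorical ratings
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} for a
#' two-column design (two occasions of one rater, or two audit modes), where
#' \eqn{p_o} is the observed proportion of agreeing items and \eqn{p_e} the
#' agreement expected from the product of the two columns' marginal rating
#' distributions. Items with a missing cell are dropped listwise.
#'
#' When both columns are constant and identical there is no variation to
#' correct for (\eqn{p_e = 1}); kappa is then undefined and returned as `NA`
#' with a warning — a known pathology of the statistic, which is why percent
#' agreement is always reported alongside it.
#'
#' @inheritParams percent_agreement
#' @return kappa in \eqn{[-1, 1]}, or `NA` when undefined.
#' @examples
#' m <- as_rating_matrix(cbind(a = rep(c(0, 1), c(25, 5)),
#'                             b = rep(c(0, 1, 0, 1), c(20, 5, 10, 5))))
#' cohen_kappa(m)
#' @export
cohen_kappa <- function(x) {
  m <- complete_cells(x)
  if (ncol(m) != 2) {
    stop_fv("cohen_kappa needs exactly 2 rating columns, got ", ncol(m),
            "; use fleiss_kappa() for multi-rater designs")
  }
  cats <- sort(unique(c(m)))
  pa <- tabulate(match(m[, 1], cats), length(cats)) / nrow(m)
  pb <- tabulate(match(m[, 2], cats), length(cats)) / nrow(m)
  p_o <- mean(m[, 1] == m[, 2])
  p_e <- sum(pa * pb)
  if (1 - p_e < .Machine$double.eps^0.5) {
    warning("kappa undefined: expected agreement is 1 (no rating variation)",
            call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for a fixed number of raters
#'
#' Multi-rater chance-corrected agreement for designs where every item is
#' rated by the same number of raters (here: all auditors rating all links).
#' Per-item agreement \eqn{P_i} is the proportion of agreeing rater pairs,
#' expected agreement is \eqn{\sum_j p_j^2} over the pooled category
#' proportions \eqn{p_j}, and \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar
#' P_e)}. Items with any missing cell are excluded (with a message giving the
#' count), preserving the equal-raters assumption.
#'
#' With two columns this is the two-rater special case of Fleiss' statistic
#' (pooled marginals), which is not in general equal to Cohen's kappa
#' (rater-specific marginals).
#'
#' @inheritParams percent_agreement
#' @return kappa in \eqn{[-1, 1]}, or `NA` when expected agreement is 1.
#' @export
fleiss_kappa <- function(x) {
  m <- complete_cells(x, log_excluded = TRUE)
  n_raters <- ncol(m)
  if (n_raters < 2) stop_fv("fleiss_kappa needs >= 2 rating columns")
  cats <- sort(unique(c(m)))
  # n_ij: items x categories count table
  counts <- vapply(cats, function(k) rowSums(m == k), numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m))
  p_j <- colSums(counts) / (nrow(m) * n_raters)
  P_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps^0.5) {
    warning("kappa undefined: expected agreement is 1 (no rating variation)",
            call. = FALSE)
    return(NA_real_)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Verbal interpretation bands for kappa
#'
#' The conventional Landis-Koch labels: 0.01-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-0.99 almost perfect;
#' values at or below zero indicate agreement no better than chance, exactly
#' 1 is perfect, and an undefined kappa maps to `"undefined"`.
#'
#' @param kappa numeric vector of kappa values (may contain `NA`).
#' @return character vector of band labels.
#' @examples
#' interpret_kappa(c(0.69, 0.9, -0.05, NA))
#' @export
interpret_kappa <- function(kappa) {
  dplyr::case_when(
    is.na(kappa) ~ "undefined",
    kappa <= 0 ~ "poor/less than chance",
    kappa <= 0.20 ~ "slight",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "substantial",
    kappa < 1 ~ "almost perfect",
    .default = "perfect"
  )
}

#' Agreement statistics for one rating matrix
#'
#' Percent agreement plus the design-appropriate kappa (Cohen's for two
#' columns, Fleiss' for three or more) and its interpretation band, as a
#' one-row tibble.
#'
#' @inheritParams percent_agreement
#' @param kappa_type `"auto"` (default: Cohen for 2 columns, Fleiss
#'   otherwise), `"cohen"` or `"fleiss"`.
#' @param agreement_method passed to [percent_agreement()].
#' @return a one-row tibble: `category`, `design`, `n_items` (complete items
#'   used), `percent_agreement`, `kappa`, `kappa_type`, `interpretation`.
#' @export
agreement <- function(x, kappa_type = c("auto", "cohen", "fleiss"),
                      agreement_method = "pairwise") {
  kappa_type <- match.arg(kappa_type)
  m <- suppressMessages(complete_cells(x))
  if (kappa_type == "auto") kappa_type <- if (ncol(m) == 2) "cohen" else "fleiss"
  k <- withCallingHandlers(
    if (kappa_type == "cohen") cohen_kappa(x) else suppressMessages(fleiss_kappa(x)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  tibble::tibble(
    category = attr(x, "category") %||% NA_character_,
    design = attr(x, "design") %||% NA_character_,
    n_items = nrow(m),
    percent_agreement = percent_agreement(x, method = agreement_method),
    kappa = k,
    kappa_type = kappa_type,
    interpretation = interpret_kappa(k)
  )
}

#' Per-category reliability report for one design
#'
#' Runs the full reliability analysis for one design over every category of
#' the instrument: builds each category's rating matrix, computes percent
#' agreement and the design-appropriate kappa, and summarises across
#' categories (mean, min, max). This is the table-shaped result the original
#' instrument evaluation reports per design.
#'
#' @param scored a long scored tibble ([score_audits()] or the simulator).
#' @param design one of `"inter_rater"`, `"intra_rater"`, `"criterion"`.
#' @param schema an `instrument_schema`; its categories define the report
#'   rows. Defaults to the categories present in `scored`.
#' @param ... passed to [build_rating_matrix()] (e.g. `occasion`, `mode`,
#'   `side_rule`).
#' @param agreement_method passed to [percent_agreement()].
#' @return a `reliability_report` object; see [tidy.reliability_report()] and
#'   [glance.reliability_report()].
#' @export
reliability_report <- function(scored, design, schema = NULL, ...,
                               agreement_method = "pairwise") {
  categories <- if (is.null(schema)) unique(scored$category) else unique(schema$category)
  results <- purrr::map(categories, function(cat) {
    m <- build_rating_matrix(scored, cat, design = design, ...)
    agreement(m, agreement_method = agreement_method)
  }) |> purrr::list_rbind()
  new_reliability_report(results, design)
}

new_reliability_report <- function(results, design) {
  structure(
    list(results = results, summary = summarize_reliability(results),
         design = design),
    class = "reliability_report"
  )
}

#' Summary statistics over per-category reliability results
#'
#' Arithmetic mean, minimum and maximum of percent agreement and kappa across
#' categories. Undefined kappas are skipped in the kappa summaries (with a
#' message); percent agreement always uses all rows.
#'
#' @param results a tibble with columns `percent_agreement` and `kappa` (one
#'   row per category), e.g. `tidy()` of a report or a published score table.
#' @return a one-row tibble: `n_categories`, mean/min/max of percent
#'   agreement, `n_kappa` (defined kappas used), mean/min/max of kappa.
#' @examples
#' summarize_reliability(
#'   dplyr::filter(fastview_published_scores(), design == "intra_rater")
#' )
#' @export
summarize_reliability <- function(results) {
  k <- results$kappa[!is.na(results$kappa)]
  if (length(k) < nrow(results)) {
    message(nrow(results) - length(k),
            " undefined kappa value(s) skipped in the kappa summary")
  }
  tibble::tibble(
    n_categories = nrow(results),
    mean_agreement = mean(results$percent_agreement),
    min_agreement = min(results$percent_agreement),
    max_agreement = max(results$percent_agreement),
    n_kappa = length(k),
    mean_kappa = if (length(k)) mean(k) else NA_real_,
    min_kappa = if (length(k)) min(k) else NA_real_,
    max_kappa = if (length(k)) max(k) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reliability report
#'
#' @param x a `reliability_report`.
#' @param ... unused.
#' @return `tidy()`: the per-category results tibble; `glance()`: the one-row
#'   cross-category summary with the design tag.
#' @export
tidy.reliability_report <- function(x, ...) x$results

#' @rdname tidy.reliability_report
#' @export
glance.reliability_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(design = x$design), x$summary)
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(format_reliability_report(x), sep = "\n")
  invisible(x)
}

#' Format a reliability report as an aligned text table
#'
#' Category rows with percent agreement (one decimal) and kappa (two
#' decimals, half-away-from-zero), followed by a mean/min/max summary block.
#'
#' @param x a `reliability_report`.
#' @return character vector of lines.
#' @export
format_reliability_report <- function(x) {
  r <- x$results
  fmt_k <- function(k) ifelse(is.na(k), "", sprintf("%.2f", round_half_up(k, 2)))
  body <- data.frame(
    Category = r$category,
    `% Agreement` = sprintf("%.1f", round_half_up(r$percent_agreement, 1)),
    K = fmt_k(r$kappa),
    Interpretation = r$interpretation,
    check.names = FALSE
  )
  s <- x$summary
  foot <- data.frame(
    Category = c("mean", "min", "max"),
    `% Agreement` = sprintf("%.1f", round_half_up(
      c(s$mean_agreement, s$min_agreement, s$max_agreement), 1)),
    K = fmt_k(c(s$mean_kappa, s$min_kappa, s$max_kappa)),
    Interpretation = "",
    check.names = FALSE
  )
  tab <- rbind(body, foot)
  widths <- vapply(names(tab), function(cl) max(nchar(c(cl, tab[[cl]]))), numeric(1))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  lines <- c(
    paste0("Reliability (", x$design, ")"),
    paste(mapply(pad, names(tab), widths), collapse = "  "),
    vapply(seq_len(nrow(body)), function(i) {
      paste(mapply(pad, unlist(body[i, ]), widths), collapse = "  ")
    }, character(1)),
    strrep("-", sum(widths) + 2 * (ncol(tab) - 1)),
    vapply(seq_len(nrow(foot)), function(i) {
      paste(mapply(pad, unlist(foot[i, ]), widths), collapse = "  ")
    }, character(1))
  )
  lines
}

#' Write a reliability report to CSV
#'
#' Writes the per-category rows followed by `mean`/`min`/`max` summary rows
#' in the same columns.
#'
#' @param x a `reliability_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reliability_report <- function(x, path) {
  r <- x$results
  s <- x$summary
  foot <- tibble::tibble(
    category = c("mean", "min", "max"),
    design = x$design,
    n_items = NA_integer_,
    percent_agreement = c(s$mean_agreement, s$min_agreement, s$max_agreement),
    kappa = c(s$mean_kappa, s$min_kappa, s$max_kappa),
    kappa_type = NA_character_,
    interpretation = NA_character_
  )
  readr::write_csv(dplyr::bind_rows(r, foot), path, na = "")
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reliability report
#'
#' Bar panels of percent agreement and kappa per category, in instrument
#' order, with the conventional kappa interpretation cut-points overlaid on
#' the kappa panel.
#'
#' @param object a `reliability_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.reliability_report <- function(object, ...) {
  r <- object$results |>
    dplyr::mutate(category = factor(.data$category, levels = rev(.data$category))) |>
    tidyr::pivot_longer(c("percent_agreement", "kappa"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      percent_agreement = "% agreement", kappa = "kappa"))
  cuts <- tibble::tibble(metric = "kappa", at = c(0.2, 0.4, 0.6, 0.8))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$value, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(data = cuts, ggplot2::aes(xintercept = .data$at),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(
      title = paste0("Reliability (", object$design, ")"),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Published reliability scores for the FASTVIEW instrument
#'
#' Per-category percent agreement and kappa from the instrument's original
#' field evaluation in Wigan, UK (three trained auditors; 54 sampled links
#' for the inter-rater design, 20 links on two occasions per auditor for the
#' intra-rater design, and 30 links audited both from desk imagery and
#' on-site for the criterion design). Bundled so that report summaries and
#' interpretation bands can be exercised against published figures; the
#' underlying link-level audit records were never published.
#'
#' @return a tibble with columns `category`, `design` (`inter_rater`,
#'   `intra_rater`, `criterion`), `percent_agreement`, `kappa`.
#' @examples
#' fastview_published_scores() |>
#'   dplyr::filter(design == "criterion") |>
#'   summarize_reliability()
#' @export
fastview_published_scores <- function() {
  readr::read_csv(
    system.file("extdata", "fastview_published_scores.csv", package = "fastview"),
    col_types = readr::cols(
      category = readr::col_character(), design = readr::col_character(),
      percent_agreement = readr::col_double(), kappa = readr::col_double()
    ), progress = FALSE
  )
}
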