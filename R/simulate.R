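#' Symmetric rater confusion matrix
#'
#' A 3x3 row-stochastic matrix over the ratings poor/fair/good: the true
#' rating is reported with probability `accuracy`, and each of the two wrong
#' ratings with probability `(1 - accuracy) / 2`.
#'
#' @param accuracy diagonal probability in (0, 1].
#' @return a 3x3 matrix with dimnames `0:2`.
#' @export
symmetric_confusion <- function(accuracy = 0.9) {
  stopifnot(accuracy > 0, accuracy <= 1)
  off <- (1 - accuracy) / 2
  m <- matrix(off, 3, 3, dimnames = list(0:2, 0:2))
  diag(m) <- accuracy
  m
}

#' Simulation configuration for synthetic audit studies
#'
#' Defines a synthetic multi-rater audit study with known ground truth: every
#' link has a latent true rating per category drawn from `prevalence`, and
#' each audit reports that truth filtered through a rater confusion matrix.
#' Errors are independent across links, categories, raters, occasions and
#' modes, which gives the model a closed-form kappa ([theoretical_kappa()])
#' that the empirical statistics can be checked against.
#'
#' The defaults reproduce the original evaluation's design shapes: three
#' auditors; 54 links rated once by everyone (inter-rater design); 20 links
#' rated twice by each auditor (intra-rater); 30 links rated from desk
#' imagery and on-site (criterion). The default prevalence (0.2, 0.5, 0.3)
#' makes fair the most common street rating; the default confusion has 0.9
#' accuracy for desk audits and 0.95 on-site (on-site auditors are not
#' subject to imagery obstructions).
#'
#' @param n_links number of links in the audit area sample (default 54).
#' @param n_raters number of auditors (default 3).
#' @param n_links_intra links per auditor in the repeat-audit design
#'   (default 20).
#' @param n_links_criterion links audited in both modes (default 30).
#' @param categories character vector of category names (default: the nine
#'   FASTVIEW categories).
#' @param prevalence probability vector over true ratings (poor, fair, good);
#'   either length 3 (shared by all categories) or a `length(categories)` x 3
#'   matrix with one row per category.
#' @param confusion a 3x3 row-stochastic matrix, or a list of one per rater,
#'   used for desk (`streetview`) audits.
#' @param confusion_onsite confusion matrix for on-site audits.
#' @param occasions number of audit occasions for the repeat design
#'   (default 2).
#' @param seed integer RNG seed; every draw derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_links = 54, n_raters = 3, n_links_intra = 20,
                       n_links_criterion = 30, categories = NULL,
                       prevalence = c(0.2, 0.5, 0.3),
                       confusion = symmetric_confusion(0.9),
                       confusion_onsite = symmetric_confusion(0.95),
                       occasions = 2, seed = 1L) {
  if (is.null(categories)) categories <- unique(fastview_schema()$category)
  if (is.matrix(prevalence)) {
    stopifnot(nrow(prevalence) == length(categories), ncol(prevalence) == 3)
  } else {
    stopifnot(length(prevalence) == 3)
    prevalence <- matrix(prevalence, nrow = length(categories), ncol = 3,
                         byrow = TRUE)
  }
  rownames(prevalence) <- categories
  check_distribution(prevalence, "prevalence")
  if (!is.list(confusion)) confusion <- rep(list(confusion), n_raters)
  stopifnot(length(confusion) == n_raters)
  for (m in confusion) check_distribution(m, "confusion")
  check_distribution(confusion_onsite, "confusion_onsite")
  stopifnot(n_links >= 1, n_raters >= 1, occasions >= 1)
  structure(list(
    n_links = as.integer(n_links), n_raters = as.integer(n_raters),
    n_links_intra = as.integer(min(n_links_intra, n_links)),
    n_links_criterion = as.integer(min(n_links_criterion, n_links)),
    categories = categories, prevalence = prevalence,
    confusion = confusion, confusion_onsite = confusion_onsite,
    occasions = as.integer(occasions), seed = as.integer(seed)
  ), class = "sim_config")
}

check_distribution <- function(m, what) {
  m <- rbind(m)
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stop_fv(what, ": rows must be non-negative and sum to 1")
  }
  invisible(m)
}

#' Draw the latent true ratings of a simulated study
#'
#' Independent draws from the per-category prevalence for every link.
#'
#' @param config a [sim_config()].
#' @return a tibble `link_id` x `category` with `true_rating` in 0/1/2;
#'   deterministic given `config$seed`.
#' @export
simulate_truth <- function(config) {
  withr::with_seed(config$seed, {
    links <- sprintf("L%03d", seq_len(config$n_links))
    purrr::map(config$categories, function(cat) {
      tibble::tibble(
        link_id = links, category = cat,
        true_rating = sample(0:2, config$n_links, replace = TRUE,
                             prob = config$prevalence[cat, ])
      )
    }) |> purrr::list_rbind()
  })
}

#' Simulate rater reports from the latent truth
#'
#' For each requested link x rater x occasion x mode cell, draws the
#' reported category rating from the rater's confusion row for the true
#' rating (the on-site confusion matrix is used for `mode = "onsite"`).
#' Reports are emitted directly at category-rating level, the level every
#' agreement statistic consumes.
#'
#' @param truth a [simulate_truth()] tibble (or a subset of its links).
#' @param config a [sim_config()].
#' @param raters rater ids to emit (default all of the config's raters).
#' @param occasions occasions to emit (default 1).
#' @param modes modes to emit (default `"streetview"`).
#' @param seed RNG seed (default `config$seed + 1`, so truth and reports use
#'   distinct streams).
#' @return a long scored tibble: `link_id`, `rater_id`, `occasion`, `mode`,
#'   `category`, `rating`.
#' @export
simulate_ratings <- function(truth, config,
                             raters = paste0("R", seq_len(config$n_raters)),
                             occasions = 1L, modes = "streetview",
                             seed = config$seed + 1L) {
  grid <- tidyr::expand_grid(
    truth, rater_id = raters, occasion = as.integer(occasions), mode = modes
  )
  rater_index <- match(grid$rater_id, paste0("R", seq_len(config$n_raters)))
  withr::with_seed(seed, {
    rating <- vapply(seq_len(nrow(grid)), function(i) {
      cm <- if (grid$mode[i] == "onsite") config$confusion_onsite
            else config$confusion[[rater_index[i]]]
      sample(0:2, 1, prob = cm[grid$true_rating[i] + 1, ])
    }, integer(1))
  })
  grid |>
    dplyr::transmute(.data$link_id, .data$rater_id, .data$occasion, .data$mode,
                     .data$category, rating = rating)
}

#' Theoretical two-rater kappa of the confusion model
#'
#' The exact Cohen-type kappa implied by the simulation model for two raters
#' with confusion matrices `confusion_a` and `confusion_b` and a shared true
#' prevalence, computed by direct enumeration of the 3x3x3 (truth, report A,
#' report B) outcome space: observed agreement is the probability both
#' raters report the same rating; expected agreement comes from the two
#' reported-rating marginals.
#'
#' This is the recovery target for the empirical statistics: at large n the
#' sample kappa of simulated data converges to this value.
#'
#' @param prevalence length-3 probability vector over true ratings.
#' @param confusion_a,confusion_b 3x3 row-stochastic confusion matrices
#'   (`confusion_b` defaults to `confusion_a`).
#' @return kappa, or `NA` (with a warning) when expected agreement is 1.
#' @examples
#' theoretical_kappa(c(1, 1, 1) / 3, symmetric_confusion(0.9))
#' @export
theoretical_kappa <- function(prevalence, confusion_a,
                              confusion_b = confusion_a) {
  check_distribution(rbind(prevalence), "prevalence")
  check_distribution(confusion_a, "confusion_a")
  check_distribution(confusion_b, "confusion_b")
  p_o <- 0
  marg_a <- numeric(3)
  marg_b <- numeric(3)
  for (t in 1:3) {
    for (ra in 1:3) {
      for (rb in 1:3) {
        p <- prevalence[t] * confusion_a[t, ra] * confusion_b[t, rb]
        if (ra == rb) p_o <- p_o + p
        marg_a[ra] <- marg_a[ra] + p
        marg_b[rb] <- marg_b[rb] + p
      }
    }
  }
  p_e <- sum(marg_a * marg_b)
  if (1 - p_e < .Machine$double.eps^0.5) {
    warning("kappa undefined: expected agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Simulate a full three-design audit study
#'
#' Generates one latent truth and the three record sets of a complete
#' reliability study:
#'
#' * `inter` — every rater audits all `n_links` links once from desk imagery
#'   (feeds the inter-rater design; 54 x 3 by default).
#' * `intra` — every rater audits a random subset of `n_links_intra` links on
#'   two occasions (intra-rater; pooled 60 x 2 by default).
#' * `criterion` — `n_links_criterion` links are assigned round-robin to
#'   raters, each audited by its rater in both modes (criterion; 30 x 2 by
#'   default).
#'
#' @param config a [sim_config()].
#' @return a list of class `audit_simulation`: `truth` plus the three long
#'   scored tibbles, and `config`.
#' @export
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  raters <- paste0("R", seq_len(config$n_raters))
  links <- unique(truth$link_id)

  inter <- simulate_ratings(truth, config, raters = raters, occasions = 1L,
                            modes = "streetview", seed = config$seed + 1L)

  intra_links <- withr::with_seed(config$seed + 2L,
                                  sort(sample(links, config$n_links_intra)))
  intra <- simulate_ratings(truth[truth$link_id %in% intra_links, ], config,
                            raters = raters, occasions = seq_len(config$occasions),
                            modes = "streetview", seed = config$seed + 3L)

  crit_links <- withr::with_seed(config$seed + 4L,
                                 sort(sample(links, config$n_links_criterion)))
  crit_truth <- truth[truth$link_id %in% crit_links, ]
  assigned <- stats::setNames(rep(raters, length.out = length(crit_links)),
                              crit_links)
  criterion <- purrr::map(raters, function(r) {
    mine <- names(assigned)[assigned == r]
    if (length(mine) == 0) return(NULL)
    simulate_ratings(crit_truth[crit_truth$link_id %in% mine, ], config,
                     raters = r, occasions = 1L,
                     modes = c("streetview", "onsite"),
                     seed = config$seed + 5L + match(r, raters))
  }) |> purrr::list_rbind()

  structure(list(truth = truth, inter = inter, intra = intra,
                 criterion = criterion, config = config),
            class = "audit_simulation")
}

#' @export
print.audit_simulation <- function(x, ...) {
  cat("<audit_simulation> ", x$config$n_links, " links, ",
      x$config$n_raters, " raters, seed ", x$config$seed, "\n",
      "  inter: ", nrow(x$inter), " reports; intra: ", nrow(x$intra),
      " reports; criterion: ", nrow(x$criterion), " reports\n", sep = "")
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Writes one records CSV per design, the latent truth, and a provenance
#' JSON (configuration, seed, package version) into `dir`.
#'
#' @param study an [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  for (d in c("inter", "intra", "criterion")) {
    readr::write_csv(study[[d]], file.path(dir, paste0(d, "_records.csv")))
  }
  cfg <- study$config
  jsonlite::write_json(list(
    tool = "fastview", version = as.character(utils::packageVersion("fastview")),
    seed = cfg$seed,
    n_links = cfg$n_links, n_raters = cfg$n_raters,
    n_links_intra = cfg$n_links_intra,
    n_links_criterion = cfg$n_links_criterion,
    occasions = cfg$occasions,
    categories = cfg$categories,
    prevalence = cfg$prevalence,
    confusion = cfg$confusion,
    confusion_onsite = cfg$confusion_onsite
  ), file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")
  invisible(dir)
}

#' Simulate factor-level audit records
#'
#' The secondary, factor-level generation path: instead of emitting category
#' ratings directly, it draws a level code for every factor of the
#' instrument consistent with each link's true category rating (all most
#' positive levels for good, all most negative for poor, one intermediate —
#' or a positive/negative mix — for fair), then flips each factor's response
#' to a uniformly random other non-N/A level with probability `flip_prob`.
#' The records validate against the schema and, at `flip_prob = 0`,
#' [score_audits()] recovers the truth exactly; the path exists to exercise
#' the scoring machinery with realistic wide records.
#'
#' @param truth a [simulate_truth()] tibble.
#' @param schema an `instrument_schema`.
#' @param flip_prob per-factor probability of an error (default 0.1).
#' @param rater_id,side,occasion,mode identifier values for the emitted rows.
#' @param seed RNG seed.
#' @return a wide audit-records tibble (see [validate_record()]).
#' @export
simulate_audit_records <- function(truth, schema, flip_prob = 0.1,
                                   rater_id = "R1", side = "A",
                                   occasion = 1L, mode = "streetview",
                                   seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob <= 1)
  sf <- schema_factors(schema)
  links <- unique(truth$link_id)
  wide <- tidyr::pivot_wider(truth, id_cols = "link_id",
                             names_from = "category", values_from = "true_rating")
  # per factor: the codes at each polarity
  by_factor <- split(tibble::as_tibble(schema), field_name(schema$category, schema$factor))

  withr::with_seed(seed, {
    recs <- tibble::tibble(link_id = links, side = side, rater_id = rater_id,
                           occasion = as.integer(occasion), mode = mode)
    for (cat in unique(sf$category)) {
      facs <- sf$factor[sf$category == cat]
      fields <- field_name(cat, facs)
      truth_cat <- wide[[cat]][match(links, wide$link_id)]
      planned <- plan_codes(truth_cat, fields, by_factor)
      for (j in seq_along(fields)) {
        codes <- planned[[j]]
        lv <- by_factor[[fields[j]]]
        usable <- lv$code[lv$polarity != "not_applicable"]
        flip <- stats::runif(length(codes)) < flip_prob
        codes[flip] <- vapply(codes[flip], function(cur) {
          alt <- setdiff(usable, cur)
          if (length(alt) == 0) cur else sample(alt, 1)
        }, character(1))
        recs[[fields[j]]] <- codes
      }
    }
    recs
  })
}

# Choose a level code per factor consistent with the true category rating.
plan_codes <- function(truth_cat, fields, by_factor) {
  pick <- function(field, pol) {
    lv <- by_factor[[field]]
    codes <- lv$code[lv$polarity == pol]
    if (length(codes) == 0) NA_character_ else codes[1]
  }
  pos <- vapply(fields, pick, character(1), pol = "positive")
  neg <- vapply(fields, pick, character(1), pol = "negative")
  mid <- vapply(fields, pick, character(1), pol = "intermediate")
  n <- length(truth_cat)
  planned <- lapply(seq_along(fields), function(j) rep(NA_character_, n))
  has_mid <- which(!is.na(mid))
  for (i in seq_len(n)) {
    codes <- switch(as.character(truth_cat[i]),
      "2" = pos,
      "0" = neg,
      "1" = {
        v <- pos
        if (length(has_mid) > 0) v[has_mid[1]] <- mid[has_mid[1]]
        else v[length(v)] <- neg[length(neg)]
        v
      }
    )
    for (j in seq_along(fields)) planned[[j]][i] <- codes[j]
  }
  planned
}
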