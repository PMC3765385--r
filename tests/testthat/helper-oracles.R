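# Independent oracles, coded directly from the defining formulas and kept
# free of any package internals.

# Cohen's kappa via an explicit contingency table.
oracle_cohen <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  cats <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = cats), factor(b, levels = cats))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Fleiss' kappa: per-item pair agreement P_i, pooled category proportions.
oracle_fleiss <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  r <- ncol(m)
  cats <- sort(unique(c(m)))
  nij <- sapply(cats, function(k) rowSums(m == k))
  nij <- matrix(nij, nrow = n)
  p_j <- colSums(nij) / (n * r)
  P_i <- (rowSums(nij^2) - r) / (r * (r - 1))
  P_e <- sum(p_j^2)
  if (abs(1 - P_e) < 1e-12) return(NA_real_)
  (mean(P_i) - P_e) / (1 - P_e)
}

# Mean pairwise two-column percent agreement by explicit enumeration.
oracle_pairwise_agreement <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  vals <- c()
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      vals <- c(vals, 100 * mean(m[, i] == m[, j]))
    }
  }
  mean(vals)
}

rm_from_cols <- function(...) as_rating_matrix(cbind(...))

# A complete wide audit record choosing, for every factor, the level at a
# fixed position: "first" (most positive) or "last_ordinal" (most negative,
# skipping N/A).
fixture_record <- function(schema, choose = c("first", "last_ordinal"), ...) {
  choose <- match.arg(choose)
  rec <- blank_record(schema, ...)
  tab <- tibble::as_tibble(schema)
  for (key in unique(paste(tab$category, tab$factor, sep = "::"))) {
    lv <- tab[paste(tab$category, tab$factor, sep = "::") == key, ]
    ord <- lv$code[lv$polarity != "not_applicable"]
    rec[[key]] <- if (choose == "first") ord[1] else ord[length(ord)]
  }
  rec
}

# Random polyline of roughly the requested length (random walk in the plane).
random_polyline <- function(target_length, n_seg = 5) {
  ang <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(n_seg, 0, 0.3))
  steps <- stats::runif(n_seg)
  steps <- steps / sum(steps) * target_length
  pts <- rbind(c(0, 0), cbind(cumsum(steps * cos(ang)), cumsum(steps * sin(ang))))
  pts + matrix(stats::runif(2, -500, 500), nrow(pts), 2, byrow = TRUE)
}
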