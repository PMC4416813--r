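#' Endpoint ANOVA with the animal as experimental unit
#'
#' Fits the study's two endpoint models. Gross endpoints (one value per
#' animal) use classical one-way ANOVA. Morphometric endpoints (several
#' tubules per animal) use hierarchical ANOVA: a fixed group effect and a
#' random animal-within-group effect; for balanced data the fixed-effect F
#' is the closed-form `MS_group / MS_animal(group)` with denominator
#' degrees of freedom `N_animals - k`, and for unbalanced data the
#' denominator mean square is the Satterthwaite-weighted combination of the
#' animal and residual mean squares with Satterthwaite degrees of freedom.
#' Group means are means of animal means; group standard errors are on the
#' animal-mean scale.
#'
#' @param table data.frame with columns `animal_id`, `group`, `value`, and
#'   for tubule-level data also `tubule_id` (or simply repeated
#'   `animal_id` rows).
#' @param alpha significance level used downstream for letters (default
#'   0.05).
#' @param kind `"one_way"`, `"nested"`, or `"auto"` (nested when any animal
#'   has more than one value).
#' @return an object of class `tubule_anova`: list with `F`, `num_df`,
#'   `den_df`, `p_value`, `kind`, `alpha`, `groups` (data.frame: `group`,
#'   `n_animals`, `mean`, `se`), and the Tukey inputs (`tukey_ms`,
#'   `tukey_df`). Pass through [tukey_pairwise()] and [letter_display()] to
#'   fill `pairwise` and `letters`.
#' @seealso [one_way_anova()], [nested_anova()], [tukey_pairwise()],
#'   [letter_display()], [summarize_groups()]
#' @export
tubule_anova <- function(table, alpha = 0.05,
                         kind = c("auto", "one_way", "nested")) {
  kind <- match.arg(kind)
  tab <- validate_endpoint_table(table)
  multi <- anyDuplicated(tab$animal_id) > 0L
  if (kind == "auto") kind <- if (multi) "nested" else "one_way"
  if (kind == "one_way" && multi)
    stop("one-way ANOVA needs exactly one value per animal")
  res <- if (kind == "one_way") fit_one_way(tab) else fit_nested(tab)
  res$alpha <- alpha
  res$pairwise <- NULL
  res$letters <- NULL
  class(res) <- "tubule_anova"
  res
}

#' One-way ANOVA for per-animal endpoints
#'
#' Classical between/within decomposition with one observation per animal:
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom and
#' group standard errors `sqrt(MS_within / n_g)`.
#'
#' @inheritParams tubule_anova
#' @return a `tubule_anova` object (see [tubule_anova()]).
#' @export
one_way_anova <- function(table, alpha = 0.05)
  tubule_anova(table, alpha, kind = "one_way")

#' Hierarchical (nested random-effect) ANOVA for per-tubule endpoints
#'
#' @inheritParams tubule_anova
#' @return a `tubule_anova` object (see [tubule_anova()]).
#' @export
nested_anova <- function(table, alpha = 0.05)
  tubule_anova(table, alpha, kind = "nested")

validate_endpoint_table <- function(table) {
  need <- c("animal_id", "group", "value")
  if (!all(need %in% names(table)))
    stop("endpoint table must have columns: ", paste(need, collapse = ", "))
  tab <- data.frame(animal_id = as.character(table$animal_id),
                    group = as.character(table$group),
                    value = as.numeric(table$value),
                    stringsAsFactors = FALSE)
  if (!all(is.finite(tab$value))) stop("endpoint values must be finite")
  gpa <- unique(tab[, c("animal_id", "group")])
  dup <- gpa$animal_id[duplicated(gpa$animal_id)]
  if (length(dup))
    stop("animal(s) appear in more than one group: ",
         paste(unique(dup), collapse = ", "))
  if (length(unique(tab$group)) < 2L) stop("need at least 2 groups")
  tab
}

check_min_animals <- function(tab) {
  gpa <- unique(tab[, c("animal_id", "group")])
  cnt <- table(gpa$group)
  small <- names(cnt)[cnt < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 animals: ",
         paste(small, collapse = ", "))
}

fit_one_way <- function(tab) {
  check_min_animals(tab)
  g <- factor(tab$group, levels = unique(tab$group))
  if (stats::var(tab$value) == 0) {       # no variability at all: F = 0
    n_g <- as.vector(table(g))
    return(list(F = 0, num_df = nlevels(g) - 1L,
                den_df = length(tab$value) - nlevels(g), p_value = 1,
                kind = "one_way",
                groups = data.frame(group = levels(g), n_animals = n_g,
                                    mean = rep(tab$value[1], nlevels(g)),
                                    se = rep(0, nlevels(g)),
                                    stringsAsFactors = FALSE),
                tukey_ms = 0, tukey_df = length(tab$value) - nlevels(g)))
  }
  fit <- stats::lm(value ~ g, data = tab)
  av <- stats::anova(fit)
  ms_within <- av$`Mean Sq`[2]
  n_g <- as.vector(table(g))
  groups <- data.frame(group = levels(g), n_animals = n_g,
                       mean = as.vector(tapply(tab$value, g, mean)),
                       se = sqrt(ms_within / n_g),
                       stringsAsFactors = FALSE)
  Fv <- av$`F value`[1]
  if (!is.finite(Fv) && av$`Sum Sq`[1] == 0) Fv <- 0  # all values identical
  list(F = Fv, num_df = av$Df[1], den_df = av$Df[2],
       p_value = stats::pf(Fv, av$Df[1], av$Df[2], lower.tail = FALSE),
       kind = "one_way", groups = groups,
       tukey_ms = ms_within, tukey_df = av$Df[2])
}

# Unbalanced nested sums of squares (Searle) with Satterthwaite-combined
# denominator; reduces exactly to MS_group / MS_animal(group) on
# (k - 1, N_animals - k) when the expected-mean-square coefficients agree.
fit_nested <- function(tab) {
  check_min_animals(tab)
  g <- factor(tab$group, levels = unique(tab$group))
  a <- factor(tab$animal_id, levels = unique(tab$animal_id))
  y <- tab$value
  N <- length(y)
  n_ij <- as.vector(table(a))                      # per animal
  ag <- tab$group[match(levels(a), tab$animal_id)] # group of each animal
  k <- nlevels(g)
  Na <- nlevels(a)

  ybar <- mean(y)
  zbar <- as.vector(tapply(y, a, mean))            # animal means
  n_i <- sapply(levels(g), function(gg) sum(n_ij[ag == gg]))
  ybar_i <- sapply(levels(g), function(gg)
    sum(y[tab$group == gg]) / n_i[[gg]])

  ss_a <- sum(n_i * (ybar_i - ybar)^2);            df_a <- k - 1L
  ss_b <- sum(n_ij * (zbar - ybar_i[ag])^2);       df_b <- Na - k
  ss_e <- sum((y - zbar[match(tab$animal_id, levels(a))])^2)
  df_e <- N - Na

  ms_a <- ss_a / df_a
  ms_b <- ss_b / df_b
  s2_over_n <- sapply(levels(g), function(gg) sum(n_ij[ag == gg]^2))
  c1 <- (N - sum(s2_over_n / n_i)) / df_b
  c2 <- (sum(s2_over_n / n_i) - sum(n_ij^2) / N) / df_a

  if (abs(c1 - c2) < 1e-9 * max(c1, c2)) {         # balanced layout
    ms_den <- ms_b
    den_df <- df_b
  } else {
    ms_e <- ss_e / df_e
    r <- c2 / c1
    ms_den <- r * ms_b + (1 - r) * ms_e
    den_df <- ms_den^2 / ((r * ms_b)^2 / df_b + ((1 - r) * ms_e)^2 / df_e)
  }
  Fv <- if (ms_den == 0) {
    if (ms_a == 0) 0 else Inf
  } else ms_a / ms_den

  # group means as means of animal means; SEs on the animal-mean scale
  b_i <- sapply(levels(g), function(gg) sum(ag == gg))
  gmean <- sapply(levels(g), function(gg) mean(zbar[ag == gg]))
  ms_wz <- sum((zbar - gmean[ag])^2) / df_b
  groups <- data.frame(group = levels(g), n_animals = as.vector(b_i),
                       mean = as.vector(gmean),
                       se = sqrt(ms_wz / b_i),
                       stringsAsFactors = FALSE)
  list(F = Fv, num_df = df_a, den_df = den_df,
       p_value = stats::pf(Fv, df_a, den_df, lower.tail = FALSE),
       kind = "nested", groups = groups,
       tukey_ms = ms_wz, tukey_df = den_df)
}

#' Tukey-adjusted pairwise comparisons
#'
#' Fills the pairwise comparison matrices of a fitted [tubule_anova()]
#' using the studentized-range distribution on the model's denominator
#' degrees of freedom (Tukey-Kramer standard error for unequal group
#' sizes). For nested models the comparison operates on the animal-mean
#' scale, the animal being the experimental unit.
#'
#' @param result a `tubule_anova` object.
#' @return the object with `pairwise` set: list with symmetric matrices
#'   `p_adj` (Tukey-adjusted) and `p_unadj` (two-sided t).
#' @export
tukey_pairwise <- function(result) {
  stopifnot(inherits(result, "tubule_anova"))
  gr <- result$groups
  k <- nrow(gr)
  p_adj <- p_un <- matrix(NA_real_, k, k, dimnames = list(gr$group, gr$group))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se2 <- result$tukey_ms * (1 / gr$n_animals[i] + 1 / gr$n_animals[j]) / 2
    diff <- abs(gr$mean[i] - gr$mean[j])
    if (se2 == 0) {
      q <- if (diff == 0) 0 else Inf
    } else q <- diff / sqrt(se2)
    p_adj[i, j] <- p_adj[j, i] <-
      stats::ptukey(q, k, result$tukey_df, lower.tail = FALSE)
    p_un[i, j] <- p_un[j, i] <-
      2 * stats::pt(q / sqrt(2), result$tukey_df, lower.tail = FALSE)
  }
  diag(p_adj) <- diag(p_un) <- 1
  result$pairwise <- list(p_adj = p_adj, p_unadj = p_un)
  result
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share a letter if and only
#' if their Tukey-adjusted p-value exceeds `alpha`, using the standard
#' insert-and-absorb algorithm (minimal letter count for the significance
#' pattern).
#'
#' @param result a `tubule_anova` object with `pairwise` filled (see
#'   [tukey_pairwise()]); if absent it is computed first.
#' @param alpha significance level; defaults to the level stored in the
#'   fit.
#' @return the object with `letters` set: named character vector per group.
#' @export
letter_display <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "tubule_anova"))
  if (is.null(result$pairwise)) result <- tukey_pairwise(result)
  p <- result$pairwise$p_adj
  k <- nrow(p)
  # drop a letter column contained in another (keep the first of duplicates)
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (v in seq_along(cols)) {
      if (!any(cols[[v]])) { keep[v] <- FALSE; next }
      for (u in seq_along(cols)) {
        if (u == v || !keep[u]) next
        v_in_u <- all(!cols[[v]] | cols[[u]])
        if (v_in_u && (!identical(cols[[u]], cols[[v]]) || u < v)) {
          keep[v] <- FALSE
          break
        }
      }
    }
    cols[keep]
  }
  cols <- list(rep(TRUE, k))                     # start: one letter for all
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (p[i, j] > alpha) next                    # not significant
    repeat {                                     # insert: split columns
      hit <- which(vapply(cols, function(cl) cl[i] && cl[j], logical(1)))
      if (!length(hit)) break
      cl <- cols[[hit[1]]]
      c1 <- cl; c1[i] <- FALSE
      c2 <- cl; c2[j] <- FALSE
      cols <- c(cols[-hit[1]], list(c1), list(c2))
    }
    cols <- absorb(cols)
  }
  ord <- order(vapply(cols, function(cl) which(cl)[1], integer(1)))
  cols <- cols[ord]
  lab <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(i)
    paste0(lab[vapply(cols, `[`, logical(1), i)], collapse = ""),
    character(1))
  names(out) <- rownames(p)
  result$letters <- out
  result
}

#' Group mean and standard error summary
#'
#' Per-group mean and standard error of animal-level values. Tubule-level
#' tables (repeated `animal_id`) are collapsed to animal means first; the
#' standard error is `sd / sqrt(n_animals)`. A group with a single animal
#' gets an `NA` standard error with a warning.
#'
#' @param table data.frame with `animal_id`, `group`, `value`.
#' @return data.frame with `group`, `n_animals`, `mean`, `se`.
#' @export
summarize_groups <- function(table) {
  tab <- validate_endpoint_table(table)
  a <- factor(tab$animal_id, levels = unique(tab$animal_id))
  z <- as.vector(tapply(tab$value, a, mean))
  ag <- tab$group[match(levels(a), tab$animal_id)]
  g <- factor(ag, levels = unique(tab$group))
  n <- as.vector(table(g))
  se <- as.vector(tapply(z, g, stats::sd)) / sqrt(n)
  if (any(n < 2L)) {
    warning("group(s) with a single animal: standard error undefined")
    se[n < 2L] <- NA_real_
  }
  data.frame(group = levels(g), n_animals = n,
             mean = as.vector(tapply(z, g, mean)), se = se,
             stringsAsFactors = FALSE)
}

#' @export
print.tubule_anova <- function(x, ...) {
  cat(sprintf("%s ANOVA: F(%s, %s) = %.4g, p = %.4g\n",
              if (x$kind == "nested") "Hierarchical" else "One-way",
              format(x$num_df), format(round(x$den_df, 2)), x$F, x$p_value))
  invisible(x)
}

#' @export
summary.tubule_anova <- function(object, ...) {
  print(object)
  gr <- object$groups
  if (!is.null(object$letters)) gr$letters <- object$letters[gr$group]
  print(gr, row.names = FALSE)
  if (!is.null(object$pairwise)) {
    cat("Tukey-adjusted pairwise p-values:\n")
    print(round(object$pairwise$p_adj, 4))
  }
  invisible(object)
}
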