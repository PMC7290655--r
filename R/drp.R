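#' Site annotation table for co-regulation analysis
#'
#' Holds a universe of phosphosite identifiers together with, per
#' binding-domain (PPBD) family, the sites predicted to interact with it,
#' and per protein-kinase (PK) family, the sites predicted to be its
#' substrates. A doubly regulated p-site (DRP) for a pair of families is a
#' site present in both subsets.
#'
#' @param universe Character vector of site identifiers (size T).
#' @param ppbd Data frame with columns `site_id`, `family`: binding-domain
#'   predictions.
#' @param pk Data frame with columns `site_id`, `family`: kinase
#'   predictions.
#' @return An object of class `site_annotation`.
#' @export
site_annotation <- function(universe, ppbd, pk) {
  universe <- unique(as.character(universe))
  ppbd <- as_tibble(ppbd)
  pk <- as_tibble(pk)
  for (tbl in list(ppbd, pk)) {
    if (!all(c("site_id", "family") %in% names(tbl))) {
      abort("annotation tables need columns site_id and family.")
    }
  }
  out_of <- setdiff(c(ppbd$site_id, pk$site_id), universe)
  if (length(out_of)) {
    abort(sprintf("%d annotated site(s) are not in the universe (e.g. %s).",
                  length(out_of), out_of[1]))
  }
  structure(
    list(universe = universe,
         ppbd_sets = lapply(split(ppbd$site_id, ppbd$family), unique),
         pk_sets = lapply(split(pk$site_id, pk$family), unique)),
    class = "site_annotation")
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf(
    "<site_annotation> %d sites; %d PPBD families; %d PK families\n",
    length(x$universe), length(x$ppbd_sets), length(x$pk_sets)))
  invisible(x)
}

get_family_set <- function(table, kind, family) {
  sets <- if (kind == "ppbd") table$ppbd_sets else table$pk_sets
  if (!family %in% names(sets)) {
    abort(sprintf("unknown %s family '%s'.", toupper(kind), family))
  }
  sets[[family]]
}

#' Doubly regulated p-sites of a family pair
#'
#' The sites annotated both to binding-domain family `K` and kinase family
#' `L`: the intersection of the two site subsets.
#'
#' @param table A [site_annotation()].
#' @param K Binding-domain family name.
#' @param L Kinase family name.
#' @return Character vector of DRP site identifiers.
#' @export
identify_drps <- function(table, K, L) {
  stopifnot(inherits(table, "site_annotation"))
  intersect(get_family_set(table, "ppbd", K),
            get_family_set(table, "pk", L))
}

#' Permutation test for PPBD-kinase family association
#'
#' Holds the binding-domain predictions fixed and redraws the kinase
#' family's site set uniformly at random from the universe (same size
#' `n_L`) in each of `rounds` rounds, recounting the DRP overlap `x'`. The
#' default empirical p-value is the add-one-smoothed proportion of rounds
#' with `x' >= x`, so it is never exactly zero; `mode = "gaussian"` instead
#' fits a normal distribution to the permuted overlaps and reports its
#' (continuity-corrected) upper tail, with a warning when the null sample
#' is visibly skewed. Under this null the overlap is exactly
#' hypergeometric, which the test suite exploits as an oracle.
#'
#' @inheritParams identify_drps
#' @param rounds Permutation rounds (default 10,000).
#' @param seed Integer seed.
#' @param mode `"empirical"` (default) or `"gaussian"`.
#' @return A one-row tibble: `ppbd_family`, `pk_family`, `x`, `m_k`,
#'   `n_l`, `universe_size`, `null_mean`, `null_sd`, `p_value`, `mode`,
#'   `rounds`.
#' @export
permutation_test <- function(table, K, L, rounds = 10000, seed = 1L,
                             mode = c("empirical", "gaussian")) {
  mode <- match.arg(mode)
  stopifnot(rounds >= 1)
  ppbd_set <- get_family_set(table, "ppbd", K)
  pk_set <- get_family_set(table, "pk", L)
  t_size <- length(table$universe)
  n_l <- length(pk_set)
  if (n_l > t_size) abort("kinase set larger than the universe.")
  x <- length(intersect(ppbd_set, pk_set))
  member <- table$universe %in% ppbd_set
  xp <- integer(rounds)
  withr::with_seed(seed, {
    for (r in seq_len(rounds)) {
      xp[r] <- sum(member[sample.int(t_size, n_l)])
    }
  })
  mu <- mean(xp)
  sdev <- sd(xp)
  p <- if (mode == "empirical") {
    (sum(xp >= x) + 1) / (rounds + 1)
  } else {
    skew <- mean((xp - mu)^3) / sdev^3
    if (!is.finite(skew) || abs(skew) >= 0.5) {
      warn("permutation null looks non-normal; prefer the empirical p-value.")
    }
    pnorm(x - 0.5, mean = mu, sd = sdev, lower.tail = FALSE)
  }
  tibble(ppbd_family = K, pk_family = L, x = x,
         m_k = length(ppbd_set), n_l = n_l, universe_size = t_size,
         null_mean = mu, null_sd = sdev, p_value = p, mode = mode,
         rounds = as.integer(rounds))
}

#' Association scan over all PPBD x PK family pairs
#'
#' Runs [permutation_test()] for every pair of annotated families and
#' controls the family-wise error rate across the grid (Bonferroni by
#' default). Set `adjust = "none"` and filter on `p_value` to use a raw
#' cutoff.
#'
#' @inheritParams permutation_test
#' @param adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return A tibble with one row per family pair, including `p_adjusted`.
#' @export
associate_families <- function(table, rounds = 10000, seed = 1L,
                               mode = c("empirical", "gaussian"),
                               adjust = "bonferroni") {
  mode <- match.arg(mode)
  grid <- expand.grid(K = names(table$ppbd_sets),
                      L = names(table$pk_sets),
                      stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(grid, function(K, L) {
    permutation_test(table, K, L, rounds = rounds,
                     seed = seed + match(K, names(table$ppbd_sets)) * 1000L +
                       match(L, names(table$pk_sets)),
                     mode = mode)
  })
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  arrange(out, .data$p_value)
}

#' Hypergeometric enrichment of annotation terms
#'
#' For each term, the upper-tail hypergeometric probability of seeing at
#' least the observed overlap between the foreground set and the term's
#' annotated set, given the background totals, plus the fold enrichment
#' (foreground fraction over background fraction).
#'
#' @param foreground Character vector, a subset of `background`.
#' @param background Character vector of all eligible identifiers.
#' @param annotations Data frame with columns `term`, `id`.
#' @param alpha Report only terms with `p_value < alpha` (default 0.05;
#'   use `alpha = 1` to keep everything).
#' @return A tibble: `term`, `overlap`, `term_size`, `foreground_size`,
#'   `background_size`, `fold_enrichment`, `p_value`, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(foreground, background, annotations,
                                      alpha = 0.05) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (length(foreground) == 0L) abort("foreground set is empty.")
  if (length(setdiff(foreground, background))) {
    abort("foreground must be a subset of the background.")
  }
  annotations <- as_tibble(annotations)
  stopifnot(all(c("term", "id") %in% names(annotations)))
  annotations <- filter(annotations, .data$id %in% background)
  n_bg <- length(background)
  n_fg <- length(foreground)
  out <- annotations |>
    group_by(.data$term) |>
    summarise(
      term_size = dplyr::n_distinct(.data$id),
      overlap = dplyr::n_distinct(intersect(.data$id, foreground)),
      .groups = "drop") |>
    mutate(
      foreground_size = n_fg,
      background_size = n_bg,
      fold_enrichment = (.data$overlap / n_fg) / (.data$term_size / n_bg),
      p_value = phyper(.data$overlap - 1, .data$term_size,
                       n_bg - .data$term_size, n_fg, lower.tail = FALSE)
    ) |>
    arrange(.data$p_value)
  filter(out, .data$p_value < alpha)
}
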