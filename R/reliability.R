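## Sorensen-Dice overlap, Spearman-Brown correction, split-half reliability.

#' Sorensen (Dice) overlap of two maps
#'
#' Binary mode: `2C / (A + B)` with `A`, `B` the set sizes and `C` the
#' intersection. Fuzzy mode: `2 sum min(a, b) / (sum a + sum b)` for maps
#' with values in `[0, 1]`; this reduces exactly to the binary index on
#' 0/1 maps. Two empty maps are defined to overlap fully (1, with a
#' warning), as agreement on absence.
#'
#' @param a,b Arrays on a shared grid.
#' @param mode `"binary"` or `"fuzzy"`.
#' @return Overlap in `[0, 1]`.
#' @export
sorensen <- function(a, b, mode = c("binary", "fuzzy")) {
  mode <- match.arg(mode)
  stop_if_not(identical(dim(a), dim(b)) && length(a) == length(b),
              "maps on different grids", class = "fcparcel_grid_error")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (mode == "binary") {
    stop_if_not(all(av %in% c(0, 1)) && all(bv %in% c(0, 1)),
                "binary mode requires 0/1 maps",
                class = "fcparcel_value_error")
    A <- sum(av); B <- sum(bv); C <- sum(av * bv)
  } else {
    stop_if_not(all(av >= 0 & av <= 1) && all(bv >= 0 & bv <= 1),
                "fuzzy mode requires values in [0, 1]",
                class = "fcparcel_value_error")
    A <- sum(av); B <- sum(bv); C <- sum(pmin(av, bv))
  }
  if (A + B == 0) {
    warning("both maps empty; overlap defined as 1")
    return(1)
  }
  2 * C / (A + B)
}

#' Spearman-Brown reliability correction
#'
#' Projects a split-half similarity to full-sample reliability:
#' `r_sb = 2 r_h / (1 + r_h)`.
#'
#' @param r_h Split-half overlap in `[0, 1]`.
#' @return Corrected coefficient in `[0, 1]`.
#' @export
spearman_brown <- function(r_h) {
  stop_if_not(all(r_h >= 0 & r_h <= 1), "r_h must be in [0, 1]",
              class = "fcparcel_value_error")
  2 * r_h / (1 + r_h)
}

#' Split-half reliability of group maps
#'
#' Repeatedly halves the cohort at random, builds the group map for each
#' half with `map_builder`, measures their Sorensen overlap `r_h`, and
#' applies the Spearman-Brown correction. With several named map sets (e.g.
#' one per seed), every set is evaluated on the same splits.
#'
#' @param map_sets Either a list of per-subject maps, or a named list of
#'   such lists (one per map id).
#' @param map_builder Function taking a list of per-subject maps and
#'   returning one group map. For fuzzy mode its output must lie in
#'   `[0, 1]` (e.g. [probability_map()] output divided by 100).
#' @param n_splits Number of random splits (default 100).
#' @param seed Integer seed for the split draws.
#' @param mode Overlap mode passed to [sorensen()] (default `"fuzzy"`).
#' @return A `reliability_report` data frame (map_id, split, r_h, r_sb)
#'   with a `summary` attribute (mean and range of r_sb).
#' @export
split_half <- function(map_sets, map_builder, n_splits = 100, seed = 7L,
                       mode = "fuzzy") {
  if (!is.list(map_sets[[1]]) || is.array(map_sets[[1]]))
    map_sets <- list(map = map_sets)
  n <- length(map_sets[[1]])
  for (ms in map_sets)
    stop_if_not(length(ms) == n, "map sets have different subject counts",
                class = "fcparcel_value_error")
  stop_if_not(n >= 4, "need at least 4 subjects", class = "fcparcel_value_error")
  stop_if_not(n %% 2 == 0,
              "subject count must be even; drop one subject first",
              class = "fcparcel_value_error")
  ids <- names(map_sets)
  if (is.null(ids)) ids <- paste0("map", seq_along(map_sets))
  halves <- with_seed(seed, lapply(seq_len(n_splits), function(s)
    sample.int(n, n / 2)))
  rows <- list()
  for (s in seq_len(n_splits)) {
    h1 <- halves[[s]]; h2 <- setdiff(seq_len(n), h1)
    for (k in seq_along(map_sets)) {
      m1 <- map_builder(map_sets[[k]][h1])
      m2 <- map_builder(map_sets[[k]][h2])
      r_h <- sorensen(m1, m2, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        map_id = ids[k], split = s, r_h = r_h,
        r_sb = spearman_brown(r_h), stringsAsFactors = FALSE)
    }
  }
  rep_df <- do.call(rbind, rows)
  attr(rep_df, "summary") <- list(mean_r_sb = mean(rep_df$r_sb),
                                  range_r_sb = range(rep_df$r_sb),
                                  n_splits = n_splits, seed = seed,
                                  mode = mode)
  class(rep_df) <- c("reliability_report", "data.frame")
  rep_df
}
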