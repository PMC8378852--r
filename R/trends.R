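# Corpus-level statistics: reactions per year, bootstrap median-yield time
# series, yield histograms with a multiples-of-ten spike index, cumulative
# reagent coverage, Zipf frequency-rank fits and class share time series.

#' Newly added reactions per year
#'
#' Counts per publication year over the kept records (after keep-earliest
#' deduplication these are novel entries). Years inside the observed span
#' with no records report 0.
#'
#' @param records record tibble.
#' @param split_by_doc_type split counts into patent/nonpatent.
#' @return tibble `year`, (`doc_type`), `n`.
#' @export
reactions_per_year <- function(records, split_by_doc_type = FALSE) {
  kk <- kept(records)
  span <- seq(min(kk$pub_year), max(kk$pub_year))
  if (split_by_doc_type) {
    kk |>
      dplyr::count(year = .data$pub_year, .data$doc_type) |>
      tidyr::complete(year = span, doc_type = c("patent", "nonpatent"),
                      fill = list(n = 0L))
  } else {
    kk |>
      dplyr::count(year = .data$pub_year) |>
      tidyr::complete(year = span, fill = list(n = 0L))
  }
}

#' Percentile-bootstrap confidence interval for a median
#'
#' @param x numeric values (NAs dropped).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed (resampling is fully seeded).
#' @return list with `statistic`, `lower`, `upper`, `level`, `n_boot`,
#'   `seed`, `n`.
#' @export
boot_median_ci <- function(x, level = 0.95, n_boot = 2000, seed = 1L) {
  x <- x[!is.na(x)]
  n <- length(x)
  med <- stats::median(x)
  if (n < 2) {
    return(list(statistic = med, lower = NA_real_, upper = NA_real_,
                level = level, n_boot = n_boot, seed = seed, n = n))
  }
  meds <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(matrix(x[idx], nrow = n), 2, stats::median)
  })
  a <- (1 - level) / 2
  qs <- unname(stats::quantile(meds, c(a, 1 - a), type = 7))
  list(statistic = med, lower = qs[1], upper = qs[2], level = level,
       n_boot = n_boot, seed = seed, n = n)
}

#' Median yield over time with bootstrap confidence bands
#'
#' Per window (consecutive years) and document type: the median reported
#' yield with a seeded percentile-bootstrap confidence interval. Windows
#' with fewer than two yields report the median only.
#'
#' @param records record tibble.
#' @param window window width in years (default 1).
#' @param level confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param split_by_doc_type split patent/nonpatent (default TRUE).
#' @return tibble `window_start`, (`doc_type`), `n`, `median_yield`,
#'   `lower`, `upper`.
#' @export
median_yield_timeseries <- function(records, window = 1, level = 0.95,
                                    n_boot = 2000, seed = 1L,
                                    split_by_doc_type = TRUE) {
  kk <- kept(records)
  kk <- kk[!is.na(kk$yield_percent), ]
  kk$window_start <- (kk$pub_year %/% window) * window
  grp_cols <- if (split_by_doc_type) c("window_start", "doc_type") else
    "window_start"
  groups <- split(seq_len(nrow(kk)),
                  lapply(grp_cols, function(g) kk[[g]]), drop = TRUE)
  rows <- lapply(seq_along(groups), function(gi) {
    ix <- groups[[gi]]
    ci <- boot_median_ci(kk$yield_percent[ix], level = level,
                         n_boot = n_boot, seed = seed + gi)
    out <- tibble::tibble(window_start = kk$window_start[ix][1],
                          n = length(ix), median_yield = ci$statistic,
                          lower = ci$lower, upper = ci$upper)
    if (split_by_doc_type) out$doc_type <- kk$doc_type[ix][1]
    out
  })
  res <- dplyr::bind_rows(rows)
  dplyr::arrange(res, .data$window_start)
}

#' Yield histogram with a multiples-of-ten spike index
#'
#' Integer-binned histogram of reported yields. The spike index
#' quantifies the round-number reporting artefact: the mean count over the
#' bins 40, 50, ..., 90 divided by the mean count over their immediate
#' neighbour bins (39, 41, 49, 51, ...). A corpus without round-number
#' preference has a spike index near 1.
#'
#' @param records record tibble.
#' @param split_by_doc_type also compute per document type.
#' @return list with `histogram` (tibble `bin`, (`doc_type`), `n`) and
#'   `spike_index` (overall; named vector per doc type when split).
#' @export
yield_histogram <- function(records, split_by_doc_type = FALSE) {
  kk <- kept(records)
  y <- round(kk$yield_percent)
  keep <- !is.na(y)
  y <- y[keep]
  hist_tb <- if (split_by_doc_type) {
    tibble::tibble(bin = y, doc_type = kk$doc_type[keep]) |>
      dplyr::count(.data$bin, .data$doc_type) |>
      tidyr::complete(bin = 0:100, doc_type = c("patent", "nonpatent"),
                      fill = list(n = 0L))
  } else {
    tibble::tibble(bin = y) |>
      dplyr::count(.data$bin) |>
      tidyr::complete(bin = 0:100, fill = list(n = 0L))
  }
  spike_of <- function(yy) {
    counts <- tabulate(yy + 1L, nbins = 101L) # bin b at index b+1
    spikes <- seq(40, 90, 10)
    nbrs <- c(spikes - 1, spikes + 1)
    denom <- mean(counts[nbrs + 1L])
    if (denom == 0) return(NA_real_)
    mean(counts[spikes + 1L]) / denom
  }
  spike <- spike_of(y)
  if (split_by_doc_type) {
    per <- vapply(c("patent", "nonpatent"), function(dt) {
      spike_of(y[kk$doc_type[keep] == dt])
    }, numeric(1))
    spike <- c(overall = spike, per)
  }
  list(histogram = hist_tb, spike_index = spike)
}

#' Cumulative reaction coverage by top reagents
#'
#' Reagents of one kind sorted by usage; the curve value at k is the
#' fraction of records using any of the top k. Records without a resolved
#' reagent of that kind are excluded from the denominator.
#'
#' @param records record tibble with resolved roles.
#' @param reagent_kind `"solvent"`, `"base"` or `"ligand"`.
#' @return tibble `k`, `name`, `n`, `frac`, `cum_frac`.
#' @export
cumulative_coverage <- function(records,
                                reagent_kind = c("solvent", "base", "ligand")) {
  reagent_kind <- match.arg(reagent_kind)
  col <- paste0(reagent_kind, "_name")
  kk <- kept(records)
  v <- kk[[col]]
  v <- v[!is.na(v)]
  tb <- sort(table(v), decreasing = TRUE)
  tibble::tibble(
    k = seq_along(tb), name = names(tb), n = as.integer(tb),
    frac = as.numeric(tb) / length(v),
    cum_frac = cumsum(as.numeric(tb)) / length(v))
}

#' Frequency-rank table of a categorical column
#'
#' @param records record tibble (kept rows used).
#' @param col column name (e.g. `"ligand_name"`).
#' @return tibble `id`, `count`, `rank` (rank 1 = most frequent).
#' @export
frequency_rank_table <- function(records, col = "ligand_name") {
  kk <- kept(records)
  v <- kk[[col]]
  v <- v[!is.na(v)]
  tb <- sort(table(v), decreasing = TRUE)
  tibble::tibble(id = names(tb), count = as.integer(tb),
                 rank = seq_along(tb))
}

#' Zipf frequency-rank fit
#'
#' Least-squares fit of log(count) on log(rank) over items with at least
#' `min_count` occurrences (the low-count tail biases the fit). The Zipf
#' exponent is the negative slope.
#'
#' @param table tibble with `count` and `rank` columns (see
#'   [frequency_rank_table()]), or a plain count vector.
#' @param min_count minimum count for inclusion (default 5).
#' @return list with `exponent`, `r_squared`, `n_used`.
#' @export
zipf_fit <- function(table, min_count = 5) {
  if (is.numeric(table)) {
    cnt <- sort(table, decreasing = TRUE)
    table <- tibble::tibble(count = cnt, rank = seq_along(cnt))
  }
  tb <- table[table$count >= min_count, ]
  if (nrow(tb) < 3) {
    abort("fewer than 3 items above min_count", class = "bhmeta_zipf_error")
  }
  fit <- stats::lm(log(count) ~ log(rank), data = tb)
  y <- log(tb$count)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(exponent = -unname(stats::coef(fit)[2]),
       r_squared = if (sst == 0) 1 else 1 - ssr / sst,
       n_used = nrow(tb))
}

#' Per-year shares of a categorical column
#'
#' @param records record tibble.
#' @param col grouping column (e.g. `"nphile_class"`, `"ligand_name"`).
#' @return tibble `year`, `group`, `n`, `share`; shares sum to 1 within
#'   each year.
#' @export
class_share_timeseries <- function(records, col = "nphile_class") {
  kk <- kept(records)
  kk <- kk[!is.na(kk[[col]]), ]
  kk |>
    dplyr::count(year = .data$pub_year, group = .data[[col]]) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
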